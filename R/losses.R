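#' Balanced focal loss
#'
#' Cost function for the binary (class 0 / class 1) slice classifier. With
#' predicted class-1 probability \eqn{\hat p}, label \eqn{p \in \{0,1\}},
#' \eqn{q = 1-p} and \eqn{\hat q = 1-\hat p}, the per-example loss is
#' \deqn{L = -[\beta\,\hat q^{\gamma} p \log \hat p +
#'            (1-\beta)\,\hat p^{\gamma} q \log \hat q]}
#' and a batch is reduced by the mean. `gamma = 0`, `beta = 0.5` recovers
#' one half of the binary cross-entropy; `gamma > 0` down-weights easy
#' (confidently correct) examples so training focuses on the hard ones,
#' which matters under severe class imbalance. Defaults `beta = 0.25`,
#' `gamma = 2`.
#'
#' @param beta class-balance weight in `[0,1]` on the class-1 term.
#' @param gamma nonnegative focusing exponent.
#' @param eps probability clamp, `p_hat` is clamped to `[eps, 1-eps]`.
#' @return `focal_params()` returns a parameter list of class `focal_params`.
#' @export
focal_params <- function(beta = 0.25, gamma = 2, eps = 1e-7) {
  stopifnot(beta >= 0, beta <= 1, gamma >= 0, eps > 0, eps < 0.5)
  structure(list(beta = beta, gamma = gamma, eps = eps),
            class = "focal_params")
}

#' @rdname focal_params
#' @param p_hat predicted probabilities of class 1, in `[0,1]`.
#' @param label 0/1 ground-truth labels, same length as `p_hat`.
#' @param params a `focal_params` object.
#' @param reduce if `TRUE` (default) return the batch mean, else per-example
#'   losses.
#' @export
focal_loss <- function(p_hat, label, params = focal_params(), reduce = TRUE) {
  if (any(p_hat < 0 | p_hat > 1 | !is.finite(p_hat)))
    stop("p_hat must lie in [0, 1]")
  stopifnot(length(p_hat) == length(label), all(label %in% c(0, 1)))
  ph <- pmin(pmax(p_hat, params$eps), 1 - params$eps)
  qh <- 1 - ph
  l <- -(params$beta * qh^params$gamma * label * log(ph) +
           (1 - params$beta) * ph^params$gamma * (1 - label) * log(qh))
  if (reduce) mean(l) else l
}

#' @rdname focal_params
#' @details `focal_loss_grad()` is the analytic derivative of the
#'   per-example loss with respect to `p_hat` (evaluated at the clamped
#'   probability), used by the network backward pass.
#' @export
focal_loss_grad <- function(p_hat, label, params = focal_params()) {
  stopifnot(length(p_hat) == length(label))
  ph <- pmin(pmax(p_hat, params$eps), 1 - params$eps)
  qh <- 1 - ph
  b <- params$beta; g <- params$gamma
  # d/dph of -(b qh^g p log ph) = b [ g qh^(g-1) log ph - qh^g / ph ]
  d1 <- b * (g * qh^(g - 1) * log(ph) - qh^g / ph)
  # d/dph of -((1-b) ph^g q log qh) = (1-b) [ -g ph^(g-1) log qh + ph^g / qh ]
  d0 <- (1 - b) * (-g * ph^(g - 1) * log(qh) + ph^g / qh)
  label * d1 + (1 - label) * d0
}

#' Training-loss configuration
#'
#' @param type `"focal"` or `"ce"` (plain binary cross-entropy).
#' @param beta,gamma focal parameters, ignored for `"ce"`.
#' @export
loss_config <- function(type = c("focal", "ce"), beta = 0.25, gamma = 2) {
  type <- match.arg(type)
  if (type == "ce") {
    # CE is the gamma = 0, beta = 0.5 member, rescaled to standard CE
    list(type = "ce", params = focal_params(beta = 0.5, gamma = 0), scale = 2)
  } else {
    list(type = "focal", params = focal_params(beta = beta, gamma = gamma),
         scale = 1)
  }
}

loss_value <- function(p_hat, label, loss_cfg) {
  loss_cfg$scale * focal_loss(p_hat, label, loss_cfg$params)
}

loss_grad_phat <- function(p_hat, label, loss_cfg) {
  loss_cfg$scale * focal_loss_grad(p_hat, label, loss_cfg$params)
}
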