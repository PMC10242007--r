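#' Toy unpaired domain mapping (cycle-consistent GAN objective)
#'
#' Harmonizes one site's preprocessed slices toward a chosen target site
#' before federated training, emulating how scanner-induced intensity
#' differences between hospitals are reduced by unpaired image-to-image
#' translation. Two residual 3-layer convolutional generators map
#' source-to-target (`g_ab`) and target-to-source (`g_ba`); two small
#' convolutional discriminators score realness per domain with
#' least-squares GAN losses, plus an L1 cycle-consistency term weighted by
#' `lambda_cyc`.
#'
#' @param lambda_cyc cycle-consistency weight (default 10).
#' @param width generator/discriminator convolution width.
#' @param kernel generator kernel size: 1 (default) for pointwise
#'   residual generators -- an intensity-transfer family that preserves
#'   spatial texture (hence subtype information) by construction and can
#'   express scanner-style gain/gamma curves -- or 3 for full 3x3
#'   convolutions.
#' @param epochs training epochs. @param lr generator SGD learning rate.
#' @param d_lr_mult multiplier on `lr` for the discriminator updates (the
#'   discriminators must track the generators closely for the adversarial
#'   signal to point the right way at toy scale).
#' @param batch_size images per update in each domain.
#' @param target_site optional target-site identifier (bookkeeping).
#' @param seed training seed.
#' @export
mapper_config <- function(lambda_cyc = 10, width = 8, epochs = 40,
                          lr = 0.005, d_lr_mult = 10, batch_size = 16,
                          kernel = 1, target_site = NULL, seed = 1L) {
  stopifnot(lambda_cyc >= 0, width >= 1, epochs >= 0, lr > 0,
            d_lr_mult > 0, batch_size >= 1, kernel %in% c(1, 3))
  structure(list(lambda_cyc = lambda_cyc, width = as.integer(width),
                 epochs = as.integer(epochs), lr = lr,
                 d_lr_mult = d_lr_mult,
                 batch_size = as.integer(batch_size),
                 kernel = as.integer(kernel),
                 target_site = target_site, seed = as.integer(seed)),
            class = "mapper_config")
}

# ---- generator: x + conv3(relu(conv2(relu(conv1(x))))) -------------------
# residual form, last conv initialized at zero so training starts from the
# identity map (shape- and channel-preserving by construction).

.build_generator <- function(width, channels = 2, kernel = 1) {
  w <- width
  if (kernel == 1) {
    param_set(list(
      c1_w = matrix(stats::rnorm(channels * w, sd = sqrt(2 / channels)),
                    w, channels),
      c1_b = numeric(w),
      c2_w = matrix(stats::rnorm(w * w, sd = sqrt(2 / w)), w, w),
      c2_b = numeric(w),
      c3_w = matrix(0, channels, w),
      c3_b = numeric(channels)))
  } else {
    param_set(list(
      c1_w = array(stats::rnorm(9 * channels * w,
                                sd = sqrt(2 / (9 * channels))),
                   c(3, 3, channels, w)),
      c1_b = numeric(w),
      c2_w = array(stats::rnorm(9 * w * w, sd = sqrt(2 / (9 * w))),
                   c(3, 3, w, w)),
      c2_b = numeric(w),
      c3_w = array(0, c(3, 3, w, channels)),
      c3_b = numeric(channels)))
  }
}

.gen_is_pointwise <- function(p) is.matrix(p$c1_w)

# pointwise generators act channel-wise on every pixel: reshape the image
# stack to (C, H*W*N) and run a small residual MLP over the channel axis
.gen_forward <- function(p, x, cache = FALSE) {
  if (!.gen_is_pointwise(p)) {
    z1 <- conv2d(x, p$c1_w, p$c1_b); a1 <- relu(z1)
    z2 <- conv2d(a1, p$c2_w, p$c2_b); a2 <- relu(z2)
    r <- conv2d(a2, p$c3_w, p$c3_b)
    y <- x + r
    return(if (cache) list(y = y, x = x, z1 = z1, a1 = a1, z2 = z2,
                           a2 = a2) else list(y = y))
  }
  d <- dim(x)
  xm <- matrix(aperm(x, c(3, 1, 2, 4)), d[3])
  z1 <- p$c1_w %*% xm + p$c1_b; a1 <- relu(z1)
  z2 <- p$c2_w %*% a1 + p$c2_b; a2 <- relu(z2)
  r <- p$c3_w %*% a2 + p$c3_b
  y <- x + aperm(array(r, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
  if (cache) list(y = y, x = x, xm = xm, z1 = z1, a1 = a1, z2 = z2,
                  a2 = a2) else list(y = y)
}

.gen_backward <- function(p, cache, dy) {
  if (!.gen_is_pointwise(p)) {
    b3 <- conv2d_grad(cache$a2, p$c3_w, dy)
    da2 <- relu_grad(cache$z2, b3$dx)
    b2 <- conv2d_grad(cache$a1, p$c2_w, da2)
    da1 <- relu_grad(cache$z1, b2$dx)
    b1 <- conv2d_grad(cache$x, p$c1_w, da1)
    return(list(grad = param_set(list(c1_w = b1$dw, c1_b = b1$db,
                                      c2_w = b2$dw, c2_b = b2$db,
                                      c3_w = b3$dw, c3_b = b3$db)),
                dx = dy + b1$dx))
  }
  d <- dim(dy)
  dr <- matrix(aperm(dy, c(3, 1, 2, 4)), d[3])
  g3w <- dr %*% t(cache$a2); g3b <- rowSums(dr)
  da2 <- relu_grad(cache$z2, t(p$c3_w) %*% dr)
  g2w <- da2 %*% t(cache$a1); g2b <- rowSums(da2)
  da1 <- relu_grad(cache$z1, t(p$c2_w) %*% da2)
  g1w <- da1 %*% t(cache$xm); g1b <- rowSums(da1)
  dxm <- t(p$c1_w) %*% da1
  dx <- dy + aperm(array(dxm, c(d[3], d[1], d[2], d[4])), c(2, 3, 1, 4))
  list(grad = param_set(list(c1_w = g1w, c1_b = g1b,
                             c2_w = g2w, c2_b = g2b,
                             c3_w = g3w, c3_b = g3b)),
       dx = dx)
}

# ---- discriminator: conv-relu-pool-conv-relu-GAP-linear ------------------

.build_discriminator <- function(width, channels = 2) {
  w <- width
  param_set(list(
    c1_w = array(stats::rnorm(9 * channels * w, sd = sqrt(2 / (9 * channels))),
                 c(3, 3, channels, w)),
    c1_b = numeric(w),
    c2_w = array(stats::rnorm(9 * w * w, sd = sqrt(2 / (9 * w))), c(3, 3, w, w)),
    c2_b = numeric(w),
    lin_w = matrix(stats::rnorm(w, sd = 1 / sqrt(w)), w, 1),
    lin_b = 0))
}

.disc_forward <- function(p, x, cache = FALSE) {
  z1 <- conv2d(x, p$c1_w, p$c1_b); a1 <- relu(z1)
  p1 <- avgpool2(a1)
  z2 <- conv2d(p1, p$c2_w, p$c2_b); a2 <- relu(z2)
  f <- gap(a2)                                   # width x N
  s <- drop(crossprod(p$lin_w, f)) + p$lin_b     # length N
  if (cache) list(s = s, x = x, z1 = z1, a1 = a1, p1 = p1, z2 = z2,
                  a2 = a2, f = f) else list(s = s)
}

.disc_backward <- function(p, cache, ds) {
  N <- length(ds)
  df <- p$lin_w %*% matrix(ds, 1, N)             # width x N
  g_lin_w <- cache$f %*% matrix(ds, N, 1)
  g_lin_b <- sum(ds)
  da2 <- relu_grad(cache$z2, gap_grad(df, dim(cache$a2)))
  b2 <- conv2d_grad(cache$p1, p$c2_w, da2)
  da1 <- relu_grad(cache$z1, avgpool2_grad(b2$dx, dim(cache$a1)))
  b1 <- conv2d_grad(cache$x, p$c1_w, da1)
  list(grad = param_set(list(c1_w = b1$dw, c1_b = b1$db,
                             c2_w = b2$dw, c2_b = b2$db,
                             lin_w = g_lin_w, lin_b = g_lin_b)),
       dx = b1$dx)
}

.as_image_array <- function(x) {
  if (inherits(x, "slice_dataset")) return(x$images)
  if (is.null(dim(x))) x <- array(x, c(1, 1, 1, length(x)))
  x
}

# apply a generator: either a plain function or a generator param_set
.apply_gen <- function(g, x) {
  if (is.function(g)) return(g(x))
  .gen_forward(g, x)$y
}

#' Cycle-consistency loss
#'
#' Mean L1 reconstruction error of the two round trips:
#' `mean |a - g_ba(g_ab(a))|` over the domain-a batch plus
#' `mean |b - g_ab(g_ba(b))|` over the domain-b batch. Generators may be
#' trained generator parameter sets or plain functions (useful for
#' analysis).
#'
#' @param g_ab generator mapping domain a (source) into domain b (target).
#' @param g_ba generator mapping domain b back into domain a.
#' @param batch_a,batch_b image batches (`(H,W,C,N)` arrays,
#'   `slice_dataset`s, or plain numeric vectors treated as 1x1 images).
#' @export
cycle_loss <- function(g_ab, g_ba, batch_a, batch_b) {
  a <- .as_image_array(batch_a); b <- .as_image_array(batch_b)
  if (length(a) == 0 || length(b) == 0) stop("empty batch")
  rec_a <- .apply_gen(g_ba, .apply_gen(g_ab, a))
  rec_b <- .apply_gen(g_ab, .apply_gen(g_ba, b))
  mean(abs(a - rec_a)) + mean(abs(b - rec_b))
}

#' Least-squares GAN losses
#'
#' `discriminator = mean((D(real)-1)^2) + mean(D(fake)^2)` and
#' `generator = mean((D(fake)-1)^2)`.
#'
#' @param D discriminator: parameter set or a plain scoring function.
#' @param real_batch,fake_batch image batches.
#' @return list `discriminator`, `generator`.
#' @export
gan_losses <- function(D, real_batch, fake_batch) {
  score <- function(x) {
    x <- .as_image_array(x)
    if (is.function(D)) D(x) else .disc_forward(D, x)$s
  }
  sr <- score(real_batch); sf <- score(fake_batch)
  list(discriminator = mean((sr - 1)^2) + mean(sf^2),
       generator = mean((sf - 1)^2))
}

#' Full mapping objective
#'
#' The generator-side objective the mapper minimizes: the two adversarial
#' terms (one per mapping direction, least-squares form) plus
#' `lambda_cyc` times the cycle-consistency loss.
#'
#' @param pair a mapper pair from [train_mapper()] (fields `g_ab`, `g_ba`,
#'   `d_a`, `d_b`).
#' @param batch_a,batch_b image batches from the two domains.
#' @param cfg a [mapper_config()] (supplies `lambda_cyc`).
#' @export
total_objective <- function(pair, batch_a, batch_b, cfg = mapper_config()) {
  a <- .as_image_array(batch_a); b <- .as_image_array(batch_b)
  fake_b <- .apply_gen(pair$g_ab, a)
  fake_a <- .apply_gen(pair$g_ba, b)
  gan_losses(pair$d_b, b, fake_b)$generator +
    gan_losses(pair$d_a, a, fake_a)$generator +
    cfg$lambda_cyc * cycle_loss(pair$g_ab, pair$g_ba, a, b)
}

#' Train the domain mapper
#'
#' Alternating least-squares GAN updates: each minibatch first updates the
#' two discriminators on real versus currently generated images, then
#' updates both generators on the adversarial plus cycle objective.
#' Deterministic given `cfg$seed`. Training starts from identity
#' generators (zero-initialized residual branch).
#'
#' @param source,target `slice_dataset`s (or `(H,W,2,N)` arrays) from the
#'   source and target domains.
#' @param cfg a [mapper_config()].
#' @return mapper pair: list `g_ab` (source to target), `g_ba`, `d_a`,
#'   `d_b`, `config`.
#' @export
train_mapper <- function(source, target, cfg = mapper_config()) {
  xa_all <- .as_image_array(source); xb_all <- .as_image_array(target)
  na <- dim(xa_all)[4]; nb <- dim(xb_all)[4]
  if (na < cfg$batch_size || nb < cfg$batch_size)
    stop("each domain needs at least batch_size images")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  ch <- dim(xa_all)[3]
  pair <- list(g_ab = .build_generator(cfg$width, ch, cfg$kernel),
               g_ba = .build_generator(cfg$width, ch, cfg$kernel),
               d_a = .build_discriminator(cfg$width, ch),
               d_b = .build_discriminator(cfg$width, ch),
               config = cfg)
  lam <- cfg$lambda_cyc; lr <- cfg$lr; bs <- cfg$batch_size
  d_lr <- lr * cfg$d_lr_mult
  n_batches <- floor(min(na, nb) / bs)
  for (ep in seq_len(cfg$epochs)) {
    oa <- sample.int(na); ob <- sample.int(nb)
    for (bt in seq_len(n_batches)) {
      ia <- oa[((bt - 1) * bs + 1):(bt * bs)]
      ib <- ob[((bt - 1) * bs + 1):(bt * bs)]
      xa <- xa_all[, , , ia, drop = FALSE]
      xb <- xb_all[, , , ib, drop = FALSE]

      fb <- .gen_forward(pair$g_ab, xa)$y
      fa <- .gen_forward(pair$g_ba, xb)$y

      # discriminator steps (generators held fixed)
      upd_d <- function(d, real, fake) {
        cr <- .disc_forward(d, real, cache = TRUE)
        cf <- .disc_forward(d, fake, cache = TRUE)
        gr <- .disc_backward(d, cr, 2 * (cr$s - 1) / length(cr$s))$grad
        gf <- .disc_backward(d, cf, 2 * cf$s / length(cf$s))$grad
        d - (gr + gf) * d_lr
      }
      pair$d_b <- upd_d(pair$d_b, xb, fb)
      pair$d_a <- upd_d(pair$d_a, xa, fa)

      # generator step: adversarial + cycle, both directions jointly
      gen_dir <- function(g_fwd, g_bwd, d_tgt, x_src) {
        cf <- .gen_forward(g_fwd, x_src, cache = TRUE)
        cd <- .disc_forward(d_tgt, cf$y, cache = TRUE)
        dx_adv <- .disc_backward(d_tgt, cd, 2 * (cd$s - 1) / length(cd$s))$dx
        cb <- .gen_forward(g_bwd, cf$y, cache = TRUE)
        dd <- -sign(x_src - cb$y) * (lam / length(x_src))
        back_b <- .gen_backward(g_bwd, cb, dd)
        back_f <- .gen_backward(g_fwd, cf, dx_adv + back_b$dx)
        list(g_fwd = back_f$grad, g_bwd = back_b$grad)
      }
      d1 <- gen_dir(pair$g_ab, pair$g_ba, pair$d_b, xa)
      d2 <- gen_dir(pair$g_ba, pair$g_ab, pair$d_a, xb)
      pair$g_ab <- pair$g_ab - (d1$g_fwd + d2$g_bwd) * lr
      pair$g_ba <- pair$g_ba - (d1$g_bwd + d2$g_fwd) * lr
    }
  }
  pair
}

#' Map a slice dataset through a trained generator
#'
#' Images are replaced by the generator output clipped to `[0,1]`; labels,
#' patient ids, views, indices and site metadata are untouched.
#'
#' @param gen generator parameter set (e.g. `pair$g_ab`) or a function.
#' @param ds a `slice_dataset`.
#' @export
map_dataset <- function(gen, ds) {
  stopifnot(inherits(ds, "slice_dataset"))
  out <- .apply_gen(gen, ds$images)
  ds$images <- pmin(pmax(out, 0), 1)
  ds
}

#' L1 distance between pixel-intensity histograms of two image sets
#'
#' Both inputs are binned on `[0,1]` with `bins` equal-width bins; the
#' distance is the L1 difference of the normalized histograms (0 for
#' identical distributions, at most 2).
#'
#' @param x,y image arrays or `slice_dataset`s.
#' @param bins number of bins.
#' @export
intensity_hist_distance <- function(x, y, bins = 20) {
  h <- function(v) {
    v <- as.vector(.as_image_array(v))
    tabulate(pmin(pmax(ceiling(v * bins), 1), bins), bins) / length(v)
  }
  sum(abs(h(x) - h(y)))
}
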