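#' Parameter sets
#'
#' A `param_set` is an ordered, named list of numeric arrays holding every
#' trainable parameter of a network (convolution kernels, attention vectors,
#' the bilinear tensor, fully connected weights and biases). It supports the
#' linear algebra that federated aggregation needs: elementwise `+`, `-`,
#' scalar `*` and `/`, inner products and the Euclidean norm, and it
#' round-trips losslessly through serialization.
#'
#' @param x named list of numeric arrays.
#' @return An object of class `param_set`.
#' @export
param_set <- function(x) {
  stopifnot(is.list(x), length(x) > 0, !is.null(names(x)))
  if (!all(vapply(x, is.numeric, logical(1))))
    stop("all parameter entries must be numeric arrays")
  structure(x, class = "param_set")
}

#' @export
Ops.param_set <- function(e1, e2) {
  op <- .Generic
  if (!op %in% c("+", "-", "*", "/"))
    stop("operation '", op, "' is not defined for param_set objects")
  if (missing(e2)) {  # unary +/-
    r <- lapply(unclass(e1), function(a) get(op)(a))
    return(structure(r, class = "param_set"))
  }
  both <- inherits(e1, "param_set") && inherits(e2, "param_set")
  if (both) {
    if (length(e1) != length(e2) || !identical(names(e1), names(e2)))
      stop("param_set shape mismatch: entries differ in number or names")
    r <- mapply(function(a, b) {
      if (!identical(dim(a), dim(b)) || length(a) != length(b))
        stop("param_set shape mismatch in entry arrays")
      get(op)(a, b)
    }, unclass(e1), unclass(e2), SIMPLIFY = FALSE)
  } else if (inherits(e1, "param_set")) {
    stopifnot(is.numeric(e2), length(e2) == 1)
    r <- lapply(unclass(e1), function(a) get(op)(a, e2))
  } else {
    stopifnot(is.numeric(e1), length(e1) == 1)
    r <- lapply(unclass(e2), function(b) get(op)(e1, b))
  }
  structure(r, class = "param_set")
}

#' @rdname param_set
#' @param u,v `param_set` objects with identical structure.
#' @export
ps_dot <- function(u, v) {
  stopifnot(inherits(u, "param_set"), inherits(v, "param_set"),
            length(u) == length(v))
  sum(mapply(function(a, b) sum(a * b), unclass(u), unclass(v)))
}

#' @rdname param_set
#' @export
ps_norm <- function(u) sqrt(ps_dot(u, u))

#' @rdname param_set
#' @export
ps_zero_like <- function(u) {
  stopifnot(inherits(u, "param_set"))
  structure(lapply(unclass(u), function(a) a * 0), class = "param_set")
}

#' Mean of a list of parameter sets
#' @param ps list of `param_set` objects of identical structure.
#' @param weights optional nonnegative weights, normalized internally.
#' @export
ps_mean <- function(ps, weights = NULL) {
  stopifnot(length(ps) >= 1)
  if (is.null(weights)) weights <- rep(1, length(ps))
  stopifnot(length(weights) == length(ps), all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  acc <- ps[[1]] * weights[1]
  if (length(ps) > 1)
    for (i in 2:length(ps)) acc <- acc + ps[[i]] * weights[i]
  acc
}

#' @rdname param_set
#' @export
n_params <- function(u) sum(vapply(unclass(u), length, integer(1)))

#' Save / load a parameter set checkpoint
#'
#' Checkpoints are written as RDS with the parameter arrays and an attached
#' architecture description, readable back into an identical object.
#' @param u `param_set`. @param path file path. @param config optional
#'   architecture description stored alongside the arrays.
#' @export
ps_save <- function(u, path, config = NULL) {
  stopifnot(inherits(u, "param_set"))
  saveRDS(list(params = unclass(u), config = config), path)
  invisible(path)
}

#' @rdname ps_save
#' @export
ps_load <- function(path) {
  obj <- readRDS(path)
  list(params = param_set(obj$params), config = obj$config)
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set> ", length(x), " arrays, ", n_params(x), " parameters\n",
      sep = "")
  invisible(x)
}
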