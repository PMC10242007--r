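#' Two-stream attention-fusion CNN configuration
#'
#' The slice classifier runs one convolutional stream per MRI modality
#' (FLAIR feeds stream 1, T1ce stream 2). Each stream stacks seven 3x3
#' convolutions with ReLU activations and 2x average pooling after layers
#' 2, 4 and 6; the final maps are global-average-pooled into per-stream
#' feature vectors, fused by learned attention weights, passed through a
#' bilinear form, two fully connected layers and a softmax head over the
#' two classes.
#'
#' The `"paper"` preset keeps the published structural facts (seven 3x3
#' conv layers per stream, two streams, the bilinear + 2xFC + softmax
#' head, 128x128 inputs); channel widths and head sizes are configuration
#' since they are not published. The `"tiny"` preset is a desk-scale
#' instance on 32x32 inputs used throughout the test benchmarks.
#'
#' @param preset `"tiny"` or `"paper"`.
#' @param width_multiplier scales every convolution width.
#' @param n_streams number of modality streams (2 for FLAIR + T1ce).
#' @param channel_widths 7 convolution output widths; default depends on
#'   preset.
#' @param pool_after layer indices followed by 2x2 average pooling.
#' @param bilinear_dim number of bilinear-form outputs.
#' @param fc_dims sizes of the two fully connected layers.
#' @param input_size square input side in pixels.
#' @param global_pool how the final convolution maps become the per-stream
#'   feature vector: `"max"` (default; picks the peak response, which
#'   keeps lesion-local texture energy visible after pooling) or `"avg"`.
#' @param seed initialization seed.
#' @return a `model_config` list; `feature_dim` is the per-stream pooled
#'   feature length (the last convolution width).
#' @export
model_config <- function(preset = c("tiny", "paper"),
                         width_multiplier = 1,
                         n_streams = 2,
                         channel_widths = NULL,
                         pool_after = c(2, 4, 6),
                         bilinear_dim = NULL,
                         fc_dims = NULL,
                         input_size = NULL,
                         global_pool = c("max", "avg"),
                         seed = 1L) {
  preset <- match.arg(preset)
  global_pool <- match.arg(global_pool)
  if (is.null(channel_widths))
    channel_widths <- if (preset == "tiny") c(2, 2, 4, 4, 4, 4, 4)
                      else c(8, 8, 16, 16, 32, 32, 32)
  channel_widths <- as.integer(channel_widths * width_multiplier)
  if (is.null(bilinear_dim)) bilinear_dim <- if (preset == "tiny") 4L else 32L
  if (is.null(fc_dims)) fc_dims <- if (preset == "tiny") c(8L, 4L) else c(64L, 32L)
  if (is.null(input_size)) input_size <- if (preset == "tiny") 32L else 128L
  cfg <- list(preset = preset, n_streams = as.integer(n_streams),
              conv_layers = 7L, kernel = 3L,
              channel_widths = channel_widths,
              pool_after = as.integer(pool_after),
              feature_dim = channel_widths[7],
              bilinear_dim = as.integer(bilinear_dim),
              fc_dims = as.integer(fc_dims), n_classes = 2L,
              input_size = as.integer(input_size),
              global_pool = global_pool, seed = as.integer(seed))
  if (length(cfg$channel_widths) != cfg$conv_layers)
    stop("channel_widths must list one width per convolutional layer")
  if (any(c(cfg$channel_widths, cfg$bilinear_dim, cfg$fc_dims,
            cfg$input_size) <= 0))
    stop("all model dimensions must be positive")
  s <- cfg$input_size
  for (l in seq_len(cfg$conv_layers))
    if (l %in% cfg$pool_after) {
      if (s %% 2 != 0) stop("input_size incompatible with pooling schedule")
      s <- s / 2
    }
  class(cfg) <- "model_config"
  cfg
}

#' Build (initialize) the classifier
#'
#' Deterministic He-style initialization given `config$seed`. Both streams
#' have identical structure but independent parameters.
#'
#' @param config a [model_config()].
#' @return list with `config`, `params` (a [param_set()]) and `n_params`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  p <- list()
  for (s in seq_len(config$n_streams)) {
    cin <- 1L
    for (l in seq_len(config$conv_layers)) {
      cout <- config$channel_widths[l]
      sd <- sqrt(2 / (9 * cin))
      p[[sprintf("s%d_conv%d_w", s, l)]] <-
        array(stats::rnorm(9 * cin * cout, sd = sd), c(3, 3, cin, cout))
      # small positive bias keeps narrow streams out of the dead-ReLU regime
      p[[sprintf("s%d_conv%d_b", s, l)]] <- rep(0.05, cout)
      cin <- cout
    }
  }
  fd <- config$feature_dim
  p[["attn_w"]] <- matrix(stats::rnorm(fd * config$n_streams, sd = 1 / sqrt(fd)),
                          fd, config$n_streams)
  K <- config$bilinear_dim
  p[["bil_B"]] <- array(stats::rnorm(fd * fd * K, sd = 1 / fd), c(fd, fd, K))
  p[["bil_b"]] <- numeric(K + 1)
  dims <- c(K + 1, config$fc_dims, config$n_classes)
  for (i in 1:3) {
    p[[sprintf("fc%d_w", i)]] <-
      matrix(stats::rnorm(dims[i] * dims[i + 1], sd = sqrt(2 / dims[i])),
             dims[i], dims[i + 1])
    p[[sprintf("fc%d_b", i)]] <- if (i < 3) rep(0.05, dims[i + 1])
                                 else numeric(dims[i + 1])
  }
  params <- param_set(p)
  list(config = config, params = params, n_params = n_params(params))
}

# RNG bookkeeping so deterministic builders do not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Attention-weighted feature fusion
#'
#' Given per-stream feature vectors \eqn{f_n} and attention parameter
#' vectors \eqn{w_n}, the fusion computes logits \eqn{z_n = w_n^\top f_n},
#' attention weights \eqn{a_n = \exp(z_n) / \sum_m \exp(z_m)} (stabilized
#' by subtracting the maximum logit) and the fused feature
#' \eqn{f = \sum_n a_n f_n}.
#'
#' @param features list of per-stream feature vectors (or matrices with one
#'   column per sample), all the same length.
#' @param attn_w matrix with one column of attention parameters per stream.
#' @return list with `fused` (vector or matrix), `weights` (per-stream
#'   attention, columns sum to 1) and `logits`.
#' @export
attention_fuse <- function(features, attn_w) {
  stopifnot(is.list(features), length(features) >= 1)
  f <- lapply(features, function(x) if (is.matrix(x)) x else matrix(x))
  fd <- nrow(f[[1]])
  if (!all(vapply(f, nrow, integer(1)) == fd))
    stop("all stream features must have the same length")
  attn_w <- as.matrix(attn_w)
  if (nrow(attn_w) != fd || ncol(attn_w) != length(f))
    stop("attention matrix must be feature_dim x n_streams")
  N <- ncol(f[[1]])
  z <- do.call(rbind, lapply(seq_along(f), function(n)
    colSums(f[[n]] * attn_w[, n])))        # n_streams x N
  a <- softmax_cols(z)
  fused <- matrix(0, fd, N)
  for (n in seq_along(f)) fused <- fused + sweep(f[[n]], 2, a[n, ], "*")
  drop1 <- ncol(f[[1]]) == 1 && !is.matrix(features[[1]])
  list(fused = if (drop1) drop(fused) else fused,
       weights = if (drop1) drop(a) else a,
       logits = if (drop1) drop(z) else z)
}

#' Forward pass of the slice classifier
#'
#' @param params `param_set` from [build_model()].
#' @param config the matching `model_config`.
#' @param x input array `(S, S, 2, N)`; channel 1 (FLAIR) feeds stream 1,
#'   channel 2 (T1ce) stream 2.
#' @param cache keep intermediates for [model_backward()].
#' @return list with `probs` (`N x 2` rows summing to 1), `attention`
#'   (`n_streams x N`), and `cache` when requested.
#' @export
model_forward <- function(params, config, x, cache = FALSE) {
  d <- dim(x)
  if (length(d) != 4 || d[3] != config$n_streams)
    stop("input must be (S, S, ", config$n_streams, ", N)")
  N <- d[4]
  streams <- vector("list", config$n_streams)
  feats <- vector("list", config$n_streams)
  for (s in seq_len(config$n_streams)) {
    h <- array(x[, , s, ], c(d[1], d[2], 1, N))
    lay <- list()
    for (l in seq_len(config$conv_layers)) {
      w <- params[[sprintf("s%d_conv%d_w", s, l)]]
      b <- params[[sprintf("s%d_conv%d_b", s, l)]]
      pooled <- l %in% config$pool_after
      blk <- .conv_block_fwd(h, w, b, pooled)
      lay[[l]] <- list(x = h, z = blk$z, pooled = pooled)
      h <- blk$out
    }
    if (identical(config$global_pool, "avg")) {
      feats[[s]] <- gap(h)                    # feature_dim x N
      streams[[s]] <- list(layers = lay, final_dim = dim(h))
    } else {
      gm <- gmp(h)                            # lesion-peak features
      feats[[s]] <- gm$f
      streams[[s]] <- list(layers = lay, final_dim = dim(h), gmp_idx = gm$idx)
    }
  }
  fus <- attention_fuse(feats, params$attn_w)
  f <- fus$fused                              # fd x N
  K <- config$bilinear_dim
  B <- params$bil_B
  fd <- config$feature_dim
  Bm <- matrix(B, fd, fd * K)
  G <- crossprod(Bm, f)                       # (fd*K) x N, stacks B_k^T f
  dim(G) <- c(fd, K, N)
  raw <- matrix(0, K, N)
  for (k in seq_len(K)) raw[k, ] <- colSums(G[, k, , drop = TRUE] *
                                              matrix(f, fd, N)) # f^T B_k f
  # per-sample L2 normalization of the bilinear vector (standard for
  # bilinear feature layers; keeps the head well conditioned regardless of
  # the feature scale and is independent of batch composition), with the
  # log-magnitude appended so the overall feature energy -- which carries
  # the texture signal -- remains visible to the classifier head
  r <- sqrt(colSums(raw^2) + 1e-12)
  biln <- sweep(raw, 2, r, "/")
  bil <- rbind(biln, log(r)) + params$bil_b
  h1z <- dense(bil, params$fc1_w, params$fc1_b); h1 <- relu(h1z)
  h2z <- dense(h1, params$fc2_w, params$fc2_b); h2 <- relu(h2z)
  logits <- dense(h2, params$fc3_w, params$fc3_b)   # 2 x N
  probs <- softmax_cols(logits)
  out <- list(probs = t(probs), attention = fus$weights)
  if (cache)
    out$cache <- list(x = x, streams = streams, feats = feats, fus = fus,
                      f = matrix(f, fd, N), G = G, raw = raw, r = r,
                      biln = biln, bil = bil,
                      h1z = h1z, h1 = h1, h2z = h2z, h2 = h2,
                      logits = logits)
  out
}

#' Backward pass: gradients of a loss w.r.t. every parameter
#'
#' @param params,config as in [model_forward()].
#' @param cache the cache from `model_forward(..., cache = TRUE)`.
#' @param dlogits upstream gradient on the class logits (`2 x N`).
#' @return `param_set` of gradients, same structure as `params`.
#' @export
model_backward <- function(params, config, cache, dlogits) {
  g <- list()
  d3 <- dense_grad(cache$h2, params$fc3_w, dlogits)
  g$fc3_w <- d3$dw; g$fc3_b <- d3$db
  dh2 <- relu_grad(cache$h2z, d3$dh)
  d2 <- dense_grad(cache$h1, params$fc2_w, dh2)
  g$fc2_w <- d2$dw; g$fc2_b <- d2$db
  dh1 <- relu_grad(cache$h1z, d2$dh)
  d1 <- dense_grad(cache$bil, params$fc1_w, dh1)
  g$fc1_w <- d1$dw; g$fc1_b <- d1$db
  dbil <- d1$dh                                # (K+1) x N
  g$bil_b <- rowSums(dbil)
  # back through the per-sample L2 normalization + log-magnitude channel
  Kb <- nrow(dbil) - 1
  dz <- dbil[seq_len(Kb), , drop = FALSE]
  dt <- dbil[Kb + 1, ]
  draw <- sweep(dz, 2, cache$r, "/") -
    sweep(cache$biln, 2, colSums(dz * cache$biln) / cache$r, "*") +
    sweep(cache$raw, 2, dt / cache$r^2, "*")

  fd <- config$feature_dim; K <- config$bilinear_dim
  f <- cache$f; N <- ncol(f)
  B <- params$bil_B
  dB <- array(0, dim(B))
  df <- matrix(0, fd, N)
  for (k in seq_len(K)) {
    Bk <- B[, , k]
    ck <- draw[k, ]
    fs <- sweep(f, 2, ck, "*")
    dB[, , k] <- tcrossprod(f, fs)             # sum_n ck f f^T
    df <- df + (Bk + t(Bk)) %*% fs             # ck (Bk + Bk^T) f
  }
  g$bil_B <- dB

  # attention fusion backward
  feats <- cache$feats
  a <- matrix(cache$fus$weights, config$n_streams, N)
  # dL/da_n = df . f_n ; softmax jacobian back to logits z_n
  dda <- do.call(rbind, lapply(seq_len(config$n_streams), function(n)
    colSums(df * feats[[n]])))
  dz <- a * sweep(dda, 2, colSums(a * dda))    # n_streams x N
  g$attn_w <- do.call(cbind, lapply(seq_len(config$n_streams), function(n)
    rowSums(sweep(feats[[n]], 2, dz[n, ], "*"))))

  dfeat <- lapply(seq_len(config$n_streams), function(n)
    sweep(df, 2, a[n, ], "*") +
      sweep(matrix(params$attn_w[, n], fd, N), 2, dz[n, ], "*"))

  for (s in seq_len(config$n_streams)) {
    st <- cache$streams[[s]]
    dh <- if (identical(config$global_pool, "avg"))
      gap_grad(dfeat[[s]], st$final_dim)
    else gmp_grad(dfeat[[s]], st$gmp_idx, st$final_dim)
    for (l in rev(seq_len(config$conv_layers))) {
      lay <- st$layers[[l]]
      w <- params[[sprintf("s%d_conv%d_w", s, l)]]
      bw <- .conv_block_bwd(lay$x, w, lay$z, dh, lay$pooled, l > 1)
      g[[sprintf("s%d_conv%d_w", s, l)]] <- bw$dw
      g[[sprintf("s%d_conv%d_b", s, l)]] <- bw$db
      if (l > 1) dh <- bw$dx
    }
  }
  param_set(g[names(params)])
}

#' Loss and gradient of the classifier on a labelled batch
#'
#' Runs the forward pass, evaluates the configured loss on the class-1
#' probabilities and backpropagates the mean loss to every parameter.
#'
#' @param params,config as in [model_forward()].
#' @param x input batch `(S,S,2,N)`. @param y 0/1 labels of length N.
#' @param loss_cfg a [loss_config()].
#' @return list `loss`, `grad` (`param_set`), `probs`.
#' @export
model_loss_grad <- function(params, config, x, y, loss_cfg = loss_config()) {
  fw <- model_forward(params, config, x, cache = TRUE)
  p1 <- fw$probs[, 2]
  N <- length(y)
  loss <- loss_value(p1, y, loss_cfg)
  dp <- loss_grad_phat(p1, y, loss_cfg) / N
  # through the 2-class softmax: dz2 = dp * p1 (1 - p1), dz1 = -dz2
  dz2 <- dp * p1 * (1 - p1)
  dlogits <- rbind(-dz2, dz2)
  grad <- model_backward(params, config, fw$cache, dlogits)
  list(loss = loss, grad = grad, probs = fw$probs)
}

#' Closed-form parameter count of a configuration
#' @param config a `model_config`.
#' @export
count_params <- function(config) {
  n <- 0
  for (s in seq_len(config$n_streams)) {
    cin <- 1
    for (l in seq_len(config$conv_layers)) {
      cout <- config$channel_widths[l]
      n <- n + 9 * cin * cout + cout
      cin <- cout
    }
  }
  fd <- config$feature_dim; K <- config$bilinear_dim
  n <- n + fd * config$n_streams                 # attention
  n <- n + fd * fd * K + K + 1                   # bilinear + bias (+ log-norm)
  dims <- c(K + 1, config$fc_dims, config$n_classes)
  for (i in 1:3) n <- n + dims[i] * dims[i + 1] + dims[i + 1]
  n
}
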