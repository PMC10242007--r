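#' Federated training configuration
#'
#' Defaults follow the study setup: `rounds = 50` communication rounds,
#' `K = 5` local epochs, batch size 50, local learning rate 0.01,
#' dynamic-regularization strength `alpha = 0.01`, weight decay 0.001, no
#' learning-rate decay across rounds, full client participation.
#'
#' @param rounds communication rounds T.
#' @param K local epochs per round.
#' @param batch_size minibatch size.
#' @param eta local learning rate.
#' @param alpha dynamic regularization strength (EtFedDyn only).
#' @param weight_decay additive L2 gradient coefficient.
#' @param momentum heavy-ball momentum on the local update direction
#'   (0 = plain SGD, the printed update rule; benchmark presets use 0.9).
#'   Each client's momentum buffer persists across communication rounds.
#' @param algorithm `"etfeddyn"` or `"fedavg"`.
#' @param loss a [loss_config()].
#' @param seed master seed; per-round per-client seeds are derived from it.
#' @param h_scale server accumulator factor; see [server_update_etfeddyn()].
#' @param eq4_as_printed audit flag: use the sign convention of the printed
#'   local-gradient recursion, which ascends the loss when `alpha = 0`
#'   (see the methods vignette); default `FALSE` uses the
#'   descent-consistent dynamic-regularizer form.
#' @param augment apply online flip/rotation augmentation during local
#'   training.
#' @export
fl_config <- function(rounds = 50, K = 5, batch_size = 50, eta = 0.01,
                      alpha = 0.01, weight_decay = 0.001, momentum = 0,
                      algorithm = c("etfeddyn", "fedavg"),
                      loss = loss_config(), seed = 1L,
                      eq4_as_printed = FALSE, h_scale = 1, augment = FALSE) {
  algorithm <- match.arg(algorithm)
  stopifnot(rounds >= 0, K >= 0, batch_size >= 1, eta >= 0, alpha >= 0,
            weight_decay >= 0)
  structure(list(rounds = as.integer(rounds), K = as.integer(K),
                 batch_size = as.integer(batch_size), eta = eta,
                 alpha = alpha, weight_decay = weight_decay,
                 momentum = momentum,
                 algorithm = algorithm, loss = loss, seed = as.integer(seed),
                 eq4_as_printed = eq4_as_printed, h_scale = h_scale,
                 augment = augment),
            class = "fl_config")
}

#' Central (pooled) training configuration
#'
#' The conventional central-learning baseline: all sites' slices pooled.
#' Defaults follow the study setup (batch 50, weight decay 1e-4, learning
#' rate 1e-3, 50 iterations, each iteration one epoch over the pool).
#' @inheritParams fl_config
#' @param learning_rate SGD step size.
#' @param iterations training epochs over the pooled data.
#' @export
cl_config <- function(batch_size = 50, weight_decay = 1e-4,
                      learning_rate = 1e-3, iterations = 50, momentum = 0,
                      loss = loss_config(), seed = 1L, augment = FALSE) {
  stopifnot(batch_size >= 1, weight_decay >= 0, learning_rate > 0,
            iterations >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, learning_rate = learning_rate,
                 iterations = as.integer(iterations), momentum = momentum,
                 loss = loss,
                 seed = as.integer(seed), augment = augment),
            class = "cl_config")
}

#' Deterministic seed derivation for round/client RNG streams
#'
#' Every source of randomness in a federated run is seeded from the config
#' seed through this map, which makes results independent of client
#' execution order and reproducible end to end.
#' @param base master seed. @param round round index. @param client client
#'   index.
#' @export
derive_seed <- function(base, round, client = 1L) {
  as.integer((as.numeric(base) %% 2147483647 + 104729 * round +
                7919 * client) %% 2147483562) + 1L
}

#' Objective wrapper for the two-stream CNN
#'
#' Adapts the classifier to the trainer interface used by the federated
#' and central optimizers: `init(seed)`, `loss_grad(params, data, idx)`,
#' `predict(params, data)`, `n_obs(data)`. `data` is a [slice_dataset()].
#'
#' @param config a [model_config()].
#' @param loss_cfg a [loss_config()].
#' @param augment apply online augmentation to training minibatches.
#' @export
cnn_objective <- function(config, loss_cfg = loss_config(), augment = FALSE) {
  list(
    init = function(seed) {
      cfg <- config; cfg$seed <- as.integer(seed)
      build_model(cfg)$params
    },
    config = config,
    loss_grad = function(params, data, idx) {
      x <- data$images[, , , idx, drop = FALSE]
      if (augment)
        for (i in seq_along(idx)) x[, , , i] <- augment(x[, , , i])
      model_loss_grad(params, config, x, data$labels[idx], loss_cfg)
    },
    predict = function(params, data)
      model_forward(params, config, data$images)$probs,
    n_obs = function(data) length(data$labels)
  )
}

# one or more epochs of minibatch SGD; caller controls the RNG seed.
.sgd_epochs <- function(w, objective, data, epochs, lr, wd, batch_size,
                        extra_grad = NULL, grad_sign = 1, momentum = 0,
                        velocity = NULL) {
  n <- objective$n_obs(data)
  if (n < 1) stop("empty training dataset")
  losses <- numeric(0)
  v <- if (is.null(velocity)) ps_zero_like(w) else velocity
  for (k in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      lg <- objective$loss_grad(w, data, idx)
      g <- lg$grad * grad_sign
      if (wd > 0) g <- g + w * wd
      # momentum smooths the stochastic gradient only; the deterministic
      # dynamic-regularizer correction enters the step directly
      v <- if (momentum > 0) v * momentum + g else g
      step <- if (is.null(extra_grad)) v else v + extra_grad(w)
      w <- w - step * lr
      losses <- c(losses, lg$loss)
    }
  }
  list(w = w, v = v, mean_loss = if (length(losses)) mean(losses) else NA_real_)
}

#' Client state
#'
#' @param client_id identifier. @param train training data (for the CNN
#'   objective, a `slice_dataset`). @param test optional held-out data.
#' @param index integer position in the federation (used for seed
#'   derivation).
#' @export
client_state <- function(client_id, train, test = NULL, index = 1L) {
  structure(list(client_id = client_id, train = train, test = test,
                 index = as.integer(index), w_i = NULL, c_i = NULL,
                 v_i = NULL),
            class = "client_state")
}

#' EtFedDyn local update
#'
#' Starting from the broadcast central weights, runs `K` local epochs of
#' minibatch SGD on the client's loss with the dynamically regularized
#' update direction
#' `g = grad(L) + weight_decay * w - c_i + alpha * (w - w_c)`,
#' then refreshes the client's gradient-correction state
#' `c_i <- c_i - alpha * (w_i - w_c)`.
#'
#' @param client a [client_state()]; `c_i` is initialized to zeros on
#'   first use.
#' @param w_c central weights broadcast this round.
#' @param cfg an [fl_config()].
#' @param objective trainer objective (e.g. [cnn_objective()]).
#' @param round communication round index (drives the RNG stream).
#' @return the updated `client_state` (fields `w_i`, `c_i`).
#' @export
local_update_etfeddyn <- function(client, w_c, cfg, objective, round = 1L) {
  if (is.null(client$c_i)) client$c_i <- ps_zero_like(w_c)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, round, client$index))
  c_i <- client$c_i; alpha <- cfg$alpha
  extra <- function(w) (w - w_c) * alpha - c_i
  fit <- .sgd_epochs(w_c, objective, client$train, cfg$K, cfg$eta,
                     cfg$weight_decay, cfg$batch_size, extra_grad = extra,
                     grad_sign = if (isTRUE(cfg$eq4_as_printed)) -1 else 1,
                     momentum = cfg$momentum, velocity = client$v_i)
  client$v_i <- fit$v
  client$w_i <- fit$w
  client$c_i <- c_i - (fit$w - w_c) * alpha
  client$train_loss <- fit$mean_loss
  client
}

#' FedAvg local update: plain SGD with weight decay from the broadcast
#' weights (no correction state, no proximal term).
#' @inheritParams local_update_etfeddyn
#' @export
local_update_fedavg <- function(client, w_c, cfg, objective, round = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, round, client$index))
  fit <- .sgd_epochs(w_c, objective, client$train, cfg$K, cfg$eta,
                     cfg$weight_decay, cfg$batch_size,
                     momentum = cfg$momentum, velocity = client$v_i)
  client$v_i <- fit$v
  client$w_i <- fit$w
  client$train_loss <- fit$mean_loss
  client
}

#' Server state and EtFedDyn central update
#'
#' The server keeps the central weights `w_c`, the gradient accumulator
#' `h_c` (initialized to zeros) and the round counter. Given the returned
#' local weights, the central update is: `wbar = mean(w_i)` (unweighted),
#' `h_c <- h_c + (w_c - wbar) / N`, then `w_c <- wbar - h_c`.
#'
#' @param w_c initial central weights.
#' @export
server_state <- function(w_c) {
  structure(list(w_c = w_c, h_c = ps_zero_like(w_c), t = 0L),
            class = "server_state")
}

#' @rdname server_state
#' @param server a `server_state`.
#' @param local_weights list of client `param_set`s, one per client.
#' @param h_scale factor on the accumulator increment. The default 1 is
#'   the printed recursion `h_c <- h_c + (w_c - wbar)/N`; setting it to
#'   the local regularization strength `alpha` gives the canonical
#'   dynamic-regularizer server, which the benchmark presets use (see the
#'   methods vignette on why the unit-scale accumulator destabilizes
#'   desk-scale training).
#' @export
server_update_etfeddyn <- function(server, local_weights, h_scale = 1) {
  stopifnot(inherits(server, "server_state"), length(local_weights) >= 1)
  N <- length(local_weights)
  wbar <- ps_mean(local_weights)
  server$h_c <- server$h_c + (server$w_c - wbar) * (h_scale / N)
  server$w_c <- wbar - server$h_c
  server$t <- server$t + 1L
  server
}

#' FedAvg central update: sample-size-weighted mean of client weights
#' @param local_weights list of client `param_set`s.
#' @param client_sizes training-set sizes, same length.
#' @export
server_update_fedavg <- function(local_weights, client_sizes) {
  stopifnot(length(local_weights) == length(client_sizes))
  ps_mean(local_weights, weights = client_sizes)
}

.eval_clients <- function(w, objective, clients) {
  accs <- rep(NA_real_, length(clients))
  correct <- 0; total <- 0
  for (i in seq_along(clients)) {
    te <- clients[[i]]$test
    if (is.null(te)) next
    probs <- objective$predict(w, te)
    pred <- as.integer(probs[, 2] > 0.5)
    y <- te$labels
    accs[i] <- mean(pred == y)
    correct <- correct + sum(pred == y); total <- total + length(y)
  }
  list(per_client = accs,
       pooled = if (total > 0) correct / total else NA_real_)
}

#' Run a federated training experiment
#'
#' T rounds of broadcast, (parallel-semantics) local updates and central
#' aggregation with all clients participating every round. Per-round
#' per-client training loss, 2D test accuracy and the central-weight
#' displacement are recorded. Fully reproducible from `cfg$seed`;
#' results do not depend on client execution order.
#'
#' @param clients list of [client_state()] objects.
#' @param cfg an [fl_config()].
#' @param objective trainer objective (e.g. [cnn_objective()]).
#' @return list with `history` (one row per round), `params` (final
#'   central weights), `server`, `clients`.
#' @export
run_federated <- function(clients, cfg, objective) {
  stopifnot(length(clients) >= 1)
  for (i in seq_along(clients)) clients[[i]]$index <- i
  server <- server_state(objective$init(cfg$seed))
  sizes <- vapply(clients, function(cl) objective$n_obs(cl$train), numeric(1))
  hist <- vector("list", cfg$rounds)
  for (t in seq_len(cfg$rounds)) {
    w_prev <- server$w_c
    clients <- lapply(clients, function(cl)
      if (cfg$algorithm == "etfeddyn")
        local_update_etfeddyn(cl, w_prev, cfg, objective, round = t)
      else local_update_fedavg(cl, w_prev, cfg, objective, round = t))
    local_w <- lapply(clients, `[[`, "w_i")
    if (cfg$algorithm == "etfeddyn") {
      hs <- if (is.null(cfg$h_scale)) 1 else cfg$h_scale
      server <- server_update_etfeddyn(server, local_w, h_scale = hs)
    } else {
      server$w_c <- server_update_fedavg(local_w, sizes)
      server$t <- server$t + 1L
    }
    ev <- .eval_clients(server$w_c, objective, clients)
    row <- data.frame(round = t,
                      train_loss = mean(vapply(clients, `[[`, numeric(1),
                                               "train_loss")),
                      test_acc = ev$pooled,
                      displacement = ps_norm(server$w_c - w_prev))
    for (i in seq_along(clients)) {
      row[[paste0("train_loss_c", i)]] <- clients[[i]]$train_loss
      row[[paste0("test_acc_c", i)]] <- ev$per_client[i]
    }
    hist[[t]] <- row
  }
  list(history = if (cfg$rounds > 0) do.call(rbind, hist) else
         data.frame(round = integer(0)),
       params = server$w_c, server = server, clients = clients)
}

#' Run the pooled central-learning baseline
#'
#' Trains the identical architecture on pooled slices with plain minibatch
#' SGD; used for the federated-versus-central comparison.
#'
#' @param train pooled training data. @param cfg a [cl_config()].
#' @param objective trainer objective. @param test optional held-out data.
#' @return list with `history` (one row per iteration) and `params`.
#' @export
run_central <- function(train, cfg, objective, test = NULL) {
  if (objective$n_obs(train) < 1) stop("empty pooled training set")
  w <- objective$init(cfg$seed)
  vel <- NULL
  hist <- vector("list", cfg$iterations)
  fake_client <- list(test = test)
  for (t in seq_len(cfg$iterations)) {
    old <- .Random.seed_save()
    set.seed(derive_seed(cfg$seed, t, 1L))
    fit <- .sgd_epochs(w, objective, train, 1L, cfg$learning_rate,
                       cfg$weight_decay, cfg$batch_size,
                       momentum = cfg$momentum, velocity = vel)
    .Random.seed_restore(old)
    w <- fit$w
    vel <- fit$v
    ev <- if (!is.null(test)) .eval_clients(w, objective, list(fake_client))
          else list(pooled = NA_real_)
    hist[[t]] <- data.frame(round = t, train_loss = fit$mean_loss,
                            test_acc = ev$pooled)
  }
  list(history = do.call(rbind, hist), params = w)
}

#' First round from which the test accuracy has stabilized
#'
#' Smallest round `t` such that the test accuracy at every round `>= t`
#' lies within `delta` of the final-round accuracy; `T` if the history
#' never stabilizes earlier.
#'
#' @param history numeric accuracy vector, or a history data frame with a
#'   `test_acc` column.
#' @param delta stability band, default 0.02.
#' @export
convergence_round <- function(history, delta = 0.02) {
  acc <- if (is.data.frame(history)) history$test_acc else history
  stopifnot(length(acc) >= 1)
  final <- acc[length(acc)]
  ok <- abs(acc - final) <= delta + 1e-9  # guard against FP representation
  stable_from <- rev(cumprod(rev(ok)))  # 1 where all later rounds are ok
  t <- which(stable_from == 1)[1]
  if (is.na(t)) length(acc) else t
}
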