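# Desk-scale benchmark federations and the experiment drivers used by the
# reproduction suite: convergence (EtFedDyn vs FedAvg), loss ablation under
# class imbalance, domain-mapping ablation, and 2D-vs-3D decision level.

#' Standard synthetic benchmark site specifications
#'
#' Two-site federations with the statistical structure the scheme targets:
#' \describe{
#'   \item{`iid`}{two balanced, identically distributed sites (separable
#'     task).}
#'   \item{`label_skew`}{label-skewed clients, 90/10 versus 10/90 class
#'     mix, the non-IID setting where client drift slows plain averaging.}
#'   \item{`imbalance`}{one pooled site with a 95:5 class ratio
#'     (minority = positive class), for the focal-versus-cross-entropy
#'     contrast.}
#'   \item{`shift`}{two sites with a strong injected intensity domain
#'     shift on site B (gain/gamma/offset), for the mapping ablation.}
#' }
#'
#' @param scenario one of `"iid"`, `"label_skew"`, `"imbalance"`,
#'   `"shift"`.
#' @param seed generation seed (per-site seeds are derived from it).
#' @return list of [site_spec()].
#' @export
benchmark_specs <- function(scenario = c("iid", "label_skew", "imbalance",
                                         "shift"),
                            seed = 1L) {
  scenario <- match.arg(scenario)
  # trivially separable class texture (near-flat versus fine stripes whose
  # frequency survives the 2x slice downsampling) so the benchmarks measure
  # optimization and aggregation behavior, not task difficulty
  sig <- list(mean = c(0.5, 0.72), freq = c(0.02, 0.2), amp = 0.35)
  s <- function(id, n0, n1, salt, shift = list(gain = 1, offset = 0,
                                               gamma = 1))
    site_spec(site_id = id, n_class0 = n0, n_class1 = n1,
              lesion_radius_range = c(8, 9), class_signal = sig,
              noise_sd = 0.02, domain_shift = shift,
              seed = .mix_seed(seed, 3L, salt))
  switch(scenario,
    iid = list(s("siteA", 14, 14, 1L), s("siteB", 14, 14, 2L)),
    label_skew = list(s("siteA", 18, 2, 1L), s("siteB", 2, 18, 2L)),
    imbalance = list(s("siteA", 38, 2, 1L)),
    shift = list(s("siteA", 14, 14, 1L),
                 s("siteB", 14, 14, 2L,
                   shift = list(gain = 0.95, offset = 0, gamma = 0.35))))
}

#' Build a federation: generate sites, split patient-wise, preprocess
#'
#' @param specs list of [site_spec()].
#' @param split_seed seed of the patient-wise 80/20 split (vary per run to
#'   re-partition as in repeated-run evaluation).
#' @param n_per_view,size,attenuate preprocessing options.
#' @param train_fraction train share of each class.
#' @return list with `clients` (one [client_state()] per site, holding
#'   train/test `slice_dataset`s), `test_scans` (per site, for 3D
#'   evaluation), `pooled_train`, `pooled_test`.
#' @export
generate_federation <- function(specs, split_seed = 1L, n_per_view = 5,
                                size = 32, attenuate = TRUE,
                                train_fraction = 0.8) {
  clients <- list(); test_scans <- list(); train_scans <- list()
  for (i in seq_along(specs)) {
    scans <- generate_site(specs[[i]])
    sp <- split_patients(scans, train_fraction = train_fraction,
                         seed = derive_seed(split_seed, 0L, i))
    tr <- preprocess_cohort(sp$train, n_per_view, size, attenuate)
    te <- preprocess_cohort(sp$test, n_per_view, size, attenuate)
    tr$site_id[] <- specs[[i]]$site_id
    te$site_id[] <- specs[[i]]$site_id
    clients[[i]] <- client_state(specs[[i]]$site_id, tr, te, index = i)
    test_scans[[specs[[i]]$site_id]] <- sp$test
    train_scans[[specs[[i]]$site_id]] <- sp$train
  }
  list(clients = clients, test_scans = test_scans,
       train_scans = train_scans,
       preprocess = list(n_per_view = n_per_view, size = size,
                         attenuate = attenuate),
       pooled_train = bind_slices(lapply(clients, `[[`, "train")),
       pooled_test = bind_slices(lapply(clients, `[[`, "test")))
}

#' Default desk-scale training configurations for the benchmarks
#'
#' Shared by the test suite and the reproduction script: 5 local epochs,
#' batch 30, local learning rate 0.01, momentum 0.9 (client-persistent),
#' alpha 0.01 with the canonically scaled server accumulator
#' (`h_scale = alpha`), weight decay 1e-4, cross-entropy objective.
#' `benchmark_model_config()` is the matching classifier: the tiny preset
#' on 16x16 inputs.
#' @param algorithm,rounds,loss,seed passed to [fl_config()].
#' @export
benchmark_fl_config <- function(algorithm = "etfeddyn", rounds = 30,
                                loss = loss_config("ce"), seed = 1L) {
  fl_config(rounds = rounds, K = 5, batch_size = 30, eta = 0.01,
            alpha = 0.01, weight_decay = 1e-4, momentum = 0.9,
            h_scale = 0.01, algorithm = algorithm, loss = loss, seed = seed)
}

#' @rdname benchmark_fl_config
#' @param seed initialization seed.
#' @export
benchmark_model_config <- function(seed = 1L)
  model_config("tiny", input_size = 16, seed = seed)

#' Map a shifted source site toward the target site before training
#'
#' Trains the toy mapper on the two clients' training slices and replaces
#' the source client's train and test images by their mapped versions
#' (target client passes through unchanged).
#'
#' @param federation from [generate_federation()].
#' @param source_index,target_index client positions.
#' @param mapper_cfg a [mapper_config()].
#' @return the federation with the source client mapped, plus `mapper`.
#' @export
harmonize_federation <- function(federation, source_index = 2L,
                                 target_index = 1L,
                                 mapper_cfg = mapper_config()) {
  src <- federation$clients[[source_index]]
  pp <- federation$preprocess
  # the mapper sees unnormalized (attenuated, resized) slices: per-slice
  # min-max normalization hides exactly the intensity differences the
  # mapping is meant to remove; normalization is applied after mapping
  raw <- function(scans) preprocess_cohort(
    scans, pp$n_per_view, pp$size, pp$attenuate, normalize = FALSE)
  src_tr <- raw(federation$train_scans[[source_index]])
  src_te <- raw(federation$test_scans[[source_index]])
  tgt_tr <- raw(federation$train_scans[[target_index]])
  pair <- train_mapper(src_tr, tgt_tr, mapper_cfg)
  src$train <- normalize_slices(map_dataset(pair$g_ab, src_tr))
  src$train$site_id[] <- src$client_id
  mapped_te <- normalize_slices(map_dataset(pair$g_ab, src_te))
  mapped_te$site_id[] <- src$client_id
  src$test <- mapped_te
  federation$clients[[source_index]] <- src
  federation$mapper <- pair
  federation$pooled_train <- bind_slices(lapply(federation$clients, `[[`,
                                                "train"))
  federation$pooled_test <- bind_slices(lapply(federation$clients, `[[`,
                                               "test"))
  federation
}

#' Convergence experiment: EtFedDyn versus FedAvg
#'
#' For each seed, builds the requested two-client federation and trains
#' both algorithms with identical partitions and initialization; reports
#' per-seed final pooled test accuracy and the round from which the test
#' accuracy stabilized (see [convergence_round()]).
#'
#' @param scenario `"iid"` or `"label_skew"`.
#' @param n_seeds number of independent repetitions.
#' @param master_seed base seed; run r uses `master_seed + r`.
#' @param rounds communication rounds.
#' @return data frame with one row per (seed, algorithm).
#' @export
experiment_convergence <- function(scenario = "label_skew", n_seeds = 5,
                                   master_seed = 1L, rounds = 30) {
  mc <- benchmark_model_config()
  rows <- list()
  for (r in seq_len(n_seeds)) {
    seed <- master_seed + r
    fed <- generate_federation(benchmark_specs(scenario, seed = seed),
                               split_seed = seed, size = mc$input_size)
    for (alg in c("etfeddyn", "fedavg")) {
      cfg <- benchmark_fl_config(alg, rounds = rounds, seed = seed)
      obj <- cnn_objective(mc, cfg$loss)
      fit <- run_federated(fed$clients, cfg, obj)
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed, algorithm = alg,
        final_acc = fit$history$test_acc[rounds],
        conv_round = convergence_round(fit$history))
    }
  }
  do.call(rbind, rows)
}

#' Loss-function ablation under 95:5 class imbalance
#'
#' Central training on the imbalanced benchmark site (38 negative / 2
#' positive patients) with the focal loss versus plain cross-entropy. The
#' focal class-balance weight is set near the inverse minority frequency
#' (`beta = 0.95` on the class-1 term) so the two minority patients'
#' slices carry comparable total loss mass to the majority. Minority
#' sensitivity cannot be estimated from the one positive held-out patient
#' the 80/20 split leaves, so each run also generates a fresh balanced
#' evaluation cohort (12 + 12 patients) from the same site family and
#' reports slice-level metrics on it.
#'
#' @inheritParams experiment_convergence
#' @param iterations central training epochs.
#' @export
experiment_loss_imbalance <- function(n_seeds = 5, master_seed = 1L,
                                      iterations = 40) {
  mc <- benchmark_model_config()
  losses <- list(focal = loss_config("focal", beta = 0.95, gamma = 2),
                 ce = loss_config("ce"))
  rows <- list()
  for (r in seq_len(n_seeds)) {
    seed <- master_seed + r
    specs <- benchmark_specs("imbalance", seed = seed)
    fed <- generate_federation(specs, split_seed = seed,
                               size = mc$input_size)
    eval_spec <- specs[[1]]
    eval_spec$site_id <- "eval"
    eval_spec$n_class0 <- 12L; eval_spec$n_class1 <- 12L
    eval_spec$seed <- derive_seed(seed, 5L, 9L)
    evalset <- preprocess_cohort(generate_site(eval_spec),
                                 size = mc$input_size)
    for (nm in names(losses)) {
      cfg <- cl_config(batch_size = 50, weight_decay = 1e-4,
                       learning_rate = 0.01, momentum = 0.9,
                       iterations = iterations,
                       loss = losses[[nm]], seed = seed)
      obj <- cnn_objective(mc, cfg$loss)
      fit <- run_central(fed$pooled_train, cfg, obj)
      probs <- obj$predict(fit$params, evalset)
      m <- metrics(confusion(as.integer(probs[, 2] > 0.5),
                             evalset$labels), level = "slice-2D")
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed, loss = nm, accuracy = m$accuracy,
        sensitivity = m$sensitivity, specificity = m$specificity)
    }
  }
  do.call(rbind, rows)
}

#' Patient-level majority-vote accuracy from slice probabilities
#'
#' Groups a slice dataset's class-1 probabilities by patient, votes with
#' the strict more-than-half rule and scores against the patient labels.
#' @param probs probability matrix from the classifier (`N x 2`).
#' @param ds the matching `slice_dataset`.
#' @export
patient_vote_accuracy <- function(probs, ds) {
  pred <- as.integer(probs[, 2] > 0.5)
  pats <- unique(ds$patient_id)
  dec <- vapply(pats, function(p)
    majority_vote(pred[ds$patient_id == p]), integer(1))
  lab <- vapply(pats, function(p) ds$labels[ds$patient_id == p][1],
                integer(1))
  mean(dec == lab)
}

#' Domain-mapping ablation under a strong injected site shift
#'
#' Two-site federation where site B carries a strong compressive
#' intensity shift; the dynamically regularized FL method is trained with
#' and without mapping site B onto site A's intensity domain, and pooled
#' test accuracy is compared at both decision levels. The primary
#' contrast is the patient-level (majority-vote) accuracy -- the
#' pipeline's actual endpoint -- which is robust to small slice-level
#' perturbations introduced by an imperfect mapper.
#'
#' @inheritParams experiment_convergence
#' @export
experiment_mapping <- function(n_seeds = 5, master_seed = 1L, rounds = 10) {
  mc <- benchmark_model_config()
  rows <- list()
  for (r in seq_len(n_seeds)) {
    seed <- master_seed + r
    fed <- generate_federation(benchmark_specs("shift", seed = seed),
                               split_seed = seed, size = mc$input_size)
    mapped <- harmonize_federation(
      fed, source_index = 2L, target_index = 1L,
      mapper_cfg = mapper_config(width = 4, epochs = 40, batch_size = 8,
                                 kernel = 1, seed = seed))
    for (nm in c("without", "with")) {
      f <- if (nm == "with") mapped else fed
      cfg <- benchmark_fl_config("etfeddyn", rounds = rounds, seed = seed)
      obj <- cnn_objective(mc, cfg$loss)
      fit <- run_federated(f$clients, cfg, obj)
      te <- bind_slices(lapply(f$clients, `[[`, "test"))
      probs <- obj$predict(fit$params, te)
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed, mapping = nm,
        accuracy = patient_vote_accuracy(probs, te),
        slice_accuracy = fit$history$test_acc[rounds])
    }
  }
  do.call(rbind, rows)
}

#' Decision-level experiment: slice-level versus majority-vote accuracy
#'
#' Trains EtFedDyn on the balanced benchmark and evaluates the final
#' central model at both decision levels on the held-out patients.
#'
#' @inheritParams experiment_convergence
#' @export
experiment_postprocessing <- function(n_seeds = 5, master_seed = 1L,
                                      rounds = 20) {
  mc <- benchmark_model_config()
  rows <- list()
  for (r in seq_len(n_seeds)) {
    seed <- master_seed + r
    fed <- generate_federation(benchmark_specs("iid", seed = seed),
                               split_seed = seed, size = mc$input_size)
    cfg <- benchmark_fl_config("etfeddyn", rounds = rounds, seed = seed)
    obj <- cnn_objective(mc, cfg$loss)
    fit <- run_federated(fed$clients, cfg, obj)
    ev <- evaluate_patient_level(fit$params, mc,
                                 unlist(fed$test_scans, recursive = FALSE))
    rows[[length(rows) + 1]] <- data.frame(
      seed = seed, acc_2d = ev$metrics_2d$accuracy,
      acc_3d = ev$metrics_3d$accuracy)
  }
  do.call(rbind, rows)
}
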