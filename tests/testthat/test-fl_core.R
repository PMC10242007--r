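test_that("scalar-toy local updates match hand-computed steps", {
  obj <- quad_objective()
  data <- list(b = 1.0)  # L = 0.5 (w - 1)^2, full batch
  w0 <- param_set(list(w = 0))
  # one plain gradient step from w = 0 with eta 0.1: w = 0.1 * b
  cfg <- fl_config(rounds = 1, K = 1, batch_size = 1, eta = 0.1, alpha = 0,
                   weight_decay = 0, seed = 5)
  cl <- client_state("c1", data)
  up <- local_update_etfeddyn(cl, w0, cfg, obj, round = 1)
  expect_equal(up$w_i$w, 0.1, tolerance = 1e-12)
  # alpha = 0, c = 0 reduces EtFedDyn to the FedAvg trajectory exactly
  upav <- local_update_fedavg(cl, w0, cfg, obj, round = 1)
  expect_identical(up$w_i, upav$w_i)
  # the update direction vanishes exactly at w = b/(1+alpha): with alpha
  # 10, b = 1, w_c = 0 the local problem's solution is ~0.0909
  wstar <- 1 / (1 + 10)
  expect_equal((wstar - 1) + 10 * (wstar - 0), 0, tolerance = 1e-12)
})

test_that("local iterates are pulled toward the center as alpha grows", {
  obj <- quad_objective()
  data <- list(b = 1.0)
  w0 <- param_set(list(w = 0))
  final_w <- vapply(c(0, 1, 10), function(alpha) {
    cfg <- fl_config(rounds = 1, K = 50, batch_size = 1, eta = 0.05,
                     alpha = alpha, weight_decay = 0, seed = 2)
    cl <- client_state("c", data)
    local_update_etfeddyn(cl, w0, cfg, obj, round = 1)$w_i$w
  }, numeric(1))
  expect_true(all(diff(final_w) < 0))           # shrinks toward w_c = 0
  expect_equal(final_w[3], 1 / 11, tolerance = 1e-3)  # b / (1 + alpha)
})

test_that("server update follows the printed accumulator recursion", {
  # scalar toy: h = 0, w_c = 1, wbar = 1.5, N = 1 -> h' = -0.5, w_c' = 2.0
  server <- server_state(param_set(list(w = 1.0)))
  server <- server_update_etfeddyn(server, list(param_set(list(w = 1.5))))
  expect_equal(server$h_c$w, -0.5)
  expect_equal(server$w_c$w, 2.0)
  expect_equal(server$t, 1L)
})

test_that("server state is a fixed point when clients return the broadcast", {
  w <- random_param_set(4)
  server <- server_state(w)
  for (round in 1:3) {
    server <- server_update_etfeddyn(server, list(w, w, w))
    expect_equal(ps_norm(server$h_c), 0)
    expect_equal(server$w_c, w)
  }
  expect_equal(server$t, 3L)
})

test_that("identical client weights average to themselves exactly", {
  u <- random_param_set(5)
  server <- server_state(ps_zero_like(u))
  server <- server_update_etfeddyn(server, list(u, u, u, u))
  # wbar = u; h moves by (0 - u)/4; w_c = u + u/4
  expect_equal(server$w_c, u + u * 0.25)
  expect_equal(server_update_fedavg(list(u, u), c(3, 9)), u)
})

test_that("fedavg server computes the sample-size-weighted mean", {
  a <- param_set(list(w = 0)); b <- param_set(list(w = 4))
  expect_equal(server_update_fedavg(list(a, b), c(1, 3))$w, 3)
  expect_equal(server_update_fedavg(list(a, b), c(1, 1))$w, 2)
  expect_equal(server_update_fedavg(list(b), 7), b)
  expect_error(server_update_fedavg(list(a, b), 1), "length")
})

test_that("single-client FedAvg is bitwise identical to centralized SGD", {
  scans <- generate_site(tiny_site(n0 = 2, n1 = 2, seed = 21))
  ds <- preprocess_cohort(scans, size = 8)
  mc <- mini_model_config()
  obj <- cnn_objective(mc, loss_config("ce"))
  flc <- fl_config(rounds = 3, K = 1, batch_size = 20, eta = 0.05,
                   alpha = 0, weight_decay = 1e-3, momentum = 0.9,
                   algorithm = "fedavg", loss = loss_config("ce"), seed = 17)
  fed <- run_federated(list(client_state("only", ds)), flc, obj)
  clc <- cl_config(batch_size = 20, weight_decay = 1e-3,
                   learning_rate = 0.05, iterations = 3, momentum = 0.9,
                   loss = loss_config("ce"), seed = 17)
  cen <- run_central(ds, clc, obj)
  expect_identical(fed$params, cen$params)
})

test_that("federated runs are reproducible and client-order invariant", {
  scans <- generate_site(tiny_site(n0 = 2, n1 = 2, seed = 22))
  ds1 <- preprocess_cohort(scans[c(1, 3)], size = 8)
  ds2 <- preprocess_cohort(scans[c(2, 4)], size = 8)
  mc <- mini_model_config()
  obj <- cnn_objective(mc, loss_config("ce"))
  cfg <- fl_config(rounds = 2, K = 2, batch_size = 10, eta = 0.05,
                   alpha = 0.01, seed = 31)
  r1 <- run_federated(list(client_state("a", ds1), client_state("b", ds2)),
                      cfg, obj)
  r2 <- run_federated(list(client_state("a", ds1), client_state("b", ds2)),
                      cfg, obj)
  expect_identical(r1$params, r2$params)
  expect_equal(nrow(r1$history), 2)
  # order invariance: clients swapped but indices preserved via per-client
  # seed derivation on their original positions
  ca <- client_state("a", ds1, index = 1L)
  cb <- client_state("b", ds2, index = 2L)
  w0 <- obj$init(cfg$seed)
  ua <- local_update_etfeddyn(ca, w0, cfg, obj, round = 1)
  ub <- local_update_etfeddyn(cb, w0, cfg, obj, round = 1)
  ub2 <- local_update_etfeddyn(cb, w0, cfg, obj, round = 1)
  ua2 <- local_update_etfeddyn(ca, w0, cfg, obj, round = 1)
  expect_identical(ua$w_i, ua2$w_i)
  expect_identical(ub$w_i, ub2$w_i)
})

test_that("zero-round and zero-epoch runs return the initial weights", {
  data <- list(b = c(1, 2))
  obj <- quad_objective()
  cfg <- fl_config(rounds = 0, K = 5, batch_size = 2, eta = 0.1, seed = 1)
  out <- run_federated(list(client_state("c", data)), cfg, obj)
  expect_equal(out$params, obj$init(cfg$seed))
  expect_equal(nrow(out$history), 0)
  cfg0 <- fl_config(rounds = 1, K = 0, batch_size = 2, eta = 0.1,
                    algorithm = "fedavg", seed = 1)
  w0 <- param_set(list(w = 0.3))
  up <- local_update_fedavg(client_state("c", data), w0, cfg0, obj)
  expect_identical(up$w_i, w0)
})

test_that("empty datasets are rejected by the trainers", {
  obj <- quad_objective()
  cfg <- fl_config(rounds = 1, K = 1, batch_size = 1, seed = 1)
  expect_error(local_update_etfeddyn(client_state("c", list(b = numeric(0))),
                                     param_set(list(w = 0)), cfg, obj),
               "empty")
  expect_error(run_central(list(b = numeric(0)), cl_config(), obj), "empty")
})

test_that("central training reduces the loss on separable toy data", {
  losses <- vapply(1:5, function(sd) {
    scans <- generate_site(tiny_site(n0 = 2, n1 = 2, seed = 40 + sd))
    ds <- preprocess_cohort(scans, size = 8)
    mc <- mini_model_config()
    obj <- cnn_objective(mc, loss_config("ce"))
    cfg <- cl_config(batch_size = 20, weight_decay = 1e-4,
                     learning_rate = 0.05, iterations = 10, momentum = 0.9,
                     loss = loss_config("ce"), seed = sd)
    h <- run_central(ds, cfg, obj)$history
    h$train_loss[10] - h$train_loss[1]
  }, numeric(1))
  expect_lt(median(losses), 0)
})

test_that("convergence_round scans stability from the left", {
  expect_equal(convergence_round(rep(0.8, 6)), 1)
  expect_equal(convergence_round(c(0.5, 0.6, 0.9, 0.91, 0.9), delta = 0.02), 3)
  expect_equal(convergence_round(c(0.2, 0.4, 0.6, 0.8, 1.0), delta = 0.02), 5)
  h <- data.frame(test_acc = c(0.5, 0.88, 0.9, 0.9))
  expect_equal(convergence_round(h, delta = 0.02), 2)
})

test_that("the printed-sign audit flag ascends the toy loss", {
  obj <- quad_objective()
  data <- list(b = 1.0)
  w0 <- param_set(list(w = 0))
  cfg <- fl_config(rounds = 1, K = 1, batch_size = 1, eta = 0.1, alpha = 0,
                   weight_decay = 0, seed = 5, eq4_as_printed = TRUE)
  up <- local_update_etfeddyn(client_state("c", data), w0, cfg, obj)
  expect_equal(up$w_i$w, -0.1, tolerance = 1e-12)  # moves away from b = 1
})
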