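test_that("cycle loss reproduces the hand-evaluated round trip", {
  # 1x1 images: x = 0.2 maps 0.2 -> 0.5 -> 0.3; y = 0.8 round-trips to 0.6
  g_fwd <- function(x) ifelse(abs(x - 0.2) < 1e-9, 0.5, x * 0.75)
  g_bwd <- function(x) ifelse(abs(x - 0.5) < 1e-9, 0.3, x)
  expect_equal(cycle_loss(g_fwd, g_bwd, 0.2, 0.8),
               abs(0.2 - 0.3) + abs(0.8 - 0.6), tolerance = 1e-9)
  # identity generators give exactly zero
  expect_equal(cycle_loss(identity, identity,
                          array(runif(32), c(4, 4, 2, 1)),
                          array(runif(32), c(4, 4, 2, 1))), 0)
  # nonnegativity for arbitrary maps
  set.seed(1)
  for (i in 1:5) {
    g1 <- function(x) x + rnorm(1, sd = 0.1)
    g2 <- function(x) x * runif(1, 0.5, 1.5)
    expect_gte(cycle_loss(g1, g2, runif(5), runif(5)), 0)
  }
  expect_error(cycle_loss(identity, identity, numeric(0), 1), "empty")
})

test_that("least-squares GAN losses match their definitions", {
  perfect <- function(x) rep(as.numeric(mean(x) > 0.5), dim(x)[4])
  real <- array(0.9, c(2, 2, 1, 3)); fake <- array(0.1, c(2, 2, 1, 3))
  gl <- gan_losses(perfect, real, fake)
  expect_equal(gl$discriminator, 0)
  half <- function(x) rep(0.5, dim(x)[4])
  gh <- gan_losses(half, real, fake)
  expect_equal(gh$discriminator, 0.5)
  expect_equal(gh$generator, 0.25)
  fooled <- function(x) rep(1, dim(x)[4])
  expect_equal(gan_losses(fooled, real, fake)$generator, 0)
})

test_that("the total objective is the additive composition of its terms", {
  set.seed(7)
  cfg <- mapper_config(lambda_cyc = 10, width = 2, epochs = 0,
                       batch_size = 2, seed = 7)
  a <- array(runif(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  b <- array(runif(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  pair <- train_mapper(a, b, cfg)   # 0 epochs: freshly initialized pair
  fake_b <- fedglio:::.gen_forward(pair$g_ab, a)$y
  fake_a <- fedglio:::.gen_forward(pair$g_ba, b)$y
  hand <- gan_losses(pair$d_b, b, fake_b)$generator +
    gan_losses(pair$d_a, a, fake_a)$generator +
    10 * cycle_loss(pair$g_ab, pair$g_ba, a, b)
  expect_equal(total_objective(pair, a, b, cfg), hand, tolerance = 1e-12)
  # lambda 0 drops the cycle term
  cfg0 <- mapper_config(lambda_cyc = 0, width = 2, epochs = 0,
                        batch_size = 2, seed = 7)
  expect_equal(total_objective(pair, a, b, cfg0),
               gan_losses(pair$d_b, b, fake_b)$generator +
                 gan_losses(pair$d_a, a, fake_a)$generator,
               tolerance = 1e-12)
  # freshly initialized generators are the identity (zero residual branch)
  expect_equal(fake_b, a)
  expect_equal(cycle_loss(pair$g_ab, pair$g_ba, a, b), 0)
})

test_that("mapper training is deterministic and shape preserving", {
  set.seed(11)
  a <- array(runif(16 * 16 * 2 * 6), c(16, 16, 2, 6))
  b <- array(runif(16 * 16 * 2 * 6), c(16, 16, 2, 6))
  cfg <- mapper_config(width = 2, epochs = 2, batch_size = 3, lr = 0.01,
                       seed = 9)
  p1 <- train_mapper(a, b, cfg)
  p2 <- train_mapper(a, b, cfg)
  expect_identical(p1$g_ab, p2$g_ab)
  expect_identical(p1$d_a, p2$d_a)
  y <- fedglio:::.gen_forward(p1$g_ab, a)$y
  expect_identical(dim(y), dim(a))
  expect_error(train_mapper(a[, , , 1:2, drop = FALSE], b,
                            mapper_config(batch_size = 4)), "batch_size")
})

test_that("map_dataset clips images and never touches labels or metadata", {
  scans <- generate_site(tiny_site(n0 = 1, n1 = 1, seed = 13))
  ds <- preprocess_cohort(scans, size = 16)
  out <- map_dataset(function(x) x * 3 - 1, ds)
  expect_true(all(out$images >= 0 & out$images <= 1))
  expect_identical(out$labels, ds$labels)
  expect_identical(out$patient_id, ds$patient_id)
  expect_identical(out$view, ds$view)
  expect_identical(out$slice_index, ds$slice_index)
  ident <- map_dataset(identity, ds)
  expect_equal(ident$images, ds$images)
  set.seed(3)
  for (i in 1:3) {
    gain <- runif(1, 0.3, 2)
    mapped <- map_dataset(function(x) x * gain, ds)
    expect_identical(mapped$labels, ds$labels)
  }
})

test_that("training the mapper reduces the intensity gap on a gain shift", {
  # target domain = source family scaled down; the trained source-to-target
  # generator should move source intensities toward the target histogram
  set.seed(21)
  src <- array(runif(16 * 16 * 2 * 24, 0.4, 1), c(16, 16, 2, 24))
  tgt <- array(runif(16 * 16 * 2 * 24, 0.4, 1) * 0.5, c(16, 16, 2, 24))
  gaps <- vapply(1:3, function(sd) {
    cfg <- mapper_config(width = 4, epochs = 40, batch_size = 8, lr = 0.005,
                         seed = sd)
    pair <- train_mapper(src, tgt, cfg)
    mapped <- fedglio:::.gen_forward(pair$g_ab, src)$y
    intensity_hist_distance(mapped, tgt) -
      intensity_hist_distance(src, tgt)
  }, numeric(1))
  expect_lt(median(gaps), 0)
})

test_that("intensity histogram distance is a valid dissimilarity", {
  x <- array(runif(100), c(5, 5, 2, 2))
  expect_equal(intensity_hist_distance(x, x), 0)
  y <- x * 0.3
  expect_gt(intensity_hist_distance(x, y), 0)
  expect_lte(intensity_hist_distance(x, y), 2)
})
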