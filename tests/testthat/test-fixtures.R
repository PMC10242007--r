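test_that("generate_site returns the requested cohort composition", {
  scans <- generate_site(tiny_site(n0 = 2, n1 = 3, seed = 4))
  expect_length(scans, 5)
  expect_equal(sort(vapply(scans, `[[`, numeric(1), "label")),
               c(0, 0, 1, 1, 1))
  expect_equal(anyDuplicated(vapply(scans, `[[`, character(1),
                                    "patient_id")), 0)
  s <- scans[[1]]
  expect_named(s$volumes, c("FLAIR", "T1ce"))
  expect_identical(dim(s$volumes$FLAIR), dim(s$mask))
  expect_true(all(s$volumes$T1ce >= 0 & s$volumes$T1ce <= 1))
  expect_true(all(s$mask %in% c(0L, 1L)))
})

test_that("site generation is byte-identical for identical spec and seed", {
  a <- generate_site(tiny_site(seed = 9))
  b <- generate_site(tiny_site(seed = 9))
  expect_identical(a, b)
  c <- generate_site(tiny_site(seed = 10))
  expect_false(identical(a[[1]]$volumes$FLAIR, c[[1]]$volumes$FLAIR))
})

test_that("impossible lesion geometry is rejected with the guarantee named", {
  expect_error(site_spec(volume_shape = c(4, 4, 4),
                         lesion_radius_range = c(1, 1)),
               "5")
  expect_error(site_spec(volume_shape = c(6, 6, 6),
                         lesion_radius_range = c(3, 3)),
               "too small")
})

test_that("every generated mask spans at least 5 slices per axis", {
  set.seed(123)
  for (i in 1:100) {
    shp <- sample(18:40, 3, replace = TRUE)
    rmax <- min(4, floor((min(shp) - 1) / 2))
    spec <- site_spec(site_id = "rnd", n_class0 = 1, n_class1 = 1,
                      volume_shape = shp,
                      lesion_radius_range = c(2, rmax),
                      seed = i)
    for (s in generate_site(spec))
      for (ax in 1:3)
        expect_gte(sum(apply(s$mask, ax, sum) > 0), 5)
  }
})

test_that("domain shift applies the stated voxel transform", {
  scan <- generate_site(tiny_site(n0 = 1, n1 = 1, seed = 2))[[1]]
  ident <- apply_domain_shift(scan, list(gain = 1, offset = 0, gamma = 1),
                              noise_sd = 0, seed = 1)
  expect_identical(ident$volumes, scan$volumes)
  doubled <- apply_domain_shift(scan, list(gain = 2, offset = 0, gamma = 1),
                                noise_sd = 0, seed = 1)
  expect_equal(doubled$volumes$FLAIR,
               array(pmin(2 * scan$volumes$FLAIR, 1), dim(scan$mask)))
  # hand value: gain 1.5, offset 0.1, gamma 2 on voxel 0.2 -> 0.16
  toy <- scan
  toy$volumes$FLAIR[] <- 0.2
  shifted <- apply_domain_shift(toy, list(gain = 1.5, offset = 0.1,
                                          gamma = 2), noise_sd = 0, seed = 1)
  expect_equal(shifted$volumes$FLAIR[1], 1.5 * 0.04 + 0.1, tolerance = 1e-12)
  expect_identical(shifted$mask, scan$mask)
  expect_error(apply_domain_shift(scan, list(gain = -1, offset = 0,
                                             gamma = 1)), "positive")
  expect_error(apply_domain_shift(scan, list(gain = 1, offset = 0,
                                             gamma = 0)), "positive")
})

test_that("patient-wise split is stratified, disjoint and deterministic", {
  scans <- generate_site(tiny_site(n0 = 5, n1 = 5, seed = 6))
  sp <- split_patients(scans, train_fraction = 0.8, seed = 3)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  lab <- function(x) vapply(x, `[[`, numeric(1), "label")
  expect_equal(sum(lab(sp$train) == 0), 4)
  expect_equal(sum(lab(sp$test) == 1), 1)
  ids <- function(x) vapply(x, `[[`, character(1), "patient_id")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(scans))
  sp2 <- split_patients(scans, train_fraction = 0.8, seed = 3)
  expect_identical(ids(sp2$train), ids(sp$train))
  expect_error(split_patients(scans, train_fraction = 1), "strictly inside")
  expect_error(split_patients(scans, train_fraction = 0), "strictly inside")
})

test_that("split covers all patients and stays disjoint across random seeds", {
  scans <- generate_site(tiny_site(n0 = 4, n1 = 7, seed = 8))
  ids <- vapply(scans, `[[`, character(1), "patient_id")
  for (sd in 1:10) {
    sp <- split_patients(scans, seed = sd)
    got <- c(vapply(sp$train, `[[`, character(1), "patient_id"),
             vapply(sp$test, `[[`, character(1), "patient_id"))
    expect_setequal(got, ids)
    expect_equal(length(got), length(ids))
  }
})

test_that("lesion intensity carries a learnable class signal", {
  # logistic regression on mean lesion intensity separates the classes,
  # averaged over independently generated cohorts
  accs <- vapply(1:5, function(sd) {
    scans <- generate_site(site_spec(site_id = "lrn", n_class0 = 25,
                                     n_class1 = 25, seed = 100 + sd))
    feat <- vapply(scans, function(s)
      mean(s$volumes$FLAIR[s$mask == 1]), numeric(1))
    lab <- vapply(scans, `[[`, numeric(1), "label")
    fit <- suppressWarnings(stats::glm(lab ~ feat, family = binomial))
    mean((fitted(fit) > 0.5) == lab)
  }, numeric(1))
  expect_gt(mean(accs), 0.8)
})

test_that("NIfTI round trip preserves volumes, masks and labels", {
  scans <- generate_site(tiny_site(n0 = 1, n1 = 1, seed = 5))
  d <- file.path(tempdir(), "site_rt")
  write_site_nifti(scans, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  back <- read_site_nifti(d)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$label, scans[[1]]$label)
  expect_equal(back[[1]]$volumes$FLAIR, scans[[1]]$volumes$FLAIR,
               tolerance = 1e-6)
  expect_identical(back[[2]]$mask, scans[[2]]$mask)
  unlink(d, recursive = TRUE)
})
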