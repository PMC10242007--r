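#' Synthetic multi-site cohort specification
#'
#' Describes one "site" (hospital) of the synthetic federation: how many
#' patients per class, the 3D volume geometry, the lesion size range, the
#' class-dependent lesion appearance and the site-level intensity domain
#' shift that emulates scanner differences. Defaults mirror a TCGA-like
#' cohort (55 negative / 112 positive patients).
#'
#' Class signal: lesions are spheres carrying class-dependent mean
#' intensity and sinusoidal texture frequency; the FLAIR-like channel shows
#' the full lesion, the T1ce-like channel emphasizes the lesion rim, so
#' the two modality streams carry correlated but distinct information.
#'
#' @param site_id short site identifier.
#' @param n_class0,n_class1 patient counts per class (label 1 is the
#'   IDH-mutation / LGG analogue positive class).
#' @param volume_shape integer `(D, H, W)` of every volume.
#' @param lesion_radius_range integer min/max lesion radius in voxels; the
#'   minimum must be at least 2 so every mask spans >= 5 slices per axis.
#' @param class_signal list with `mean` (length-2 per-class lesion mean
#'   intensity), `freq` (per-class texture frequency, cycles/voxel) and
#'   `amp` (texture amplitude); class means must differ.
#' @param domain_shift list `gain`, `offset`, `gamma` applied voxelwise as
#'   `clip(gain * v^gamma + offset + noise, 0, 1)`.
#' @param noise_sd voxel noise standard deviation.
#' @param seed site generation seed.
#' @export
site_spec <- function(site_id = "site",
                      n_class0 = 55, n_class1 = 112,
                      volume_shape = c(32, 32, 32),
                      lesion_radius_range = c(5, 8),
                      class_signal = list(mean = c(0.5, 0.72),
                                          freq = c(0.06, 0.42),
                                          amp = 0.3),
                      domain_shift = list(gain = 1, offset = 0, gamma = 1),
                      noise_sd = 0.02,
                      seed = 1L) {
  spec <- list(site_id = site_id, n_class0 = as.integer(n_class0),
               n_class1 = as.integer(n_class1),
               volume_shape = as.integer(volume_shape),
               lesion_radius_range = as.integer(lesion_radius_range),
               class_signal = class_signal, domain_shift = domain_shift,
               noise_sd = noise_sd, seed = as.integer(seed))
  if (spec$n_class0 + spec$n_class1 < 2)
    stop("a site needs at least 2 patients")
  if (length(spec$volume_shape) != 3 || any(spec$volume_shape < 1))
    stop("volume_shape must be a positive integer triple")
  if (class_signal$mean[1] == class_signal$mean[2])
    stop("class_signal means must have nonzero separation")
  if (spec$lesion_radius_range[1] < 2)
    stop("minimum lesion radius below 2 cannot guarantee >= 5 ",
         "tumor-bearing slices along each axis")
  if (any(spec$volume_shape < 2 * spec$lesion_radius_range[1] + 1))
    stop("volume_shape too small to host a lesion satisfying the ",
         ">= 5 tumor-slices-per-axis guarantee")
  if (spec$noise_sd < 0) stop("noise_sd must be nonnegative")
  class(spec) <- "site_spec"
  spec
}

#' Generate one synthetic site cohort
#'
#' Deterministically generates `n_class0 + n_class1` patient scans: two
#' co-registered modality volumes (`FLAIR`, `T1ce`) in `[0,1]`, a binary
#' spherical tumor mask spanning at least 5 slices along every axis, the
#' class label and site provenance. The site's domain shift and noise are
#' applied to the volumes (never to the mask).
#'
#' @param spec a [site_spec()].
#' @return list of `patient_scan` objects, labels in generation order
#'   `c(rep(0, n_class0), rep(1, n_class1))`.
#' @export
generate_site <- function(spec) {
  stopifnot(inherits(spec, "site_spec"))
  labels <- c(rep(0L, spec$n_class0), rep(1L, spec$n_class1))
  lapply(seq_along(labels), function(j) {
    pid <- sprintf("%s_p%03d", spec$site_id, j)
    scan <- .generate_scan(spec, pid, labels[j],
                           seed = .mix_seed(spec$seed, 17L, j))
    apply_domain_shift(scan, spec$domain_shift, noise_sd = spec$noise_sd,
                       seed = .mix_seed(spec$seed, 29L, j))
  })
}

.mix_seed <- function(base, salt, j) {
  as.integer((as.numeric(base) %% 2147483647 + 97561 * salt + 7919 * j) %%
               2147483562) + 1L
}

.generate_scan <- function(spec, patient_id, label, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- spec$volume_shape
  pick <- function(v) v[sample.int(length(v), 1)]  # safe for length-1 vectors
  r <- pick(seq(spec$lesion_radius_range[1], spec$lesion_radius_range[2]))
  ctr <- vapply(d, function(n) pick(seq(r + 1, n - r)), numeric(1))
  ax <- lapply(seq_len(3), function(i) seq_len(d[i]) - ctr[i])
  dist2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  mask <- array(as.integer(dist2 <= r^2), d)
  dist <- sqrt(dist2)
  rim <- mask == 1 & dist >= r - 1.5

  cs <- spec$class_signal
  mu <- cs$mean[label + 1]
  fr <- cs$freq[label + 1]
  phase <- stats::runif(1, 0, 2 * pi)
  coord <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  texture <- cs$amp * sin(2 * pi * fr * coord + phase)

  background <- 0.25 + 0.05 * sin(2 * pi * 0.05 * coord + phase / 2)
  flair <- background
  flair[mask == 1] <- mu + texture[mask == 1]
  t1ce <- background * 0.9
  t1ce[mask == 1] <- (mu - 0.10) + texture[mask == 1]
  t1ce[rim] <- pmin(mu + 0.15 + texture[rim], 1)

  structure(list(patient_id = patient_id, site_id = spec$site_id,
                 label = label,
                 volumes = list(FLAIR = pmin(pmax(flair, 0), 1),
                                T1ce = pmin(pmax(t1ce, 0), 1)),
                 mask = mask),
            class = "patient_scan")
}

#' Apply a scanner-style intensity domain shift to a scan
#'
#' Each voxel `v` of each modality becomes
#' `clip(gain * v^gamma + offset + e, 0, 1)` with `e ~ N(0, noise_sd^2)`.
#' The mask and label are untouched. Volumes are assumed in `[0,1]`, so
#' the clipping ceiling is 1.
#'
#' @param scan a `patient_scan`.
#' @param shift list with positive `gain`, real `offset`, positive `gamma`.
#' @param noise_sd nonnegative noise standard deviation.
#' @param seed RNG seed for the noise.
#' @export
apply_domain_shift <- function(scan, shift, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(scan, "patient_scan"))
  if (shift$gain <= 0 || shift$gamma <= 0)
    stop("gain and gamma of a domain shift must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  scan$volumes <- lapply(scan$volumes, function(v) {
    if (any(v < 0)) stop("volumes must be nonnegative")
    out <- shift$gain * v^shift$gamma + shift$offset
    if (noise_sd > 0) out <- out + stats::rnorm(length(v), sd = noise_sd)
    array(pmin(pmax(out, 0), 1), dim(v))
  })
  scan
}

#' Patient-wise stratified train/test split
#'
#' Splits scans so that no patient contributes to both sets and each
#' class's train share is as close to `train_fraction` as rounding allows
#' (each class keeps at least one patient per side when it has two or
#' more).
#'
#' @param scans list of `patient_scan`.
#' @param train_fraction fraction in (0, 1); default 0.8.
#' @param seed split seed.
#' @return list `train`, `test` of scans.
#' @export
split_patients <- function(scans, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly inside (0, 1)")
  labels <- vapply(scans, function(s) s$label, numeric(1))
  if (length(unique(labels)) < 2 || any(table(labels) < 1))
    stop("need at least one patient per class")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_tr <- round(length(idx) * train_fraction)
    if (length(idx) >= 2) n_tr <- min(max(n_tr, 1), length(idx) - 1)
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  list(train = scans[sort(train_idx)],
       test = scans[sort(setdiff(seq_along(scans), train_idx))])
}

#' Write / read a site as NIfTI volumes plus a CSV manifest
#'
#' One `.nii.gz` file per modality plus `<patient>_mask.nii.gz`; labels and
#' provenance in `manifest.csv` (columns `patient_id`, `site_id`, `label`,
#' `flair_file`, `t1ce_file`, `mask_file`).
#'
#' @param scans list of `patient_scan`. @param dir output directory.
#' @export
write_site_nifti <- function(scans, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(scans, function(s) {
    files <- c(flair_file = paste0(s$patient_id, "_FLAIR.nii.gz"),
               t1ce_file = paste0(s$patient_id, "_T1ce.nii.gz"),
               mask_file = paste0(s$patient_id, "_mask.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(s$volumes$FLAIR),
                       file.path(dir, files["flair_file"]))
    RNifti::writeNifti(RNifti::asNifti(s$volumes$T1ce),
                       file.path(dir, files["t1ce_file"]))
    RNifti::writeNifti(RNifti::asNifti(s$mask), file.path(dir, files["mask_file"]))
    data.frame(patient_id = s$patient_id, site_id = s$site_id,
               label = s$label, t(files), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_site_nifti
#' @export
read_site_nifti <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    vol <- function(f) {
      a <- RNifti::readNifti(file.path(dir, f))
      array(as.numeric(a), dim(a))
    }
    structure(list(patient_id = row$patient_id, site_id = row$site_id,
                   label = as.integer(row$label),
                   volumes = list(FLAIR = vol(row$flair_file),
                                  T1ce = vol(row$t1ce_file)),
                   mask = {
                     m <- vol(row$mask_file)
                     array(as.integer(m > 0.5), dim(m))
                   }),
              class = "patient_scan")
  })
}
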