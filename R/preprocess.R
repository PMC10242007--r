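# From 3D scans to the 2D two-channel slice records the classifier consumes:
# tumor-slice extraction (5 per view x 3 views), outside-mask attenuation,
# bilinear resize, per-slice min-max normalization, and online augmentation.

.views <- c("axial", "coronal", "sagittal")  # axes 1, 2, 3 of (D,H,W)

.slice3d <- function(vol, axis, i) {
  switch(axis, vol[i, , ], vol[, i, ], vol[, , i])
}

#' Extract the tumor-bearing 2D slices of a scan
#'
#' For each of the three orthogonal views, selects the `n_per_view` slices
#' with the largest tumor cross-sectional area (ties broken by the lower
#' slice index). Returns native-resolution records; resizing and
#' normalization happen downstream (see [preprocess_scan()]).
#'
#' @param scan a `patient_scan`.
#' @param n_per_view slices per view, default 5 (so 15 records per scan).
#' @return list of records: `patient_id`, `view`, `slice_index` (1-based),
#'   `label`, `image` (H x W x 2 array, channels FLAIR then T1ce) and
#'   `mask` (H x W).
#' @export
extract_tumor_slices <- function(scan, n_per_view = 5) {
  stopifnot(inherits(scan, "patient_scan"), n_per_view >= 1)
  out <- list()
  for (axis in 1:3) {
    areas <- apply(scan$mask, axis, sum)
    nonempty <- which(areas > 0)
    if (length(nonempty) < n_per_view)
      stop("scan ", scan$patient_id, ": only ", length(nonempty),
           " tumor-bearing slices along the ", .views[axis],
           " axis, need ", n_per_view)
    chosen <- order(-areas, seq_along(areas))[seq_len(n_per_view)]
    for (i in chosen) {
      img <- array(0, c(dim(.slice3d(scan$mask, axis, i)), 2))
      img[, , 1] <- .slice3d(scan$volumes$FLAIR, axis, i)
      img[, , 2] <- .slice3d(scan$volumes$T1ce, axis, i)
      out[[length(out) + 1]] <-
        list(patient_id = scan$patient_id, view = .views[axis],
             slice_index = i, label = scan$label, image = img,
             mask = .slice3d(scan$mask, axis, i))
    }
  }
  out
}

#' Attenuate pixels outside the tumor mask
#'
#' Pixels outside the mask are multiplied by exactly 1/3; pixels inside are
#' unchanged. Note the operation is not idempotent: applying it twice
#' attenuates the outside by 1/9.
#'
#' @param image 2D matrix or H x W x C array.
#' @param mask 2D binary matrix co-shaped with the image plane.
#' @export
attenuate_outside_mask <- function(image, mask) {
  d <- dim(image)
  if (!identical(as.integer(d[1:2]), as.integer(dim(mask))))
    stop("image and mask shapes do not match")
  f <- ifelse(mask > 0, 1, 1 / 3)
  if (length(d) == 2) image * f
  else image * array(f, d)
}

# shared bilinear sampler: sample `img` (matrix) at fractional coordinates
# (yi, xi), column-major order; coordinates outside the grid give `fill`.
.bilinear_map <- function(img, yi, xi, out_dim, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  y0 <- floor(yi); x0 <- floor(xi)
  ty <- yi - y0; tx <- xi - x0
  gv <- function(y, x) {
    ok <- y >= 1 & y <= H & x >= 1 & x <= W
    v <- rep(fill, length(y))
    v[ok] <- img[cbind(y[ok], x[ok])]
    v
  }
  v <- gv(y0, x0) * (1 - ty) * (1 - tx) + gv(y0 + 1, x0) * ty * (1 - tx) +
    gv(y0, x0 + 1) * (1 - ty) * tx + gv(y0 + 1, x0 + 1) * ty * tx
  matrix(v, out_dim[1], out_dim[2])
}

#' Bilinear resize of a 2D image
#' @param img matrix. @param size output side(s), scalar or `(H, W)`.
#' @export
resize_bilinear <- function(img, size) {
  if (length(size) == 1) size <- c(size, size)
  H <- nrow(img); W <- ncol(img)
  if (H == size[1] && W == size[2]) return(img)
  yc <- (seq_len(size[1]) - 0.5) * H / size[1] + 0.5
  xc <- (seq_len(size[2]) - 0.5) * W / size[2] + 0.5
  yc <- pmin(pmax(yc, 1), H)
  xc <- pmin(pmax(xc, 1), W)
  .bilinear_map(img, rep(yc, times = size[2]), rep(xc, each = size[1]), size)
}

#' Resize to a square and min-max normalize to [0, 1]
#'
#' Per-slice min-max normalization; a constant input maps to all zeros.
#'
#' @param image 2D matrix (one channel).
#' @param size output side, default 128.
#' @export
resize_normalize <- function(image, size = 128) {
  if (length(image) == 0) stop("empty image")
  out <- resize_bilinear(image, size)
  rng <- range(out)
  if (rng[2] > rng[1]) (out - rng[1]) / (rng[2] - rng[1])
  else out * 0
}

#' Rotate a 2D image by `angle` degrees (bilinear, zero padding)
#' @param img matrix. @param angle degrees, counterclockwise.
#' @export
rotate_bilinear <- function(img, angle) {
  if (angle == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  y <- rep(seq_len(H), times = W) - cy
  x <- rep(seq_len(W), each = H) - cx
  # inverse rotation of output coordinates
  yi <- cos(th) * y + sin(th) * x + cy
  xi <- -sin(th) * y + cos(th) * x + cx
  .bilinear_map(img, yi, xi, c(H, W))
}

#' Online training augmentation
#'
#' Horizontal flip with probability 0.5 and rotation by an angle drawn
#' uniformly from [-10, +10] degrees (bilinear interpolation, zero
#' padding), output clipped to [0, 1]. Applied only during training, never
#' to test slices. `augment_slice()` is the deterministic core;
#' `augment()` draws flip/angle from the current RNG stream.
#'
#' @param image H x W x C array (or matrix) with values in [0, 1].
#' @param flip logical, apply horizontal flip.
#' @param angle rotation angle in degrees.
#' @export
augment_slice <- function(image, flip, angle) {
  one <- function(m) {
    if (flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    pmin(pmax(rotate_bilinear(m, angle), 0), 1)
  }
  if (length(dim(image)) == 2) return(one(image))
  out <- image
  for (c in seq_len(dim(image)[3])) out[, , c] <- one(image[, , c])
  out
}

#' @rdname augment_slice
#' @export
augment <- function(image) {
  augment_slice(image, flip = stats::runif(1) < 0.5,
                angle = stats::runif(1, -10, 10))
}

#' Full slice preprocessing of one scan
#'
#' Extraction (largest tumor cross-sections, `n_per_view` per view), then
#' outside-mask attenuation at native resolution, then bilinear resize to
#' `size` and per-slice per-channel min-max normalization.
#'
#' @param scan a `patient_scan`. @param n_per_view slices per view.
#' @param size output side. @param attenuate apply the 1/3 outside-mask
#'   attenuation (default TRUE).
#' @param normalize apply the per-slice min-max normalization (default
#'   TRUE); domain mapping operates on unnormalized slices, which are
#'   normalized afterwards with [normalize_slices()].
#' @return a `slice_dataset`; see [slice_dataset()].
#' @export
preprocess_scan <- function(scan, n_per_view = 5, size = 128,
                            attenuate = TRUE, normalize = TRUE) {
  recs <- extract_tumor_slices(scan, n_per_view)
  slice_dataset(lapply(recs, function(r) {
    img <- if (attenuate) attenuate_outside_mask(r$image, r$mask) else r$image
    out <- array(0, c(size, size, 2))
    for (c in 1:2) out[, , c] <- if (normalize)
      resize_normalize(img[, , c], size) else
      resize_bilinear(img[, , c], size)
    r$image <- out
    r$mask <- NULL
    r
  }))
}

#' Per-slice min-max normalization of a whole dataset
#'
#' Applies the same per-slice per-channel min-max rule as
#' [resize_normalize()] to every image of a `slice_dataset` (a constant
#' channel maps to zeros).
#' @param ds a `slice_dataset`.
#' @export
normalize_slices <- function(ds) {
  stopifnot(inherits(ds, "slice_dataset"))
  for (i in seq_len(dim(ds$images)[4])) for (c in 1:2) {
    m <- ds$images[, , c, i]
    rng <- range(m)
    ds$images[, , c, i] <- if (rng[2] > rng[1])
      (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  }
  ds
}

#' Slice datasets
#'
#' Container for preprocessed 2D records: `images` `(S, S, 2, N)` in
#' `[0,1]`, `labels` (0/1), and provenance vectors `patient_id`, `view`,
#' `slice_index`, `site_id`.
#'
#' @param records list of records with `image`, `label`, `patient_id`,
#'   `view`, `slice_index` and optionally `site_id`.
#' @export
slice_dataset <- function(records) {
  stopifnot(length(records) >= 1)
  S <- dim(records[[1]]$image)[1]
  images <- array(0, c(S, S, 2, length(records)))
  for (i in seq_along(records)) images[, , , i] <- records[[i]]$image
  structure(list(
    images = images,
    labels = vapply(records, function(r) as.integer(r$label), integer(1)),
    patient_id = vapply(records, function(r) r$patient_id, character(1)),
    view = vapply(records, function(r) r$view, character(1)),
    slice_index = vapply(records, function(r) as.integer(r$slice_index),
                         integer(1)),
    site_id = vapply(records, function(r)
      if (is.null(r$site_id)) NA_character_ else r$site_id, character(1))
  ), class = "slice_dataset")
}

#' @rdname slice_dataset
#' @param ... `slice_dataset` objects to concatenate.
#' @export
bind_slices <- function(...) {
  ds <- list(...)
  if (length(ds) == 1 && is.list(ds[[1]]) && !inherits(ds[[1]], "slice_dataset"))
    ds <- ds[[1]]
  stopifnot(all(vapply(ds, inherits, logical(1), "slice_dataset")))
  S <- dim(ds[[1]]$images)[1]
  N <- sum(vapply(ds, function(d) dim(d$images)[4], integer(1)))
  images <- array(0, c(S, S, 2, N))
  at <- 0
  for (d in ds) {
    n <- dim(d$images)[4]
    images[, , , at + seq_len(n)] <- d$images
    at <- at + n
  }
  structure(list(images = images,
                 labels = unlist(lapply(ds, `[[`, "labels")),
                 patient_id = unlist(lapply(ds, `[[`, "patient_id")),
                 view = unlist(lapply(ds, `[[`, "view")),
                 slice_index = unlist(lapply(ds, `[[`, "slice_index")),
                 site_id = unlist(lapply(ds, `[[`, "site_id"))),
            class = "slice_dataset")
}

#' Number of slices in a dataset
#' @param ds a `slice_dataset`.
#' @export
n_slices <- function(ds) length(ds$labels)

#' Preprocess a whole cohort into one slice dataset
#' @param scans list of `patient_scan`.
#' @inheritParams preprocess_scan
#' @export
preprocess_cohort <- function(scans, n_per_view = 5, size = 128,
                              attenuate = TRUE, normalize = TRUE) {
  bind_slices(lapply(scans, preprocess_scan, n_per_view = n_per_view,
                     size = size, attenuate = attenuate,
                     normalize = normalize))
}

#' Persist / load a slice dataset (RDS arrays + CSV index mirror)
#' @param ds a `slice_dataset`. @param path `.rds` path; a sibling `.csv`
#'   index (everything but the pixel data) is written next to it.
#' @export
write_slices <- function(ds, path) {
  saveRDS(unclass(ds), path)
  idx <- data.frame(patient_id = ds$patient_id, site_id = ds$site_id,
                    view = ds$view, slice_index = ds$slice_index,
                    label = ds$labels)
  utils::write.csv(idx, sub("\\.rds$", ".csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_slices
#' @export
read_slices <- function(path) structure(readRDS(path), class = "slice_dataset")
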