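#' Majority vote over a patient's slice predictions
#'
#' A patient is assigned the positive class (IDH mutation / LGG analogue,
#' label 1) if and only if strictly more than half of their M predicted 2D
#' slices are class 1; even-M ties therefore resolve to class 0. With the
#' default 15 slices per patient ties cannot occur.
#'
#' @param slice_preds vector of 0/1 slice predictions, length M >= 1.
#' @return 0 or 1.
#' @export
majority_vote <- function(slice_preds) {
  if (length(slice_preds) < 1) stop("majority_vote needs at least one slice")
  stopifnot(all(slice_preds %in% c(0, 1)))
  as.integer(sum(slice_preds) > length(slice_preds) / 2)
}

#' Confusion counts with the positive class = IDH mutation / LGG
#'
#' @param predictions 0/1 predictions. @param labels 0/1 ground truth.
#' @param positive_class the label counted as positive (default 1).
#' @return list of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(predictions, labels, positive_class = 1) {
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  pos <- labels == positive_class
  pp <- predictions == positive_class
  structure(list(TP = sum(pos & pp), FP = sum(!pos & pp),
                 TN = sum(!pos & !pp), FN = sum(pos & !pp)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+FP+TN+FN)`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(FP+TN)`. A zero denominator yields `NA` (flagged
#' undefined, never silently 0).
#'
#' @param counts a [confusion()] result.
#' @param level optional label (`"slice-2D"` or `"patient-3D"`) carried in
#'   the report.
#' @return list of class `metrics_report`.
#' @export
metrics <- function(counts, level = NA_character_) {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- counts$TP + counts$FP + counts$TN + counts$FN
  if (tot == 0) stop("all confusion counts are zero")
  sens_den <- counts$TP + counts$FN
  spec_den <- counts$FP + counts$TN
  structure(list(
    accuracy = (counts$TP + counts$TN) / tot,
    sensitivity = if (sens_den > 0) counts$TP / sens_den else NA_real_,
    specificity = if (spec_den > 0) counts$TN / spec_den else NA_real_,
    level = level, counts = counts), class = "metrics_report")
}

#' Patient-level (3D scan) evaluation of a trained classifier
#'
#' Extracts the same 15 tumor slices per test patient as training-style
#' preprocessing (no augmentation), runs the forward pass, thresholds the
#' class-1 probability at 0.5 per slice, majority-votes per patient and
#' reports both patient-level and pooled slice-level metrics. Patients
#' violating the slice guarantee are skipped with a warning.
#'
#' @param params trained `param_set`. @param config the `model_config`.
#' @param test_scans list of `patient_scan`.
#' @param n_per_view slices per view (default 5).
#' @param attenuate apply outside-mask attenuation (default TRUE).
#' @return list with `patients` (data frame: patient_id, label, n_slices,
#'   n_positive_slices, decision), `metrics_3d`, `metrics_2d`.
#' @export
evaluate_patient_level <- function(params, config, test_scans,
                                   n_per_view = 5, attenuate = TRUE) {
  rows <- list(); slice_pred <- integer(0); slice_lab <- integer(0)
  for (scan in test_scans) {
    ds <- tryCatch(
      preprocess_scan(scan, n_per_view = n_per_view,
                      size = config$input_size, attenuate = attenuate),
      error = function(e) {
        warning("skipping patient ", scan$patient_id, ": ",
                conditionMessage(e))
        NULL
      })
    if (is.null(ds)) next
    probs <- model_forward(params, config, ds$images)$probs
    pred <- as.integer(probs[, 2] > 0.5)
    rows[[length(rows) + 1]] <-
      data.frame(patient_id = scan$patient_id, label = scan$label,
                 n_slices = length(pred), n_positive_slices = sum(pred),
                 decision = majority_vote(pred))
    slice_pred <- c(slice_pred, pred)
    slice_lab <- c(slice_lab, ds$labels)
  }
  if (!length(rows)) stop("no evaluable test patients")
  patients <- do.call(rbind, rows)
  list(patients = patients,
       metrics_3d = metrics(confusion(patients$decision, patients$label),
                            level = "patient-3D"),
       metrics_2d = metrics(confusion(slice_pred, slice_lab),
                            level = "slice-2D"))
}

#' Aggregate metrics over repeated runs
#'
#' Element-wise mean and sample (n-1) standard deviation of accuracy,
#' sensitivity and specificity across runs; undefined (`NA`) entries
#' propagate, and a single run has an undefined standard deviation.
#'
#' @param reports list of [metrics()] reports from independent runs.
#' @return list with `mean`, `sd` (each accuracy/sensitivity/specificity)
#'   and `n_runs`.
#' @export
aggregate_runs <- function(reports) {
  stopifnot(length(reports) >= 1)
  pull <- function(f) vapply(reports, function(r) r[[f]], numeric(1))
  agg <- function(v) {
    if (any(is.na(v))) return(list(mean = NA_real_, sd = NA_real_))
    list(mean = mean(v),
         sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }
  a <- agg(pull("accuracy")); s <- agg(pull("sensitivity"))
  p <- agg(pull("specificity"))
  list(mean = list(accuracy = a$mean, sensitivity = s$mean,
                   specificity = p$mean),
       sd = list(accuracy = a$sd, sensitivity = s$sd, specificity = p$sd),
       n_runs = length(reports))
}

#' Write metrics as CSV (columns level, run, accuracy, sensitivity,
#' specificity) and JSON
#' @param reports list of `metrics_report`. @param path base path without
#'   extension; `.csv` and `.json` are written.
#' @export
write_metrics <- function(reports, path) {
  df <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(level = r$level, run = i, accuracy = r$accuracy,
               sensitivity = r$sensitivity, specificity = r$specificity)
  }))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(df, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(df)
}
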