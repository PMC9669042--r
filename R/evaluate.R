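#' Classify datapoints against a reference total fluid intake
#'
#' With `delta = actual_tfi - reference_tfi` and the 500 mOsm/kg hydration
#' threshold: `delta >= 0` and U_Osm below threshold is a true positive
#' (drank at least the recommended amount and is well hydrated);
#' `delta >= 0` with U_Osm at or above threshold is a false positive (the
#' reference was not high enough to ensure optimal hydration);
#' `delta < 0` with low U_Osm is a false negative (the reference could have
#' been lower); `delta < 0` with high U_Osm is a true negative. Ties
#' (`delta = 0`) belong to the `>= 0` row.
#'
#' @param actual_tfi,reference_tfi observed and reference 24 h total fluid
#'   intake (mL), vectors of equal length.
#' @param actual_uosm observed 24 h urine osmolality (mOsm/kg).
#' @param threshold hydration threshold (default 500 mOsm/kg).
#' @return character vector in `{"TP","FP","FN","TN"}`.
#' @export
classify_datapoint <- function(actual_tfi, reference_tfi, actual_uosm,
                               threshold = 500) {
  if (length(actual_tfi) != length(reference_tfi) ||
      length(actual_tfi) != length(actual_uosm))
    stop("length mismatch")
  if (anyNA(actual_tfi) || anyNA(reference_tfi) || anyNA(actual_uosm))
    stop("missing values must be excluded upstream")
  delta <- actual_tfi - reference_tfi
  hydrated <- actual_uosm < threshold
  ifelse(delta >= 0, ifelse(hydrated, "TP", "FP"),
         ifelse(hydrated, "FN", "TN"))
}

#' Build a contingency table of classification outcomes
#'
#' @inheritParams classify_datapoint
#' @return A `contingency_table` with counts `tp`, `fp`, `fn`, `tn`,
#'   `total` and the threshold used.
#' @export
build_contingency <- function(actual_tfi, reference_tfi, actual_uosm,
                              threshold = 500) {
  if (length(actual_tfi) == 0L)
    return(contingency_table(0, 0, 0, 0, threshold))
  cls <- classify_datapoint(actual_tfi, reference_tfi, actual_uosm, threshold)
  contingency_table(sum(cls == "TP"), sum(cls == "FP"),
                    sum(cls == "FN"), sum(cls == "TN"), threshold)
}

#' Contingency table from cell counts
#' @param tp,fp,fn,tn non-negative datapoint counts.
#' @param threshold_uosm hydration threshold (default 500 mOsm/kg).
#' @return A `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn, threshold_uosm = 500) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 total = tp + fp + fn + tn,
                 threshold_uosm = threshold_uosm),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table (threshold %g mOsm/kg), n = %d\n",
              x$threshold_uosm, x$total))
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(c("delta >= 0", "delta < 0"),
                              c("U < thr", "U >= thr")))
  print(m)
  if (x$total > 0)
    cat(sprintf("accuracy %.1f%%, acceptable %.1f%%\n",
                100 * accuracy(x), 100 * acceptable_classification(x)))
  invisible(x)
}

#' Overall accuracy of a contingency table
#'
#' `(TP + TN) / (TP + FP + FN + TN)`.
#' @param ct a `contingency_table` with a positive total.
#' @return proportion in `[0, 1]`.
#' @export
accuracy <- function(ct) {
  if (ct$total == 0) stop("accuracy undefined for an empty table")
  (ct$tp + ct$tn) / ct$total
}

#' Acceptable-classification rate of a contingency table
#'
#' `(TP + FN + TN) / (TP + FP + FN + TN)`: false negatives (people drinking
#' less than the reference yet still well hydrated) count as acceptable;
#' only false positives — a reference too low for an underhydrated person —
#' are penalized. Always at least as large as [accuracy()].
#' @inheritParams accuracy
#' @return proportion in `[0, 1]`.
#' @export
acceptable_classification <- function(ct) {
  if (ct$total == 0) stop("acceptable classification undefined for an empty table")
  (ct$tp + ct$fn + ct$tn) / ct$total
}

#' EFSA adequate-intake fluid baseline
#'
#' EFSA sets daily Adequate Intakes for total water of 2.5 L for adult men
#' and 2.0 L for adult women; with about 80% of total water coming from
#' fluids, the fluid thresholds are 2.0 L and 1.6 L respectively.
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param fluid_fraction fraction of total water from fluids (default 0.80).
#' @param total_ai_mL named total-water AIs in mL
#'   (default `c(male = 2500, female = 2000)`).
#' @return reference fluid intake in mL.
#' @export
efsa_reference_tfi <- function(sex, fluid_fraction = 0.80,
                               total_ai_mL = c(male = 2500, female = 2000)) {
  sex <- as.character(sex)
  bad <- !sex %in% names(total_ai_mL)
  if (any(bad))
    stop("baseline undefined for sex category: ",
         paste(unique(sex[bad]), collapse = ", "))
  unname(total_ai_mL[sex] * fluid_fraction)
}

#' Score advice against the EFSA guideline baseline
#'
#' Builds two contingency tables from the same classified rows — one with
#' the advisor's optimized total fluid intake as reference, one with the
#' sex-specific EFSA fluid threshold — and reports accuracy and acceptable
#' classification for each. Rows with missing actual TFI or urine
#' osmolality are excluded (counted in `n_excluded`).
#'
#' @param test_rows test-set visit records (need `total_fluid_intake`,
#'   `urine_osm`, `sex`).
#' @param recommendations output of [advise_testset()] aligned to
#'   `test_rows` via its `row` column.
#' @param threshold hydration threshold (default 500 mOsm/kg).
#' @param fluid_fraction passed to [efsa_reference_tfi()].
#' @return A `metrics_report`: data.frame `summary` with one row per
#'   comparator (cells, accuracy, acceptable), the two tables, and counts.
#' @export
compare_to_guidelines <- function(test_rows, recommendations, threshold = 500,
                                  fluid_fraction = 0.80) {
  test_rows <- as.data.frame(test_rows)
  rec <- as.data.frame(recommendations)
  if (nrow(rec) == 0L) stop("no recommendations to evaluate")
  rows <- test_rows[rec$row, , drop = FALSE]
  ok <- !is.na(rows$total_fluid_intake) & !is.na(rows$urine_osm)
  rows <- rows[ok, , drop = FALSE]; rec <- rec[ok, , drop = FALSE]
  ct_alg <- build_contingency(rows$total_fluid_intake, rec$optimized_tfi,
                              rows$urine_osm, threshold)
  ct_efsa <- build_contingency(rows$total_fluid_intake,
                               efsa_reference_tfi(rows$sex, fluid_fraction),
                               rows$urine_osm, threshold)
  summ <- do.call(rbind, lapply(
    list(algorithm = ct_alg, efsa = ct_efsa), function(ct)
      data.frame(tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn,
                 accuracy = accuracy(ct),
                 acceptable = acceptable_classification(ct))))
  summ <- cbind(comparator = rownames(summ), summ)
  rownames(summ) <- NULL
  structure(list(summary = summ, algorithm = ct_alg, efsa = ct_efsa,
                 n_classified = ct_alg$total, n_excluded = sum(!ok)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Classification vs guidelines (n = %d classified, %d excluded)\n",
              x$n_classified, x$n_excluded))
  s <- x$summary
  s$accuracy <- sprintf("%.1f%%", 100 * s$accuracy)
  s$acceptable <- sprintf("%.1f%%", 100 * s$acceptable)
  print(s, row.names = FALSE)
  invisible(x)
}
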