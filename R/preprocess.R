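#' Eligibility criteria for cohort filtering
#'
#' Healthy-adult filters applied before modelling: age and BMI windows,
#' a plasma-osmolality dehydration ceiling (values above 310 mOsm/kg
#' correspond to roughly 5% body-weight loss and indicate dehydration),
#' a minimum plausible 24 h total fluid intake, and a completeness
#' requirement on the response and anthropometrics. Records with missing
#' intake fields are retained: tree learners route missing values natively,
#' and such records still carry useful information.
#'
#' @param age_range years, default `c(18, 65)`.
#' @param bmi_range kg/m^2, default `c(18, 30)`.
#' @param plasma_osm_max mOsm/kg; rows strictly above are removed (default 310).
#' @param tfi_min mL; rows strictly below are removed (default 200).
#' @param require_complete_core if `TRUE` (default) rows must have urine
#'   osmolality and all anthropometrics observed; intake fields are exempt.
#' @return An object of class `eligibility_criteria`.
#' @export
eligibility_criteria <- function(age_range = c(18, 65),
                                 bmi_range = c(18, 30),
                                 plasma_osm_max = 310,
                                 tfi_min = 200,
                                 require_complete_core = TRUE) {
  if (length(age_range) != 2L || diff(age_range) <= 0) stop("age_range degenerate")
  if (length(bmi_range) != 2L || diff(bmi_range) <= 0) stop("bmi_range degenerate")
  stopifnot_scalar_num(plasma_osm_max, "plasma_osm_max", positive = TRUE)
  stopifnot_scalar_num(tfi_min, "tfi_min")
  if (tfi_min < 0) stop("`tfi_min` must be >= 0")
  structure(list(age_range = age_range, bmi_range = bmi_range,
                 plasma_osm_max = plasma_osm_max, tfi_min = tfi_min,
                 require_complete_core = isTRUE(require_complete_core)),
            class = "eligibility_criteria")
}

#' Apply eligibility filters to visit records
#'
#' Each removed row is attributed to the first criterion it violates, in the
#' order age, BMI, incomplete core data, plasma osmolality, minimum total
#' fluid intake. Missing plasma osmolality or total fluid intake does not
#' trigger the corresponding filter; such rows are retained (and counted in
#' `retained_with_missing_intake` when intake is missing).
#'
#' @param rows visit records (data.frame).
#' @param criteria an [eligibility_criteria()].
#' @return list with `rows` (the retained records) and `report`, a
#'   `filter_report` with `rows_in`, `rows_out`, `removed_by_reason`,
#'   `retained_with_missing_intake`.
#' @export
apply_eligibility_filters <- function(rows, criteria = eligibility_criteria()) {
  if (!inherits(criteria, "eligibility_criteria"))
    stop("`criteria` must be eligibility_criteria()")
  rows <- as.data.frame(rows)
  n <- nrow(rows)
  reasons <- c("age", "bmi", "incomplete_core", "plasma_osm", "tfi_min")
  removed <- setNames(integer(length(reasons)), reasons)
  if (n == 0L) {
    report <- structure(list(rows_in = 0L, rows_out = 0L,
                             removed_by_reason = removed,
                             retained_with_missing_intake = 0L),
                        class = "filter_report")
    return(list(rows = rows, report = report))
  }
  fail <- rep(NA_character_, n)
  viol <- function(x, lo, hi) !is.na(x) & (x < lo | x > hi)
  mark <- function(fail, bad, reason) ifelse(is.na(fail) & bad, reason, fail)
  fail <- mark(fail, viol(rows$age, criteria$age_range[1], criteria$age_range[2]), "age")
  fail <- mark(fail, viol(rows$bmi, criteria$bmi_range[1], criteria$bmi_range[2]), "bmi")
  if (criteria$require_complete_core) {
    core <- intersect(CORE_FIELDS, names(rows))
    incomplete <- !complete.cases(rows[, core, drop = FALSE])
    fail <- mark(fail, incomplete, "incomplete_core")
  }
  fail <- mark(fail, !is.na(rows$plasma_osm) & rows$plasma_osm > criteria$plasma_osm_max,
               "plasma_osm")
  fail <- mark(fail, !is.na(rows$total_fluid_intake) &
                 rows$total_fluid_intake < criteria$tfi_min, "tfi_min")
  keep <- is.na(fail)
  tab <- table(factor(fail[!keep], levels = reasons))
  removed[reasons] <- as.integer(tab[reasons])
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- structure(list(
    rows_in = n,
    rows_out = nrow(out),
    removed_by_reason = removed,
    retained_with_missing_intake = sum(is.na(out$total_fluid_intake) |
                                         is.na(out$plain_water))
  ), class = "filter_report")
  stopifnot(report$rows_in == report$rows_out + sum(report$removed_by_reason))
  list(rows = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Eligibility filter report\n")
  cat(sprintf("  rows in: %d, rows retained: %d\n", x$rows_in, x$rows_out))
  for (nm in names(x$removed_by_reason))
    if (x$removed_by_reason[[nm]] > 0)
      cat(sprintf("  removed (%s): %d\n", nm, x$removed_by_reason[[nm]]))
  cat(sprintf("  retained with missing intake: %d\n",
              x$retained_with_missing_intake))
  invisible(x)
}

#' Participant-level train/test split
#'
#' Participants (not rows) are partitioned so that every row of a
#' participant lands in exactly one set, preventing leakage of
#' within-person correlation across the split. The participant ID list is
#' sorted, shuffled under `seed`, and the first `ceiling(ratio * n)` IDs go
#' to training (rounding toward train); the assignment is therefore stable
#' under row reordering.
#'
#' @param rows visit records with a `participant_id` column.
#' @param ratio target train proportion in (0,1), default 0.75.
#' @param seed integer seed.
#' @return A `split_result` list: `train`, `test` (row subsets),
#'   `train_participants`, `test_participants`, `ratio`, `seed`.
#' @export
split_by_participant <- function(rows, ratio = 0.75, seed = 1L) {
  rows <- as.data.frame(rows)
  if (is.null(rows$participant_id)) stop("rows must carry `participant_id`")
  if (!(ratio > 0 && ratio < 1)) stop("`ratio` must lie in (0, 1)")
  ids <- sort(unique(as.character(rows$participant_id)))
  if (length(ids) == 1L) {
    warning("single participant: all rows assigned to the training set")
    train_ids <- ids; test_ids <- character(0)
  } else {
    shuffled <- withr::with_seed(as.integer(seed), sample(ids))
    n_train <- ceiling(ratio * length(ids))
    train_ids <- sort(shuffled[seq_len(n_train)])
    test_ids <- sort(setdiff(ids, train_ids))
  }
  train <- rows[rows$participant_id %in% train_ids, , drop = FALSE]
  test <- rows[rows$participant_id %in% test_ids, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  structure(list(train = train, test = test,
                 train_participants = train_ids, test_participants = test_ids,
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("Participant split (ratio %.2f, seed %d)\n", x$ratio, x$seed))
  cat(sprintf("  train: %d participants / %d rows\n",
              length(x$train_participants), nrow(x$train)))
  cat(sprintf("  test:  %d participants / %d rows\n",
              length(x$test_participants), nrow(x$test)))
  invisible(x)
}
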