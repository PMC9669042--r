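#' Assemble a full pipeline configuration
#'
#' Bundles the per-stage configurations into one validated object. The
#' global seed is mandatory and drives every stage.
#'
#' @param cohort a [cohort_spec()].
#' @param physiology a [physiology_params()].
#' @param criteria an [eligibility_criteria()].
#' @param policy a [feature_policy()].
#' @param learner learner kind for the deployed surrogate.
#' @param n_search,cv_folds tuning budget for [fit_surrogate()].
#' @param constraints an [advisor_constraints()].
#' @param split_ratio train proportion.
#' @param baseline guideline baseline label (only `"efsa"` supported).
#' @param seed global integer seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(cohort = cohort_spec(seed = seed),
                       physiology = physiology_params(),
                       criteria = eligibility_criteria(),
                       policy = feature_policy(),
                       learner = "xgboost",
                       n_search = 50, cv_folds = 5,
                       constraints = advisor_constraints(),
                       split_ratio = 0.75,
                       baseline = "efsa",
                       seed = 1L) {
  if (is.null(seed)) stop("config invalid: missing required field `seed`")
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(physiology, "physiology_params"),
            inherits(criteria, "eligibility_criteria"),
            inherits(policy, "feature_policy"),
            inherits(constraints, "advisor_constraints"))
  if (!identical(baseline, "efsa"))
    stop("config invalid: unsupported `baseline` (only \"efsa\")")
  if (!(split_ratio > 0 && split_ratio < 1))
    stop("config invalid: `split_ratio` must lie in (0, 1)")
  structure(list(cohort = cohort, physiology = physiology,
                 criteria = criteria, policy = policy, learner = learner,
                 n_search = n_search, cv_folds = cv_folds,
                 constraints = constraints, split_ratio = split_ratio,
                 baseline = baseline, seed = as.integer(seed)),
            class = "run_config")
}

# canonical (recursively key-sorted) JSON rendering, hashed with md5 so
# semantically identical configs hash identically regardless of key order
sort_rec <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    lapply(x, sort_rec)
  } else x
}

#' Hash a pipeline configuration
#' @param config a `run_config` (or any list).
#' @return md5 hex string of the canonical JSON rendering.
#' @export
config_hash <- function(config) {
  canon <- jsonlite::toJSON(sort_rec(unclass(config)), auto_unbox = TRUE,
                            digits = NA, force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(canon), tf)
  unname(tools::md5sum(tf))
}

#' Run the full advice pipeline
#'
#' Executes simulate -> filter -> split -> rank/prune features -> fit
#' surrogate -> interpret -> advise -> score as one seeded run, writing
#' every stage artifact under `out_dir` (cohort and train/test CSVs,
#' filter report JSON, importance and PDP/ALE curve CSVs, a serialized
#' model, advice CSV, metrics report JSON) plus a `manifest.json` with the
#' config hash, artifact paths, per-stage row counts and wall times.
#' Reruns with the same config reproduce the CSV/JSON artifacts.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print stage-boundary row counts.
#' @return A `run_manifest` list (invisibly also written as JSON).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("hydrorun"),
                         verbose = FALSE) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  paths <- list(); counts <- list(); times <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  cohort <- stage("simulate", generate_cohort(config$cohort, config$physiology))
  paths$cohort <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, paths$cohort)
  counts$cohort_rows <- nrow(cohort)
  say("simulate: %d rows", nrow(cohort))

  filt <- stage("filter", apply_eligibility_filters(cohort, config$criteria))
  paths$filter_report <- file.path(out_dir, "filters.json")
  jsonlite::write_json(unclass(filt$report), paths$filter_report,
                       auto_unbox = TRUE, pretty = TRUE)
  counts$filtered_rows <- nrow(filt$rows)
  say("filter: %d rows retained", nrow(filt$rows))

  sp <- stage("split", split_by_participant(filt$rows, config$split_ratio,
                                            seed = config$seed))
  paths$train <- file.path(out_dir, "train.csv")
  paths$test <- file.path(out_dir, "test.csv")
  write_cohort(sp$train, paths$train); write_cohort(sp$test, paths$test)
  counts$train_rows <- nrow(sp$train); counts$test_rows <- nrow(sp$test)
  say("split: %d train / %d test rows", nrow(sp$train), nrow(sp$test))

  imp <- stage("rank", rank_features(sp$train, seed = config$seed))
  features <- prune_features(imp, config$policy)
  paths$importance <- file.path(out_dir, "importance.csv")
  write.csv(imp, paths$importance, row.names = FALSE)
  counts$features <- length(features)

  model <- stage("fit", fit_surrogate(sp$train, features,
                                      learner = config$learner,
                                      n_search = config$n_search,
                                      cv_folds = config$cv_folds,
                                      seed = config$seed))
  paths$model <- file.path(out_dir, "model.rds")
  saveRDS(model, paths$model)
  say("fit: best CV MAE %.2f", min(model$cv$cv_mae))

  curves <- stage("interpret", {
    rows_obs <- sp$train[!is.na(sp$train$plain_water), , drop = FALSE]
    list(pdp = pdp_ice(model, rows_obs, "plain_water"),
         ale = ale(model, rows_obs, "plain_water"))
  })
  paths$pdp <- file.path(out_dir, "pdp_plain_water.csv")
  paths$ale <- file.path(out_dir, "ale_plain_water.csv")
  write_curve(curves$pdp, paths$pdp); write_curve(curves$ale, paths$ale)

  advice <- stage("advise", advise_testset(model, sp$test, config$constraints))
  paths$advice <- file.path(out_dir, "advice.csv")
  write.csv(advice, paths$advice, row.names = FALSE)
  counts$advised_rows <- nrow(advice)
  counts$skipped_rows <- length(attr(advice, "skipped"))
  say("advise: %d advised, %d skipped", nrow(advice),
      length(attr(advice, "skipped")))

  report <- stage("score", compare_to_guidelines(sp$test, advice))
  paths$report <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(summary = report$summary,
                            n_classified = report$n_classified,
                            n_excluded = report$n_excluded),
                       paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  counts$classified_rows <- report$n_classified

  manifest <- structure(list(
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("hydroadvisor")),
    artifacts = lapply(paths, normalizePath),
    row_counts = counts,
    wall_time_s = times
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run", x$config_hash, "\n")
  for (nm in names(x$row_counts))
    cat(sprintf("  %s: %s\n", nm, x$row_counts[[nm]]))
  invisible(x)
}
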