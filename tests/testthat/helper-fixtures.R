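# Shared fixtures, built once per test run and memoised.

memo <- local({
  store <- new.env(parent = emptyenv())
  function(key, expr) {
    if (!exists(key, store)) assign(key, force(expr), store)
    get(key, store)
  }
})

noise_free_params <- function() physiology_params(uosm_noise_sd_log = 0)

# small mixed cohort with noise and missingness, for structural tests
small_cohort <- function() memo("small_cohort",
  generate_cohort(cohort_spec(n_participants = 120, seed = 42)))

# noise-free cohort + fitted surrogate shared by interpretation/advice tests
nf_fixture <- function() memo("nf_fixture", {
  co <- generate_cohort(cohort_spec(n_participants = 250, seed = 202,
                                    missing_fluid_fraction = 0.1),
                        noise_free_params())
  filt <- apply_eligibility_filters(co)
  sp <- split_by_participant(filt$rows, 0.75, seed = 202)
  feats <- prune_features(rank_features(sp$train, seed = 202), feature_policy())
  model <- fit_surrogate(sp$train, feats, learner = "xgboost",
                         n_search = 4, cv_folds = 3, seed = 202)
  list(cohort = co, split = sp, features = feats, model = model,
       params = noise_free_params())
})

# surrogate on the "actionable" feature set (no aggregate-intake aliases):
# aggregate totals mask the plain-water effect in overwrite-style PDPs, so
# interpretation checks inspect a model where water itself carries the signal
actionable_fixture <- function() memo("actionable_fixture", {
  fx <- nf_fixture()
  feats <- setdiff(fx$features,
                   c("total_fluid_intake", "total_water_intake",
                     "food_moisture_mL"))
  model <- fit_surrogate(fx$split$train, feats, learner = "xgboost",
                         n_search = 4, cv_folds = 3, seed = 303)
  list(split = fx$split, model = model, features = feats)
})

# full-scale noise-free fixture for closed-loop and oracle-agreement checks:
# ~600 participants as in the study's cohort scale
closed_loop_fixture <- function() memo("closed_loop_fixture", {
  co <- generate_cohort(cohort_spec(n_participants = 600, seed = 2024,
                                    missing_fluid_fraction = 0.1),
                        noise_free_params())
  filt <- apply_eligibility_filters(co)
  sp <- split_by_participant(filt$rows, 0.75, seed = 2024)
  feats <- prune_features(rank_features(sp$train, seed = 2024), feature_policy())
  model <- fit_surrogate(sp$train, feats, learner = "xgboost",
                         n_search = 8, cv_folds = 3, seed = 2024)
  eligible <- sp$test[!is.na(sp$test$plain_water) &
                        !is.na(sp$test$total_fluid_intake), ]
  advice <- advise_testset(model, eligible)
  list(split = sp, model = model, eligible = eligible, advice = advice,
       params = noise_free_params())
})

# true (noise-free) urine osmolality after moving a record's plain water to w,
# with the same TFI/TWI coupling the advisor applies
true_uosm_at_water <- function(record, w, params) {
  shifted <- record
  delta <- w - record$plain_water
  shifted$plain_water <- w
  shifted$total_fluid_intake <- record$total_fluid_intake + delta
  shifted$total_water_intake <- record$total_water_intake + delta
  forward_uosm(shifted, params, noise_draw = 0)
}

# worked advice examples published for four test-set individuals
# (original/optimized urine osmolality, plain water, total fluid intake)
published_advice_rows <- function() {
  data.frame(
    age = c(20, 42, 20, 26),
    height = c(161, 160, 178, 181),
    weight = c(67, 67, 68.3, 75.2),
    sex = c("female", "female", "male", "male"),
    uosm_orig = c(1139, 1020, 750, 330),
    uosm_opt = c(492, 505, 501, 498),
    water_orig = c(500, 250, 1500, 2000),
    water_opt = c(1298, 1313, 1750, 1298),
    tfi_orig = c(1200, 1000, 2172, 4115),
    tfi_opt = c(1998, 2063, 2422, 3413)
  )
}
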