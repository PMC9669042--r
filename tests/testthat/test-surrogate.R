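test_that("mae matches its printed formula, hand cases and a loop oracle", {
  expect_equal(mae(c(500, 600), c(480, 620)), 20)
  x <- rnorm(10)
  expect_equal(mae(x, x), 0)
  expect_error(mae(1:3, 1:2), "length mismatch")
  expect_error(mae(c(1, NA), c(1, 2)), "missing")

  withr::with_seed(99, {
    a <- rnorm(1000, 500, 100); p <- rnorm(1000, 500, 100)
  })
  oracle <- 0
  for (i in seq_along(a)) oracle <- oracle + abs(a[i] - p[i])
  oracle <- oracle / length(a)
  expect_equal(mae(a, p), oracle)
  expect_equal(mae(a, p), mae(p, a))
})

test_that("feature ranking recovers planted structure", {
  withr::with_seed(21, {
    n <- 600
    df <- data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      plain_water = runif(n, 0, 4000),
      weight = runif(n, 50, 100),
      noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n), noise4 = rnorm(n)
    )
    df$urine_osm <- 10 * df$weight * 1000 / (df$plain_water + 1500)
  })
  imp <- rank_features(df, seed = 1)
  expect_equal(sum(imp$fractional_gain), 1, tolerance = 1e-9)
  expect_true(all(imp$fractional_gain >= 0))
  expect_setequal(imp$rank, seq_len(nrow(imp)))
  expect_setequal(head(imp$feature, 2), c("plain_water", "weight"))
})

test_that("a single dominant signal takes most of the gain", {
  withr::with_seed(22, {
    n <- 800
    df <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                     signal = runif(n), n1 = rnorm(n), n2 = rnorm(n),
                     n3 = rnorm(n))
    df$urine_osm <- 500 + 400 * df$signal + rnorm(n, sd = 5)
  })
  imp <- rank_features(df, seed = 1)
  expect_equal(imp$feature[1], "signal")
  expect_gt(imp$fractional_gain[1], 0.5)
})

test_that("a duplicated column splits its gain with the original", {
  withr::with_seed(23, {
    n <- 500
    df <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                     x = runif(n), z = rnorm(n))
    df$urine_osm <- 300 + 300 * df$x + 50 * df$z + rnorm(n, sd = 10)
  })
  imp1 <- rank_features(df, seed = 1)
  df$x_dup <- df$x
  imp2 <- rank_features(df, seed = 1)
  g1 <- imp1$fractional_gain[imp1$feature == "x"]
  g2 <- sum(imp2$fractional_gain[imp2$feature %in% c("x", "x_dup")])
  expect_lt(abs(g2 - g1) / g1, 0.2)
})

test_that("ranking rejects a constant response", {
  df <- data.frame(participant_id = sprintf("P%02d", 1:30),
                   a = rnorm(30), b = rnorm(30), urine_osm = 500)
  expect_error(rank_features(df), "degenerate response")
})

test_that("feature pruning follows the policy", {
  candidates <- c(sprintf("v%03d", 1:105), "urine_volume", "n_micturitions")
  allowed23 <- sprintf("v%03d", 1:23)
  pol <- feature_policy(allowed_features = allowed23)
  expect_equal(prune_features(candidates, pol), allowed23)  # 23 of 107 kept

  pol2 <- feature_policy(excluded_features = character(0),
                         allowed_features = allowed23)
  expect_equal(prune_features(candidates, pol2), allowed23)

  expect_error(feature_policy(allowed_features = c("v001", "urine_volume")),
               "excluded")
  expect_error(prune_features(c("urine_volume", "n_micturitions"),
                              feature_policy()), "no features remain")
  # urine-derived features never survive the default policy
  expect_false(any(c("urine_volume", "n_micturitions") %in%
                     prune_features(candidates, feature_policy())))
})

test_that("cross-validation folds never split a participant", {
  ids <- rep(sprintf("P%03d", 1:40), times = rep(1:4, 10))
  folds <- hydroadvisor:::grouped_folds(ids, 5, seed = 1)
  expect_true(all(tapply(folds, ids, function(f) length(unique(f))) == 1L))
  expect_equal(sort(unique(folds)), 1:5)
})

test_that("a deep tree model memorizes its training set", {
  co <- small_cohort()
  rows <- co[!is.na(co$plain_water), ][1:50, ]
  space <- surrogate_search_space()
  space$max_depth <- c(8L, 8L); space$nrounds <- c(400L, 400L)
  space$eta <- c(0.3, 0.3); space$subsample <- c(1, 1)
  m <- fit_surrogate(rows, c("plain_water", "weight", "age", "height"),
                     n_search = 1, cv_folds = 2, seed = 1, search = space)
  expect_lt(m$training_mae, 5)
  expect_lt(mae(rows$urine_osm, predict(m, rows)), 5)
})

test_that("the noise-free surrogate recovers the forward model accurately", {
  co <- generate_cohort(cohort_spec(n_participants = 300, seed = 77,
                                    missing_fluid_fraction = 0),
                        noise_free_params())
  sp <- split_by_participant(apply_eligibility_filters(co)$rows, seed = 77)
  feats <- prune_features(rank_features(sp$train, seed = 77))
  m <- fit_surrogate(sp$train, feats, n_search = 6, cv_folds = 3, seed = 77)
  test_mae <- mae(sp$test$urine_osm, predict(m, sp$test))
  expect_lt(test_mae, 0.1 * sd(sp$test$urine_osm))
})

test_that("both learners predict finitely on records with missing intake", {
  fx <- nf_fixture()
  rows_na <- fx$split$test
  rows_na$plain_water[1:5] <- NA
  p <- predict(fx$model, rows_na)
  expect_true(all(is.finite(p)))

  rf <- fit_surrogate(fx$split$train, fx$features, learner = "ranger",
                      n_search = 2, cv_folds = 2, seed = 1)
  expect_true(all(is.finite(predict(rf, rows_na))))
})

test_that("an all-missing feature column is dropped with a warning", {
  fx <- nf_fixture()
  tr <- fx$split$train
  tr$ghost <- NA_real_
  expect_warning(
    m <- fit_surrogate(tr, c(fx$features, "ghost"), n_search = 1,
                       cv_folds = 2, seed = 1),
    "all-missing")
  expect_false("ghost" %in% m$features)
})

test_that("learner comparison repeats splits and reports stability", {
  co <- generate_cohort(cohort_spec(n_participants = 120, seed = 31,
                                    missing_fluid_fraction = 0),
                        noise_free_params())
  rows <- apply_eligibility_filters(co)$rows
  feats <- c("plain_water", "total_fluid_intake", "total_water_intake",
             "weight", "height", "age", "sex")
  rep5 <- compare_learners(rows, c("xgboost", "ranger"), feats,
                           n_repeats = 5, n_search = 2, cv_folds = 2, seed = 8)
  expect_equal(dim(rep5$mae), c(2L, 5L))
  expect_true(all(is.finite(rep5$mae)))
  expect_true(all(is.finite(rep5$summary$mean_mae)))
  expect_true(all(is.finite(rep5$summary$sd_mae)))
  expect_equal(rep5$summary$mean_mae, unname(rowMeans(rep5$mae)))

  rep1 <- compare_learners(rows, "xgboost", feats, n_repeats = 1,
                           n_search = 2, cv_folds = 2, seed = 8)
  expect_true(rep1$sd_undefined)
  expect_true(is.na(rep1$summary$sd_mae))
})

test_that("shuffling the response can only hurt the test error", {
  fx <- nf_fixture()
  sp <- fx$split
  shuffled <- sp$train
  shuffled$urine_osm <- withr::with_seed(1, sample(shuffled$urine_osm))
  m_bad <- fit_surrogate(shuffled, fx$features, n_search = 2, cv_folds = 2,
                         seed = 1)
  mae_bad <- mae(sp$test$urine_osm, predict(m_bad, sp$test))
  mae_good <- mae(sp$test$urine_osm, predict(fx$model, sp$test))
  expect_gte(mae_bad, mae_good)
})
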