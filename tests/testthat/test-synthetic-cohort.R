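test_that("forward model is the osmolar-clearance ratio when noise is zero", {
  # weight 60 kg at 10 mOsm/kg/day -> 600 mOsm load; no dietary terms
  params <- physiology_params(dietary_osmole_coefficients = numeric(0),
                              uosm_noise_sd_log = 0, uosm_ceiling = 2000)
  rec <- data.frame(weight = 60, total_water_intake = 1200 - 300 + 900)
  expect_equal(forward_uosm(rec, params), 600 / 1.2)  # 500 mOsm/kg
  rec$total_water_intake <- 500 - 300 + 900
  expect_equal(forward_uosm(rec, params), 600 / 0.5)  # 1200 mOsm/kg
})

test_that("forward model is homogeneous in osmolar load before clipping", {
  params <- physiology_params(dietary_osmole_coefficients = numeric(0),
                              uosm_noise_sd_log = 0, uosm_ceiling = 1e6)
  rec1 <- data.frame(weight = 40, total_water_intake = 2000)
  rec2 <- data.frame(weight = 80, total_water_intake = 2000)
  expect_equal(forward_uosm(rec2, params), 2 * forward_uosm(rec1, params))
})

test_that("noise-free forward model decreases strictly along a water sweep", {
  params <- noise_free_params()
  twi <- seq(1000, 4000, by = 100)
  recs <- data.frame(weight = 70, total_water_intake = twi,
                     protein_g = 80, sodium_mg = 2800)
  u <- forward_uosm(recs, params)
  expect_true(all(diff(u) <= 0))  # non-increasing throughout
  unclipped <- u < params$uosm_ceiling & u > params$uosm_floor
  expect_true(all(diff(u[unclipped]) < 0))  # strict away from the clip bounds
  expect_true(all(u >= params$uosm_floor & u <= params$uosm_ceiling))
})

test_that("physiology parameter validation rejects inconsistent settings", {
  expect_error(physiology_params(uosm_floor = 1500), "uosm_floor")
  expect_error(physiology_params(food_water_fraction = 1.2), "food_water_fraction")
  expect_error(physiology_params(urine_volume_floor_mL = -10), "positive")
  expect_error(forward_uosm(data.frame(weight = 70), physiology_params()),
               "required fields")
})

test_that("cohort generation is reproducible and respects the spec", {
  spec <- cohort_spec(n_participants = 100, seed = 7)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1, co2)

  expect_equal(length(unique(co1$participant_id)), 100)
  # visit counts per participant match the drawn schedule
  expect_true(all(table(co1$participant_id) %in% 1:4))
  # marginals inside configured ranges
  expect_true(all(co1$age >= 19 & co1$age <= 51))
  expect_true(all(co1$bmi >= 18 & co1$bmi <= 30))
  ok <- !is.na(co1$plain_water)
  expect_true(all(co1$plain_water[ok] <= co1$total_fluid_intake[ok]))
  expect_true(all(co1$total_fluid_intake[ok] <= co1$total_water_intake[ok]))
  expect_true(all(co1$urine_osm > 0))
  # BMI consistent with height/weight within rounding
  expect_true(all(abs(co1$bmi - co1$weight / (co1$height / 100)^2) <= 0.1))
  # time-invariant fields shared within participant
  by_part <- split(co1[, c("sex", "height")], co1$participant_id)
  expect_true(all(vapply(by_part, function(d) nrow(unique(d)) == 1L, logical(1))))
})

test_that("female share matches the configured fraction within binomial bounds", {
  co <- generate_cohort(cohort_spec(n_participants = 500, seed = 3))
  share <- mean(tapply(co$sex, co$participant_id, `[`, 1) == "female")
  half_width <- 2.576 * sqrt(0.63 * 0.37 / 500)  # 99% binomial interval
  expect_gt(share, 0.63 - half_width)
  expect_lt(share, 0.63 + half_width)
})

test_that("missingness is participant-level and obeys the configured fraction", {
  co0 <- generate_cohort(cohort_spec(n_participants = 80, seed = 5,
                                     missing_fluid_fraction = 0))
  expect_false(anyNA(co0$plain_water))
  expect_false(anyNA(co0$total_fluid_intake))

  co <- generate_cohort(cohort_spec(n_participants = 200, seed = 5,
                                    missing_fluid_fraction = 0.25))
  miss_by_part <- tapply(is.na(co$plain_water), co$participant_id, mean)
  expect_true(all(miss_by_part %in% c(0, 1)))  # all-or-none per participant
  expect_gt(mean(miss_by_part == 1), 0.25 - 3 * sqrt(0.25 * 0.75 / 200))
  expect_lt(mean(miss_by_part == 1), 0.25 + 3 * sqrt(0.25 * 0.75 / 200))
})

test_that("enlarging the cohort leaves existing participants untouched", {
  co50 <- generate_cohort(cohort_spec(n_participants = 50, seed = 9))
  co60 <- generate_cohort(cohort_spec(n_participants = 60, seed = 9))
  keep <- co60$participant_id %in% unique(co50$participant_id)
  expect_identical(co50, structure(co60[keep, , drop = FALSE],
                                   row.names = seq_len(sum(keep))))
})

test_that("outlier injection creates the requested filter-exercising records", {
  co <- generate_cohort(cohort_spec(n_participants = 50, seed = 1,
                                    missing_fluid_fraction = 0))
  out <- inject_outliers(co, n_dehydrated = 3, n_low_tfi = 2, seed = 1)
  expect_equal(sum(out$plasma_osm > 310), 3)
  expect_equal(sum(out$total_fluid_intake < 200), 2)
  expect_true(all(out$plain_water <= out$total_fluid_intake))

  expect_identical(inject_outliers(co, 0, 0), co)
  expect_error(inject_outliers(co[1:3, ], 3, 2, seed = 1), "not enough")
})

test_that("injected outliers are exactly what the eligibility filters remove", {
  co <- generate_cohort(cohort_spec(n_participants = 50, seed = 1,
                                    missing_fluid_fraction = 0))
  clean <- apply_eligibility_filters(co)$rows  # baseline passes all filters
  out <- inject_outliers(clean, 3, 2, seed = 4)
  res <- apply_eligibility_filters(out)
  expect_equal(nrow(res$rows), nrow(clean) - 5)
  expect_equal(unname(res$report$removed_by_reason[["plasma_osm"]]), 3)
  expect_equal(unname(res$report$removed_by_reason[["tfi_min"]]), 2)
})

test_that("cohort CSV round-trips through the schema-sidecar writer", {
  co <- small_cohort()[1:25, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_true(file.exists(paste0(path, ".schema.json")))
  back <- read_cohort(path)
  expect_equal(back$urine_osm, co$urine_osm)
  expect_equal(is.na(back$plain_water), is.na(co$plain_water))
})
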