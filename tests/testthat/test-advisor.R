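linear_stub <- function(intercept = 800, slope = -0.1) {
  function_model(function(d) intercept + slope * d$plain_water,
                 c("plain_water", "total_fluid_intake"))
}

stub_record <- function(water = 1000, tfi = 1800, twi = 2200) {
  data.frame(plain_water = water, total_fluid_intake = tfi,
             total_water_intake = twi, weight = 70)
}

test_that("water_response slices without mutating the record", {
  rec <- stub_record()
  m <- linear_stub()
  # identity slice at the record's own water
  expect_equal(as.numeric(water_response(m, rec, rec$plain_water)),
               as.numeric(predict(m, rec)))
  # linear stub: response linear with the stub's slope
  w <- c(0, 1000, 2000, 4000)
  r <- as.numeric(water_response(m, rec, w))
  expect_equal(diff(r) / diff(w), rep(-0.1, 3))
  expect_equal(rec, stub_record())  # untouched
})

test_that("water_response shifts TFI and total water by the water delta", {
  probe <- function_model(function(d) d$total_fluid_intake + d$total_water_intake,
                          c("plain_water", "total_fluid_intake",
                            "total_water_intake"))
  rec <- stub_record(water = 1000, tfi = 1800, twi = 2200)
  out <- as.numeric(water_response(probe, rec, c(1000, 1500)))
  expect_equal(out[2] - out[1], 2 * 500)
  # a record violating plain_water <= TFI is clamped and flagged
  bad <- stub_record(water = 1000, tfi = 1100)
  r <- water_response(probe, bad, 2000)  # shifted TFI 2100 >= water: fine
  expect_false(attr(r, "clamped"))
})

test_that("the grid oracle is exhaustive and handles boundary cases", {
  cons <- advisor_constraints()
  m <- linear_stub(810, -0.1)  # crosses 500 at w = 3100
  rec <- stub_record()
  # two-point grid: the better endpoint wins
  r2 <- brute_force_invert(m, rec, cons, step_mL = 4050)
  expect_equal(r2$optimized_water, 4050)  # response 405, inside band
  # coarse grid: the grid point whose response is nearest the target
  r <- brute_force_invert(m, rec, cons, step_mL = 400)
  cand <- seq(0, 4050, by = 400)
  resp <- 810 - 0.1 * cand
  expect_equal(r$optimized_water, cand[which.min(abs(resp - 500))])
  # band unreachable: decreasing response always above 625
  m_hi <- linear_stub(5000, -0.1)
  r_inf <- brute_force_invert(m_hi, rec, cons, step_mL = 50)
  expect_equal(r_inf$solver_status, "infeasible")
  expect_equal(r_inf$optimized_water, 4050)
  expect_false(r_inf$feasible)
})

test_that("the solver lands on the target for a smooth monotone response", {
  cons <- advisor_constraints()
  m <- linear_stub(810, -0.1)
  rec <- stub_record()
  r <- recommend_water(m, rec, cons)
  expect_equal(r$optimized_water, 3100, tolerance = 0.01)
  expect_equal(r$predicted_uosm_at_optimum, 500, tolerance = 1)
  expect_true(r$feasible)
  expect_equal(r$solver_status, "converged")
  expect_equal(r$optimized_tfi - r$original_tfi,
               r$optimized_water - r$original_water)
})

test_that("advice direction follows the sign of the hydration deficit", {
  fx <- nf_fixture()
  cons <- advisor_constraints()
  rows <- fx$split$test[!is.na(fx$split$test$plain_water), ]
  preds <- predict(fx$model, rows)
  over <- which(preds > cons$uosm_max)[1:5]
  under <- which(preds < cons$uosm_min)[1:5]
  for (i in over[!is.na(over)]) {
    r <- recommend_water(fx$model, rows[i, ], cons)
    expect_gt(r$optimized_water, r$original_water)
  }
  for (i in under[!is.na(under)]) {
    r <- recommend_water(fx$model, rows[i, ], cons)
    expect_lt(r$optimized_water, r$original_water)
  }
})

test_that("the solver matches the grid oracle on fitted surrogates", {
  fx <- nf_fixture()
  cons <- advisor_constraints()
  rows <- fx$split$test[!is.na(fx$split$test$plain_water), ][1:30, ]
  for (i in seq_len(nrow(rows))) {
    rec <- recommend_water(fx$model, rows[i, ], cons)
    orc <- brute_force_invert(fx$model, rows[i, ], cons, step_mL = 50)
    obj <- function(r) {
      v <- max(0, cons$uosm_min - r$predicted_uosm_at_optimum,
               r$predicted_uosm_at_optimum - cons$uosm_max)
      (r$predicted_uosm_at_optimum - cons$target_uosm)^2 + 1e6 * v^2
    }
    agree <- obj(rec) <= obj(orc) + 1e-6 ||
      abs(rec$optimized_water - orc$optimized_water) <= 50
    expect_true(agree)
  }
})

test_that("a model without plain water among its features is not actionable", {
  m <- function_model(function(d) d$weight * 10, "weight")
  expect_error(recommend_water(m, stub_record()), "non-actionable")
})

test_that("test-set advising skips undefined rows and keeps the coupling", {
  fx <- nf_fixture()
  rows <- fx$split$test[1:40, ]
  rows$plain_water[3] <- NA
  adv <- advise_testset(fx$model, rows)
  expect_true(all(attr(adv, "skipped") %in% which(is.na(rows$plain_water) |
                                                    is.na(rows$total_fluid_intake))))
  expect_equal(nrow(adv) + length(attr(adv, "skipped")), nrow(rows))
  expect_equal(adv$optimized_tfi - adv$original_tfi,
               adv$optimized_water - adv$original_water)
  expect_true(all(adv$optimized_water >= 0 & adv$optimized_water <= 4050))
  # feasible flag is exactly band membership of the predicted optimum
  band <- adv$predicted_uosm_at_optimum >= 375 &
    adv$predicted_uosm_at_optimum <= 625
  expect_equal(adv$feasible, band)

  empty <- advise_testset(fx$model, rows[0, ])
  expect_equal(nrow(empty), 0L)
})
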