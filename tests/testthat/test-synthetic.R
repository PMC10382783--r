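test_that("generated cohorts match the requested prevalence and structure", {
  spec <- base_cfg$cohort$reference
  spec$n_patients <- 10000L
  cohort <- generate_cohort(spec, seed = 14)
  expect_identical(nrow(cohort), 10000L)
  phat <- mean(cohort$error_flag)
  expect_lt(abs(phat - 0.653), 3 * sqrt(0.653 * 0.347 / 10000))
  # cost and decrement present exactly on the error branch
  expect_identical(is.na(cohort$error_cost), !cohort$error_flag)
  expect_identical(is.na(cohort$utility_decrement), !cohort$error_flag)
  expect_true(all(cohort$contact_minutes >= 0))
  expect_true(all(cohort$error_cost[cohort$error_flag] >= 0))
  # moment matching of the minutes marginal
  expect_equal(mean(cohort$contact_minutes), 40.6, tolerance = 0.03)
  expect_equal(sd(cohort$contact_minutes), 29.17, tolerance = 0.05)
})

test_that("degenerate cohort specs behave", {
  spec <- cohort_spec("reference", n_patients = 50, p_error = 0.5,
                      time_mean = 40, time_sd = 0, cost_mean = 1000,
                      cost_sd = 0, decrement_mean = -0.03, decrement_sd = 0)
  cohort <- generate_cohort(spec, seed = 15)
  expect_true(all(cohort$contact_minutes == 40))
  expect_true(all(cohort$error_cost[cohort$error_flag] == 1000))
  expect_true(all(cohort$utility_decrement[cohort$error_flag] == -0.03))
  one <- generate_cohort(cohort_spec("intervention", 1, 1, 70, 50, 600, 600,
                                     -0.02, 0.07), seed = 16)
  expect_identical(nrow(one), 1L)
  expect_true(one$error_flag && !is.na(one$error_cost))
  expect_error(cohort_spec("reference", 0, 0.5, 40, 29, 1000, 500, -0.03, 0.07),
               "n_patients")
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(base_cfg$cohort$intervention, seed = 17)
  b <- generate_cohort(base_cfg$cohort$intervention, seed = 17)
  expect_identical(a, b)
})

test_that("a large cohort recovers the arm parameters it was generated from", {
  spec <- base_cfg$cohort$reference
  spec$n_patients <- 20000L
  cohort <- generate_cohort(spec, seed = 18)
  est <- estimate_inputs_from_cohort(cohort, rate_per_minute = 0.9166972,
                                     n_boot = 500, seed = 18)
  expect_lt(abs(est$p_error$mean - 0.653), 3 * sqrt(0.653 * 0.347 / 20000))
  expect_lt(abs(est$error_cost$mean - 1091.12), 3 * est$error_cost$sd)
  expect_lt(abs(est$utility_decrement$mean - (-0.02906349626)),
            3 * est$utility_decrement$sd)
  expect_lt(abs(est$labour_cost$mean - 40.6 * 0.9166972),
            3 * est$labour_cost$sd)
  expect_identical(est$p_error$n, 20000L)
})

test_that("a cohort with no error cases degrades gracefully", {
  spec <- cohort_spec("reference", 20, 0, 40, 29, 1000, 500, -0.03, 0.07)
  cohort <- generate_cohort(spec, seed = 19)
  expect_warning(est <- estimate_inputs_from_cohort(cohort), "no error cases")
  expect_identical(est$p_error$mean, 0)
  expect_null(est$error_cost)
  expect_null(est$utility_decrement)
})

test_that("the end-to-end synthetic pipeline agrees with the base case", {
  cohort <- base_cfg$cohort
  cohort$reference$n_patients <- 5000L
  cohort$intervention$n_patients <- 5000L
  fit <- synthetic_pipeline(cohort, n_boot = 500, seed = 20)
  expect_identical(fit$incremental$dominance, "intervention_dominant")
  expect_lt(fit$incremental$icer, 0)
  expect_lt(fit$incremental$delta_cost, 0)
  # point estimates land near the generating values
  expect_equal(fit$outcomes$expected_cost[1], 749.71, tolerance = 0.1)
  expect_equal(fit$outcomes$expected_cost[2], 175.48, tolerance = 0.1)
})
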