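test_that("expected outcomes reproduce the published base case", {
  sc <- expected_outcome(base_cfg$reference)
  pact <- expected_outcome(base_cfg$intervention)
  expect_equal(round(sc$expected_cost, 2), 749.71)
  expect_equal(round(pact$expected_cost, 2), 175.48)
  expect_equal(round(sc$expected_effect, 9), -0.018978463)
  expect_equal(round(pact$expected_effect, 9), -0.003262228)
})

test_that("a zero error probability collapses to the labour-only branch", {
  arm <- list(p_error = 0, error_cost = 1000, labour_cost = 50,
              utility_decrement = -0.1)
  out <- expected_outcome(arm)
  expect_identical(out$expected_cost, 50)
  expect_identical(out$expected_effect, 0)
})

test_that("incremental analysis reproduces the published ICER and dominance", {
  fit <- cua(base_cfg)
  inc <- fit$incremental
  expect_equal(round(inc$delta_cost, 2), -574.23)
  expect_equal(round(inc$delta_effect, 9), 0.015716235)
  expect_equal(inc$icer, -36537.24, tolerance = 1e-6)
  expect_identical(inc$dominance, "intervention_dominant")
  tab <- base_case_table(fit)
  expect_identical(tab$strategy, c("SC", "PACT"))
  expect_identical(tab$cost, c(749.71, 175.48))
  expect_identical(tab$dominance[2], "intervention_dominant")
})

test_that("dominance follows the quadrant, never the ICER sign", {
  out <- function(c, e) list(expected_cost = c, expected_effect = e)
  # identical arms: equivalent, undefined ICER
  eq <- incremental(out(10, -0.1), out(10, -0.1))
  expect_false(eq$icer_defined)
  expect_true(is.na(eq$icer))
  expect_identical(eq$dominance, "equivalent")
  # costlier and less effective: reference dominates; ratio is also negative
  rd <- incremental(out(110, -0.11), out(10, -0.1))
  expect_identical(rd$dominance, "reference_dominant")
  expect_lt(rd$icer, 0)
  # both negative ICERs, opposite quadrants
  id <- incremental(out(10, -0.09), out(110, -0.1))
  expect_identical(id$dominance, "intervention_dominant")
  expect_lt(id$icer, 0)
  # trade-off quadrants
  expect_identical(incremental(out(110, -0.09), out(10, -0.1))$dominance,
                   "trade_off_ne")
  expect_identical(incremental(out(10, -0.11), out(110, -0.1))$dominance,
                   "trade_off_sw")
})

test_that("net monetary benefit follows lambda * effect - cost", {
  inc <- cua(base_cfg)$incremental
  expect_equal(nmb(inc$delta_cost, inc$delta_effect, 0), 574.23,
               tolerance = 1e-4)
  expect_equal(nmb(inc$delta_cost, inc$delta_effect, 45000),
               45000 * 0.015716235 + 574.22789, tolerance = 1e-6)
  expect_identical(nmb(0, 0, 12345), 0)
  expect_error(nmb(1, 1, -1), "lambda")
  # dominant intervention has positive NMB at every threshold
  lambdas <- seq(0, 100000, by = 5000)
  expect_true(all(nmb(inc$delta_cost, inc$delta_effect, lambdas) > 0))
})

test_that("expected cost is affine in each of its inputs", {
  cost_at <- function(p, c, l)
    expected_outcome(list(p_error = p, error_cost = c, labour_cost = l,
                          utility_decrement = -0.1))$expected_cost
  # zero second difference along each coordinate
  for (args in list(list(c(0.1, 0.2, 0.3), 100, 10),
                    list(0.5, c(100, 200, 300), 10),
                    list(0.5, 100, c(10, 20, 30)))) {
    grid <- do.call(Vectorize(cost_at), args)
    expect_equal(diff(diff(grid)), 0)
  }
})

test_that("coef and print expose the fitted model", {
  fit <- cua(base_cfg)
  cf <- coef(fit)
  expect_length(cf, 8)
  expect_identical(unname(cf["reference.p_error"]), 0.653)
  expect_output(print(fit), "intervention_dominant")
  expect_output(summary(fit), "Net monetary benefit")
})
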