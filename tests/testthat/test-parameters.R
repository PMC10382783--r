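test_that("packaged base case carries the published point estimates", {
  cfg <- base_cfg
  expect_identical(cfg$reference$p_error$mean, 0.653)
  expect_identical(cfg$intervention$p_error$mean, 0.139)
  expect_identical(cfg$reference$error_cost$mean, 1091.12)
  expect_identical(cfg$intervention$error_cost$mean, 638.73)
  expect_identical(cfg$reference$labour_cost$mean, 37.21)
  expect_identical(cfg$intervention$labour_cost$mean, 86.70)
  # full-precision decrements, not the 3-decimal summary rounding
  expect_identical(cfg$reference$utility_decrement$mean, -0.02906349626)
  expect_identical(cfg$intervention$utility_decrement$mean, -0.023469269)
  expect_equal(cfg$reference$error_cost$ci_low, 702.51)
  expect_equal(cfg$intervention$labour_cost$ci_high, 119.77)
  # PSA overrides are complete and valid
  expect_setequal(names(cfg$psa$overrides),
                  c("reference.p_error", "intervention.p_error",
                    "reference.error_cost", "intervention.error_cost",
                    "reference.labour_cost", "intervention.labour_cost",
                    "reference.utility_decrement",
                    "intervention.utility_decrement"))
  expect_equal(cfg$psa$overrides$reference.p_error$alpha, 372.96)
})

test_that("packaged configuration file loads to the base case", {
  path <- system.file("extdata", "base_case.yaml", package = "cuatree")
  expect_true(nzchar(path))
  cfg <- load_config(path)
  expect_identical(cfg$reference$p_error$mean, 0.653)
  expect_identical(cfg$intervention$p_error$mean, 0.139)
  expect_equal(cfg, base_cfg)
})

test_that("config round-trips through YAML and JSON", {
  cfg <- base_cfg
  cfg$reference$p_error$mean <- 0.5
  cfg$wtp <- c(0, 10000, 20000, 45000)  # irregular grid
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_config(cfg, path)
    expect_equal(load_config(path), cfg, info = ext)
    unlink(path)
  }
})

test_that("schema violations are rejected with the offending field named", {
  cfg_list <- yaml::read_yaml(system.file("extdata", "base_case.yaml",
                                          package = "cuatree"))
  # probability outside [0, 1]
  bad <- cfg_list
  bad$reference$p_error$mean <- 1.2
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, path)
  expect_error(load_config(path), "p_error")

  # non-increasing willingness-to-pay grid
  bad <- cfg_list
  bad$wtp <- c(0, 45000, 10000)
  yaml::write_yaml(bad, path)
  expect_error(load_config(path), "increasing")

  # unknown keys, top level and nested
  bad <- cfg_list
  bad$discounting <- 0.04
  yaml::write_yaml(bad, path)
  expect_error(load_config(path), "discounting")
  bad <- cfg_list
  bad$reference$p_error$stdev <- 0.1
  yaml::write_yaml(bad, path)
  expect_error(load_config(path), "stdev")

  # missing file
  expect_error(load_config(tempfile()), "not found")
  unlink(path)
})

test_that("point_estimate enforces its invariants", {
  expect_error(point_estimate(5, ci = c(6, 10)), "bracket")
  expect_error(point_estimate(5, sd = -1), "non-negative")
  expect_error(point_estimate(5, n = 0.5), "positive integer")
  pe <- point_estimate(5, sd = 1, ci = c(3, 8), n = 10)
  expect_identical(pe$ci_low, 3)
  expect_identical(pe$n, 10L)
})

test_that("arm and config constructors enforce sign and ordering invariants", {
  pe <- function(m, ...) point_estimate(m, ...)
  expect_error(arm_parameters("reference", pe(1.2), pe(1), pe(1), pe(-0.1)),
               "p_error")
  expect_error(arm_parameters("reference", pe(0.5), pe(-1), pe(1), pe(-0.1)),
               "error_cost")
  expect_error(arm_parameters("reference", pe(0.5), pe(1), pe(1), pe(0.1)),
               "utility_decrement")
  expect_error(model_config(base_cfg$reference, base_cfg$intervention,
                            wtp = c(0, 2, 1)), "increasing")
  expect_error(psa_settings(iterations = 0), "iterations")
  expect_error(dsa_settings(relative_variation = 1.5), "relative_variation")
})
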