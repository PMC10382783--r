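test_that("method-of-moments beta fits reproduce the published hyperparameters", {
  b_sc <- beta_from_moments(0.653, 0.2 / sqrt(101))
  expect_lt(rel_err(b_sc$alpha, 372.96), 0.001)
  expect_lt(rel_err(b_sc$beta, 198.19), 0.001)
  b_pact <- beta_from_moments(0.139, 0.2 / sqrt(108))
  expect_lt(rel_err(b_pact$alpha, 44.78), 0.001)
  expect_lt(rel_err(b_pact$beta, 277.36), 0.001)
  # symmetric mean gives alpha = beta and exact mean
  b <- beta_from_moments(0.5, 0.05)
  expect_equal(b$alpha, b$beta)
  expect_equal(dist_mean(b), 0.5)
  expect_error(beta_from_moments(0.5, 0.6), "too large")
})

test_that("method-of-moments gamma fits reproduce the published hyperparameters", {
  g_sc <- gamma_from_moments(1091.12, 220.92 / sqrt(1000))
  expect_lt(rel_err(g_sc$alpha, 24393.59), 0.001)
  expect_lt(rel_err(g_sc$beta, 0.04473), 0.001)
  g_pact <- gamma_from_moments(638.73, 205.76 / sqrt(1000))
  expect_lt(rel_err(g_pact$alpha, 9636.58), 0.001)
  expect_lt(rel_err(g_pact$beta, 0.06628), 0.001)
  expect_error(gamma_from_moments(-1, 1), "must be > 0")
})

test_that("distribution means round-trip to machine precision", {
  set.seed(5)
  for (i in 1:25) {
    m <- runif(1, 0.05, 0.95)
    se <- runif(1, 0.005, 0.4) * sqrt(m * (1 - m))
    expect_equal(dist_mean(beta_from_moments(m, se)), m)
    mc <- runif(1, 1, 5000); sec <- runif(1, 0.01, 1) * mc
    expect_equal(dist_mean(gamma_from_moments(mc, sec)), mc)
    d <- -runif(1, 0, 0.5)
    expect_equal(dist_mean(disutility_spec(d, runif(1, 0.001, 0.1))), d)
  }
})

test_that("the disutility construction shifts, fits and flips a gamma", {
  # SC decrement: gamma on 1 + |d|; hyperparameters near the published pair
  sp <- disutility_spec(-0.02906349626, 0.072 / sqrt(65))
  expect_identical(sp$family, "one_minus_gamma")
  expect_lt(rel_err(sp$alpha, 13279.82), 0.001)
  expect_equal(sp$alpha * sp$beta, 1.02906349626)
  # sampled decrements centre on the decrement
  set.seed(9)
  x <- sample_dist(sp, 20000)
  expect_equal(mean(x), -0.0291, tolerance = 0.01)
  # mass outside [-1, 0] is small (pgamma oracle: ~5.1e-4)
  outside <- pgamma(1, shape = sp$alpha, scale = sp$beta) +
    pgamma(2, shape = sp$alpha, scale = sp$beta, lower.tail = FALSE)
  expect_lt(outside, 1e-3)
  # zero decrement: draws centre on zero
  sp0 <- disutility_spec(0, 0.01)
  expect_equal(dist_mean(sp0), 0)
  expect_error(disutility_spec(0.1, 0.01), "<= 0")
})

test_that("derivation mode rebuilds the published beta/gamma set from moments", {
  specs <- build_psa_specs(base_cfg, mode = "derivation")
  published <- list(reference.p_error = c(372.96, 198.19),
                    intervention.p_error = c(44.78, 277.36),
                    reference.error_cost = c(24393.59, 0.04473),
                    intervention.error_cost = c(9636.58, 0.06628))
  for (id in names(published)) {
    expect_lt(rel_err(specs[[id]]$alpha, published[[id]][1]), 0.001)
    expect_lt(rel_err(specs[[id]]$beta, published[[id]][2]), 0.001)
  }
})

test_that("reproduction mode demands a complete override set", {
  cfg <- base_cfg
  cfg$psa$overrides$reference.p_error <- NULL
  expect_error(build_psa_specs(cfg, "reproduction"), "reference.p_error")
})

test_that("parameter sampling is seeded, independent and degenerate at se -> 0", {
  specs <- build_psa_specs(base_cfg)
  set.seed(4); d1 <- sample_parameters(specs, 50)
  set.seed(4); d2 <- sample_parameters(specs, 50)
  expect_identical(d1, d2)
  expect_identical(dim(d1), c(50L, 8L))
  # distribution-mean property at scale
  set.seed(6)
  p <- sample_dist(specs$reference.p_error, 10000)
  se <- sd(p) / sqrt(length(p))
  expect_lt(abs(mean(p) - 0.653), 3 * se + 1e-4)
  # tiny se collapses draws onto the mean
  tight <- gamma_from_moments(100, 1e-7)
  expect_equal(sample_dist(tight, 10), rep(100, 10), tolerance = 1e-6)
})

test_that("reproduction-mode PSA dominates everywhere, as published", {
  draws <- run_psa(base_cfg, n_iter = 1000, seed = 2)
  expect_identical(nrow(draws), 1000L)
  # every pair in the south-east quadrant
  expect_true(all(draws$delta_cost < 0 & draws$delta_effect > 0))
  # NMB positive for every draw even at a zero threshold
  expect_true(all(nmb(draws$delta_cost, draws$delta_effect, 0) > 0))
  # CEAC identically 1 on the whole 0-50,000 grid
  curve <- ceac(draws, seq(0, 50000, by = 1000))
  expect_true(all(curve$probability == 1))
  # Monte-Carlo mean of delta cost near the deterministic -574.23
  mc_se <- sd(draws$delta_cost) / sqrt(nrow(draws))
  expect_lt(abs(mean(draws$delta_cost) - (-574.23)), 3 * mc_se)
})

test_that("PSA is reproducible and mode/seed are recorded", {
  d1 <- run_psa(base_cfg, n_iter = 100, seed = 8)
  d2 <- run_psa(base_cfg, n_iter = 100, seed = 8)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  expect_identical(attr(d1, "mode"), "reproduction")
  expect_identical(attr(d1, "seed"), 8)
  fit <- cua(base_cfg)
  d3 <- simulate(fit, nsim = 100, seed = 8)
  expect_equal(as.data.frame(d3), as.data.frame(d1))
})

test_that("degenerate distributions collapse the PSA onto the base case", {
  cfg <- base_cfg
  ids <- names(cfg$psa$overrides)
  cfg$psa$overrides <- setNames(lapply(ids, function(id) {
    m <- coef(cua(base_cfg))[[id]]
    sp <- if (grepl("p_error", id)) beta_from_moments(m, 1e-8)
          else if (grepl("utility_decrement", id)) disutility_spec(m, 1e-8)
          else gamma_from_moments(m, 1e-8)
    list(family = sp$family, alpha = sp$alpha, beta = sp$beta)
  }), ids)
  draws <- run_psa(cfg, n_iter = 20, seed = 10)
  inc <- cua(base_cfg)$incremental
  expect_equal(draws$delta_cost, rep(inc$delta_cost, 20), tolerance = 1e-4)
  expect_equal(draws$delta_effect, rep(inc$delta_effect, 20),
               tolerance = 1e-4)
})

test_that("CEAC is monotone when every draw gains effect, with a strict tie rule", {
  draws <- run_psa(base_cfg, n_iter = 500, seed = 12)
  stopifnot(all(draws$delta_effect > 0))
  curve <- ceac(draws, seq(0, 100000, by = 2500))
  expect_true(all(diff(curve$probability) >= 0))
  # a draw with NMB exactly zero counts as not cost-effective
  fake <- structure(data.frame(iteration = 1L, delta_cost = 100,
                               delta_effect = 0.01),
                    class = c("cua_psa", "data.frame"))
  expect_identical(ceac(fake, 10000)$probability, 0)
  expect_identical(ceac(fake, 10001)$probability, 1)
})
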