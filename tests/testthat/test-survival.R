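test_that("surviving fraction from counts, plating efficiency and SE", {
  expect_equal(surviving_fraction(30, 500, 0.4)$sf, 0.15)
  expect_equal(surviving_fraction(200, 500, 0.4)$sf, 1)
  expect_equal(surviving_fraction(0, 500, 0.4)$sf, 0)
  sf <- surviving_fraction(30, 500, 0.4)
  p <- 30 / 500
  expect_equal(sf$se, sqrt(p * (1 - p) / 500) / 0.4)
  expect_error(surviving_fraction(30, 500, 0), "pe")
  expect_error(surviving_fraction(600, 500, 0.4), "colonies")
})

test_that("noise-free LQ and linear curves are recovered exactly", {
  d <- c(0.5, 1, 2, 4, 5, 6, 8, 10)
  sf <- exp(-0.21 * d - 0.05 * d^2)
  fit <- fit_survival(d, sf, "LQ")
  expect_equal(fit$alpha, 0.21, tolerance = 1e-6)
  expect_equal(fit$beta, 0.05, tolerance = 1e-6)
  expect_false(fit$alpha_at_bound)

  sf_lin <- exp(-0.87 * d)
  fl <- fit_survival(d, sf_lin, "linear")
  expect_equal(fl$alpha, 0.87, tolerance = 1e-9)
  expect_true(is.na(fl$beta))
})

test_that("the non-negativity constraint pins alpha for curvature-only data", {
  # survival whose unconstrained linear coefficient is negative; the
  # constrained fit reports alpha = 0 at the bound
  d <- c(1, 2, 4, 6, 8)
  sf <- exp(0.05 * d - 0.12 * d^2)
  fit <- fit_survival(d, sf, "LQ")
  expect_true(fit$alpha_at_bound)
  expect_equal(fit$alpha, 0)
  expect_true(is.na(fit$alpha_se))
  # boundary solution: beta = sum(d^2 y)/sum(d^4) with the negative
  # linear trend folded in
  expect_equal(fit$beta, sum(d^2 * -log(sf)) / sum(d^4), tolerance = 1e-9)
})

test_that("four-point photon data fit agrees with the brute-force oracle", {
  d <- c(2, 4, 6, 8)
  sf <- c(0.60, 0.15, 0.043, 0.036)
  fit <- fit_survival(d, sf, "LQ")
  oracle <- lq_grid_oracle(d, sf)
  expect_equal(fit$alpha, unname(oracle["alpha"]), tolerance = 1e-4)
  expect_equal(fit$beta, unname(oracle["beta"]), tolerance = 1e-4)
})

test_that("degenerate survival inputs are rejected", {
  expect_error(fit_survival(c(1, 2), c(0.5, 0.3), "LQ"), "3 distinct")
  expect_error(fit_survival(c(1, 1), c(0.5, 0.45), "linear"), "2 distinct")
  expect_warning(
    fit_survival(c(1, 2, 4, 6), c(0.5, 0.2, 0.05, 0), "LQ"), "SF = 0")
  expect_error(
    suppressWarnings(fit_survival(c(1, 2, 4), c(0, 0, 0), "LQ")),
    "no usable")
})

test_that("dose_at_survival inverts the LQ curve", {
  expect_equal(dose_at_survival(log(10), 0.1), 1)
  expect_equal(dose_at_survival(0.21, 0.1, beta = 0.05), 5.004,
               tolerance = 1e-4)
  expect_equal(dose_at_survival(0.21, 1, beta = 0.05), 0)
  expect_error(dose_at_survival(0, 0.1, beta = 0), "flat")
  # round trip at arbitrary doses
  d <- c(0.5, 1, 2, 4, 5, 6, 8, 10)
  fit <- fit_survival(d, exp(-0.21 * d - 0.05 * d^2), "LQ")
  for (D in c(0.7, 2.3, 9.5)) {
    expect_equal(dose_at_survival(fit, sf_model(fit, D)), D,
                 tolerance = 1e-6)
  }
  # monotone decreasing in alpha and beta
  expect_gt(dose_at_survival(0.1, 0.1, beta = 0.05),
            dose_at_survival(0.2, 0.1, beta = 0.05))
  expect_gt(dose_at_survival(0.21, 0.1, beta = 0.01),
            dose_at_survival(0.21, 0.1, beta = 0.05))
})

test_that("RBE ratios match the printed endpoint arithmetic", {
  expect_equal(rbe(5.1, 2.6), 1.96, tolerance = 0.005)
  expect_equal(rbe(17.8, 3.3), 5.39, tolerance = 0.005)
  expect_equal(rbe(4, 4), 1)
  # invariant under common dose rescaling
  expect_equal(rbe(5.1, 2.6), rbe(2 * 5.1, 2 * 2.6))
  expect_error(rbe(0, 1), "> 0")
})

test_that("alpha/beta ratio with delta-method SE and edge flags", {
  d <- c(0.5, 1, 2, 4, 5, 6, 8, 10)
  fit <- fit_survival(d, exp(-0.21 * d - 0.05 * d^2), "LQ")
  abr <- alpha_beta_ratio(fit)
  expect_equal(abr$ratio, 4.2, tolerance = 1e-4)
  expect_false(abr$unbounded)
  # alpha pinned at zero -> ratio 0
  sfq <- exp(-0.12 * d^2) * rep(c(1.03, 0.97), 4)
  fq <- fit_survival(d, sfq, "LQ")
  expect_equal(alpha_beta_ratio(fq)$ratio, 0)
  # beta at zero -> unbounded
  flin <- fit_survival(d, exp(-0.87 * d) * rep(c(1.01, 0.99), 4), "LQ")
  if (flin$beta == 0) {
    expect_true(alpha_beta_ratio(flin)$unbounded)
  }
  expect_error(alpha_beta_ratio(fit_survival(d, exp(-0.87 * d), "linear")),
               "LQ")
})

test_that("count-level Poisson fits estimate PE and match the LS fit broadly", {
  cfg <- sim_config(seed = 31)
  dat <- simulate_clonogenic(cfg)
  fit <- fit_survival_counts(dat$dose_Gy, dat$colonies, dat$seeded, "LQ")
  expect_lt(abs(fit$pe - 0.4), 0.05)
  expect_lt(abs(fit$alpha - 0.21), 0.15)
  expect_lt(abs(fit$beta - 0.05), 0.03)
  # degenerate inputs
  expect_error(
    fit_survival_counts(c(1, 2, 4), c(10, 5, 2), 500, "LQ"), "control")
  expect_error(
    fit_survival_counts(c(0, 1, 2, 4), c(200, 0, 0, 0), 500, "LQ"),
    "zero colonies")
  # non-negativity: increasing counts with dose pin the response
  expect_error(
    fit_survival_counts(c(0, 0, 1, 2, 4), c(50, 60, 80, 120, 200), 500,
                        "linear"),
    "negative alpha")
})

test_that("Poisson-noise LQ fits cover the truth at nominal rates", {
  # 3 replicates x 8 doses, 500 seeded, pe 0.4, alpha 0.21, beta 0.05;
  # 95% Wald intervals should cover the truth in >= 90% of seeded runs
  n_runs <- 200
  cov_a <- cov_b <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- sim_config(seed = i)
    dat <- simulate_clonogenic(cfg)
    fit <- fit_survival_counts(dat$dose_Gy, dat$colonies, dat$seeded, "LQ")
    cov_a[i] <- !is.na(fit$alpha_se) &&
      abs(fit$alpha - cfg$alpha) <= 1.96 * fit$alpha_se
    cov_b[i] <- !is.na(fit$beta_se) &&
      abs(fit$beta - cfg$beta) <= 1.96 * fit$beta_se
  }
  expect_gte(mean(cov_a), 0.9)
  expect_gte(mean(cov_b), 0.9)
})
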