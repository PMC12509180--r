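test_that("noise-free factorial data are interpolated exactly", {
  d <- build_design(1, 3, seed = 1)
  x <- simulate_experiment(d, effect_scenario("main_only", 10),
                           variance_components(0, 0, 0), seed = 1)
  fit <- fit_lmm(x, "biomass_g", full_factorial)
  cf <- coef(fit)
  expect_equal(unname(cf["(Intercept)"]), 100, tolerance = 1e-10)
  expect_equal(unname(cf[c("insecticide", "fungicide", "molluscicide")]),
               c(10, 10, 10), tolerance = 1e-10)
  expect_equal(unname(cf[grep(":", names(cf))]), rep(0, 4), tolerance = 1e-8)
  expect_equal(unname(fit$varcomp["residual"]), 0, tolerance = 1e-8)
})

test_that("fixed estimates on balanced data equal the normal-equations oracle", {
  x <- sim_fixture(n_sites = 1, family = "superadditive", effect_pct = 10,
                   seed = 31)
  # columns arranged in the fitted model's term order
  X <- cbind(1, encode_treatments(x, "indicator")[, c("i", "f", "m", "i:f",
                                                      "i:m", "f:m", "i:f:m")])
  beta_hat <- ols_oracle(X, x$biomass_g)

  ols_fit <- fit_lmm(x, "biomass_g", full_factorial)
  expect_equal(unname(coef(ols_fit)), unname(beta_hat), tolerance = 1e-8)

  # with a balanced block random intercept the fixed part is unchanged
  mix_fit <- fit_lmm(x, "biomass_g", full_factorial,
                     random = "block_id", method = "reml")
  expect_equal(unname(coef(mix_fit)), unname(beta_hat), tolerance = 1e-8)
})

test_that("row order never affects the fit", {
  x <- sim_fixture(n_sites = 4, family = "main_only", effect_pct = 10,
                   seed = 33)
  f1 <- fit_lmm(x, "biomass_g", full_factorial, random = rcb_random)
  set.seed(1)
  f2 <- fit_lmm(x[sample(nrow(x)), ], "biomass_g", full_factorial,
                random = rcb_random)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("the log transform composes with a pre-logged response", {
  x <- sim_fixture(n_sites = 3, vc = variance_components(10, 5, 8), seed = 35)
  x$log_biomass <- log(x$biomass_g)
  f_log <- fit_lmm(x, "biomass_g", full_factorial, random = rcb_random,
                   transform = "log")
  f_pre <- fit_lmm(x, "log_biomass", full_factorial, random = rcb_random)
  expect_equal(coef(f_log), coef(f_pre), tolerance = 1e-10)
  expect_equal(f_log$varcomp, f_pre$varcomp, tolerance = 1e-8)

  x$biomass_g[1] <- -2
  expect_error(fit_lmm(x, "biomass_g", full_factorial, transform = "log"),
               "offset")
})

test_that("perfect collinearity is rejected with the offending column named", {
  x <- sim_fixture(n_sites = 2, seed = 37)
  x$dup <- x$insecticide
  expect_error(fit_lmm(x, "biomass_g", "insecticide + dup"),
               "collinear.*dup")
})

test_that("variance components are recovered from a large simulation", {
  x <- sim_fixture(n_sites = 200, seed = 39)
  fit <- fit_lmm(x, "biomass_g", full_factorial, random = rcb_random,
                 method = "reml")
  expect_equal(unname(fit$varcomp["site_id"]), 372.7, tolerance = 0.10)
  expect_equal(unname(fit$varcomp["residual"]), 15.33, tolerance = 0.05)
})

test_that("lrt_test follows the chi-squared reference and its preconditions", {
  x <- sim_fixture(n_sites = 5, family = "main_only", effect_pct = 10,
                   seed = 41)
  full <- fit_lmm(x, "biomass_g", full_factorial, random = rcb_random,
                  method = "ml")
  red <- fit_lmm(x, "biomass_g", drop_term_fixed("insecticide"),
                 random = rcb_random, method = "ml")

  # identical models: statistic 0, p = 1
  self <- lrt_test(full, full)
  expect_equal(self$statistic, 0, tolerance = 1e-10)
  expect_equal(self$p_value, 1)

  lrt <- lrt_test(full, red)
  expect_equal(lrt$df, 1)
  # chi-squared(1) survival identity: p = 2 * (1 - Phi(sqrt(stat)))
  expect_equal(lrt$p_value, 2 * stats::pnorm(-sqrt(lrt$statistic)),
               tolerance = 1e-10)
  # numerical-integration oracle for the survival function
  oracle <- stats::integrate(function(t) stats::dchisq(t, 1),
                             lrt$statistic, Inf, rel.tol = 1e-12)$value
  expect_equal(lrt$p_value, oracle, tolerance = 1e-10)

  # df-1 quantile identity: statistic 3.841459 gives p ~ 0.05
  expect_equal(stats::pchisq(stats::qchisq(0.95, 1), 1, lower.tail = FALSE),
               0.05, tolerance = 1e-12)

  # REML fits are refused for the comparison
  full_reml <- fit_lmm(x, "biomass_g", full_factorial, random = rcb_random)
  expect_error(lrt_test(full_reml, red), "ml")
  # non-nested fixed parts are refused
  xx <- x
  xx$n_excluded <- n_groups_recode(xx)
  other <- fit_lmm(xx, "biomass_g", "insecticide + n_excluded",
                   random = rcb_random, method = "ml")
  expect_error(lrt_test(full, other), "nested")
})

test_that("wald_summary matches an independent survival-function oracle", {
  skip_if_not_installed("pracma")
  x <- sim_fixture(n_sites = 4, family = "main_only", effect_pct = 8,
                   seed = 43)
  fit <- fit_lmm(x, "biomass_g", full_factorial, random = rcb_random)
  w <- wald_summary(fit)
  expect_true(all(w$p >= 0 & w$p <= 1))
  # p = erfc(|z| / sqrt(2)), computed independently of pnorm
  expect_equal(w$p, pracma::erfc(abs(w$z) / sqrt(2)), tolerance = 1e-10)
  # |z| at the 5% two-sided point
  expect_equal(2 * stats::pnorm(-1.959964), 0.05, tolerance = 1e-6)

  # zero-SE conventions
  fake <- fit
  fake$coefficients$se[1] <- 0
  fake$coefficients$estimate[2] <- 0
  fake$coefficients$se[2] <- 0
  fake$coefficients <- within(fake$coefficients, {
    stat <- ifelse(se > 0, estimate / se, ifelse(estimate == 0, 0, Inf))
    p <- ifelse(se > 0, 2 * stats::pnorm(-abs(stat)),
                ifelse(estimate == 0, 1, 0))
  })
  w2 <- wald_summary(fake)
  expect_equal(w2$p[1], 0)
  expect_equal(w2$p[2], 1)
})

test_that("the likelihood-ratio test holds its nominal size under the null", {
  pw <- estimate_power(effect_scenario("null"), variance_components(),
                       n_sites = 10, term = "insecticide", n_sim = 1000,
                       alpha = 0.05, seed = 51)
  # exact binomial 99% band around 0.05 at n = 1000
  band <- qbinom(c(0.005, 0.995), 1000, 0.05) / 1000
  expect_gte(pw$n_reject / 1000, band[1])
  expect_lte(pw$n_reject / 1000, band[2])
})
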