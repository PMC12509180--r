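test_that("effect scenarios encode the three families correctly", {
  s <- effect_scenario("main_only", 10, 100)
  expect_equal(c(s$beta_i, s$beta_f, s$beta_m), c(10, 10, 10))
  expect_equal(c(s$beta_fm, s$beta_im, s$beta_if, s$beta_ifm), rep(0, 4))

  n <- effect_scenario("null", 0, 100)
  expect_equal(n$beta0, 100)
  expect_equal(sum(abs(unlist(n[grep("^beta_", names(n))]))), 0)

  sup <- effect_scenario("superadditive", 20)
  expect_equal(sup$beta_fm, 20)
  expect_equal(c(sup$beta_im, sup$beta_if, sup$beta_ifm), rep(0, 3))
  sup_all <- effect_scenario("superadditive", 20, all_pairs = TRUE)
  expect_equal(c(sup_all$beta_im, sup_all$beta_if), c(20, 20))

  comp <- effect_scenario("compensatory", 5, 100)
  expect_equal(c(comp$beta_fm, comp$beta_im, comp$beta_if), rep(-10, 3))
  expect_equal(comp$beta_ifm, 15)

  expect_error(effect_scenario("main_only", 10, baseline = -5), "baseline")
})

test_that("expected_mean evaluates the fixed part under indicator coding", {
  combo <- function(i, f, m) data.frame(insecticide = i, fungicide = f,
                                        molluscicide = m)
  # superadditive 20%: fungicide+molluscicide plot totals a 60% increase
  expect_equal(expected_mean(effect_scenario("superadditive", 20),
                             combo(0, 1, 1)), 160)
  # control always returns the baseline
  for (fam in c("null", "main_only", "superadditive", "compensatory")) {
    expect_equal(expected_mean(effect_scenario(fam, 15), combo(0, 0, 0)), 100)
  }
  # main-only 10%: all three biocides give 130 g
  expect_equal(expected_mean(effect_scenario("main_only", 10),
                             combo(1, 1, 1)), 130)
  # compensatory: every multi-biocide combination sits exactly at baseline
  comp <- effect_scenario("compensatory", 5)
  multi <- subset(treatment_combos(),
                  insecticide + fungicide + molluscicide >= 2)
  expect_equal(expected_mean(comp, multi), rep(100, nrow(multi)))
  single <- subset(treatment_combos(),
                   insecticide + fungicide + molluscicide == 1)
  expect_equal(expected_mean(comp, single), rep(105, 3))
})

test_that("simulate_experiment is exact with zero variance components", {
  d <- build_design(2, 3, seed = 1)
  x0 <- simulate_experiment(d, effect_scenario("null"),
                            variance_components(0, 0, 0), seed = 5)
  expect_equal(x0$biomass_g, rep(100, 48))

  x1 <- simulate_experiment(d, effect_scenario("main_only", 10),
                            variance_components(0, 0, 0), seed = 5)
  expect_equal(x1$biomass_g,
               100 + 10 * (x1$insecticide + x1$fungicide + x1$molluscicide))

  expect_error(variance_components(-1, 0, 0), "non-negative")
})

test_that("simulated data are seeded and reproduce bit-identically", {
  d <- build_design(3, 3, seed = 2)
  vc <- variance_components()
  a <- simulate_experiment(d, effect_scenario("null"), vc, seed = 11)
  b <- simulate_experiment(d, effect_scenario("null"), vc, seed = 11)
  expect_identical(a, b)
  c <- simulate_experiment(d, effect_scenario("null"), vc, seed = 12)
  expect_false(identical(a$biomass_g, c$biomass_g))
})

test_that("block draws are shared by all plots of a block", {
  d <- build_design(4, 3, seed = 3)
  x <- simulate_experiment(d, effect_scenario("null"),
                           variance_components(0, 7.82, 0), seed = 9)
  per_block <- tapply(x$biomass_g, interaction(x$site_id, x$block_id),
                      function(v) diff(range(v)))
  expect_equal(max(per_block), 0)
  expect_gt(stats::sd(tapply(x$biomass_g,
                             interaction(x$site_id, x$block_id), mean)), 0)
})

test_that("site-level spread matches the requested standard deviation", {
  d <- build_design(10000, 1, seed = 4)
  x <- simulate_experiment(d, effect_scenario("null"), variance_components(),
                           seed = 21)
  site_means <- tapply(x$biomass_g, x$site_id, mean)
  # sd of site means = sqrt(372.7^2 + 7.82^2 + 15.33^2/8)
  expect_equal(stats::sd(site_means), 372.7, tolerance = 0.02)
})

test_that("Monte-Carlo means converge to the expected cell means", {
  d <- build_design(2, 3, seed = 6)
  scen <- effect_scenario("superadditive", 10)
  vc <- variance_components(50, 7.82, 15.33)
  sims <- sapply(1:200, function(r)
    simulate_experiment(d, scen, vc, seed = 1000 + r)$biomass_g)
  mu <- expected_mean(scen, d)
  # per-plot SE of the mean over 200 replicates
  se <- sqrt(50^2 + 7.82^2 + 15.33^2) / sqrt(200)
  expect_true(all(abs(rowMeans(sims) - mu) < 3 * se))
})

test_that("multi-year simulation injects persistent plots and year trends", {
  d <- build_design(3, 3, seed = 8)
  x <- simulate_experiment(d, effect_scenario("null"),
                           variance_components(0, 0, 10), seed = 13,
                           n_years = 3, beta_year = 2, beta_year_i = 5)
  expect_equal(nrow(x), 3 * nrow(d))
  expect_equal(sort(unique(x$year_since_start)), 0:2)
  # plot effects persist: control plots differ across years only by the trend
  p0 <- x[x$year_since_start == 0 & x$insecticide == 0, "biomass_g"]
  p2 <- x[x$year_since_start == 2 & x$insecticide == 0, "biomass_g"]
  expect_equal(p2 - p0, rep(4, length(p0)))
  pi0 <- x[x$year_since_start == 0 & x$insecticide == 1, "biomass_g"]
  pi2 <- x[x$year_since_start == 2 & x$insecticide == 1, "biomass_g"]
  expect_equal(pi2 - pi0, rep(4 + 10, length(pi0)))
})

test_that("community generator respects targeting and richness bounds", {
  d <- build_design(8, 3, seed = 10)

  one <- simulate_community(d, community_scenario(n_species = 1,
                                                  pool_frac = 1), seed = 3)
  rich <- tapply(one$cover$cover_pct,
                 interaction(one$cover$site_id, one$cover$plot_id,
                             one$cover$block_id), function(v) sum(v > 0))
  expect_true(all(rich == 1))

  # neutral multiplier: mean cover unrelated to the insecticide treatment
  neu <- simulate_community(d, community_scenario(multiplier = 1,
                                                  target = "dominant"),
                            seed = 4)$cover
  m0 <- mean(neu$cover_pct[neu$insecticide == 0])
  m1 <- mean(neu$cover_pct[neu$insecticide == 1])
  expect_lt(abs(m0 - m1) / m0, 0.1)

  # consumers suppressing the dominant: exclusion plots are less even
  sup <- simulate_community(d, community_scenario(target = "dominant",
                                                  multiplier = 0.2),
                            seed = 5)$cover
  sh <- sapply(split(sup$cover_pct,
                     interaction(sup$site_id, sup$block_id, sup$plot_id,
                                 drop = TRUE)), shannon)
  ins <- sapply(split(sup$insecticide,
                      interaction(sup$site_id, sup$block_id, sup$plot_id,
                                  drop = TRUE)), function(v) v[1])
  expect_lt(mean(sh[ins == 1]), mean(sh[ins == 0]))

  # covers are floored at the reporting minimum
  expect_true(all(sup$cover_pct >= 0.1))
})
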