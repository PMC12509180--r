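# Monte-Carlo power analysis for the multi-site factorial design.

factorial_terms <- c(
  "insecticide", "fungicide", "molluscicide",
  "insecticide:fungicide", "insecticide:molluscicide",
  "fungicide:molluscicide", "insecticide:fungicide:molluscicide"
)

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Exact two-sided confidence interval for a binomial proportion from beta
#' quantiles: the lower bound is the `(1-level)/2` quantile of
#' Beta(x, n-x+1) (0 when x = 0) and the upper bound the `1-(1-level)/2`
#' quantile of Beta(x+1, n-x) (1 when x = n).
#'
#' @param x Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(lower, upper)` on the proportion scale.
#' @examples
#' round(100 * clopper_pearson(292, 300), 2)  # 94.81, 98.84
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    stop_invalid("`level` must be in (0, 1)")
  }
  if (!is.numeric(x) || !is.numeric(n) || length(x) != 1L || length(n) != 1L ||
      n < 1 || x < 0 || x > n || x != floor(x) || n != floor(n)) {
    stop_invalid("need integer counts with 0 <= x <= n and n >= 1")
  }
  a <- 1 - level
  lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lo, upper = hi)
}

#' Monte-Carlo power for one scenario and tested term
#'
#' Estimates the power of the multi-site factorial design to detect a
#' treatment term: each replicate simulates a fresh experiment (new site,
#' block, and plot draws) under `scenario` and `vc`, fits the full
#' `insecticide * fungicide * molluscicide` mixed model (indicator coding,
#' ML) with random intercepts for site and block-within-site, and performs
#' a likelihood-ratio test of `term` by refitting without it. Power is the
#' proportion of replicates with p < `alpha`, reported with its exact
#' binomial confidence interval.
#'
#' Replicate seeds derive deterministically from `seed` (counter-based), so
#' runs are reproducible. A replicate whose fit triggers a convergence
#' warning is redrawn once; if the redraw also fails it is counted as a
#' non-rejection and tallied in `n_failed`.
#'
#' @param scenario An [effect_scenario()].
#' @param vc A [variance_components()] object.
#' @param n_sites,n_blocks Design dimensions (network default 35 x 3).
#' @param term The fixed term tested, one of the seven factorial terms
#'   (e.g. `"insecticide"` or `"fungicide:molluscicide"`).
#' @param n_sim Number of simulated replicates (>= 1).
#' @param alpha Two-sided significance threshold.
#' @param seed Master seed.
#' @param ci_level Confidence level of the exact interval.
#' @return An object of class `factex_power`: a list with the scenario
#'   family and effect size, tested term, `n_sim`, `n_reject`, `power_pct`,
#'   `ci_lo_pct`, `ci_hi_pct`, and bookkeeping counts.
#' @examples
#' \donttest{
#' estimate_power(effect_scenario("main_only", 20), variance_components(),
#'                n_sim = 20, seed = 1)
#' }
#' @export
estimate_power <- function(scenario, vc = variance_components(),
                           n_sites = 35, n_blocks = 3,
                           term = "insecticide", n_sim = 300, alpha = 0.05,
                           seed = 1L, ci_level = 0.95) {
  stopifnot(inherits(scenario, "effect_scenario"), n_sim >= 1)
  if (!term %in% factorial_terms) {
    stop_invalid("`term` must be one of: ", paste(factorial_terms, collapse = ", "))
  }
  design <- build_design(n_sites, n_blocks, seed = seed)
  tmpl <- power_templates(design, term, scenario, vc, seed)

  n_reject <- 0L
  n_retried <- 0L
  n_failed <- 0L
  for (r in seq_len(n_sim)) {
    res <- one_power_rep(tmpl, design, scenario, vc,
                         replicate_seed(seed, r))
    if (is.na(res)) {
      n_retried <- n_retried + 1L
      res <- one_power_rep(tmpl, design, scenario, vc,
                           replicate_seed(seed, r, salt = 1L))
      if (is.na(res)) {
        n_failed <- n_failed + 1L
        res <- 1  # counted as a non-rejection
      }
    }
    if (res < alpha) n_reject <- n_reject + 1L
  }
  ci <- clopper_pearson(n_reject, n_sim, ci_level)
  structure(list(
    family = scenario$family, effect_pct = scenario$effect_pct, term = term,
    n_sites = n_sites, n_blocks = n_blocks, n_sim = as.integer(n_sim),
    n_reject = n_reject, power_pct = 100 * n_reject / n_sim,
    ci_lo_pct = 100 * ci[["lower"]], ci_hi_pct = 100 * ci[["upper"]],
    alpha = alpha, seed = seed, n_retried = n_retried, n_failed = n_failed
  ), class = "factex_power")
}

#' @export
print.factex_power <- function(x, ...) {
  cat(sprintf(
    "Power (%s, %.3g%%), term %s: %.2f%% [%.2f, %.2f] (%d/%d rejections)\n",
    x$family, x$effect_pct, x$term, x$power_pct, x$ci_lo_pct, x$ci_hi_pct,
    x$n_reject, x$n_sim))
  if (x$n_failed > 0) {
    cat(sprintf("  %d replicate(s) failed to converge after retry\n", x$n_failed))
  }
  invisible(x)
}

# Fit ML template models (full + reduced) once; replicates only change the
# response via lme4::refit, which keeps the power loop fast.
power_templates <- function(design, term, scenario, vc, seed) {
  dat <- simulate_experiment(design, scenario, vc,
                             seed = replicate_seed(seed, 0L))
  dat$site_id <- factor(dat$site_id)
  dat$site_block <- interaction(dat$site_id, dat$block_id, drop = TRUE)
  full_fml <- stats::as.formula(
    "biomass_g ~ insecticide * fungicide * molluscicide + (1 | site_id) + (1 | site_block)")
  red_terms <- setdiff(factorial_terms, term)
  red_fml <- stats::as.formula(paste(
    "biomass_g ~", paste(red_terms, collapse = " + "),
    "+ (1 | site_id) + (1 | site_block)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE)
  full <- suppressWarnings(suppressMessages(
    lme4::lmer(full_fml, data = dat, REML = FALSE, control = ctrl)))
  red <- suppressWarnings(suppressMessages(
    lme4::lmer(red_fml, data = dat, REML = FALSE, control = ctrl)))
  df <- length(lme4::fixef(full)) - length(lme4::fixef(red))
  list(full = full, red = red, df = df)
}

# One replicate: returns the LRT p-value, or NA on a convergence warning.
one_power_rep <- function(tmpl, design, scenario, vc, rep_seed) {
  y <- simulate_experiment(design, scenario, vc, seed = rep_seed)$biomass_g
  ok <- TRUE
  p <- tryCatch({
    f <- withCallingHandlers(
      lme4::refit(tmpl$full, y),
      warning = function(w) { ok <<- FALSE; invokeRestart("muffleWarning") })
    r <- withCallingHandlers(
      lme4::refit(tmpl$red, y),
      warning = function(w) { ok <<- FALSE; invokeRestart("muffleWarning") })
    stat <- max(0, 2 * (as.numeric(stats::logLik(f)) -
                          as.numeric(stats::logLik(r))))
    stats::pchisq(stat, tmpl$df, lower.tail = FALSE)
  }, error = function(e) NA_real_)
  if (!ok) return(NA_real_)
  p
}

#' The network's replication presets for the power table
#'
#' The fifteen scenario rows of the network power summary: main-effect,
#' superadditive, and compensatory families, each at effect sizes 5, 7.5,
#' 10, 15, and 20 percent of the 100 g baseline.
#'
#' @return A data frame with columns `family` and `effect_pct`.
#' @export
replication_presets <- function() {
  data.frame(
    family = rep(c("main_only", "superadditive", "compensatory"), each = 5),
    effect_pct = rep(c(20, 15, 10, 7.5, 5), times = 3),
    stringsAsFactors = FALSE
  )
}

#' Monte-Carlo power table across scenario presets
#'
#' Runs [estimate_power()] for each row of `presets`. Main-effect presets
#' test the insecticide term; superadditive and compensatory presets test
#' the fungicide:molluscicide interaction.
#'
#' @param presets Data frame with columns `family` and `effect_pct`
#'   (default [replication_presets()]).
#' @param vc,n_sites,n_blocks,n_sim,alpha,seed As in [estimate_power()];
#'   each row uses its own deterministic substream of `seed`.
#' @param baseline Baseline biomass in g.
#' @return A data frame of class `factex_power_table` with one row per
#'   preset: `family`, `effect_pct`, `term`, `n_sim`, `n_reject`,
#'   `power_pct`, `ci_lo_pct`, `ci_hi_pct`.
#' @export
power_table <- function(presets = replication_presets(),
                        vc = variance_components(), n_sites = 35,
                        n_blocks = 3, n_sim = 300, alpha = 0.05, seed = 1L,
                        baseline = 100) {
  if (is.null(presets) || nrow(presets) == 0L) {
    out <- data.frame(family = character(0), effect_pct = numeric(0),
                      term = character(0), n_sim = integer(0),
                      n_reject = integer(0), power_pct = numeric(0),
                      ci_lo_pct = numeric(0), ci_hi_pct = numeric(0))
    class(out) <- c("factex_power_table", "data.frame")
    return(out)
  }
  rows <- vector("list", nrow(presets))
  for (k in seq_len(nrow(presets))) {
    family <- as.character(presets$family[k])
    pct <- presets$effect_pct[k]
    scen <- effect_scenario(family, pct, baseline)
    term <- if (family %in% c("superadditive", "compensatory")) {
      "fungicide:molluscicide"
    } else {
      "insecticide"
    }
    pw <- estimate_power(scen, vc, n_sites, n_blocks, term, n_sim, alpha,
                         seed = replicate_seed(seed, k, salt = 7L))
    rows[[k]] <- data.frame(family = family, effect_pct = pct, term = term,
                            n_sim = pw$n_sim, n_reject = pw$n_reject,
                            power_pct = pw$power_pct,
                            ci_lo_pct = pw$ci_lo_pct,
                            ci_hi_pct = pw$ci_hi_pct,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("factex_power_table", "data.frame")
  out
}
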