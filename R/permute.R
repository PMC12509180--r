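# Within-block permutation engine and false-positive calibration.

#' Permute a response within blocks
#'
#' Reassigns the response values of every (site, block) uniformly at random
#' to that block's plots, without replacement: the per-block multiset of
#' values is preserved exactly while any treatment-response association is
#' destroyed. Treatment columns are untouched.
#'
#' @param table A plot table with the response column present.
#' @param seed Optional integer seed (the caller's RNG state is preserved
#'   when given); with `seed = NULL` the current RNG stream is used.
#' @param response Name of the response column (default `"biomass_g"`).
#' @return The table with the response column permuted within blocks.
#' @export
permute_within_blocks <- function(table, seed = NULL, response = "biomass_g") {
  check_plot_table(table, response = response)
  idx <- split(seq_len(nrow(table)),
               interaction(table$site_id, table$block_id, drop = TRUE))
  shuffle <- function() {
    y <- table[[response]]
    for (ix in idx) {
      if (length(ix) > 1L) y[ix] <- y[sample(ix)]
    }
    table[[response]] <- y
    table
  }
  if (is.null(seed)) shuffle() else with_seed(seed, shuffle())
}

#' Permutation-based false-positive analysis
#'
#' Calibrates the false-positive rate of the factorial analysis by
#' repeatedly shuffling the response within blocks and refitting the model
#' `log(biomass) ~ insecticide * fungicide * molluscicide` with effect
#' (+/-1) treatment coding and random intercepts for site and
#' block-within-site. For every iteration the per-term Wald p-values are
#' read from the model summary; the result counts, per term, how often
#' p < `alpha` across iterations. Because permutation destroys any
#' treatment-response association, every non-intercept proportion should
#' sit at `alpha` regardless of what the input data contain.
#'
#' If a `year_since_start` column is present, only each plot's most recent
#' record enters the analysis.
#'
#' @param table A plot table with a positive response (after `offset`) when
#'   `transform = "log"`.
#' @param n_iter Number of permutations.
#' @param alpha Significance threshold counted as a positive.
#' @param seed Integer seed; identical seeds give identical counts.
#' @param transform `"log"` (the default analysis scale) or `"identity"`.
#' @param offset Constant added to the response before transforming; use it
#'   to shift data positive for the log scale.
#' @param method Restricted (`"reml"`, default) or unrestricted (`"ml"`)
#'   likelihood for the fits.
#' @param response Name of the response column.
#' @return A data frame of class `factex_fpr` with one row per model term
#'   (intercept plus the seven treatment terms): `term`, `total`,
#'   `significant`, `proportion`.
#' @examples
#' \donttest{
#' d <- simulate_experiment(build_design(6, 3), effect_scenario("null"),
#'                          variance_components(0, 8, 15), seed = 1)
#' false_positive_analysis(d, n_iter = 50, seed = 1)
#' }
#' @export
false_positive_analysis <- function(table, n_iter = 10000, alpha = 0.05,
                                    seed = 1L,
                                    transform = c("log", "identity"),
                                    offset = 0,
                                    method = c("reml", "ml"),
                                    response = "biomass_g") {
  transform <- match.arg(transform)
  method <- match.arg(method)
  check_plot_table(table, response = response)
  stopifnot(n_iter >= 1, alpha > 0, alpha < 1)

  dat <- as.data.frame(table)
  if ("year_since_start" %in% names(dat)) {
    key <- interaction(dat$site_id, dat$block_id, dat$plot_id, drop = TRUE)
    latest <- stats::ave(dat$year_since_start, key, FUN = max)
    dat <- dat[dat$year_since_start == latest, , drop = FALSE]
  }

  y <- dat[[response]] + offset
  if (transform == "log") {
    if (any(!is.finite(y)) || any(y <= 0)) {
      stop_invalid("response must be strictly positive for the log ",
                   "transform; supply an `offset` or use ",
                   "transform = \"identity\"")
    }
    y <- log(y)
  }

  # +/-1 effect coding, named so that model terms read as treatments
  dat$insecticide <- 2 * dat$insecticide - 1
  dat$fungicide <- 2 * dat$fungicide - 1
  dat$molluscicide <- 2 * dat$molluscicide - 1
  dat$.y <- y
  dat$site_id <- factor(dat$site_id)
  dat$site_block <- interaction(dat$site_id, dat$block_id, drop = TRUE)

  ctrl <- lme4::lmerControl(calc.derivs = FALSE)
  template <- suppressWarnings(suppressMessages(lme4::lmer(
    .y ~ insecticide * fungicide * molluscicide + (1 | site_id) +
      (1 | site_block),
    data = dat, REML = (method == "reml"), control = ctrl)))
  terms <- names(lme4::fixef(template))

  idx <- split(seq_len(nrow(dat)), dat$site_block)
  counts <- stats::setNames(integer(length(terms)), terms)
  n_failed <- 0L
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      yy <- dat$.y
      for (ix in idx) {
        if (length(ix) > 1L) yy[ix] <- yy[sample(ix)]
      }
      fit <- tryCatch(
        suppressWarnings(suppressMessages(lme4::refit(template, yy))),
        error = function(e) NULL)
      if (is.null(fit)) {
        n_failed <- n_failed + 1L
        next
      }
      est <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))
      p <- ifelse(se > 0, 2 * stats::pnorm(-abs(est / se)),
                  ifelse(est == 0, 1, 0))
      counts <- counts + as.integer(p < alpha)
    }
  })

  out <- data.frame(term = terms, total = as.integer(n_iter),
                    significant = as.integer(counts),
                    proportion = as.numeric(counts) / n_iter,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  attr(out, "transform") <- transform
  attr(out, "offset") <- offset
  attr(out, "n_failed") <- n_failed
  class(out) <- c("factex_fpr", "data.frame")
  out
}

#' @export
print.factex_fpr <- function(x, ...) {
  cat(sprintf(
    "Within-block permutation false-positive analysis (%d iterations, alpha = %g)\n",
    x$total[1], attr(x, "alpha")))
  print.data.frame(cbind(x[, c("term", "total", "significant")],
                         proportion = round(x$proportion, 4)),
                   row.names = FALSE)
  invisible(x)
}
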