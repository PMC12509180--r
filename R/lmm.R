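#' Fit the linear (mixed) model used throughout the package
#'
#' Uniform fitting contract for all package analyses: a fixed-effect
#' formula built from term labels, optional nested random intercepts,
#' indicator or effect (+/-1) coding of the biocide treatments, and an
#' optional log transform of the response. With random intercepts the model
#' is fitted by [lme4::lmer()]; without any it reduces to ordinary least
#' squares via [stats::lm()].
#'
#' On a balanced design with indicator coding the fixed-effect estimates
#' equal the corresponding cell-mean contrasts.
#'
#' @param data A plot table (or response table) containing all referenced
#'   columns.
#' @param response Name of the response column.
#' @param fixed Right-hand-side of the fixed part as a character string,
#'   e.g. `"insecticide * fungicide * molluscicide"`.
#' @param random Character vector of grouping labels for random
#'   intercepts, e.g. `c("site_id", "site_id:block_id")`; `NULL` for OLS.
#' @param coding `"indicator"` (0/1, the default) or `"effect"` (-1/+1)
#'   coding of the three treatment columns.
#' @param transform `"identity"` or `"log"` (natural log of the response;
#'   the response must then be positive).
#' @param method `"reml"` (restricted likelihood, the default) or `"ml"`
#'   (unrestricted; required for likelihood-ratio comparisons of fixed
#'   effects).
#' @return An object of class `factex_fit`: a list with the per-term
#'   coefficient table (`term`, `estimate`, `se`, `stat`, `p`), the
#'   random-effect and residual SDs (`varcomp`), log-likelihoods under both
#'   criteria (`logLik_ml`, `logLik_reml`), a `converged` flag, `singular`
#'   flag, `n_obs`, and the underlying fitted model (`model`).
#' @examples
#' d <- simulate_experiment(build_design(4, 3), effect_scenario("main_only", 10),
#'                          variance_components(), seed = 1)
#' fit <- fit_lmm(d, "biomass_g", "insecticide * fungicide * molluscicide",
#'                random = c("site_id", "site_id:block_id"))
#' coef(fit)
#' @export
fit_lmm <- function(data, response, fixed, random = NULL,
                    coding = c("indicator", "effect"),
                    transform = c("identity", "log"),
                    method = c("reml", "ml")) {
  coding <- match.arg(coding)
  transform <- match.arg(transform)
  method <- match.arg(method)
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop_invalid("`data` must be a non-empty data frame")
  }
  if (!response %in% names(data)) {
    stop_invalid("response column '", response, "' not found in `data`")
  }

  dat <- as.data.frame(data)
  if (coding == "effect") {
    for (tr in intersect(c("insecticide", "fungicide", "molluscicide"),
                         names(dat))) {
      if (!all(dat[[tr]] %in% c(0, 1))) {
        stop_invalid("effect coding requires 0/1 treatment column '", tr, "'")
      }
      dat[[tr]] <- 2 * dat[[tr]] - 1
    }
  }
  y <- dat[[response]]
  if (transform == "log") {
    if (any(!is.finite(y)) || any(y <= 0)) {
      stop_invalid("log transform requires a strictly positive response; ",
                   "add an offset or use transform = \"identity\"")
    }
    y <- log(y)
  }
  dat[[".y"]] <- y

  fixed_terms <- attr(stats::terms(stats::reformulate(fixed)), "term.labels")
  if (length(fixed_terms) == 0L) fixed_terms <- character(0)

  # fail early on perfect collinearity, naming the aliased columns
  mm <- stats::model.matrix(stats::reformulate(fixed, intercept = TRUE), dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop_invalid("perfectly collinear fixed-effect column(s): ",
                 paste(aliased, collapse = ", "))
  }

  groups <- random
  if (!is.null(groups) && length(groups) == 0L) groups <- NULL
  miss_g <- if (is.null(groups)) character(0) else
    setdiff(unique(unlist(strsplit(groups, ":", fixed = TRUE))), names(dat))
  if (length(miss_g)) {
    stop_invalid("grouping column(s) not found: ", paste(miss_g, collapse = ", "))
  }

  msgs <- character(0)
  converged <- TRUE
  if (is.null(groups)) {
    fml <- stats::as.formula(paste(".y ~", fixed))
    model <- stats::lm(fml, data = dat)
    est <- stats::coef(model)
    # vcov warns about "essentially perfect fit" on noise-free data
    se <- sqrt(diag(suppressWarnings(stats::vcov(model))))
    varcomp <- c(residual = stats::sigma(model))
    ll_ml <- as.numeric(stats::logLik(model))
    ll_reml <- NA_real_
    dev <- stats::deviance(model)
    singular <- FALSE
  } else {
    re <- paste(sprintf("(1 | %s)", groups), collapse = " + ")
    fml <- stats::as.formula(paste(".y ~", fixed, "+", re))
    model <- withCallingHandlers(
      lme4::lmer(fml, data = dat, REML = (method == "reml"),
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        converged <<- FALSE
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      }
    )
    est <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- stats::setNames(vc$sdcor, ifelse(vc$grp == "Residual",
                                                "residual", vc$grp))
    if (method == "reml") {
      ll_reml <- as.numeric(stats::logLik(model))
      ll_ml <- as.numeric(stats::logLik(lme4::refitML(model)))
    } else {
      ll_ml <- as.numeric(stats::logLik(model))
      ll_reml <- NA_real_
    }
    dev <- -2 * ll_ml
    singular <- lme4::isSingular(model)
  }

  stat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf))
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(est / se)),
              ifelse(est == 0, 1, 0))
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), stat = unname(stat), p = unname(p),
                      row.names = NULL, stringsAsFactors = FALSE)

  structure(list(
    call = match.call(), response = response, fixed = fixed,
    fixed_terms = fixed_terms, random = groups, coding = coding,
    transform = transform, method = method, coefficients = coefs,
    varcomp = varcomp, logLik_ml = ll_ml, logLik_reml = ll_reml,
    deviance = dev, converged = converged, singular = singular,
    messages = msgs, n_obs = nrow(dat), data = data, model = model
  ), class = "factex_fit")
}

#' @export
print.factex_fit <- function(x, ...) {
  kind <- if (is.null(x$random)) "Linear model" else "Linear mixed model"
  cat(sprintf("%s fit (%s, %s coding%s), n = %d\n", kind, toupper(x$method),
              x$coding,
              if (x$transform == "log") ", log response" else "", x$n_obs))
  cat("  fixed: ", x$response, " ~ ", x$fixed, "\n", sep = "")
  if (!is.null(x$random)) {
    cat("  random intercepts:", paste(x$random, collapse = ", "), "\n")
  }
  cm <- as.matrix(x$coefficients[, c("estimate", "se", "stat", "p")])
  rownames(cm) <- x$coefficients$term
  stats::printCoefmat(cm, P.values = TRUE, has.Pvalue = TRUE,
                      signif.stars = FALSE)
  if (!x$converged) cat("warning: fit flagged as not cleanly converged\n")
  if (x$singular) cat("note: singular fit (a variance component is zero)\n")
  invisible(x)
}

#' @export
summary.factex_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.factex_fit")
}

#' @export
print.summary.factex_fit <- function(x, ...) {
  print(x$fit)
  cat("\nStandard deviations of random components (g):\n")
  print(round(x$fit$varcomp, 4))
  cat(sprintf("\nlogLik (ML) = %.3f", x$fit$logLik_ml))
  if (!is.na(x$fit$logLik_reml)) {
    cat(sprintf(", logLik (REML) = %.3f", x$fit$logLik_reml))
  }
  cat("\n")
  invisible(x)
}

#' @export
coef.factex_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
predict.factex_fit <- function(object, ...) stats::predict(object$model, ...)

#' @export
residuals.factex_fit <- function(object, ...) stats::residuals(object$model, ...)

#' @export
logLik.factex_fit <- function(object, ...) {
  if (object$method == "ml" || is.null(object$random)) object$logLik_ml
  else object$logLik_reml
}

#' Likelihood-ratio test between two nested fits
#'
#' Compares two nested fixed-effect specifications fitted to the same data
#' by unrestricted maximum likelihood. The statistic is twice the
#' log-likelihood difference (clamped at zero) referred to a chi-squared
#' distribution whose degrees of freedom equal the difference in the number
#' of fixed-effect coefficients.
#'
#' @param full,reduced `factex_fit` objects fitted with `method = "ml"`,
#'   `reduced` nested in `full`.
#' @return A list with `statistic`, `df`, and `p_value`.
#' @examples
#' d <- simulate_experiment(build_design(4, 3), effect_scenario("null"),
#'                          variance_components(), seed = 2)
#' f <- fit_lmm(d, "biomass_g", "insecticide * fungicide * molluscicide",
#'              random = c("site_id", "site_id:block_id"), method = "ml")
#' r <- fit_lmm(d, "biomass_g", "fungicide * molluscicide + insecticide:fungicide +
#'              insecticide:molluscicide + insecticide:fungicide:molluscicide",
#'              random = c("site_id", "site_id:block_id"), method = "ml")
#' lrt_test(f, r)
#' @export
lrt_test <- function(full, reduced) {
  stopifnot(inherits(full, "factex_fit"), inherits(reduced, "factex_fit"))
  if (!is.null(full$random) && full$method != "ml") {
    stop_invalid("`full` must be fitted with method = \"ml\"")
  }
  if (!is.null(reduced$random) && reduced$method != "ml") {
    stop_invalid("`reduced` must be fitted with method = \"ml\"")
  }
  if (full$n_obs != reduced$n_obs || full$response != reduced$response ||
      full$transform != reduced$transform) {
    stop_invalid("models must be fitted to the same response and data")
  }
  if (!identical(sort(full$random %||% character(0)),
                 sort(reduced$random %||% character(0)))) {
    stop_invalid("models must share the same random-effect structure")
  }
  if (!all(canonical_terms(reduced$fixed_terms) %in%
             canonical_terms(full$fixed_terms))) {
    stop_invalid("`reduced` is not nested in `full`: extra term(s) ",
                 paste(setdiff(canonical_terms(reduced$fixed_terms),
                               canonical_terms(full$fixed_terms)),
                       collapse = ", "))
  }
  df <- nrow(full$coefficients) - nrow(reduced$coefficients)
  if (df < 0) stop_invalid("`reduced` has more coefficients than `full`")
  stat <- max(0, 2 * (full$logLik_ml - reduced$logLik_ml))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Wald summary of a fitted model
#'
#' Per-term two-sided p-values from estimate/SE against the standard normal
#' reference, as read from a model summary. A zero SE yields p = 0 for a
#' non-zero estimate and p = 1 for a zero estimate.
#'
#' @param fit A `factex_fit`.
#' @return A data frame with columns `term`, `estimate`, `se`, `z`, `p`.
#' @export
wald_summary <- function(fit) {
  stopifnot(inherits(fit, "factex_fit"))
  if (!fit$converged) {
    warning("Wald summary of a fit flagged as not converged", call. = FALSE)
  }
  cf <- fit$coefficients
  data.frame(term = cf$term, estimate = cf$estimate, se = cf$se,
             z = cf$stat, p = cf$p, row.names = NULL,
             stringsAsFactors = FALSE)
}
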