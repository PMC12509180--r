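# Pre-registered analysis models and community response construction.

#' Shannon diversity of a cover vector
#'
#' `H = -sum(p * log(p))` in nats, with `p` the relative covers of the
#' species with positive cover.
#'
#' @param cover Non-negative numeric vector of per-species covers; at least
#'   one entry must be positive.
#' @return Shannon index in nats.
#' @examples
#' shannon(c(25, 25, 25, 25))  # log(4)
#' @export
shannon <- function(cover) {
  if (!is.numeric(cover) || any(is.na(cover)) || any(cover < 0)) {
    stop_invalid("`cover` must be non-negative and free of NA")
  }
  s <- sum(cover)
  if (s <= 0) stop_invalid("Shannon diversity is undefined for all-zero cover")
  p <- cover[cover > 0] / s
  -sum(p * log(p))
}

#' Species richness of a cover vector
#'
#' @param cover Non-negative numeric vector of per-species covers.
#' @return Count of species with positive cover.
#' @export
richness <- function(cover) {
  if (!is.numeric(cover) || any(is.na(cover)) || any(cover < 0)) {
    stop_invalid("`cover` must be non-negative and free of NA")
  }
  sum(cover > 0)
}

#' Percent cover per functional group
#'
#' Aggregates per-species cover into functional-group percentages of total
#' cover. Species missing from the mapping are assigned to `"other"` (with
#' a message).
#'
#' @param cover Non-negative numeric vector of per-species covers.
#' @param species Character vector of species names, same length as `cover`.
#' @param groups Named character vector mapping species to group labels
#'   (names = species), or a data frame with columns `species` and `group`.
#' @return Named numeric vector: percent of total cover per group.
#' @export
group_cover <- function(cover, species, groups) {
  stopifnot(length(cover) == length(species))
  if (any(cover < 0)) stop_invalid("`cover` must be non-negative")
  s <- sum(cover)
  if (s <= 0) stop_invalid("group cover is undefined for all-zero cover")
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$species))
  }
  g <- unname(groups[as.character(species)])
  if (anyNA(g)) {
    message("species not in the group mapping assigned to 'other': ",
            paste(unique(species[is.na(g)]), collapse = ", "))
    g[is.na(g)] <- "other"
  }
  out <- tapply(cover, g, sum) / s * 100
  stats::setNames(as.numeric(out), names(out))
}

#' Number of excluded consumer groups
#'
#' Recodes the three biocide flags as the count of consumer groups reduced
#' (0-3), the alternative explanatory variable to the full three-way
#' factorial.
#'
#' @param table A plot table.
#' @return Integer vector, one entry per row.
#' @export
n_groups_recode <- function(table) {
  check_plot_table_treatments(table)
  as.integer(table$insecticide + table$fungicide + table$molluscicide)
}

#' Plot-level community responses from a cover table
#'
#' Collapses a long per-species cover table into one row per plot (and
#' year, if present) with richness, Shannon diversity, total cover, and,
#' given a group mapping, percent cover per functional group.
#'
#' @param cover_table Long cover table (as from [simulate_community()] or
#'   [read_cover()]).
#' @param groups Optional species-to-group mapping (see [group_cover()]).
#' @return A data frame keyed by plot (and year) with response columns.
#' @export
community_responses <- function(cover_table, groups = NULL) {
  keys <- intersect(c("site_id", "block_id", "plot_id", "insecticide",
                      "fungicide", "molluscicide", "year_since_start",
                      "calendar_year"), names(cover_table))
  fac <- interaction(cover_table[keys], drop = TRUE, lex.order = TRUE)
  split_ix <- split(seq_len(nrow(cover_table)), fac)
  rows <- lapply(split_ix, function(ix) {
    cv <- cover_table$cover_pct[ix]
    base <- cover_table[ix[1], keys, drop = FALSE]
    base$richness <- richness(cv)
    base$shannon <- if (sum(cv) > 0) shannon(cv) else NA_real_
    base$total_cover <- sum(cv)
    if (!is.null(groups)) {
      gc <- group_cover(cv, cover_table$species[ix], groups)
      for (g in names(gc)) base[[paste0("cover_", g)]] <- gc[[g]]
    }
    base
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- 0
    r[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-site factorial model
#'
#' The pre-registered single-site analysis: with one time point, an
#' ordinary least-squares fit of
#' `response ~ block + insecticide * molluscicide * fungicide` with block
#' as a categorical covariate; with several time points, the longitudinal
#' variant `response ~ block + year_since_start * insecticide * fungicide *
#' molluscicide` with random intercepts for calendar year and plot.
#'
#' @param site_data Response table for a single site.
#' @param response Response column name.
#' @param transform,method Passed to [fit_lmm()].
#' @return A `factex_fit`.
#' @export
fit_site_model <- function(site_data, response = "biomass_g",
                           transform = "identity", method = "reml") {
  check_plot_table(site_data, response = response)
  if (length(unique(site_data$site_id)) != 1L) {
    stop_invalid("`site_data` must contain exactly one site")
  }
  dat <- as.data.frame(site_data)
  dat$block_id <- factor(dat$block_id)
  multi_year <- "year_since_start" %in% names(dat) &&
    length(unique(dat$year_since_start)) > 1L
  if (!multi_year) {
    fit_lmm(dat, response,
            "block_id + insecticide * molluscicide * fungicide",
            random = NULL, transform = transform, method = method)
  } else {
    dat$plot_uid <- interaction(dat$block_id, dat$plot_id, drop = TRUE)
    dat$calendar_year <- factor(dat$calendar_year)
    fit_lmm(dat, response,
            "block_id + year_since_start * insecticide * fungicide * molluscicide",
            random = c("calendar_year", "plot_uid"),
            transform = transform, method = method)
  }
}

# Shared preparation of the cross-site random structure.
overall_structure <- function(dat) {
  dat$site_id <- factor(dat$site_id)
  dat$site_block <- interaction(dat$site_id, dat$block_id, drop = TRUE)
  dat$site_plot <- interaction(dat$site_block, dat$plot_id, drop = TRUE)
  dat
}

#' Cross-site longitudinal model
#'
#' The pre-registered analysis across sites and years:
#' `response ~ year_since_start * insecticide * fungicide * molluscicide`
#' with random intercepts for site, block-within-site, plot-within-block,
#' and calendar-year-within-site. `year_since_start` is continuous with 0
#' at each site's baseline. With single-year data the year terms and the
#' calendar-year intercept are dropped (with a warning) and the model
#' reduces to the factorial with site and block intercepts.
#'
#' @param all_data Response table across sites (and years).
#' @param response Response column name.
#' @param transform,method Passed to [fit_lmm()].
#' @return A `factex_fit`.
#' @export
fit_overall_model <- function(all_data, response = "biomass_g",
                              transform = "identity", method = "reml") {
  check_plot_table(all_data, response = response)
  dat <- overall_structure(as.data.frame(all_data))
  years <- if ("year_since_start" %in% names(dat)) {
    length(unique(dat$year_since_start))
  } else 1L
  if (years > 1L) {
    if (any(dat$year_since_start < 0)) {
      stop_invalid("`year_since_start` must be >= 0 (0 at baseline)")
    }
    dat$calendar_year <- factor(dat$calendar_year)
    rand <- c("site_id", "site_block", "site_plot", "calendar_year:site_id")
    if (length(unique(dat$calendar_year)) < 2L) {
      warning("single calendar year: dropping the calendar_year:site ",
              "random intercept", call. = FALSE)
      rand <- setdiff(rand, "calendar_year:site_id")
    }
    fit_lmm(dat, response,
            "year_since_start * insecticide * fungicide * molluscicide",
            random = rand, transform = transform, method = method)
  } else {
    warning("single-year data: dropping year terms and the ",
            "calendar_year:site and plot random intercepts", call. = FALSE)
    fit_lmm(dat, response, "insecticide * fungicide * molluscicide",
            random = c("site_id", "site_block"),
            transform = transform, method = method)
  }
}

#' Context-dependency model
#'
#' Tests whether consumer effects vary with a per-site driver (climate,
#' soil, control richness or productivity): the driver is centred and
#' scaled, joined by site, and interacted with the treatments (and
#' `year_since_start` where present) on top of the cross-site random
#' structure.
#'
#' @param all_data Response table across sites.
#' @param driver A data frame with columns `site_id` and `value` (one row
#'   per site), or a named numeric vector keyed by site.
#' @param response Response column name.
#' @param transform,method Passed to [fit_lmm()].
#' @return A `factex_fit` with `driver_z` interaction terms.
#' @export
fit_context_model <- function(all_data, driver, response = "biomass_g",
                              transform = "identity", method = "reml") {
  check_plot_table(all_data, response = response)
  if (is.data.frame(driver)) {
    driver <- stats::setNames(driver$value, as.character(driver$site_id))
  }
  sites <- unique(as.character(all_data$site_id))
  miss <- setdiff(sites, names(driver))
  if (length(miss)) {
    stop_invalid("driver value missing for site(s): ",
                 paste(miss, collapse = ", "))
  }
  if (stats::sd(driver[sites]) == 0) {
    stop_invalid("driver is constant across sites; context terms are ",
                 "inestimable")
  }
  dat <- overall_structure(as.data.frame(all_data))
  dv <- driver[as.character(dat$site_id)]
  dat$driver_z <- as.numeric(scale(dv))
  years <- if ("year_since_start" %in% names(dat)) {
    length(unique(dat$year_since_start))
  } else 1L
  if (years > 1L) {
    dat$calendar_year <- factor(dat$calendar_year)
    rand <- c("site_id", "site_block", "site_plot", "calendar_year:site_id")
    fixed <- "(driver_z + year_since_start) * insecticide * fungicide * molluscicide"
  } else {
    rand <- c("site_id", "site_block")
    fixed <- "driver_z * insecticide * fungicide * molluscicide"
  }
  fit_lmm(dat, response, fixed, random = rand, transform = transform,
          method = method)
}

#' Backward stepwise simplification of interaction terms
#'
#' Simplifies a fitted factorial model by likelihood-ratio tests, starting
#' from the highest interaction order: within an order the term with the
#' largest LRT p-value is removed first, and removal continues while the
#' test is non-significant at `alpha`. Main effects (and other first-order
#' terms) are never removed, and a term is protected while a retained
#' higher-order interaction contains it. All comparisons use unrestricted
#' maximum likelihood refits of the original data.
#'
#' @param fit A `factex_fit` (refitted with ML internally if needed).
#' @param alpha Retention threshold: a term is dropped when its LRT
#'   p-value is `>= alpha`.
#' @return A list of class `factex_simplify`: `fit` (the final ML fit) and
#'   `log`, an ordered data frame of (`term`, `statistic`, `df`,
#'   `p_value`, `action`) for every test performed.
#' @export
simplify_model <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "factex_fit"))
  refit_terms <- function(terms) {
    fit_lmm(fit$data, fit$response, paste(terms, collapse = " + "),
            random = fit$random, coding = fit$coding,
            transform = fit$transform, method = "ml")
  }
  current_terms <- fit$fixed_terms
  current <- if (fit$method == "ml") fit else refit_terms(current_terms)

  term_order <- function(t) lengths(strsplit(t, ":", fixed = TRUE))
  term_vars <- function(t) strsplit(t, ":", fixed = TRUE)
  log <- list()

  ord <- term_order(current_terms)
  for (o in sort(unique(ord[ord > 1L]), decreasing = TRUE)) {
    repeat {
      ords <- term_order(current_terms)
      protected <- vapply(seq_along(current_terms), function(k) {
        vk <- term_vars(current_terms[k])[[1]]
        any(vapply(seq_along(current_terms), function(j) {
          j != k && ords[j] > ords[k] &&
            all(vk %in% term_vars(current_terms[j])[[1]])
        }, logical(1)))
      }, logical(1))
      cand <- current_terms[ords == o & !protected]
      if (length(cand) == 0L) break
      tests <- lapply(cand, function(tm) {
        red <- refit_terms(setdiff(current_terms, tm))
        c(list(term = tm, red = red), lrt_test(current, red))
      })
      ps <- vapply(tests, function(t) t$p_value, numeric(1))
      worst <- which.max(ps)
      t <- tests[[worst]]
      if (t$p_value >= alpha) {
        log[[length(log) + 1L]] <- data.frame(
          term = t$term, statistic = t$statistic, df = t$df,
          p_value = t$p_value, action = "dropped",
          stringsAsFactors = FALSE)
        current_terms <- setdiff(current_terms, t$term)
        current <- t$red
      } else {
        for (t2 in tests) {
          log[[length(log) + 1L]] <- data.frame(
            term = t2$term, statistic = t2$statistic, df = t2$df,
            p_value = t2$p_value, action = "kept",
            stringsAsFactors = FALSE)
        }
        break
      }
    }
  }
  structure(list(fit = current,
                 log = if (length(log)) do.call(rbind, log) else
                   data.frame(term = character(0), statistic = numeric(0),
                              df = integer(0), p_value = numeric(0),
                              action = character(0))),
            class = "factex_simplify")
}

#' @export
print.factex_simplify <- function(x, ...) {
  cat("Stepwise interaction simplification\n")
  if (nrow(x$log)) {
    lg <- x$log
    lg$statistic <- round(lg$statistic, 3)
    lg$p_value <- signif(lg$p_value, 3)
    print.data.frame(lg, row.names = FALSE)
  }
  cat("\nFinal fixed terms:", paste(x$fit$fixed_terms, collapse = " + "), "\n")
  invisible(x)
}
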