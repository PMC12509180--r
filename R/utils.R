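# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never perturb the user's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seed for replicate r of a master seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
replicate_seed <- function(seed, r, salt = 0L) {
  (abs(as.numeric(seed)) %% 1000003 + 1000003 * r + 97 * salt) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Order-invariant term labels: variables within an interaction are sorted,
# so "a:b" and "b:a" compare equal.
canonical_terms <- function(terms) {
  vapply(strsplit(terms, ":", fixed = TRUE),
         function(v) paste(sort(v), collapse = ":"), character(1))
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# Checks for the canonical plot-table columns.
check_plot_table <- function(x, response = NULL) {
  needed <- c("site_id", "block_id", "plot_id",
              "insecticide", "fungicide", "molluscicide")
  miss <- setdiff(needed, names(x))
  if (length(miss)) {
    stop_invalid("plot table is missing column(s): ",
                 paste(miss, collapse = ", "))
  }
  for (tr in c("insecticide", "fungicide", "molluscicide")) {
    if (!all(x[[tr]] %in% c(0, 1))) {
      bad <- which(!(x[[tr]] %in% c(0, 1)))
      stop_invalid("treatment column '", tr, "' must be 0/1; offending row(s): ",
                   paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (!is.null(response) && !response %in% names(x)) {
    stop_invalid("plot table is missing the response column '", response, "'")
  }
  invisible(x)
}
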