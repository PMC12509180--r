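#' The full 2^3 factorial of biocide treatments
#'
#' Enumerates the eight treatment combinations of the consumer-exclusion
#' factorial: each of insecticide, fungicide, and molluscicide either
#' withheld (0) or applied (1). The first row is the untreated control.
#'
#' @return A data frame with 8 rows and columns `insecticide`, `fungicide`,
#'   `molluscicide` (0/1 integers).
#' @examples
#' treatment_combos()
#' @export
treatment_combos <- function() {
  tc <- expand.grid(insecticide = 0:1, fungicide = 0:1, molluscicide = 0:1,
                    KEEP.OUT.ATTRS = FALSE)
  tc[order(tc$insecticide + tc$fungicide + tc$molluscicide), , drop = FALSE][
    , c("insecticide", "fungicide", "molluscicide")]
}

#' Build a multi-site randomized complete block factorial layout
#'
#' Constructs the plot table of a multi-site consumer-exclusion experiment:
#' each site holds `n_blocks` randomized complete blocks, and each block
#' receives every one of the eight biocide combinations exactly once
#' (8 plots per block, `8 * n_blocks` plots per site).
#'
#' Randomization of treatment order within a block uses a generator seeded
#' deterministically from `(seed, site, block)`, so a design is reproducible
#' and adding sites or blocks never reshuffles existing ones. The caller's
#' RNG state is left untouched.
#'
#' @param n_sites Number of sites (>= 1).
#' @param n_blocks Number of blocks per site (>= 1; the network standard is 3).
#' @param seed Integer randomization seed.
#' @return A data frame (one row per plot) with columns `site_id`,
#'   `block_id`, `plot_id` (1-8 within block, in field order), and the three
#'   0/1 treatment columns. `nrow = n_sites * n_blocks * 8`.
#' @examples
#' d <- build_design(n_sites = 2, n_blocks = 3, seed = 1)
#' table(d$site_id)           # 24 plots per site
#' @export
build_design <- function(n_sites, n_blocks = 3, seed = 1L) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || is.na(n_sites) ||
      n_sites < 1 || n_sites != floor(n_sites)) {
    stop_invalid("invalid design: `n_sites` must be a positive integer")
  }
  if (!is.numeric(n_blocks) || length(n_blocks) != 1L || is.na(n_blocks) ||
      n_blocks < 1 || n_blocks != floor(n_blocks)) {
    stop_invalid("invalid design: `n_blocks` must be a positive integer")
  }
  combos <- treatment_combos()
  out <- vector("list", n_sites * n_blocks)
  k <- 0L
  for (s in seq_len(n_sites)) {
    for (b in seq_len(n_blocks)) {
      k <- k + 1L
      perm <- with_seed(block_seed(seed, s, b), sample.int(8L))
      out[[k]] <- data.frame(
        site_id = sprintf("S%02d", s),
        block_id = sprintf("B%d", b),
        plot_id = seq_len(8L),
        combos[perm, , drop = FALSE],
        row.names = NULL
      )
    }
  }
  do.call(rbind, out)
}

# Per-block seed derived from (seed, site, block); < 2^31 - 1.
block_seed <- function(seed, s, b) {
  ((abs(as.numeric(seed)) %% 1000003) * 10007 + s * 131 + b) %% 2147483647
}

#' Encode the factorial treatments as model-matrix columns
#'
#' Produces the seven treatment columns of the 2^3 factorial (three mains,
#' three two-way products, one three-way product) under either indicator
#' (0/1) or effect (-1/+1) coding. Interaction columns are elementwise
#' products of the coded main columns.
#'
#' @param table A plot table with 0/1 columns `insecticide`, `fungicide`,
#'   `molluscicide`.
#' @param scheme `"indicator"` maps absent/applied to 0/1; `"effect"` maps
#'   them to -1/+1 (the coding used for summary-based interpretation of
#'   main effects).
#' @return A numeric matrix with columns `i`, `f`, `m`, `f:m`, `i:m`,
#'   `i:f`, `i:f:m`.
#' @examples
#' encode_treatments(treatment_combos(), "effect")
#' @export
encode_treatments <- function(table, scheme = c("indicator", "effect")) {
  scheme <- match.arg(scheme)
  check_plot_table_treatments(table)
  i <- table$insecticide
  f <- table$fungicide
  m <- table$molluscicide
  if (scheme == "effect") {
    i <- 2 * i - 1
    f <- 2 * f - 1
    m <- 2 * m - 1
  }
  cbind(i = i, f = f, m = m, "f:m" = f * m, "i:m" = i * m, "i:f" = i * f,
        "i:f:m" = i * f * m)
}

check_plot_table_treatments <- function(x) {
  needed <- c("insecticide", "fungicide", "molluscicide")
  miss <- setdiff(needed, names(x))
  if (length(miss)) {
    stop_invalid("missing treatment column(s): ", paste(miss, collapse = ", "))
  }
  for (tr in needed) {
    if (!all(x[[tr]] %in% c(0, 1))) {
      stop_invalid("treatment column '", tr, "' must be coded 0/1")
    }
  }
  invisible(x)
}

#' Check randomized-complete-block balance of a plot table
#'
#' @param table A plot table.
#' @return `TRUE` invisibly if every (site, block) contains each of the 8
#'   treatment combinations exactly once; otherwise an error.
#' @export
check_balance <- function(table) {
  check_plot_table(table)
  key <- interaction(table$site_id, table$block_id, drop = TRUE)
  combo <- paste(table$insecticide, table$fungicide, table$molluscicide)
  tab <- table(key, combo)
  if (ncol(tab) != 8L || any(tab != 1L)) {
    stop_invalid("design is not a balanced randomized complete block: ",
                 "every (site, block) must contain all 8 combinations once")
  }
  invisible(TRUE)
}
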