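# CSV readers/writers for plot-level biomass and species-cover sheets.
# Dialect: UTF-8, comma-separated, "." decimal, mandatory header row;
# biomass in grams, cover in percent (units embedded in column names).

biomass_required <- c("site_id", "block_id", "plot_id", "insecticide",
                      "fungicide", "molluscicide", "biomass_g")
cover_required <- c("site_id", "block_id", "plot_id", "species", "cover_pct")

check_headers <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_invalid("'", path, "' is missing required column(s): ",
                 paste(miss, collapse = ", "))
  }
}

coerce_treatments <- function(df, path) {
  for (tr in c("insecticide", "fungicide", "molluscicide")) {
    v <- suppressWarnings(as.numeric(df[[tr]]))
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad)) {
      stop_invalid("'", path, "': non-binary value in column '", tr,
                   "' at data row(s) ",
                   paste(utils::head(bad, 5), collapse = ", "))
    }
    df[[tr]] <- as.integer(v)
  }
  df
}

check_duplicates <- function(df, path, extra = character(0)) {
  keys <- c("site_id", "block_id", "plot_id",
            intersect(c("year_since_start", "calendar_year"), names(df)),
            intersect(extra, names(df)))
  key <- do.call(paste, c(df[keys], sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    stop_invalid("'", path, "': duplicated key (",
                 paste(keys, collapse = ", "), ") at data row(s) ",
                 paste(utils::head(which(dup), 5), collapse = ", "))
  }
}

#' Read a plot-level biomass sheet
#'
#' Reads and validates a long-format biomass CSV: required headers, 0/1
#' treatment flags (coerced to integer), numeric positive-or-any biomass,
#' and unique (site, block, plot\[, year\]) keys.
#'
#' @param path Path to a CSV file.
#' @return A validated plot table.
#' @export
read_biomass <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_headers(df, biomass_required, path)
  df <- coerce_treatments(df, path)
  df$biomass_g <- as.numeric(df$biomass_g)
  if (anyNA(df$biomass_g)) {
    stop_invalid("'", path, "': non-numeric biomass_g at data row(s) ",
                 paste(utils::head(which(is.na(df$biomass_g)), 5),
                       collapse = ", "))
  }
  for (cn in c("site_id", "block_id")) df[[cn]] <- as.character(df[[cn]])
  check_duplicates(df, path)
  df
}

#' Read a species cover sheet
#'
#' Reads and validates a long-format percent-cover CSV. Total plot cover
#' above 100% is accepted (species canopies overlap).
#'
#' @param path Path to a CSV file.
#' @return A validated cover table.
#' @export
read_cover <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_headers(df, cover_required, path)
  if (all(c("insecticide", "fungicide", "molluscicide") %in% names(df))) {
    df <- coerce_treatments(df, path)
  }
  df$cover_pct <- as.numeric(df$cover_pct)
  if (anyNA(df$cover_pct) || any(df$cover_pct < 0)) {
    stop_invalid("'", path, "': cover_pct must be numeric and >= 0")
  }
  for (cn in c("site_id", "block_id", "species")) {
    df[[cn]] <- as.character(df[[cn]])
  }
  check_duplicates(df, path, extra = "species")
  df
}

#' Write a plot table to CSV
#'
#' Serializes a plot table with the canonical column order (keys,
#' treatments, then any response/year columns).
#'
#' @param table A plot table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(table, path) {
  lead <- intersect(c("site_id", "block_id", "plot_id", "insecticide",
                      "fungicide", "molluscicide"), names(table))
  rest <- setdiff(names(table), lead)
  utils::write.csv(table[c(lead, rest)], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
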