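`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half up
#'
#' Rounds to `digits` decimals with exact halves going away from zero
#' (for positive input, upward). Used for all printed percentages so that
#' e.g. 52.35 prints as 52.4, matching the convention of published
#' demographic tables rather than R's round-half-even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # tiny nudge guards against binary representation of exact halves
  floor(x * p + 0.5 + 1e-9) / p
}

#' Parse FAERS-style compact dates
#'
#' FAERS dates are 8-digit `YYYYMMDD`, but partial dates (`YYYYMM`, `YYYY`)
#' occur. Partial dates are imputed to the interval midpoint — the 15th of
#' the month, or July 1 of the year — and flagged imprecise so that
#' interval statistics (time to onset) can exclude them.
#'
#' @param x character vector of raw date strings
#' @return list with `date` (Date, `NA` when blank/unparseable) and
#'   `imprecise` (logical; `NA` when the date itself is `NA`)
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[!is.na(x) & x == ""] <- NA_character_
  n <- nchar(x)
  out <- rep(as.Date(NA), length(x))
  imprecise <- rep(FALSE, length(x))
  full <- !is.na(n) & n == 8L
  ym   <- !is.na(n) & n == 6L
  yy   <- !is.na(n) & n == 4L
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  out[ym]   <- as.Date(paste0(x[ym], "15"), format = "%Y%m%d")
  out[yy]   <- as.Date(paste0(x[yy], "0701"), format = "%Y%m%d")
  imprecise[ym | yy] <- TRUE
  imprecise[is.na(out)] <- NA
  list(date = out, imprecise = imprecise)
}

#' Normalize an event/drug term for matching
#'
#' Lower-cases, trims, and collapses internal whitespace. All PT, SOC and
#' drug-name comparisons in the package go through this one function.
#'
#' @param x character vector
#' @return normalized character vector
#' @export
normalize_term <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

## Short deterministic fingerprint of an R object (stamped into output
## tables for provenance). Polynomial hash over the deparsed object.
config_fingerprint <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "niceNames")), collapse = "\n")
  b <- utf8ToInt(txt)
  h <- 0
  m <- 2147483647
  for (i in seq_along(b)) h <- (h * 31 + b[i]) %% m
  sprintf("%08x", h)
}

## Write a data.frame as TSV with a provenance comment header.
write_tsv_stamped <- function(df, path, fingerprint = NULL) {
  hdr <- sprintf("# faersignal %s%s", as.character(packageVersion("faersignal")),
                 if (is.null(fingerprint)) "" else paste0(" config=", fingerprint))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
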