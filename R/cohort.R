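## Target-drug cohort selection, MedDRA hierarchy attachment, and the
## demographic summary table.

#' Define a target-drug query
#'
#' A query is a label, a list of case-insensitive substring patterns
#' matched against the normalized verbatim drug name, and the FAERS role
#' codes that qualify a mention (by default primary and secondary suspect).
#'
#' @param label cohort label, e.g. `"ide-cel"`
#' @param patterns non-empty character vector of match strings (brand,
#'   generic and development code names)
#' @param roles subset of `c("PS", "SS", "C", "I")`; default suspects only
#' @return object of class `drug_query`
#' @export
drug_query <- function(label, patterns, roles = c("PS", "SS")) {
  stopifnot(is.character(label), length(label) == 1L,
            is.character(patterns), length(patterns) >= 1L,
            length(roles) >= 1L, all(roles %in% c("PS", "SS", "C", "I")))
  structure(list(label = label, patterns = normalize_term(patterns),
                 roles = roles), class = "drug_query")
}

#' Shipped default queries for the two anti-BCMA CAR-T products
#'
#' Best-effort pattern lists covering brand, generic and development code
#' names as they appear verbatim in FAERS; override by building your own
#' [drug_query()] when a different string set is needed.
#'
#' @return named list of `drug_query` objects (`ide_cel`, `cilta_cel`)
#' @export
default_drug_queries <- function() {
  list(
    ide_cel = drug_query("ide-cel",
      c("abecma", "idecabtagene", "ide-cel", "bb2121", "bb-2121")),
    cilta_cel = drug_query("cilta-cel",
      c("carvykti", "ciltacabtagene", "cilta-cel", "jnj-68284528",
        "jnj-4528", "lcar-b38m"))
  )
}

match_drug_rows <- function(drugs, query) {
  nm <- normalize_term(drugs$drug_name)
  hit <- rep(FALSE, length(nm))
  for (p in query$patterns) hit <- hit | grepl(p, nm, fixed = TRUE)
  hit & drugs$role %in% query$roles
}

#' Select the reports mentioning a target drug
#'
#' A report enters the cohort when at least one of its drug entries matches
#' any query pattern (case-insensitive substring on the normalized name)
#' with a role in the query's role set. Cohorts for different drugs are not
#' exclusive.
#'
#' @param reports a deduplicated `faers_reports` object
#' @param query a [drug_query()]
#' @return a `faers_reports` object restricted to matching reports
#' @export
select_cohort <- function(reports, query) {
  stopifnot(inherits(reports, "faers_reports"), inherits(query, "drug_query"))
  hit <- match_drug_rows(reports$drugs, query)
  ids <- unique(reports$drugs$primaryid[hit])
  if (length(ids) == 0L)
    warning(sprintf("select_cohort: no reports matched query '%s'", query$label),
            call. = FALSE)
  out <- subset_reports(reports, ids)
  attr(out, "query") <- query
  out
}

## Outcome severity priority used to reduce FAERS multi-outcome reports to
## the single category printed in demographic tables. CA/RI/OT all fold
## into "Other".
OUTCOME_PRIORITY <- c(DE = 1, LT = 2, HO = 3, DS = 4, CA = 5, RI = 5, OT = 5)
OUTCOME_LABELS <- c(`1` = "Death", `2` = "Life-threatening",
                    `3` = "Hospitalization", `4` = "Disability", `5` = "Other")

primary_outcome <- function(reports) {
  oc <- reports$outcomes
  lab <- rep("Unknown or missing", nrow(reports$demo))
  names(lab) <- reports$demo$primaryid
  if (nrow(oc)) {
    pr <- oc[, .(p = min(OUTCOME_PRIORITY[outc_cod], na.rm = TRUE)), by = primaryid]
    lab[pr$primaryid] <- OUTCOME_LABELS[as.character(pr$p)]
  }
  unname(lab)
}

band_counts <- function(values, levels) {
  n <- table(factor(values, levels = levels))
  as.integer(n)
}

#' Demographic summary of a cohort (published-table shape)
#'
#' Tabulates sex, weight bands (<50, 50-100, >100 kg), age bands (<18,
#' 18-64, >=65 years), reporter type, outcome (one category per report by
#' severity priority death > life-threatening > hospitalization >
#' disability > other), report year (from FDA receipt date) and reporting
#' country (United States vs other). Unknown/missing is always its own
#' category so each block sums to the cohort size. Percentages are
#' 100*n/N rounded half-up to one decimal.
#'
#' @param cohort a non-empty `faers_reports` object
#' @return data.frame with columns `block`, `category`, `n`, `pct`
#' @export
summarize_demographics <- function(cohort) {
  stopifnot(inherits(cohort, "faers_reports"))
  N <- nrow(cohort$demo)
  if (N == 0L) stop("summarize_demographics: empty cohort")
  d <- cohort$demo
  unk <- "Unknown or missing"

  sex <- c(F = "Female", M = "Male", unknown = unk)[d$sex]
  wt <- ifelse(is.na(d$weight_kg), unk,
        ifelse(d$weight_kg < 50, "<50",
        ifelse(d$weight_kg <= 100, "50-100", ">100")))
  age <- ifelse(is.na(d$age_years), unk,
         ifelse(d$age_years < 18, "<18",
         ifelse(d$age_years < 65, "18-64", ">=65")))
  rep_ <- c(healthcare_professional = "Healthcare professionals",
            consumer = "Consumers", unknown = unk)[d$reporter]
  outc <- primary_outcome(cohort)
  yr <- ifelse(is.na(d$fda_dt), unk, format(d$fda_dt, "%Y"))
  ctry <- ifelse(d$country %in% c("US", "USA", "UNITED STATES"), "United States",
          ifelse(d$country == "UNKNOWN", unk, "Other country"))

  blocks <- list(
    sex = list(v = sex, lev = c("Female", "Male", unk)),
    weight_kg = list(v = wt, lev = c("<50", "50-100", ">100", unk)),
    age_group = list(v = age, lev = c("<18", "18-64", ">=65", unk)),
    reporter = list(v = rep_, lev = c("Healthcare professionals", "Consumers", unk)),
    outcome = list(v = outc, lev = c("Death", "Life-threatening", "Hospitalization",
                                     "Disability", "Other", unk)),
    report_year = list(v = yr, lev = sort(unique(yr))),
    country = list(v = ctry, lev = c("United States", "Other country", unk))
  )
  out <- data.table::rbindlist(lapply(names(blocks), function(bn) {
    b <- blocks[[bn]]
    n <- band_counts(b$v, b$lev)
    data.table::data.table(block = bn, category = b$lev, n = n,
                           pct = round_half_up(100 * n / N, 1))
  }))
  attr(out, "cohort_size") <- N
  as.data.frame(out)
}

#' Read a PT -> SOC mapping table
#'
#' The package ships no MedDRA dictionary (MedDRA is licensed); supply a
#' two-column tab-separated table with columns `pt` and `soc` (optionally
#' `hlgt`), such as the mini-dictionary emitted by the synthetic-data
#' generator.
#'
#' @param path TSV file path
#' @return data.table with normalized `pt_norm` key plus `pt`, `soc`
#'   (and `hlgt` if present)
#' @export
read_meddra_map <- function(path) {
  m <- data.table::fread(path, sep = "\t", colClasses = "character", na.strings = "")
  data.table::setnames(m, tolower(names(m)))
  stopifnot(all(c("pt", "soc") %in% names(m)))
  m[, pt_norm := normalize_term(pt)]
  unique(m, by = "pt_norm")
}

#' Attach the MedDRA hierarchy to reaction terms
#'
#' Annotates every reaction PT with its system organ class (and high-level
#' group term, when the map provides one). Lookup is case-insensitive
#' after whitespace normalization. Unmapped PTs are retained with `NA` SOC
#' and the unmapped fraction is attached; a fraction above 50% triggers a
#' prominent warning (likely wrong dictionary version).
#'
#' @param reports a `faers_reports` object
#' @param map a mapping table from [read_meddra_map()] (or any data.frame
#'   with `pt` and `soc` columns)
#' @return the report set with `soc` (and `hlgt`) columns on `reactions`
#'   and attribute `unmapped_fraction`
#' @export
attach_meddra <- function(reports, map) {
  stopifnot(inherits(reports, "faers_reports"))
  map <- data.table::as.data.table(map)
  if (!"pt_norm" %in% names(map)) map[, pt_norm := normalize_term(pt)]
  map <- unique(map, by = "pt_norm")
  rx <- data.table::copy(reports$reactions)
  rx[, pt_norm := normalize_term(pt)]
  keep <- intersect(c("pt_norm", "soc", "hlgt"), names(map))
  rx <- merge(rx, map[, ..keep], by = "pt_norm", all.x = TRUE, sort = FALSE)
  rx[, pt_norm := NULL]
  unmapped <- if (nrow(rx)) mean(is.na(rx$soc)) else 0
  if (unmapped > 0.5)
    warning(sprintf("attach_meddra: %.1f%% of reaction PTs are unmapped - is this the right PT->SOC table?",
                    100 * unmapped), call. = FALSE)
  out <- reports
  out$reactions <- rx
  attr(out, "unmapped_fraction") <- unmapped
  out
}
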