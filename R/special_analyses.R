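## Stratified and subset analyses: sex/age subgroups, within-cohort sex
## difference RORs, death-outcome disproportionality, and secondary
## malignancy screening at the high-level-group-term level.

#' Restrict a report set to a named stratum
#'
#' Strata: `"all"`, `"female"`, `"male"`, `"age_18_64"` (18 <= age < 65),
#' `"age_65plus"`, `"under_18"`, and `"death"` (outcome codes include DE).
#' Reports with unknown sex/age are excluded from the corresponding strata
#' (they remain in `"all"`), matching the usual stratified-analysis
#' convention of explicit unknown buckets only in the overall table.
#'
#' @param x a `faers_reports` object
#' @param stratum stratum name
#' @return a restricted `faers_reports` object
#' @export
stratum_filter <- function(x, stratum) {
  d <- x$demo
  ids <- switch(stratum,
    all = d$primaryid,
    female = d$primaryid[d$sex == "F"],
    male = d$primaryid[d$sex == "M"],
    age_18_64 = d$primaryid[!is.na(d$age_years) & d$age_years >= 18 & d$age_years < 65],
    age_65plus = d$primaryid[!is.na(d$age_years) & d$age_years >= 65],
    under_18 = d$primaryid[!is.na(d$age_years) & d$age_years < 18],
    death = intersect(d$primaryid, x$outcomes$primaryid[x$outcomes$outc_cod == "DE"]),
    stop("unknown stratum: ", stratum)
  )
  subset_reports(x, ids)
}

DEFAULT_STRATA <- c("female", "male", "age_18_64", "age_65plus")

#' Per-stratum disproportionality tables
#'
#' Runs the full ROR/IC scan separately inside each stratum: both the
#' universe (comparator) and the cohort are restricted before the 2x2
#' tables are built. The under-18 stratum is omitted by default
#' (insufficient reports in this therapeutic area). A stratum with no
#' target-drug reports yields an empty table carrying a `note` attribute.
#'
#' @param universe full deduplicated `faers_reports`
#' @param cohort target-drug `faers_reports`
#' @param strata character vector of [stratum_filter()] names
#' @param level `"PT"` or `"SOC"`
#' @param criteria [signal_criteria()]
#' @return named list of signal tables (one per stratum)
#' @export
subgroup_signals <- function(universe, cohort, strata = DEFAULT_STRATA,
                             level = "PT", criteria = signal_criteria()) {
  out <- lapply(strata, function(s) {
    u <- stratum_filter(universe, s)
    co <- subset_reports(cohort, intersect(cohort$demo$primaryid, u$demo$primaryid))
    if (nrow(co$demo) == 0L) {
      empty <- detect_signals(disproportionality(u, co, level = level), criteria)
      empty <- empty[0, , drop = FALSE]
      attr(empty, "note") <- sprintf("no target-drug reports in stratum '%s'", s)
      return(empty)
    }
    res <- detect_signals(disproportionality(u, co, level = level), criteria)
    res$stratum <- s
    res
  })
  names(out) <- strata
  out
}

#' Within-cohort female-vs-male reporting odds ratio
#'
#' For each event, the 2x2 table is built inside the target-drug cohort
#' with rows sex (F/M) and columns event (yes/no); ROR > 1 means the event
#' is relatively more reported among female recipients. Wald CI as in
#' [compute_ror()]; reports of unknown sex are excluded. Swapping the
#' sexes inverts the ROR exactly.
#'
#' @param cohort target-drug `faers_reports` with at least one female and
#'   one male report
#' @param events optional character vector of PTs; default all PTs in the
#'   cohort
#' @param level `"PT"` or `"SOC"`
#' @return data.frame: `event`, `n_female`, `n_male`, `ror_f_vs_m`,
#'   `ror_ci_low`, `ror_ci_high`, `ror_undefined`
#' @export
sex_difference_ror <- function(cohort, events = NULL, level = "PT") {
  fem <- stratum_filter(cohort, "female")
  mal <- stratum_filter(cohort, "male")
  nF <- nrow(fem$demo); nM <- nrow(mal$demo)
  if (nF < 1L || nM < 1L)
    stop("sex_difference_ror: need at least one female and one male report")
  pairs <- event_pairs(cohort, level)
  pairs <- pairs[primaryid %in% c(fem$demo$primaryid, mal$demo$primaryid)]
  pairs[, is_f := primaryid %in% fem$demo$primaryid]
  counts <- pairs[, .(event = event[1L], aF = sum(is_f), aM = sum(!is_f)),
                  by = event_norm]
  if (!is.null(events)) counts <- counts[event_norm %in% normalize_term(events)]
  ror <- compute_ror(counts$aF, nF - counts$aF, counts$aM, nM - counts$aM)
  out <- data.frame(event = counts$event, n_female = counts$aF,
                    n_male = counts$aM,
                    ror_f_vs_m = ror$ror, ror_ci_low = ror$ror_ci_low,
                    ror_ci_high = ror$ror_ci_high,
                    ror_undefined = ror$ror_undefined,
                    stringsAsFactors = FALSE)
  out[order(-out$n_female - out$n_male, out$event), , drop = FALSE]
}

#' Death-outcome disproportionality and demographics
#'
#' Restricts both the universe and the cohort to reports whose outcome
#' codes include death (DE), recomputes the ROR/IC scan against the
#' death-restricted universe, and summarizes the demographics of the death
#' subset.
#'
#' @inheritParams subgroup_signals
#' @return list: `signals` (data.frame), `demographics` (data.frame or
#'   `NULL`), `n_death_cohort`, `note`
#' @export
death_outcome_signals <- function(universe, cohort, level = "PT",
                                  criteria = signal_criteria()) {
  u <- stratum_filter(universe, "death")
  co <- stratum_filter(cohort, "death")
  co <- subset_reports(co, intersect(co$demo$primaryid, u$demo$primaryid))
  if (nrow(co$demo) == 0L) {
    return(list(signals = NULL, demographics = NULL, n_death_cohort = 0L,
                note = "no death-outcome reports in cohort"))
  }
  res <- detect_signals(disproportionality(u, co, level = level), criteria)
  list(signals = res, demographics = summarize_demographics(co),
       n_death_cohort = nrow(co$demo), note = NA_character_)
}

#' Read a malignancy term-group table
#'
#' Tab-separated columns `group` (high-level-group-term-style name) and
#' `pt` (member preferred term). The shipped
#' `inst/extdata/malignancy_groups_synthetic.tsv` carries illustrative PT
#' memberships only (the real hierarchy is MedDRA-licensed) and is meant
#' to be replaced by the user's own table.
#'
#' @param path TSV file path
#' @return data.table with `group`, `pt`, `pt_norm`
#' @export
read_malignancy_groups <- function(path) {
  g <- data.table::fread(path, sep = "\t", colClasses = "character", na.strings = "")
  data.table::setnames(g, tolower(names(g)))
  stopifnot(all(c("group", "pt") %in% names(g)))
  g[, pt_norm := normalize_term(pt)]
  unique(g, by = c("group", "pt_norm"))
}

#' Secondary-malignancy screening at group level
#'
#' Aggregates each term group's member PTs into one composite event (a
#' report counts once per group), computes IC/IC025 - the statistic of
#' choice for these sparse events, since it stays defined at zero counts -
#' plus the ROR where defined, and attaches onset summaries (mean/median
#' TTO) per group when TTO records are supplied.
#'
#' @param universe full deduplicated `faers_reports`
#' @param cohort target-drug `faers_reports`
#' @param groups data.frame with `group` and `pt` columns (see
#'   [read_malignancy_groups()])
#' @param ttos optional [compute_tto()] data.frame for the cohort
#' @return data.frame: `group`, `n_cases`, `a`..`d`, IC and ROR columns,
#'   `tto_mean`, `tto_median`, `tto_n`
#' @export
malignancy_screen <- function(universe, cohort, groups, ttos = NULL) {
  groups <- data.table::as.data.table(groups)
  if (!"pt_norm" %in% names(groups)) groups[, pt_norm := normalize_term(pt)]
  pairs <- event_pairs(universe, "PT")
  target_ids <- intersect(cohort$demo$primaryid, universe$demo$primaryid)
  N <- nrow(universe$demo)
  n_target <- length(target_ids)

  res <- lapply(split(groups, by = "group", sorted = TRUE), function(g) {
    hits <- pairs[event_norm %in% g$pt_norm]
    with_event <- unique(hits$primaryid)
    a <- sum(with_event %in% target_ids)
    c_ <- length(with_event) - a
    b <- n_target - a
    d <- N - n_target - c_
    ic <- compute_ic(a, b, c_, d)
    ror <- compute_ror(a, b, c_, d)
    tto_m <- tto_med <- NA_real_; tto_n <- 0L
    if (!is.null(ttos)) {
      tt <- ttos$tto_days[ttos$validity == "valid" &
                            normalize_term(ttos$event) %in% g$pt_norm]
      if (length(tt)) { tto_m <- mean(tt); tto_med <- median(tt); tto_n <- length(tt) }
    }
    data.frame(group = g$group[1L], n_cases = a, a = a, b = b, c = c_, d = d,
               ic = ic$ic, ic025 = ic$ic025, ror = ror$ror,
               ror_ci_low = ror$ror_ci_low, ror_ci_high = ror$ror_ci_high,
               tto_mean = tto_m, tto_median = tto_med, tto_n = tto_n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
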