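## 2x2 contingency construction and ROR / IC disproportionality statistics.
##
## Counting unit: (report, term) pairs define event occurrence - a report
## mentioning a PT twice counts once, and at SOC level a report counts once
## per distinct SOC. a, b, c, d count reports, never pair multiplicity.

event_pairs <- function(reports, level = c("PT", "SOC")) {
  level <- match.arg(level)
  rx <- reports$reactions
  if (level == "SOC") {
    if (!"soc" %in% names(rx))
      stop("SOC-level analysis requires attach_meddra() first")
    pairs <- rx[!is.na(soc), .(primaryid, event = soc)]
  } else {
    pairs <- rx[!is.na(pt), .(primaryid, event = pt)]
  }
  pairs[, event := as.character(event)]
  unique(pairs[, .(primaryid, event, event_norm = normalize_term(event))],
         by = c("primaryid", "event_norm"))
}

#' Build the 2x2 contingency table for one drug-event pair
#'
#' `a` counts target-drug reports mentioning the event, `b` target-drug
#' reports not mentioning it, `c` and `d` the same among all remaining
#' reports in the universe. The universe is the full deduplicated report
#' set (restricted to a stratum upstream when needed), matching the usual
#' "all other drugs" comparator.
#'
#' @param universe `faers_reports`: all reports in the analysis stratum
#' @param cohort `faers_reports`: the target-drug reports (subset of
#'   universe; ids outside the universe are ignored)
#' @param event PT or SOC term (case-insensitive)
#' @param level `"PT"` or `"SOC"`
#' @return list with `a`, `b`, `c`, `d`, `n` (= a + b + c + d), `event`,
#'   `level`
#' @export
build_contingency <- function(universe, cohort, event, level = c("PT", "SOC")) {
  level <- match.arg(level)
  pairs <- event_pairs(universe, level)
  target_ids <- intersect(cohort$demo$primaryid, universe$demo$primaryid)
  N <- nrow(universe$demo)
  n_target <- length(target_ids)
  ev <- normalize_term(event)
  with_event <- unique(pairs$primaryid[pairs$event_norm == ev])
  a <- sum(with_event %in% target_ids)
  c_ <- length(with_event) - a
  list(a = a, b = n_target - a, c = c_, d = N - n_target - c_,
       n = N, event = event, level = level)
}

#' Reporting odds ratio with 95% Wald confidence interval
#'
#' ROR = (a d)/(b c); CI = exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#' Any zero cell leaves the ROR undefined (`NA`) with a reason code rather
#' than applying a continuity correction; set `continuity = TRUE` to add
#' Haldane's 0.5 to every cell of affected tables instead.
#'
#' @param a,b,c,d cell counts (vectors of equal length, or a single table
#'   list from [build_contingency()] passed as `a`)
#' @param conf confidence level (default 0.95)
#' @param continuity apply +0.5 to all cells of tables with a zero cell
#' @return data.frame with `ror`, `ror_ci_low`, `ror_ci_high`,
#'   `ror_undefined` (reason code or `NA`)
#' @export
compute_ror <- function(a, b = NULL, c = NULL, d = NULL, conf = 0.95,
                        continuity = FALSE) {
  if (is.list(a)) { b <- a$b; c <- a$c; d <- a$d; a <- a$a }
  stopifnot(all(c(a, b, c, d) >= 0))
  z <- qnorm(1 - (1 - conf) / 2)
  aa <- as.numeric(a); bb <- as.numeric(b); cc <- as.numeric(c); dd <- as.numeric(d)
  zero <- aa == 0 | bb == 0 | cc == 0 | dd == 0
  reason <- rep(NA_character_, length(aa))
  if (continuity) {
    aa[zero] <- aa[zero] + 0.5; bb[zero] <- bb[zero] + 0.5
    cc[zero] <- cc[zero] + 0.5; dd[zero] <- dd[zero] + 0.5
    reason[zero] <- "continuity_corrected"
    zero <- rep(FALSE, length(aa))
  } else {
    reason[zero] <- "zero_cell"
  }
  ror <- ifelse(zero, NA_real_, (aa * dd) / (bb * cc))
  se <- ifelse(zero, NA_real_, sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd))
  data.frame(ror = ror,
             ror_ci_low = exp(log(ror) - z * se),
             ror_ci_high = exp(log(ror) + z * se),
             ror_undefined = reason,
             stringsAsFactors = FALSE)
}

#' Information component (BCPNN) with IC025
#'
#' The shrunk observed/expected log2 ratio: with E = (a+b)(a+c)/N,
#' IC = log2((a + 0.5)/(E + 0.5)), and the closed-form lower credibility
#' bound IC025 = IC - 3.3 (a+0.5)^-1/2 - 2 (a+0.5)^-3/2. Defined for
#' a = 0, which is what makes the IC usable for sparse events (rare
#' malignancies) where the ROR is undefined.
#'
#' @inheritParams compute_ror
#' @return data.frame with `ic`, `ic025`, `expected` (E)
#' @export
compute_ic <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.list(a)) { b <- a$b; c <- a$c; d <- a$d; a <- a$a }
  N <- as.numeric(a) + b + c + d
  stopifnot(all(N > 0))
  E <- (as.numeric(a) + b) * (as.numeric(a) + c) / N
  ic <- log2((a + 0.5) / (E + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  data.frame(ic = ic, ic025 = ic025, expected = E)
}

#' Disproportionality scan over all events at one level
#'
#' Builds every event's 2x2 table against the universe in one vectorized
#' pass (identical counting rule to [build_contingency()]) and evaluates
#' ROR and IC for each.
#'
#' @param universe `faers_reports`: all reports in the stratum
#' @param cohort `faers_reports`: target-drug reports
#' @param level `"PT"` or `"SOC"`
#' @param events optional character vector restricting the scan; default
#'   all events observed in the universe
#' @param continuity passed to [compute_ror()]
#' @return data.frame, one row per event: `level`, `event`, `n_cases` (=a),
#'   `a`, `b`, `c`, `d`, ROR columns, IC columns
#' @export
disproportionality <- function(universe, cohort, level = c("PT", "SOC"),
                               events = NULL, continuity = FALSE) {
  level <- match.arg(level)
  pairs <- event_pairs(universe, level)
  target_ids <- intersect(cohort$demo$primaryid, universe$demo$primaryid)
  N <- nrow(universe$demo)
  n_target <- length(target_ids)
  pairs[, in_target := primaryid %in% target_ids]
  counts <- pairs[, .(event = event[1L], a = sum(in_target), total = .N),
                  by = event_norm]
  if (!is.null(events)) counts <- counts[event_norm %in% normalize_term(events)]
  a <- counts$a
  b <- n_target - a
  c_ <- counts$total - a
  d <- N - n_target - c_
  res <- data.frame(level = rep(level, nrow(counts)), event = counts$event, n_cases = a,
                    a = a, b = b, c = c_, d = d, stringsAsFactors = FALSE)
  res <- cbind(res, compute_ror(a, b, c_, d, continuity = continuity),
               compute_ic(a, b, c_, d))
  res[order(-res$n_cases, res$event), , drop = FALSE]
}

#' Signal criteria
#'
#' Default thresholds: an ROR signal needs at least `min_cases` reports and
#' a Wald CI lower bound above `ror_lower`; an IC signal needs
#' IC025 above `ic025_lower`. No multiple-testing correction is applied,
#' matching standard pharmacovigilance screening practice.
#'
#' @param min_cases minimum case count for the ROR criterion (default 3)
#' @param ror_lower ROR CI lower-bound threshold (default 1)
#' @param ic025_lower IC025 threshold (default 0)
#' @return list of class `signal_criteria`
#' @export
signal_criteria <- function(min_cases = 3L, ror_lower = 1, ic025_lower = 0) {
  structure(list(min_cases = min_cases, ror_lower = ror_lower,
                 ic025_lower = ic025_lower), class = "signal_criteria")
}

#' Apply signal criteria to a disproportionality table
#'
#' @param results data.frame from [disproportionality()]
#' @param criteria a [signal_criteria()] object
#' @return `results` with logical columns `ror_signal` and `ic_signal`
#' @export
detect_signals <- function(results, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  results$ror_signal <- !is.na(results$ror_ci_low) &
    results$n_cases >= criteria$min_cases &
    results$ror_ci_low > criteria$ror_lower
  results$ic_signal <- !is.na(results$ic025) & results$ic025 > criteria$ic025_lower
  results
}

#' Top-k signal ranking
#'
#' Orders signal-positive events descending by the chosen statistic (ROR by
#' default, as in published top-20 tables); ties broken by case count
#' (descending) then event name.
#'
#' @param results output of [detect_signals()]
#' @param k number of rows to keep (a larger `k` returns the full list)
#' @param by ranking key: `"ror"` or `"ic"`
#' @return the ranked, truncated data.frame
#' @export
rank_top <- function(results, k = 20L, by = c("ror", "ic")) {
  by <- match.arg(by)
  flag <- if (by == "ror") results$ror_signal else results$ic_signal
  pos <- results[!is.na(flag) & flag, , drop = FALSE]
  key <- pos[[by]]
  ord <- order(-key, -pos$n_cases, pos$event)
  pos <- pos[ord, , drop = FALSE]
  utils::head(pos, k)
}

#' Flag signals absent from the product label
#'
#' A signal-positive event (ROR or IC criterion) whose PT is not in the
#' supplied label term list is marked unexpected. Non-signals are never
#' flagged. An empty label list marks every signal unexpected, with a
#' warning.
#'
#' @param results output of [detect_signals()]
#' @param label_terms character vector of labelled PTs (case-insensitive)
#' @return `results` with a logical `unexpected` column
#' @export
flag_unexpected <- function(results, label_terms) {
  if (length(label_terms) == 0L)
    warning("flag_unexpected: empty label term list - every signal will be marked unexpected",
            call. = FALSE)
  is_signal <- (results$ror_signal %||% FALSE) | (results$ic_signal %||% FALSE)
  listed <- normalize_term(results$event) %in% normalize_term(label_terms)
  results$unexpected <- is_signal & !listed
  results
}

#' Wald-width feasibility of a printed ROR confidence interval
#'
#' For a 95% Wald interval, log(hi/lo)/(2 z) equals sqrt(1/a + 1/b + 1/c +
#' 1/d), which cannot be smaller than sqrt(1/a). Given only a published
#' case count and CI, this checks that the pair is internally consistent
#' with a Wald construction.
#'
#' @param n_cases the `a` cell
#' @param ci_low,ci_high published CI bounds
#' @param conf confidence level
#' @return logical; attributes `implied_se` and `min_se`
#' @export
ror_ci_feasible <- function(n_cases, ci_low, ci_high, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  implied <- log(ci_high / ci_low) / (2 * z)
  minimum <- sqrt(1 / n_cases)
  structure(implied >= minimum, implied_se = implied, min_se = minimum)
}
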