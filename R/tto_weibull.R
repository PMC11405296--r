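## Time-to-onset: event date minus earliest matching therapy start, onset
## window summaries, and a two-parameter Weibull MLE with failure-type
## classification from the shape parameter.

#' Compute time-to-onset records for a cohort
#'
#' For each (report, reaction) in the cohort, TTO is the event date minus
#' the earliest therapy start date among drug entries matching the query,
#' in whole days. Every record carries a validity code:
#' `valid`, `negative` (event before start), `missing_start`,
#' `missing_event`, or `imprecise_date` (a partial date entered the
#' difference; excluded from fits unless `include_imprecise = TRUE`).
#'
#' @param cohort a `faers_reports` cohort
#' @param query the [drug_query()] identifying which drug entries' start
#'   dates count
#' @param include_imprecise treat midpoint-imputed partial dates as valid
#' @return data.frame: `report_id`, `event` (PT), `tto_days` (integer, `NA`
#'   unless valid), `validity`
#' @export
compute_tto <- function(cohort, query, include_imprecise = FALSE) {
  stopifnot(inherits(cohort, "faers_reports"), inherits(query, "drug_query"))
  dg <- cohort$drugs[match_drug_rows(cohort$drugs, query) & !is.na(start_dt)]
  starts <- if (nrow(dg)) {
    dg[, .(start_dt = min(start_dt),
           start_imprecise = start_imprecise[which.min(start_dt)]),
       by = primaryid]
  } else {
    data.table::data.table(primaryid = character(0),
                           start_dt = as.Date(character(0)),
                           start_imprecise = logical(0))
  }
  rec <- merge(cohort$reactions[, .(primaryid, pt)],
               cohort$demo[, .(primaryid, event_dt, event_imprecise)],
               by = "primaryid", all.x = TRUE, sort = FALSE)
  rec <- merge(rec, starts, by = "primaryid", all.x = TRUE, sort = FALSE)

  tto <- as.integer(rec$event_dt - rec$start_dt)
  imprecise <- (rec$event_imprecise %in% TRUE) | (rec$start_imprecise %in% TRUE)
  validity <- ifelse(is.na(rec$event_dt), "missing_event",
              ifelse(is.na(rec$start_dt), "missing_start",
              ifelse(imprecise & !include_imprecise, "imprecise_date",
              ifelse(tto < 0, "negative", "valid"))))
  out <- data.frame(report_id = rec$primaryid, event = rec$pt,
                    tto_days = ifelse(validity == "valid", tto, NA_integer_),
                    validity = validity, stringsAsFactors = FALSE)
  out[order(out$report_id, out$event), , drop = FALSE]
}

valid_ttos <- function(ttos) {
  if (is.data.frame(ttos)) ttos$tto_days[ttos$validity == "valid"] else ttos[!is.na(ttos)]
}

#' Onset-window summary
#'
#' Median (midpoint-of-middle-two convention), mean, quartiles, and the
#' proportions of onsets on day 0 and within 30 days, over valid records
#' only.
#'
#' @param ttos a [compute_tto()] data.frame, or a numeric vector of valid
#'   onset days
#' @param window day cutoff for the "early onset" proportion (default 30)
#' @return list: `n_valid`, `mean`, `median`, `q1`, `q3`,
#'   `prop_within_window`, `prop_day0`, `window`; all-`NA` summary (with
#'   `n_valid = 0`) when no record is valid
#' @export
onset_window_summary <- function(ttos, window = 30) {
  x <- valid_ttos(ttos)
  if (length(x) == 0L)
    return(list(n_valid = 0L, mean = NA_real_, median = NA_real_,
                q1 = NA_real_, q3 = NA_real_, prop_within_window = NA_real_,
                prop_day0 = NA_real_, window = window))
  q <- unname(quantile(x, c(0.25, 0.75), type = 7))
  list(n_valid = length(x), mean = mean(x), median = median(x),
       q1 = q[1], q3 = q[2],
       prop_within_window = mean(x <= window),
       prop_day0 = mean(x == 0),
       window = window)
}

weibull_negloglik <- function(par, x) {
  k <- exp(par[1]); lam <- exp(par[2])
  -(length(x) * (log(k) - k * log(lam)) + (k - 1) * sum(log(x)) - sum((x / lam)^k))
}

weibull_negloglik_grad <- function(par, x) {
  k <- exp(par[1]); lam <- exp(par[2])
  n <- length(x)
  r <- (x / lam)^k
  dk <- n / k - n * log(lam) + sum(log(x)) - sum(r * log(x / lam))
  dlam <- -n * k / lam + k * sum(r) / lam
  -c(dk * k, dlam * lam)  # chain rule for log-parameters
}

weibull_fail <- function(reason, n_used = 0L) {
  structure(list(converged = FALSE, reason = reason, n_used = n_used,
                 alpha = NA_real_, alpha_ci = c(NA_real_, NA_real_),
                 beta = NA_real_, beta_ci = c(NA_real_, NA_real_),
                 log_likelihood = NA_real_, failure_type = "indeterminate"),
            class = "weibull_fit")
}

#' Two-parameter Weibull maximum-likelihood fit
#'
#' Fits scale alpha (days) and shape beta to positive onset times by
#' maximizing the Weibull log-likelihood over log-parameters (BFGS with
#' analytic gradient from a moment-based start). 95% CIs are Wald
#' intervals on the log scale (so the bounds are always positive),
#' back-transformed. Day-0 onsets, which Weibull support excludes but
#' which dominate CAR-T reporting, are shifted to 0.5 day by default;
#' alternatives are dropping them or adding one day to every record.
#'
#' @param ttos a [compute_tto()] data.frame or numeric vector of onset days
#' @param zero_handling `"shift"` (0 -> `shift` days), `"drop"`, or
#'   `"offset"` (+1 day to all records)
#' @param shift replacement value for day-0 onsets under `"shift"`
#' @param conf confidence level
#' @param min_n minimum usable records (default 10); fewer gives an
#'   explicit failure result, never an error
#' @return object of class `weibull_fit`: `alpha`, `alpha_ci`, `beta`,
#'   `beta_ci`, `n_used`, `log_likelihood`, `failure_type`, `converged`
#' @export
weibull_mle <- function(ttos, zero_handling = c("shift", "drop", "offset"),
                        shift = 0.5, conf = 0.95, min_n = 10L) {
  zero_handling <- match.arg(zero_handling)
  x <- as.numeric(valid_ttos(ttos))
  x <- x[!is.na(x) & x >= 0]
  x <- switch(zero_handling,
              shift = { x[x == 0] <- shift; x },
              drop = x[x > 0],
              offset = x + 1)
  x <- x[x > 0]
  if (length(x) < min_n)
    return(weibull_fail(sprintf("fewer than %d usable records", min_n), length(x)))
  if (length(unique(x)) == 1L)
    return(weibull_fail("degenerate sample: all values equal", length(x)))

  # moment-based start: shape from the SD of log-times (Gumbel relation),
  # scale from the log-mean plus Euler-Mascheroni correction
  s <- stats::sd(log(x))
  k0 <- min(max(1.2 / s, 0.05), 50)
  lam0 <- exp(mean(log(x)) + 0.5772156649 / k0)
  opt <- tryCatch(
    optim(c(log(k0), log(lam0)), weibull_negloglik, gr = weibull_negloglik_grad,
          x = x, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) NULL)
  if (is.null(opt)) return(weibull_fail("optimizer error", length(x)))
  grad <- weibull_negloglik_grad(opt$par, x)
  if (sqrt(sum(grad^2)) > 1e-4 * max(1, length(x)))
    return(weibull_fail("gradient norm above tolerance at optimum", length(x)))

  H <- optimHess(opt$par, weibull_negloglik, gr = weibull_negloglik_grad, x = x)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(diag(V) <= 0))
    return(weibull_fail("singular observed information", length(x)))
  z <- qnorm(1 - (1 - conf) / 2)
  se <- sqrt(diag(V))
  beta <- exp(opt$par[1]); alpha <- exp(opt$par[2])
  beta_ci <- exp(opt$par[1] + c(-1, 1) * z * se[1])
  alpha_ci <- exp(opt$par[2] + c(-1, 1) * z * se[2])
  fit <- structure(list(converged = TRUE, reason = NA_character_,
                        n_used = length(x),
                        alpha = alpha, alpha_ci = alpha_ci,
                        beta = beta, beta_ci = beta_ci,
                        log_likelihood = -opt$value,
                        vcov_log = V,
                        zero_handling = zero_handling,
                        failure_type = NA_character_),
                   class = "weibull_fit")
  fit$failure_type <- classify_failure_type(fit)
  fit
}

#' @export
print.weibull_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<weibull_fit> failed: %s (n=%d)\n", x$reason, x$n_used))
  } else {
    cat(sprintf("<weibull_fit> n=%d  scale alpha=%.2f (%.2f, %.2f)  shape beta=%.2f (%.2f, %.2f)  %s\n",
                x$n_used, x$alpha, x$alpha_ci[1], x$alpha_ci[2],
                x$beta, x$beta_ci[1], x$beta_ci[2], x$failure_type))
  }
  invisible(x)
}

#' Failure-type classification from the shape-parameter CI
#'
#' `early` when the whole CI for beta lies below 1 (hazard declines: onsets
#' concentrate right after administration), `wear_out` when it lies above
#' 1 (hazard rises with time on therapy), `random` when the CI contains 1
#' (memoryless/exponential-like onsets), `indeterminate` for failed fits.
#'
#' @param fit a `weibull_fit`
#' @return one of `"early"`, `"random"`, `"wear_out"`, `"indeterminate"`
#' @export
classify_failure_type <- function(fit) {
  if (!isTRUE(fit$converged) || any(is.na(fit$beta_ci))) return("indeterminate")
  if (fit$beta_ci[2] < 1) "early"
  else if (fit$beta_ci[1] > 1) "wear_out"
  else "random"
}
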