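#!/usr/bin/env Rscript
# Time-to-onset: validity accounting, onset-window summaries, the
# two-parameter Weibull fit with failure-type classification, and the
# per-SOC onset table (box-plot-ready).

source(file.path("analysis", "_common.R"))

universe <- load_universe()
queries <- study_queries()

for (qn in names(queries)) {
  q <- queries[[qn]]
  cohort <- select_cohort(universe, q)
  tt <- compute_tto(cohort, q)
  write.table(tt, file.path(RESULTS, sprintf("%s_tto_records.tsv", qn)),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cat(sprintf("\n%s: %d (report, event) records\n", qn, nrow(tt)))
  print(table(tt$validity))
  s <- onset_window_summary(tt)
  cat(sprintf("  onset: median %.1f d (IQR %.1f-%.1f), mean %.1f d; %.1f%% within 30 d, %.1f%% on day 0\n",
              s$median, s$q1, s$q3, s$mean,
              100 * s$prop_within_window, 100 * s$prop_day0))

  fit <- weibull_mle(tt)
  print(fit)
  jsonlite::write_json(
    list(summary = s,
         weibull = list(n_used = fit$n_used, alpha = fit$alpha,
                        alpha_ci = fit$alpha_ci, beta = fit$beta,
                        beta_ci = fit$beta_ci, failure_type = fit$failure_type)),
    file.path(RESULTS, sprintf("%s_tto_fit.json", qn)),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # per-SOC onset distribution (data behind the usual box plots)
  rx <- universe$reactions
  socmap <- unique(data.frame(pt_norm = normalize_term(rx$pt), soc = rx$soc))
  tt_ok <- tt[tt$validity == "valid", ]
  tt_ok$pt_norm <- normalize_term(tt_ok$event)
  bysoc <- merge(tt_ok, socmap, by = "pt_norm")[, c("report_id", "soc", "event", "tto_days")]
  write.table(bysoc[order(bysoc$soc, bysoc$report_id), ],
              file.path(RESULTS, sprintf("%s_tto_by_soc.tsv", qn)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
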