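#!/usr/bin/env Rscript
# Select the two drug cohorts and produce the characteristics tables
# (sex, weight, age bands, reporter, outcome, year, country).

source(file.path("analysis", "_common.R"))

universe <- load_universe()
queries <- study_queries()

for (qn in names(queries)) {
  cohort <- select_cohort(universe, queries[[qn]])
  dm <- summarize_demographics(cohort)
  f <- file.path(RESULTS, sprintf("%s_demographics.tsv", qn))
  write.table(dm, f, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("\n%s cohort: N = %d (-> %s)\n", qn, nreports(cohort), f))
  top <- dm[dm$block %in% c("sex", "outcome"), ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-9s %-20s %5d (%.1f)\n",
                top$block[i], top$category[i], top$n[i], top$pct[i]))
}
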