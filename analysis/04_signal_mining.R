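#!/usr/bin/env Rscript
# Disproportionality signal mining: ROR (Wald 95% CI) and IC (IC025) at PT
# and SOC level, top-20 ranking by ROR, and unexpected-signal flagging
# against the shipped label term lists.

source(file.path("analysis", "_common.R"))

universe <- load_universe()
queries <- study_queries()
labels <- read.delim(system.file("extdata", "label_terms_default.tsv",
                                 package = "faersignal"))

for (qn in names(queries)) {
  q <- queries[[qn]]
  cohort <- select_cohort(universe, q)
  terms <- labels$pt[labels$drug == q$label]

  pt <- flag_unexpected(detect_signals(disproportionality(universe, cohort, "PT")),
                        terms)
  soc <- detect_signals(disproportionality(universe, cohort, "SOC"))
  top <- rank_top(pt, 20)

  for (nm in c("signals_pt", "signals_soc", "top20")) {
    obj <- switch(nm, signals_pt = pt, signals_soc = soc, top20 = top)
    write.table(obj, file.path(RESULTS, sprintf("%s_%s.tsv", qn, nm)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cat(sprintf("\n%s: %d PT signals (ROR or IC) out of %d PTs; %d SOC signals\n",
              qn, sum(pt$ror_signal | pt$ic_signal), nrow(pt),
              sum(soc$ror_signal | soc$ic_signal)))
  cat("top 5 by ROR:\n")
  for (i in seq_len(min(5, nrow(top))))
    cat(sprintf("  %-55s n=%4d ROR %8.2f (%.2f-%.2f)  IC %5.2f (%5.2f)%s\n",
                top$event[i], top$n_cases[i], top$ror[i], top$ror_ci_low[i],
                top$ror_ci_high[i], top$ic[i], top$ic025[i],
                if (isTRUE(top$unexpected[i])) "  [unexpected]" else ""))
}
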