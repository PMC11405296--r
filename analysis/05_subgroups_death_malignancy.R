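#!/usr/bin/env Rscript
# Stratified and subset analyses: sex/age subgroup signal tables,
# within-cohort female-vs-male RORs, death-outcome disproportionality,
# and the secondary-malignancy group screen with onset summaries.

source(file.path("analysis", "_common.R"))

universe <- load_universe()
queries <- study_queries()
groups <- read_malignancy_groups(system.file("extdata",
  "malignancy_groups_synthetic.tsv", package = "faersignal"))

for (qn in names(queries)) {
  q <- queries[[qn]]
  cohort <- select_cohort(universe, q)

  sg <- subgroup_signals(universe, cohort)
  for (s in names(sg))
    write.table(sg[[s]], file.path(RESULTS, sprintf("%s__%s__signals.tsv", qn, s)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("\n%s subgroup signal counts: %s\n", qn,
              paste(sprintf("%s=%d", names(sg),
                            vapply(sg, function(t) sum(t$ror_signal), 0L)),
                    collapse = ", ")))

  sexdiff <- sex_difference_ror(cohort)
  write.table(sexdiff, file.path(RESULTS, sprintf("%s_sex_difference.tsv", qn)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fem <- sexdiff[!is.na(sexdiff$ror_ci_low) & sexdiff$ror_ci_low > 1, ]
  mal <- sexdiff[!is.na(sexdiff$ror_ci_high) & sexdiff$ror_ci_high < 1, ]
  cat(sprintf("  female-enriched events: %s\n",
              paste(head(fem$event, 3), collapse = "; ")))
  cat(sprintf("  male-enriched events:   %s\n",
              paste(head(mal$event, 3), collapse = "; ")))

  de <- death_outcome_signals(universe, cohort)
  if (!is.null(de$signals)) {
    write.table(de$signals, file.path(RESULTS, sprintf("%s_death_signals.tsv", qn)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(de$demographics,
                file.path(RESULTS, sprintf("%s_death_demographics.tsv", qn)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("  death subset: %d reports, %d ROR signals\n",
                de$n_death_cohort, sum(de$signals$ror_signal)))
  }

  tt <- compute_tto(cohort, q)
  scr <- malignancy_screen(universe, cohort, groups, ttos = tt)
  write.table(scr, file.path(RESULTS, sprintf("%s_malignancy_screen.tsv", qn)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- scr[scr$ic025 > 0, ]
  for (i in seq_len(nrow(sig)))
    cat(sprintf("  malignancy signal: %-45s n=%3d IC025 %.2f median TTO %s d\n",
                sig$group[i], sig$n_cases[i], sig$ic025[i],
                ifelse(is.na(sig$tto_median[i]), "-", sig$tto_median[i])))
}
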