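#!/usr/bin/env Rscript
# Generate the study-condition dataset: FAERS-dialect quarterly tables for
# a 20,000-report background with two anti-BCMA CAR-T cohorts and ten
# implanted drug-event signals of known relative reporting rate.

source(file.path("analysis", "_common.R"))

cfg <- study_config()
sim <- simulate_faers(cfg)
paths <- write_faers(sim, RAW_DIR)

man <- sim$manifest
cat(sprintf("simulated %d unique reports (+%d duplicate records) into %s\n",
            man$n_unique_reports, man$n_duplicate_records, RAW_DIR))
cat(sprintf("background per-report PT probability p0 = %.5f\n", man$p_background_pt))
cat("implanted signals (design rate -> realized case count):\n")
for (im in man$implants)
  cat(sprintf("  %-9s %-55s rate %3d  stratum %-10s a = %d\n",
              im$drug, im$pt, im$rate, im$stratum, im$actual_a))
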