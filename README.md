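# faersignal

Safety signal detection and time-to-onset modelling for spontaneous
adverse-event reports, built around the analysis a pharmacovigilance group
runs on the FDA Adverse Event Reporting System (FAERS): ingest the
quarterly "$"-delimited ASCII tables, deduplicate cases by the
FDA-recommended rule, select target-drug cohorts, mine drug–event
disproportionality signals, and model when the events occur. The worked
study is the safety profile of the two anti-BCMA CAR-T products
(idecabtagene vicleucel and ciltacabtagene autoleucel) — hallmark
toxicities such as cytokine release syndrome, stratified sex/age signals,
death-outcome associations, and late-onset secondary malignancies — but
every drug and event is configuration, not code.

## The statistics

For each (drug, event) pair, reports are cross-classified into the 2×2
table

|                | event | other events |
|----------------|-------|--------------|
| **target drug**| a     | b            |
| **other drugs**| c     | d            |

and two disproportionality statistics are computed:

* **Reporting odds ratio**: ROR = (a·d)/(b·c), with the 95% Wald interval
  exp(ln ROR ± z·√(1/a + 1/b + 1/c + 1/d)). A zero cell leaves the ROR
  undefined (flagged, no silent continuity correction). Default signal
  criterion: a ≥ 3 and CI lower bound > 1.
* **Information component** (BCPNN): with E = (a+b)(a+c)/N,
  IC = log₂((a + ½)/(E + ½)) and
  IC025 = IC − 3.3(a + ½)^−½ − 2(a + ½)^−3/2. The IC stays defined at
  a = 0, which is what makes it usable for sparse events such as secondary
  malignancies. Signal criterion: IC025 > 0.

Time to onset (event date − earliest matching therapy start) is modelled
with a two-parameter Weibull via maximum likelihood; Wald CIs are computed
on the log-parameters. The shape β classifies the hazard: β < 1 with the
whole CI below 1 is *early failure* (onsets concentrate right after
administration), a CI containing 1 is *random*, a CI above 1 is
*wear-out* — the regime that flags events needing long-term surveillance.

Because real FAERS analyses also require the licensed MedDRA dictionary,
the package includes a first-class synthetic generator
(`simulate_faers()`) that emits FAERS-dialect files with implanted signals
of known relative reporting rate, duplicate chains, stratum-restricted
effects, and Weibull onset times — so the whole pipeline is testable with
exact ground truth, and `expected_contingency()` gives the closed-form
table each implant should produce.

## Worked example

```r
library(faersignal)

cfg <- simulation_config(
  n_reports = 8000, seed = 2024,
  pt_names = replace(sprintf("Synthetic PT %03d", 1:200),
                     1:2, c("Cytokine release syndrome", "Febrile bone marrow aplasia")),
  target_drugs = list(list(name = "ABECMA", share = 0.05)),
  implants = list(sim_implant("ABECMA", "Cytokine release syndrome", rate = 80),
                  sim_implant("ABECMA", "Febrile bone marrow aplasia", rate = 30)))

universe <- deduplicate(sim_reports(simulate_faers(cfg)))
#> <faers_reports> 8000 report(s), 13503 drug row(s), 15351 reaction row(s), 6560 outcome row(s)
#>   deduplicated: 400 record(s) removed

cohort <- select_cohort(universe, drug_query("ide-cel", "abecma"))
signals <- detect_signals(disproportionality(universe, cohort, "PT"))
rank_top(signals, 3)[, c("event", "n_cases", "ror", "ror_ci_low", "ror_ci_high", "ic", "ic025")]
#>                           event n_cases       ror ror_ci_low ror_ci_high       ic      ic025
#> 26    Cytokine release syndrome     306 343.04258  247.16881  476.104625 3.985090  3.7962230
#> 36  Febrile bone marrow aplasia     110  38.85511   28.29073   53.364448 3.516776  3.2011239
#> 129            Synthetic PT 039       8   2.71525    1.28651    5.730683 1.186838 -0.0257584

weibull_mle(compute_tto(cohort, drug_query("ide-cel", "abecma")))
#> <weibull_fit> n=1185  scale alpha=20.25 (18.14, 22.60)  shape beta=0.55 (0.53, 0.57)  early
```

Reading the output: the two implanted signals are recovered at the top of
the ranking with tight intervals (both design rates sit inside the fitted
CIs once the rate is translated through the generative model, see
`expected_contingency()`), the third row is a borderline background
fluctuation that the IC criterion correctly declines to flag
(IC025 < 0), and the onset fit lands in the early-failure regime
(β = 0.55, CI entirely below 1): most events occur shortly after
administration.

## The analysis workflow

The `analysis/` scripts run the full study end to end on a 20,000-report
synthetic universe with two CAR-T cohorts and ten implanted signals, and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R                 # FAERS-dialect files + ground-truth manifest
Rscript analysis/02_ingest_dedup.R             # parse back, FDA dedup rule
Rscript analysis/03_demographics.R             # characteristics tables
Rscript analysis/04_signal_mining.R            # ROR/IC at PT & SOC level, top-20, unexpected flags
Rscript analysis/05_subgroups_death_malignancy.R
Rscript analysis/06_time_to_onset.R            # onset windows, Weibull fits, per-SOC tables
```

Real quarterly files work the same way: point `parse_quarter()` at the
downloaded DEMO/DRUG/REAC/OUTC/THER tables, supply your own PT→SOC table
(`read_meddra_map()`) in place of the generator's mini-dictionary, and the
identical code path runs. `run_pipeline()` wraps all stages into one
call that emits the complete report bundle.

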