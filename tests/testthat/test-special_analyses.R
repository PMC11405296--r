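test_that("stratum filters restrict by sex, age band and death outcome; unknowns drop out", {
  rep <- mk_reports(
    demo = data.frame(primaryid = as.character(1:6),
                      sex = c("F", "M", "F", "unknown", "M", "F"),
                      age_years = c(30, 70, NA, 50, 17, 65)),
    outcomes = data.frame(primaryid = c("1", "2"), outc_cod = c("DE", "HO"))
  )
  expect_setequal(stratum_filter(rep, "female")$demo$primaryid, c("1", "3", "6"))
  expect_setequal(stratum_filter(rep, "age_18_64")$demo$primaryid, c("1", "4"))
  expect_setequal(stratum_filter(rep, "age_65plus")$demo$primaryid, c("2", "6"))
  expect_setequal(stratum_filter(rep, "under_18")$demo$primaryid, "5")
  expect_setequal(stratum_filter(rep, "death")$demo$primaryid, "1")
  expect_error(stratum_filter(rep, "martians"), "unknown stratum")
})

test_that("a-counts over disjoint exhaustive sex strata sum to the overall a", {
  uni <- random_fixture(17, n = 300, n_drugs = 4, n_pts = 10)
  co <- select_cohort(uni, drug_query("d", "drug01"))
  overall <- disproportionality(uni, co, "PT")
  parts <- lapply(list(
    stratum_filter(uni, "female"),
    stratum_filter(uni, "male"),
    subset_reports(uni, uni$demo$primaryid[uni$demo$sex == "unknown"])
  ), function(u) {
    disproportionality(u, subset_reports(co, u$demo$primaryid), "PT")
  })
  for (ev in overall$event) {
    a_sum <- sum(vapply(parts, function(p) {
      hit <- p$a[p$event == ev]
      if (length(hit)) hit else 0L
    }, numeric(1)))
    expect_equal(a_sum, overall$a[overall$event == ev])
  }
})

test_that("a stratum-restricted implanted signal is detected only in its stratum", {
  cfg <- simulation_config(
    n_reports = 4000, seed = 31, duplicate_fraction = 0,
    implants = list(sim_implant("IDE-CEL", "Synthetic PT 020", rate = 40,
                                stratum = "female")))
  uni <- deduplicate(sim_reports(simulate_faers(cfg)))
  co <- select_cohort(uni, drug_query("ide-cel", "ide-cel"))
  sg <- subgroup_signals(uni, co, c("female", "male"))
  f <- sg$female; m <- sg$male
  expect_true(f$ror_signal[f$event == "Synthetic PT 020"])
  m_row <- m[m$event == "Synthetic PT 020", ]
  expect_true(nrow(m_row) == 0 || !isTRUE(m_row$ror_signal))
})

test_that("a stratum with no target-drug reports yields an empty table with a note", {
  uni <- mk_reports(
    demo = data.frame(primaryid = c("1", "2"), sex = c("M", "M")),
    drugs = data.frame(primaryid = c("1", "2"), drug_name = c("T", "X"), role = "PS"),
    reactions = data.frame(primaryid = c("1", "2"), pt = "Pyrexia")
  )
  co <- select_cohort(uni, drug_query("t", "t"))
  sg <- subgroup_signals(uni, co, c("female"))
  expect_equal(nrow(sg$female), 0L)
  expect_match(attr(sg$female, "note"), "no target-drug reports")
})

test_that("female-vs-male ROR matches the direct formula and inverts under sex swap", {
  mk_sexed <- function(sexes, with_event) {
    n <- length(sexes)
    pid <- as.character(seq_len(n))
    mk_reports(
      demo = data.frame(primaryid = pid, sex = sexes),
      drugs = data.frame(primaryid = pid, drug_name = "T", role = "PS"),
      reactions = data.frame(primaryid = pid,
                             pt = ifelse(with_event, "Target event", "Filler"))
    )
  }
  sexes <- rep(c("F", "M"), each = 100)
  with_event <- c(rep(TRUE, 20), rep(FALSE, 80), rep(TRUE, 5), rep(FALSE, 95))
  co <- mk_sexed(sexes, with_event)
  r <- sex_difference_ror(co, events = "Target event")
  expect_equal(r$ror_f_vs_m, (20 * 95) / (80 * 5))  # = 4.75

  swapped <- mk_sexed(ifelse(sexes == "F", "M", "F"), with_event)
  r2 <- sex_difference_ror(swapped, events = "Target event")
  expect_equal(r2$ror_f_vs_m, 1 / r$ror_f_vs_m)

  sym <- mk_sexed(sexes, rep(c(TRUE, FALSE), times = c(10, 90) + 0)[c(1:100, 1:100)])
  expect_equal(sex_difference_ror(sym, events = "Target event")$ror_f_vs_m, 1.0)
})

test_that("a female-enriched implant shows a sex-difference ROR above 1", {
  cfg <- simulation_config(
    n_reports = 4000, seed = 57, duplicate_fraction = 0,
    target_drugs = list(list(name = "IDE-CEL", share = 0.12)),
    implants = list(sim_implant("IDE-CEL", "Synthetic PT 008", rate = 50,
                                stratum = "female")))
  uni <- deduplicate(sim_reports(simulate_faers(cfg)))
  co <- select_cohort(uni, drug_query("ide-cel", "ide-cel"))
  r <- sex_difference_ror(co, events = "Synthetic PT 008")
  expect_gt(r$ror_ci_low, 1)
})

test_that("death-outcome analysis restricts universe and cohort and summarizes the subset", {
  cfg <- simulation_config(
    n_reports = 4000, seed = 71, duplicate_fraction = 0,
    implants = list(sim_implant("IDE-CEL", "Synthetic PT 030", rate = 60,
                                stratum = "death")))
  uni <- deduplicate(sim_reports(simulate_faers(cfg)))
  co <- select_cohort(uni, drug_query("ide-cel", "ide-cel"))
  de <- death_outcome_signals(uni, co)
  # subset containment
  expect_true(all(stratum_filter(co, "death")$demo$primaryid %in% co$demo$primaryid))
  expect_equal(de$n_death_cohort, nreports(stratum_filter(co, "death")))
  # implanted only among death reports: signals in the death subset...
  expect_true(de$signals$ror_signal[de$signals$event == "Synthetic PT 030"])
  # ...but not overall
  overall <- detect_signals(disproportionality(uni, co, "PT"))
  o_row <- overall[overall$event == "Synthetic PT 030", ]
  expect_false(isTRUE(o_row$ror_signal) && o_row$ror > 10)
  expect_equal(sum(de$demographics$n[de$demographics$block == "sex"]),
               de$n_death_cohort)
})

test_that("reports with a death outcome among others are included in the death subset", {
  rep <- mk_reports(
    demo = data.frame(primaryid = c("1", "2")),
    outcomes = data.frame(primaryid = c("1", "1", "2"), outc_cod = c("HO", "DE", "HO"))
  )
  expect_setequal(stratum_filter(rep, "death")$demo$primaryid, "1")
})

test_that("malignancy screening aggregates groups, keeps IC defined at zero, attaches TTO", {
  pts <- sprintf("Synthetic PT %03d", 1:50)
  pts[7] <- "Acute myeloid leukaemia"
  cfg <- simulation_config(
    n_reports = 4000, n_background_pts = 50, seed = 83, duplicate_fraction = 0,
    pt_names = pts,
    implants = list(sim_implant("IDE-CEL", "Acute myeloid leukaemia", rate = 20,
                                tto_shape = 2, tto_scale = 400)))
  uni <- deduplicate(sim_reports(simulate_faers(cfg)))
  q <- drug_query("ide-cel", "ide-cel")
  co <- select_cohort(uni, q)
  groups <- data.frame(
    group = c("Leukaemias", "Leukaemias", "Plasma cell neoplasms"),
    pt = c("Acute myeloid leukaemia", "Chronic lymphocytic leukaemia",
           "Plasma cell myeloma"))
  tt <- compute_tto(co, q)
  scr <- malignancy_screen(uni, co, groups, ttos = tt)
  leu <- scr[scr$group == "Leukaemias", ]
  expect_gt(leu$ic025, 0)          # late-onset implant detected by IC
  expect_gt(leu$tto_median, 300)   # Weibull(2, 400) onsets are late
  pcn <- scr[scr$group == "Plasma cell neoplasms", ]
  expect_equal(pcn$n_cases, 0)
  expect_lte(pcn$ic, 0)            # a = 0 keeps the IC defined, never a signal
  expect_lt(pcn$ic025, 0)
  expect_true(is.na(pcn$ror))      # zero cells: ROR undefined by design
})
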