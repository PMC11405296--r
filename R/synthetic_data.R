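## Synthetic FAERS-like quarterly tables with known ground truth: a
## multi-drug multi-PT reporting background, implanted drug-event signals
## of configurable relative reporting rate, duplicate report chains, and
## Weibull-distributed onset times. The generator writes the same "$"
## dialect the parser reads, so round-trip is itself a test.

SIM_SOC_NAMES <- c(
  "Immune system disorders",
  "Blood and lymphatic system disorders",
  "Nervous system disorders",
  "Investigations",
  "Gastrointestinal disorders",
  "Infections and infestations",
  "General disorders and administration site conditions",
  "Metabolism and nutrition disorders",
  "Vascular disorders",
  "Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
)

sim_demographic_defaults <- function() {
  list(
    # marginal distributions emulating a CAR-T reporting cohort: male
    # predominance, mostly older adults, mostly US healthcare-professional
    # reports, ~10% death outcome
    sex = c(F = 0.37, M = 0.52, unknown = 0.11),
    age = c(under_18 = 0.00, age_18_64 = 0.34, age_65plus = 0.47, unknown = 0.19),
    weight = c(lt50 = 0.015, b50_100 = 0.565, gt100 = 0.075, unknown = 0.345),
    reporter = c(healthcare_professional = 0.71, consumer = 0.12, unknown = 0.17),
    outcome = c(death = 0.105, life_threatening = 0.06, hospitalization = 0.28,
                other = 0.37),
    country_us = 0.78
  )
}

#' Define an implanted drug-event signal
#'
#' @param drug target drug name (must be one of the config's target drugs)
#' @param pt preferred term (must be in the simulated PT universe)
#' @param rate relative reporting rate (>= 1): on eligible target-drug
#'   reports the PT appears with probability `rate * p0`, where p0 is the
#'   background per-report PT probability
#' @param stratum optional restriction (`"female"`, `"male"`,
#'   `"age_18_64"`, `"age_65plus"`, `"death"`); the implant fires only on
#'   reports in the stratum
#' @param tto_shape,tto_scale optional Weibull onset parameters for reports
#'   carrying this implant (e.g. shape 2, scale 400 for a late-onset
#'   malignancy-like signal); default inherits the config's baseline onset
#'   distribution
#' @return list of class `sim_implant`
#' @export
sim_implant <- function(drug, pt, rate, stratum = NULL,
                        tto_shape = NULL, tto_scale = NULL) {
  stopifnot(rate >= 1)
  if (!is.null(stratum))
    stopifnot(stratum %in% c("female", "male", "age_18_64", "age_65plus", "death"))
  structure(list(drug = drug, pt = pt, rate = rate, stratum = stratum,
                 tto_shape = tto_shape, tto_scale = tto_scale),
            class = "sim_implant")
}

#' Simulation configuration
#'
#' Validated parameter set for [simulate_faers()]. Defaults describe the
#' emulated reporting background: 5,000 reports over the 2019-2023 window,
#' 50 background drugs, 200 background PTs with per-report multiplicity
#' K ~ max(1, Poisson(1.7)), one target drug holding 5% of reports, 5%
#' duplicate chains, and baseline onset times drawn from Weibull(shape
#' 0.43, scale 12.67 days) - the early-failure onset regime characteristic
#' of CAR-T adverse events.
#'
#' @param n_reports number of unique reports (before duplicate chains)
#' @param n_background_drugs,n_background_pts background universe sizes
#' @param bg_pt_lambda Poisson mean of background PTs per report (min 1)
#' @param target_drugs list of `list(name=, share=)`; shares of reports
#' @param implants list of [sim_implant()] objects
#' @param duplicate_fraction fraction of reports receiving one duplicate
#'   record (shared CASEID, earlier FDA_DT, distinct PRIMARYID)
#' @param date_window character length-2, earliest/latest event date
#' @param demographics named list of probability tables; see
#'   `faersignal:::sim_demographic_defaults()` for the shape
#' @param tto_default list with `shape`, `scale`: baseline Weibull onset
#' @param concom_lambda Poisson mean of concomitant (role C) drugs
#' @param pt_names optional character vector (length `n_background_pts`)
#'   naming the PT universe; default synthetic names
#' @param seed integer RNG seed; a fixed seed gives byte-identical output
#' @return object of class `sim_config`
#' @export
simulation_config <- function(n_reports = 5000L,
                              n_background_drugs = 50L,
                              n_background_pts = 200L,
                              bg_pt_lambda = 1.7,
                              target_drugs = list(list(name = "IDE-CEL", share = 0.05)),
                              implants = list(),
                              duplicate_fraction = 0.05,
                              date_window = c("2019-01-01", "2023-12-31"),
                              demographics = sim_demographic_defaults(),
                              tto_default = list(shape = 0.43, scale = 12.67),
                              concom_lambda = 0.7,
                              pt_names = NULL,
                              seed = 1L) {
  stopifnot(n_reports >= 10, n_background_drugs >= 1, n_background_pts >= 2,
            bg_pt_lambda > 0, duplicate_fraction >= 0, duplicate_fraction < 1,
            length(target_drugs) >= 1)
  shares <- vapply(target_drugs, function(t) t$share, numeric(1))
  tnames <- vapply(target_drugs, function(t) t$name, character(1))
  stopifnot(all(shares > 0), sum(shares) < 0.9, !anyDuplicated(tnames))
  for (p in c("sex", "age", "weight", "reporter")) {
    stopifnot(abs(sum(demographics[[p]]) - 1) < 1e-8)
  }
  if (is.null(pt_names)) {
    pt_names <- sprintf("Synthetic PT %03d", seq_len(n_background_pts))
  }
  stopifnot(length(pt_names) == n_background_pts, !anyDuplicated(pt_names))
  cfg <- structure(list(
    n_reports = as.integer(n_reports),
    n_background_drugs = as.integer(n_background_drugs),
    n_background_pts = as.integer(n_background_pts),
    bg_pt_lambda = bg_pt_lambda,
    target_drugs = target_drugs,
    implants = implants,
    duplicate_fraction = duplicate_fraction,
    date_window = as.Date(date_window),
    demographics = demographics,
    tto_default = tto_default,
    concom_lambda = concom_lambda,
    pt_names = pt_names,
    drug_names = c(tnames, sprintf("BACKGROUND DRUG %02d", seq_len(n_background_drugs))),
    seed = as.integer(seed)
  ), class = "sim_config")

  p0 <- background_pt_prob(cfg)
  for (im in implants) {
    stopifnot(inherits(im, "sim_implant"))
    if (!im$drug %in% tnames)
      stop("implant drug not among target drugs: ", im$drug)
    if (!im$pt %in% pt_names)
      stop("implant pt not in the PT universe: ", im$pt)
    if (im$rate * p0 > 0.95)
      stop(sprintf("infeasible implant (%s, %s): rate %.1f forces event probability %.2f > 0.95",
                   im$drug, im$pt, im$rate, im$rate * p0))
  }
  keys <- vapply(implants, function(im) paste(im$drug, im$pt, sep = "|"), character(1))
  if (anyDuplicated(keys)) stop("duplicate implant (drug, pt) pairs")
  cfg
}

#' Background per-report PT inclusion probability
#'
#' Under the generative model - K ~ max(1, Poisson(lambda)) PT slots drawn
#' with replacement from `n_background_pts` terms, then de-duplicated - the
#' probability that a given PT appears on a given report is the exact
#' closed form `E[1 - (1 - 1/n_pts)^K]`, evaluated by summing the Poisson
#' mass to numerical exhaustion.
#'
#' @param config a `sim_config`
#' @return scalar probability
#' @export
background_pt_prob <- function(config) {
  lam <- config$bg_pt_lambda
  npt <- config$n_background_pts
  kmax <- max(50, ceiling(lam + 20 * sqrt(lam)))
  k <- 0:kmax
  sum(dpois(k, lam) * (1 - (1 - 1 / npt)^pmax(1, k)))
}

sim_stratum_mask <- function(stratum, sex, age_band, has_de) {
  switch(stratum,
    female = sex == "F",
    male = sex == "M",
    age_18_64 = age_band == "age_18_64",
    age_65plus = age_band == "age_65plus",
    death = has_de,
    stop("unknown implant stratum: ", stratum))
}

fmt_dt <- function(d) ifelse(is.na(d), "", format(d, "%Y%m%d"))

#' Simulate a FAERS-like report set with known ground truth
#'
#' Generates DEMO/DRUG/REAC/OUTC/THER tables in the parser's dialect (all
#' character columns, FAERS column names), an implant manifest recording
#' the true non-null structure, and a mini PT->SOC dictionary. Duplicate
#' chains share CASEID with strictly earlier FDA_DT and a distinct (higher)
#' PRIMARYID, so [deduplicate()] must keep exactly the original records.
#'
#' @param config a [simulation_config()]
#' @return object of class `faers_sim`: list with `tables` (named list of
#'   character data.tables), `manifest` (seed, duplicate chains, per-implant
#'   truth, p0), `meddra` (pt/soc data.table), `config`
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  dem <- config$demographics
  tnames <- vapply(config$target_drugs, function(t) t$name, character(1))
  shares <- vapply(config$target_drugs, function(t) t$share, numeric(1))
  bg_share <- (1 - sum(shares)) / config$n_background_drugs
  drug_probs <- c(shares, rep(bg_share, config$n_background_drugs))

  primaryid <- as.character(1000000000 + seq_len(n))
  caseid <- as.character(500000000 + seq_len(n))
  drug_of <- sample(config$drug_names, n, replace = TRUE, prob = drug_probs)

  sex <- sample(names(dem$sex), n, replace = TRUE, prob = dem$sex)
  age_band <- sample(names(dem$age), n, replace = TRUE, prob = dem$age)
  age <- round(ifelse(age_band == "under_18", runif(n, 2, 17),
               ifelse(age_band == "age_18_64", runif(n, 18, 64.99),
               ifelse(age_band == "age_65plus", runif(n, 65, 90), NA))))
  wt_band <- sample(names(dem$weight), n, replace = TRUE, prob = dem$weight)
  wt <- round(ifelse(wt_band == "lt50", runif(n, 38, 49.9),
              ifelse(wt_band == "b50_100", runif(n, 50, 100),
              ifelse(wt_band == "gt100", runif(n, 100.1, 145), NA))), 1)
  reporter <- sample(names(dem$reporter), n, replace = TRUE, prob = dem$reporter)
  occp <- c(healthcare_professional = "MD", consumer = "CN", unknown = "")[reporter]
  country <- ifelse(runif(n) < dem$country_us, "US",
                    sample(c("JP", "FR", "DE", "CA", "GB"), n, replace = TRUE))

  days <- seq(config$date_window[1], config$date_window[2], by = "day")
  event_dt <- sample(days, n, replace = TRUE)
  fda_dt <- event_dt + sample(7:120, n, replace = TRUE)

  has_de <- runif(n) < dem$outcome["death"]
  has_lt <- runif(n) < dem$outcome["life_threatening"]
  has_ho <- runif(n) < dem$outcome["hospitalization"]
  has_ot <- runif(n) < dem$outcome["other"]

  # background reaction pairs: with-replacement slots, de-duplicated
  K <- pmax(1L, rpois(n, config$bg_pt_lambda))
  pairs <- data.table::data.table(rid = rep(seq_len(n), K),
                                  ptid = sample.int(config$n_background_pts, sum(K),
                                                    replace = TRUE))
  pairs <- unique(pairs)

  # implants: replace background presence on eligible reports by an exact
  # Bernoulli(rate * p0)
  p0 <- background_pt_prob(config)
  implant_truth <- list()
  report_implant <- rep(NA_integer_, n)  # first implant governing a report's TTO
  for (i in seq_along(config$implants)) {
    im <- config$implants[[i]]
    ptid_i <- match(im$pt, config$pt_names)
    elig <- which(drug_of == im$drug)
    if (!is.null(im$stratum))
      elig <- elig[sim_stratum_mask(im$stratum, sex[elig], age_band[elig], has_de[elig])]
    p_im <- min(im$rate * p0, 0.95)
    pairs <- pairs[!(ptid == ptid_i & rid %in% elig)]
    sel <- elig[rbinom(length(elig), 1L, p_im) == 1L]
    if (length(sel))
      pairs <- rbind(pairs, data.table::data.table(rid = sel, ptid = ptid_i))
    govern <- sel[is.na(report_implant[sel])]
    if (!is.null(im$tto_shape)) report_implant[govern] <- i
    implant_truth[[i]] <- list(
      drug = im$drug, pt = im$pt, rate = im$rate,
      stratum = im$stratum %||% "all",
      p_target = p_im, p_background = p0,
      n_eligible = length(elig),
      expected_a = length(elig) * p_im,
      actual_a = length(sel),
      case_primaryids = primaryid[sort(sel)],
      tto_shape = im$tto_shape %||% config$tto_default$shape,
      tto_scale = im$tto_scale %||% config$tto_default$scale
    )
  }
  pairs <- unique(pairs)
  data.table::setorder(pairs, rid, ptid)

  # onset: baseline Weibull, overridden per report by its governing implant
  tto <- rweibull(n, config$tto_default$shape, config$tto_default$scale)
  for (i in seq_along(config$implants)) {
    im <- config$implants[[i]]
    if (is.null(im$tto_shape)) next
    g <- which(report_implant == i)
    if (length(g)) tto[g] <- rweibull(length(g), im$tto_shape, im$tto_scale)
  }
  tto_days <- as.integer(round(tto))
  start_dt <- event_dt - tto_days

  # concomitant background drugs, role C
  ncon <- pmin(rpois(n, config$concom_lambda), 3L)
  con_rid <- rep(seq_len(n), ncon)
  con_drug <- sprintf("BACKGROUND DRUG %02d",
                      sample.int(config$n_background_drugs, length(con_rid), replace = TRUE))
  suspect_role <- sample(c("PS", "SS"), n, replace = TRUE, prob = c(0.85, 0.15))

  demo <- data.table::data.table(
    PRIMARYID = primaryid, CASEID = caseid,
    FDA_DT = fmt_dt(fda_dt), EVENT_DT = fmt_dt(event_dt),
    AGE = ifelse(is.na(age), "", as.character(age)),
    AGE_COD = ifelse(is.na(age), "", "YR"),
    SEX = ifelse(sex == "unknown", "", sex),
    WT = ifelse(is.na(wt), "", as.character(wt)),
    WT_COD = ifelse(is.na(wt), "", "KG"),
    OCCP_COD = occp,
    OCCR_COUNTRY = country
  )
  drug <- rbind(
    data.table::data.table(PRIMARYID = primaryid, DRUG_SEQ = "1",
                           DRUGNAME = drug_of, ROLE_COD = suspect_role),
    data.table::data.table(PRIMARYID = primaryid[con_rid],
                           DRUG_SEQ = as.character(1L + sequence(ncon)),
                           DRUGNAME = con_drug, ROLE_COD = "C")
  )
  data.table::setorder(drug, PRIMARYID, DRUG_SEQ)
  reac <- data.table::data.table(PRIMARYID = primaryid[pairs$rid],
                                 PT = config$pt_names[pairs$ptid])
  outc <- rbind(
    data.table::data.table(PRIMARYID = primaryid[has_de], OUTC_COD = "DE"),
    data.table::data.table(PRIMARYID = primaryid[has_lt], OUTC_COD = "LT"),
    data.table::data.table(PRIMARYID = primaryid[has_ho], OUTC_COD = "HO"),
    data.table::data.table(PRIMARYID = primaryid[has_ot], OUTC_COD = "OT")
  )
  data.table::setorder(outc, PRIMARYID, OUTC_COD)
  ther <- data.table::data.table(PRIMARYID = primaryid, DSG_DRUG_SEQ = "1",
                                 START_DT = fmt_dt(start_dt))

  # duplicate chains: one clone per sampled report, same CASEID, strictly
  # earlier FDA_DT, higher PRIMARYID -> dedup must keep the original
  n_dup <- floor(config$duplicate_fraction * n)
  chains <- data.table::data.table(caseid = character(0),
                                   kept_primaryid = character(0),
                                   dup_primaryid = character(0))
  if (n_dup > 0) {
    dup_idx <- sort(sample.int(n, n_dup))
    dup_pid <- as.character(2000000000 + seq_len(n_dup))
    dup_fda <- fda_dt[dup_idx] - sample(5:60, n_dup, replace = TRUE)
    dd <- demo[dup_idx]
    dd[, `:=`(PRIMARYID = dup_pid, FDA_DT = fmt_dt(dup_fda))]
    demo <- rbind(demo, dd)
    clone <- function(tab) {
      cl <- tab[tab$PRIMARYID %in% primaryid[dup_idx]]
      cl[, PRIMARYID := dup_pid[match(PRIMARYID, primaryid[dup_idx])]]
      cl
    }
    drug <- rbind(drug, clone(drug))
    reac <- rbind(reac, clone(reac))
    outc <- rbind(outc, clone(outc))
    ther <- rbind(ther, clone(ther))
    chains <- data.table::data.table(caseid = caseid[dup_idx],
                                     kept_primaryid = primaryid[dup_idx],
                                     dup_primaryid = dup_pid)
  }

  # mini PT->SOC dictionary: keyword-matched where the PT name suggests an
  # organ class, cyclic assignment otherwise
  soc <- SIM_SOC_NAMES[1 + (seq_len(config$n_background_pts) - 1) %% length(SIM_SOC_NAMES)]
  neo <- grepl("neoplasm|leukaemi|lymphoma|myeloma|carcinoma|melanoma|malignan",
               config$pt_names, ignore.case = TRUE)
  soc[neo] <- SIM_SOC_NAMES[10]
  meddra <- data.table::data.table(pt = config$pt_names, soc = soc)

  manifest <- list(
    seed = config$seed,
    n_unique_reports = n,
    n_duplicate_records = n_dup,
    n_rows_demo = nrow(demo),
    p_background_pt = p0,
    duplicate_chains = chains,
    implants = implant_truth
  )
  structure(list(tables = list(DEMO = demo, DRUG = drug, REAC = reac,
                               OUTC = outc, THER = ther),
                 manifest = manifest, meddra = meddra, config = config),
            class = "faers_sim")
}

#' Write a simulated report set in the FAERS file dialect
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `OUTC.txt`, `THER.txt`
#' ("$"-delimited with header), `manifest.json`, and `meddra_map.tsv`.
#' Output is byte-identical for a fixed config (including seed).
#'
#' @param sim a `faers_sim` from [simulate_faers()]
#' @param dir output directory (created if needed)
#' @return named character vector of the table file paths, invisibly
#' @export
write_faers <- function(sim, dir) {
  stopifnot(inherits(sim, "faers_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tn in names(sim$tables)) {
    tab <- sim$tables[[tn]]
    path <- file.path(dir, paste0(tn, ".txt"))
    lines <- c(paste(names(tab), collapse = "$"),
               do.call(paste, c(as.list(tab), sep = "$")))
    writeLines(lines, path)
    paths[tn] <- path
  }
  data.table::fwrite(sim$meddra, file.path(dir, "meddra_map.tsv"), sep = "\t")
  manifest <- sim$manifest
  manifest$duplicate_chains <- as.data.frame(manifest$duplicate_chains)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Assemble simulated tables into a report set without touching disk
#'
#' Wraps the simulated tables as a parsed-quarter object and runs the same
#' [assemble_reports()] path used for real files.
#'
#' @param sim a `faers_sim`
#' @return a `faers_reports` object (not yet deduplicated)
#' @export
sim_reports <- function(sim) {
  stopifnot(inherits(sim, "faers_sim"))
  raw <- structure(list(tables = sim$tables, quarter_label = "SIM", log = list()),
                   class = "faers_raw")
  assemble_reports(raw)
}

#' Expected 2x2 table under the generative model
#'
#' Closed-form expected counts for one (drug, PT) pair implied by the
#' simulation config: with s the drug's report share, p0 the background PT
#' probability, and an implant of rate r restricted to a stratum of
#' probability q, the target-drug event probability is
#' q min(r p0, 0.95) + (1 - q) p0 (q = 1 unrestricted), and the
#' non-target probability is p0. Used by calibration tests; the expected
#' ROR is (p_t/(1-p_t)) / (p0/(1-p0)).
#'
#' @param config a `sim_config`
#' @param drug drug name in the config universe
#' @param pt PT name in the config universe
#' @return list: `a`, `b`, `c`, `d` (expected counts over the deduplicated
#'   set), `p_target`, `p_background`, `expected_ror`
#' @export
expected_contingency <- function(config, drug, pt) {
  stopifnot(inherits(config, "sim_config"))
  tnames <- vapply(config$target_drugs, function(t) t$name, character(1))
  shares <- vapply(config$target_drugs, function(t) t$share, numeric(1))
  if (!drug %in% config$drug_names) stop("unknown drug: ", drug)
  if (!pt %in% config$pt_names) stop("unknown pt: ", pt)
  s <- if (drug %in% tnames) shares[match(drug, tnames)]
       else (1 - sum(shares)) / config$n_background_drugs
  p0 <- background_pt_prob(config)
  p_t <- p0
  for (im in config$implants) {
    if (im$drug == drug && im$pt == pt) {
      q <- if (is.null(im$stratum)) 1 else {
        dem <- config$demographics
        switch(im$stratum,
               female = unname(dem$sex["F"]),
               male = unname(dem$sex["M"]),
               age_18_64 = unname(dem$age["age_18_64"]),
               age_65plus = unname(dem$age["age_65plus"]),
               death = unname(dem$outcome["death"]))
      }
      p_t <- q * min(im$rate * p0, 0.95) + (1 - q) * p0
    }
  }
  n <- config$n_reports
  a <- n * s * p_t
  b <- n * s * (1 - p_t)
  c_ <- n * (1 - s) * p0
  d <- n * (1 - s) * (1 - p0)
  list(a = a, b = b, c = c_, d = d, p_target = p_t, p_background = p0,
       expected_ror = (p_t / (1 - p_t)) / (p0 / (1 - p0)))
}
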