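# Shared settings for the numbered analysis scripts: one fixed
# study-condition simulation standing in for the FAERS download, plus the
# output locations. Source()d by every script; everything is deterministic.

library(faersignal)

RESULTS <- file.path("results")
RAW_DIR <- file.path(RESULTS, "synthetic_faers")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

# PT universe: mostly synthetic background terms, with the handful of
# clinically meaningful terms the implanted signals use.
study_pt_names <- function(n = 200) {
  pts <- sprintf("Synthetic PT %03d", seq_len(n))
  pts[1] <- "Cytokine release syndrome"
  pts[2] <- "Immune effector cell-associated neurotoxicity syndrome"
  pts[3] <- "Febrile bone marrow aplasia"
  pts[4] <- "Parkinsonism"
  pts[5] <- "Acute myeloid leukaemia"
  pts[6] <- "Bell's palsy"
  pts[7] <- "Arthralgia"
  pts
}

# Two anti-BCMA CAR-T cohorts over a shared reporting background, with
# implanted signals spanning every analysis: hallmark toxicities (CRS,
# ICANS), an unexpected haematological signal, a male-restricted and a
# female-restricted signal, a death-restricted signal, and a late-onset
# secondary-malignancy signal (Weibull shape 2, scale 400 days).
study_config <- function(seed = 20240101 %% 2^31) {
  simulation_config(
    n_reports = 20000,
    n_background_pts = 200,
    target_drugs = list(list(name = "ABECMA", share = 0.034),
                        list(name = "CARVYKTI", share = 0.042)),
    pt_names = study_pt_names(),
    implants = list(
      sim_implant("ABECMA", "Cytokine release syndrome", rate = 90),
      sim_implant("ABECMA", "Immune effector cell-associated neurotoxicity syndrome", rate = 60),
      sim_implant("ABECMA", "Febrile bone marrow aplasia", rate = 40),
      sim_implant("ABECMA", "Parkinsonism", rate = 35, stratum = "male"),
      sim_implant("ABECMA", "Arthralgia", rate = 30, stratum = "female"),
      sim_implant("ABECMA", "Synthetic PT 050", rate = 50, stratum = "death"),
      sim_implant("ABECMA", "Acute myeloid leukaemia", rate = 25,
                  tto_shape = 2, tto_scale = 400),
      sim_implant("CARVYKTI", "Cytokine release syndrome", rate = 70),
      sim_implant("CARVYKTI", "Bell's palsy", rate = 45),
      sim_implant("CARVYKTI", "Acute myeloid leukaemia", rate = 20,
                  tto_shape = 2, tto_scale = 400)
    ),
    duplicate_fraction = 0.05,
    seed = seed
  )
}

study_queries <- function() {
  list(ide_cel = drug_query("ide-cel", c("abecma", "idecabtagene", "bb2121")),
       cilta_cel = drug_query("cilta-cel", c("carvykti", "ciltacabtagene", "jnj-68284528")))
}

load_universe <- function() {
  paths <- file.path(RAW_DIR, paste0(c("DEMO", "DRUG", "REAC", "OUTC", "THER"), ".txt"))
  names(paths) <- c("DEMO", "DRUG", "REAC", "OUTC", "THER")
  if (!all(file.exists(paths)))
    stop("run analysis/01_simulate.R first")
  uni <- deduplicate(assemble_reports(parse_quarter(paths, "SIM")))
  attach_meddra(uni, read_meddra_map(file.path(RAW_DIR, "meddra_map.tsv")))
}
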