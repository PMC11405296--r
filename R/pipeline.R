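## End-to-end orchestration: ingest (or simulate) -> deduplicate -> per-drug
## cohorting, demographics, ROR/IC signal tables, subgroup / sex-difference /
## death / malignancy analyses, TTO summaries and Weibull fits -> a
## publication-shaped TSV/JSON report bundle.

#' Run the full signal-detection pipeline
#'
#' Executes every analysis stage and writes the report bundle to
#' `out_dir`: a dedup manifest, per-drug demographic tables, PT- and
#' SOC-level signal tables, top-k rankings, unexpected-signal lists,
#' per-stratum subgroup tables, sex-difference tables, death-outcome
#' tables, malignancy screens, TTO summaries with Weibull fits, and a
#' machine-readable run summary. Each output table carries the package
#' version and a config fingerprint in a header comment. A stage failure
#' marks the bundle partial in the run summary instead of aborting the
#' run.
#'
#' @param input either a directory of FAERS quarterly files (containing
#'   DEMO.txt, DRUG.txt, REAC.txt and optionally OUTC/THER), a
#'   `faers_sim`, or an assembled `faers_reports` object
#' @param queries named list of [drug_query()] objects (default the two
#'   shipped anti-BCMA CAR-T queries)
#' @param meddra_map PT->SOC table ([read_meddra_map()] output or path);
#'   `NULL` skips SOC-level stages
#' @param label_terms named list (by query name) of labelled-PT character
#'   vectors for unexpected-signal flagging; `NULL` skips the flagging
#' @param malignancy_groups data.frame or path for [malignancy_screen()];
#'   `NULL` skips the screen
#' @param criteria [signal_criteria()]
#' @param strata subgroup strata (`NULL` or `character(0)` disables)
#' @param top_k rows kept in the ranking tables
#' @param out_dir output directory
#' @return invisibly, a list with the in-memory results and per-stage
#'   status; side effect: the bundle under `out_dir`
#' @export
run_pipeline <- function(input,
                         queries = default_drug_queries(),
                         meddra_map = NULL,
                         label_terms = NULL,
                         malignancy_groups = NULL,
                         criteria = signal_criteria(),
                         strata = DEFAULT_STRATA,
                         top_k = 20L,
                         out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- config_fingerprint(list(queries = queries, criteria = criteria,
                                strata = strata, top_k = top_k))
  status <- list()
  results <- list()
  stage <- function(name, expr) {
    out <- tryCatch(list(value = expr, ok = TRUE, error = NA_character_),
                    error = function(e) list(value = NULL, ok = FALSE,
                                             error = conditionMessage(e)))
    status[[name]] <<- list(ok = out$ok, error = out$error)
    message(sprintf("[%s] %s", if (out$ok) "ok" else "FAIL", name))
    out$value
  }
  emit <- function(df, file) write_tsv_stamped(df, file.path(out_dir, file), fp)

  reports <- stage("ingest", {
    if (inherits(input, "faers_reports")) input
    else if (inherits(input, "faers_sim")) sim_reports(input)
    else {
      files <- file.path(input, paste0(FAERS_TABLES, ".txt"))
      names(files) <- FAERS_TABLES
      files <- files[file.exists(files)]
      assemble_reports(parse_quarter(files))
    }
  })
  if (is.null(reports)) stop("pipeline: ingest failed: ", status$ingest$error)

  universe <- stage("deduplicate", deduplicate(reports))
  stage("dedup_manifest", {
    jsonlite::write_json(list(
      n_in = nreports(reports), n_out = nreports(universe),
      removed = attr(universe, "removed"),
      orphans = as.list(attr(universe, "orphans") %||% integer(0))
    ), file.path(out_dir, "dedup_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  })

  if (is.character(meddra_map) && length(meddra_map) == 1L)
    meddra_map <- read_meddra_map(meddra_map)
  if (!is.null(meddra_map))
    universe <- stage("attach_meddra", attach_meddra(universe, meddra_map))
  if (is.character(malignancy_groups) && length(malignancy_groups) == 1L)
    malignancy_groups <- read_malignancy_groups(malignancy_groups)

  for (qn in names(queries)) {
    q <- queries[[qn]]
    cohort <- stage(paste0(qn, ":cohort"), select_cohort(universe, q))
    if (is.null(cohort) || nreports(cohort) == 0L) next
    res <- list(cohort_size = nreports(cohort))

    res$demographics <- stage(paste0(qn, ":demographics"), {
      dm <- summarize_demographics(cohort)
      emit(dm, sprintf("%s__demographics.tsv", qn))
      dm
    })
    res$signals_pt <- stage(paste0(qn, ":signals_pt"), {
      sp <- detect_signals(disproportionality(universe, cohort, "PT"), criteria)
      if (!is.null(label_terms))
        sp <- flag_unexpected(sp, label_terms[[qn]] %||% character(0))
      emit(sp, sprintf("%s__signals_pt.tsv", qn))
      sp
    })
    if (!is.null(meddra_map)) {
      res$signals_soc <- stage(paste0(qn, ":signals_soc"), {
        ss <- detect_signals(disproportionality(universe, cohort, "SOC"), criteria)
        emit(ss, sprintf("%s__signals_soc.tsv", qn))
        ss
      })
    }
    if (!is.null(res$signals_pt)) {
      res$top <- stage(paste0(qn, ":top_ranked"), {
        tp <- rank_top(res$signals_pt, k = top_k)
        emit(tp, sprintf("%s__top%d.tsv", qn, top_k))
        tp
      })
      if (!is.null(label_terms)) {
        res$unexpected <- stage(paste0(qn, ":unexpected"), {
          ux <- res$signals_pt[res$signals_pt$unexpected %in% TRUE, , drop = FALSE]
          emit(ux, sprintf("%s__unexpected.tsv", qn))
          ux
        })
      }
    }
    if (length(strata)) {
      res$subgroups <- stage(paste0(qn, ":subgroups"), {
        sg <- subgroup_signals(universe, cohort, strata, criteria = criteria)
        for (s in names(sg))
          emit(sg[[s]], sprintf("%s__%s__signals.tsv", qn, s))
        sg
      })
      res$sex_difference <- stage(paste0(qn, ":sex_difference"), {
        sd_ <- sex_difference_ror(cohort)
        emit(sd_, sprintf("%s__sex_difference.tsv", qn))
        sd_
      })
    }
    res$death <- stage(paste0(qn, ":death"), {
      de <- death_outcome_signals(universe, cohort, criteria = criteria)
      if (!is.null(de$signals)) emit(de$signals, sprintf("%s__death_signals.tsv", qn))
      if (!is.null(de$demographics))
        emit(de$demographics, sprintf("%s__death_demographics.tsv", qn))
      de
    })
    res$tto <- stage(paste0(qn, ":tto"), {
      tt <- compute_tto(cohort, q)
      emit(tt, sprintf("%s__tto_records.tsv", qn))
      summ <- onset_window_summary(tt)
      fit <- weibull_mle(tt)
      jsonlite::write_json(
        list(summary = summ,
             weibull = list(n_used = fit$n_used, converged = fit$converged,
                            alpha = fit$alpha, alpha_ci = fit$alpha_ci,
                            beta = fit$beta, beta_ci = fit$beta_ci,
                            failure_type = fit$failure_type,
                            log_likelihood = fit$log_likelihood)),
        file.path(out_dir, sprintf("%s__tto_fit.json", qn)),
        auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
      list(records = tt, summary = summ, fit = fit)
    })
    if (!is.null(meddra_map) && !is.null(res$tto)) {
      stage(paste0(qn, ":tto_by_soc"), {
        rx <- universe$reactions
        tt <- data.table::as.data.table(res$tto$records)
        tt[, pt_norm := normalize_term(event)]
        socmap <- unique(rx[!is.na(soc), .(pt_norm = normalize_term(pt), soc)],
                         by = "pt_norm")
        bysoc <- merge(tt[validity == "valid"], socmap, by = "pt_norm")
        emit(bysoc[, .(report_id, soc, event, tto_days)],
             sprintf("%s__tto_by_soc.tsv", qn))
      })
    }
    if (!is.null(malignancy_groups)) {
      res$malignancy <- stage(paste0(qn, ":malignancy"), {
        mg <- malignancy_screen(universe, cohort, malignancy_groups,
                                ttos = res$tto$records)
        emit(mg, sprintf("%s__malignancy_screen.tsv", qn))
        mg
      })
    }
    results[[qn]] <- res
  }

  ok <- all(vapply(status, function(s) isTRUE(s$ok), logical(1)))
  summary <- list(
    package_version = as.character(packageVersion("faersignal")),
    config_fingerprint = fp,
    n_reports_in = nreports(reports),
    n_reports_deduplicated = nreports(universe),
    removed_duplicates = attr(universe, "removed"),
    cohort_sizes = lapply(results, function(r) r$cohort_size),
    complete = ok,
    stages = status
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(list(results = results, status = status, universe = universe,
                 summary = summary))
}
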