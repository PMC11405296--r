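## FAERS quarterly ASCII ingestion: "$"-delimited tables -> typed report set
## -> FDA-recommended deduplication.

FAERS_TABLES <- c("DEMO", "DRUG", "REAC", "OUTC", "THER", "RPSR", "INDI")
FAERS_MANDATORY <- c("DEMO", "DRUG", "REAC")

## Column-name dialects seen across quarters are normalized through this
## alias map (keys upper-cased before lookup). Legacy pre-2012Q4 ISR-keyed
## files are out of scope.
FAERS_COL_ALIASES <- c(
  "PRIMARY_ID" = "PRIMARYID",
  "CASE_ID"    = "CASEID",
  "CASE"       = "CASEID",
  "GNDR_COD"   = "SEX",
  "DRUGNAME"   = "DRUGNAME",
  "PROD_AI"    = "PROD_AI"
)

normalize_faers_colnames <- function(x) {
  x <- toupper(trimws(x))
  hit <- x %in% names(FAERS_COL_ALIASES)
  x[hit] <- unname(FAERS_COL_ALIASES[x[hit]])
  x
}

read_faers_table <- function(path, table_name) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop(sprintf("%s: empty file '%s'", table_name, path))
  header <- strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]
  header <- normalize_faers_colnames(header)
  if (length(header) < 1L || any(header == ""))
    stop(sprintf("%s: unparseable header in '%s'", table_name, path))
  ncol <- length(header)

  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(body, "$", fixed = TRUE)
  # strsplit drops a single trailing empty token; restore it so a trailing
  # "$" shows up as an empty final field
  trailing <- endsWith(body, "$")
  if (any(trailing)) fields[trailing] <- lapply(fields[trailing], function(f) c(f, ""))
  nf <- lengths(fields)

  n_trailing_extra <- 0L
  n_malformed <- 0L
  # one extra, empty, final field: tolerated with a logged count
  extra_empty <- nf == ncol + 1L & vapply(fields, function(f) f[[length(f)]] == "", logical(1))
  if (any(extra_empty)) {
    fields[extra_empty] <- lapply(fields[extra_empty], function(f) f[-length(f)])
    nf[extra_empty] <- ncol
    n_trailing_extra <- sum(extra_empty)
    warning(sprintf("%s: %d row(s) with an extra trailing '$' (empty final field dropped)",
                    table_name, n_trailing_extra), call. = FALSE)
  }
  short <- nf < ncol
  long  <- nf > ncol
  if (any(short)) fields[short] <- lapply(fields[short], function(f) c(f, rep(NA_character_, ncol - length(f))))
  if (any(long))  fields[long]  <- lapply(fields[long],  function(f) f[seq_len(ncol)])
  n_malformed <- sum(short) + sum(long)
  if (n_malformed > 0L)
    warning(sprintf("%s: %d malformed row(s) (field count != header) coerced, not dropped",
                    table_name, n_malformed), call. = FALSE)

  m <- if (length(fields)) matrix(unlist(fields, use.names = FALSE), ncol = ncol, byrow = TRUE)
       else matrix(character(0), ncol = ncol)
  dt <- data.table::as.data.table(m)
  data.table::setnames(dt, header)
  for (j in names(dt)) data.table::set(dt, j = j, value = {
    v <- trimws(dt[[j]]); v[v == ""] <- NA_character_; v
  })
  attr(dt, "n_malformed") <- n_malformed
  attr(dt, "n_trailing_extra") <- n_trailing_extra
  dt[]
}

#' Parse one FAERS quarter
#'
#' Reads the "$"-delimited quarterly ASCII tables (DEMO, DRUG, REAC, OUTC,
#' THER, RPSR, INDI) into character data.tables with normalized column
#' names. Rows are kept in source order; rows whose field count disagrees
#' with the header are coerced (padded or truncated) and counted, never
#' silently dropped.
#'
#' @param paths named character vector or list mapping table names (subset
#'   of DEMO, DRUG, REAC, OUTC, THER, RPSR, INDI) to file paths. DEMO, DRUG
#'   and REAC are mandatory.
#' @param quarter_label label such as `"2023Q4"` carried in the result.
#' @return object of class `faers_raw`: list with `tables` (named list of
#'   data.tables), `quarter_label`, and `log` (per-table malformed-row
#'   counts).
#' @export
parse_quarter <- function(paths, quarter_label = NA_character_) {
  paths <- unlist(paths)
  names(paths) <- toupper(names(paths))
  unknown <- setdiff(names(paths), FAERS_TABLES)
  if (length(unknown)) stop("unknown FAERS table name(s): ", paste(unknown, collapse = ", "))
  missing_mand <- setdiff(FAERS_MANDATORY, names(paths))
  if (length(missing_mand))
    stop("missing mandatory FAERS table(s): ", paste(missing_mand, collapse = ", "))
  absent <- paths[!file.exists(paths)]
  if (length(absent)) stop("file(s) not found: ", paste(absent, collapse = ", "))

  tables <- lapply(names(paths), function(tn) read_faers_table(paths[[tn]], tn))
  names(tables) <- names(paths)
  log <- lapply(tables, function(t)
    list(n_rows = nrow(t),
         n_malformed = attr(t, "n_malformed"),
         n_trailing_extra = attr(t, "n_trailing_extra")))
  structure(list(tables = tables, quarter_label = quarter_label, log = log),
            class = "faers_raw")
}

need_cols <- function(dt, cols) {
  miss <- setdiff(cols, names(dt))
  for (m in miss) data.table::set(dt, j = m, value = NA_character_)
  dt
}

AGE_TO_YEARS <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
                  DY = 1 / 365.25, HR = 1 / 8766)
WT_TO_KG <- c(KG = 1, KGS = 1, LBS = 0.45359237, GMS = 0.001)
HCP_CODES <- c("MD", "PH", "OT", "HP", "RN")
CONSUMER_CODES <- c("CN", "CSM")
OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Assemble typed safety reports from parsed quarters
#'
#' Joins DRUG/REAC/OUTC/THER rows onto DEMO by PRIMARYID and converts raw
#' fields to typed values: dates via the partial-date midpoint rule, AGE +
#' AGE_COD to years, WT + WT_COD to kilograms, occupation codes to a
#' reporter class, and therapy start dates joined per (PRIMARYID,
#' DRUG_SEQ). Rows in satellite tables whose PRIMARYID has no DEMO row are
#' excluded and counted as orphans. Quarters are concatenated before any
#' deduplication, since duplicate chains cross quarter boundaries.
#'
#' @param raw a `faers_raw` object from [parse_quarter()], or a list of them
#'   (multiple quarters).
#' @return object of class `faers_reports`: list of data.tables `demo`,
#'   `drugs`, `reactions`, `outcomes`, with attribute `orphans` (named
#'   per-table counts).
#' @export
assemble_reports <- function(raw) {
  if (inherits(raw, "faers_raw")) raw <- list(raw)
  stopifnot(all(vapply(raw, inherits, logical(1), "faers_raw")))
  get_tab <- function(name) {
    parts <- lapply(raw, function(q) q$tables[[name]])
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) return(NULL)
    data.table::rbindlist(parts, fill = TRUE)
  }

  demo_raw <- get_tab("DEMO")
  if (is.null(demo_raw) || nrow(demo_raw) == 0L) stop("no DEMO rows to assemble")
  need_cols(demo_raw, c("PRIMARYID", "CASEID", "FDA_DT", "EVENT_DT", "AGE",
                        "AGE_COD", "SEX", "WT", "WT_COD", "OCCP_COD",
                        "OCCR_COUNTRY", "REPORTER_COUNTRY"))

  fda <- parse_faers_date(demo_raw$FDA_DT)
  evt <- parse_faers_date(demo_raw$EVENT_DT)
  age_mult <- AGE_TO_YEARS[toupper(demo_raw$AGE_COD)]
  age <- suppressWarnings(as.numeric(demo_raw$AGE)) * unname(age_mult)
  age[!is.na(age) & age < 0] <- NA_real_
  wt_mult <- WT_TO_KG[toupper(demo_raw$WT_COD)]
  wt_mult[is.na(demo_raw$WT_COD)] <- 1  # bare WT: FAERS default unit is kg
  wt <- suppressWarnings(as.numeric(demo_raw$WT)) * unname(wt_mult)
  wt[!is.na(wt) & wt < 0] <- NA_real_
  sex <- toupper(trimws(demo_raw$SEX))
  sex[!sex %in% c("F", "M") | is.na(sex)] <- "unknown"
  occ <- toupper(trimws(demo_raw$OCCP_COD))
  reporter <- ifelse(occ %in% HCP_CODES, "healthcare_professional",
              ifelse(occ %in% CONSUMER_CODES, "consumer", "unknown"))
  country <- demo_raw$OCCR_COUNTRY
  country[is.na(country)] <- demo_raw$REPORTER_COUNTRY[is.na(country)]
  country[is.na(country)] <- "unknown"

  demo <- data.table::data.table(
    primaryid = demo_raw$PRIMARYID,
    caseid = demo_raw$CASEID,
    fda_dt = fda$date,
    sex = sex,
    age_years = age,
    weight_kg = wt,
    reporter = reporter,
    country = toupper(country),
    event_dt = evt$date,
    event_imprecise = evt$imprecise
  )
  demo <- demo[!is.na(primaryid)]
  known <- unique(demo$primaryid)
  orphans <- c(DRUG = 0L, REAC = 0L, OUTC = 0L, THER = 0L)

  drug_raw <- get_tab("DRUG")
  need_cols(drug_raw, c("PRIMARYID", "DRUG_SEQ", "DRUGNAME", "ROLE_COD"))
  orphans["DRUG"] <- sum(!drug_raw$PRIMARYID %in% known)
  drug_raw <- drug_raw[PRIMARYID %in% known]
  drugs <- data.table::data.table(
    primaryid = drug_raw$PRIMARYID,
    drug_seq = drug_raw$DRUG_SEQ,
    drug_name = toupper(trimws(drug_raw$DRUGNAME)),
    role = toupper(trimws(drug_raw$ROLE_COD))
  )

  ther_raw <- get_tab("THER")
  if (!is.null(ther_raw) && nrow(ther_raw)) {
    need_cols(ther_raw, c("PRIMARYID", "DSG_DRUG_SEQ", "START_DT"))
    orphans["THER"] <- sum(!ther_raw$PRIMARYID %in% known)
    ther_raw <- ther_raw[PRIMARYID %in% known]
    st <- parse_faers_date(ther_raw$START_DT)
    ther <- data.table::data.table(primaryid = ther_raw$PRIMARYID,
                                   drug_seq = ther_raw$DSG_DRUG_SEQ,
                                   start_dt = st$date,
                                   start_imprecise = st$imprecise)
    # earliest dated start per drug entry; precise dates win over imprecise
    data.table::setorder(ther, primaryid, drug_seq, start_dt, start_imprecise, na.last = TRUE)
    ther <- ther[!is.na(start_dt), .SD[1L], by = .(primaryid, drug_seq)]
    drugs <- merge(drugs, ther, by = c("primaryid", "drug_seq"),
                   all.x = TRUE, sort = FALSE)
  } else {
    drugs[, `:=`(start_dt = as.Date(NA), start_imprecise = NA)]
  }

  reac_raw <- get_tab("REAC")
  need_cols(reac_raw, c("PRIMARYID", "PT"))
  orphans["REAC"] <- sum(!reac_raw$PRIMARYID %in% known)
  reac_raw <- reac_raw[PRIMARYID %in% known & !is.na(PT)]
  reactions <- data.table::data.table(primaryid = reac_raw$PRIMARYID,
                                      pt = trimws(reac_raw$PT))

  outc_raw <- get_tab("OUTC")
  if (!is.null(outc_raw) && nrow(outc_raw)) {
    need_cols(outc_raw, c("PRIMARYID", "OUTC_COD"))
    orphans["OUTC"] <- sum(!outc_raw$PRIMARYID %in% known)
    outc_raw <- outc_raw[PRIMARYID %in% known & !is.na(OUTC_COD)]
    outcomes <- data.table::data.table(primaryid = outc_raw$PRIMARYID,
                                       outc_cod = toupper(trimws(outc_raw$OUTC_COD)))
    outcomes <- outcomes[outc_cod %in% OUTCOME_CODES]
  } else {
    outcomes <- data.table::data.table(primaryid = character(0), outc_cod = character(0))
  }

  if (sum(orphans) > 0L)
    message(sprintf("assemble_reports: excluded %d orphan row(s) with PRIMARYID absent from DEMO (%s)",
                    sum(orphans),
                    paste(sprintf("%s=%d", names(orphans), orphans), collapse = ", ")))

  structure(list(demo = demo, drugs = drugs, reactions = reactions,
                 outcomes = outcomes),
            orphans = orphans, class = "faers_reports")
}

#' @export
print.faers_reports <- function(x, ...) {
  cat(sprintf("<faers_reports> %d report(s), %d drug row(s), %d reaction row(s), %d outcome row(s)\n",
              nrow(x$demo), nrow(x$drugs), nrow(x$reactions), nrow(x$outcomes)))
  rem <- attr(x, "removed")
  if (!is.null(rem)) cat(sprintf("  deduplicated: %d record(s) removed\n", rem))
  invisible(x)
}

#' Number of reports in a report set
#' @param x a `faers_reports` object
#' @return integer count of DEMO rows
#' @export
nreports <- function(x) nrow(x$demo)

#' Subset a report set by PRIMARYID
#'
#' Filters all component tables to the given report ids, preserving the
#' relational structure.
#'
#' @param x a `faers_reports` object
#' @param primaryids character vector of report ids to keep
#' @return a `faers_reports` object
#' @export
subset_reports <- function(x, primaryids) {
  out <- structure(list(
    demo = x$demo[primaryid %in% primaryids],
    drugs = x$drugs[primaryid %in% primaryids],
    reactions = x$reactions[primaryid %in% primaryids],
    outcomes = x$outcomes[primaryid %in% primaryids]
  ), class = "faers_reports")
  attr(out, "removed") <- attr(x, "removed")
  out
}

#' FDA-recommended case deduplication
#'
#' Keeps exactly one report per CASEID: the one with the most recent
#' FDA_DT; ties on FDA_DT are broken by the higher PRIMARYID (numeric
#' comparison when ids parse as numbers, lexicographic otherwise). A report
#' with unknown FDA_DT sorts earliest, so any dated version of the same
#' case wins. The number of discarded records is attached as attribute
#' `removed`. Output row order is sorted by PRIMARYID, making the result
#' independent of input order.
#'
#' @param x a `faers_reports` object
#' @return a deduplicated `faers_reports` object with attribute `removed`
#' @export
deduplicate <- function(x) {
  stopifnot(inherits(x, "faers_reports"))
  demo <- data.table::copy(x$demo)
  pid_num <- suppressWarnings(as.numeric(demo$primaryid))
  rk <- order(order(demo$fda_dt, !is.na(pid_num), pid_num, demo$primaryid,
                    na.last = FALSE))
  demo[, keep_rank := rk]
  # keep_rank is the position in ascending (fda_dt, id) order; the maximum
  # within each caseid is the record to keep
  kept <- demo[, .(primaryid = primaryid[which.max(keep_rank)]), by = caseid]$primaryid
  removed <- nrow(demo) - length(kept)
  out <- subset_reports(x, kept)
  data.table::setorder(out$demo, primaryid)
  data.table::setorder(out$drugs, primaryid, drug_seq)
  data.table::setorder(out$reactions, primaryid, pt)
  data.table::setorder(out$outcomes, primaryid, outc_cod)
  attr(out, "removed") <- removed
  attr(out, "orphans") <- attr(x, "orphans")
  out
}

#' Write a report set as TSV tables plus a JSON manifest
#'
#' Serializes the four component tables (demo, drugs, reactions, outcomes)
#' as tab-separated files and a `manifest.json` with counts (reports,
#' removed duplicates, orphans, date-imprecision counts). Dates are written
#' ISO-8601. [read_reports()] restores an identical object.
#'
#' @param x a `faers_reports` object
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_reports <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in c("demo", "drugs", "reactions", "outcomes")) {
    data.table::fwrite(x[[tab]], file.path(dir, paste0(tab, ".tsv")),
                       sep = "\t", na = "", quote = FALSE, logical01 = FALSE,
                       dateTimeAs = "ISO")
  }
  manifest <- list(
    n_reports = nrow(x$demo),
    removed_duplicates = attr(x, "removed") %||% NA_integer_,
    orphans = as.list(attr(x, "orphans") %||% integer(0)),
    n_imprecise_event_dt = sum(x$demo$event_imprecise, na.rm = TRUE),
    n_imprecise_start_dt = sum(x$drugs$start_imprecise, na.rm = TRUE)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(dir)
}

#' Read a report set written by [write_reports()]
#'
#' @param dir directory containing the TSV tables and manifest
#' @return a `faers_reports` object
#' @export
read_reports <- function(dir) {
  rd <- function(f, date_cols = character(0), lgl_cols = character(0),
                 num_cols = character(0)) {
    dt <- data.table::fread(file.path(dir, f), sep = "\t", colClasses = "character",
                            na.strings = "", keepLeadingZeros = TRUE)
    for (j in date_cols) data.table::set(dt, j = j, value = as.Date(dt[[j]]))
    for (j in lgl_cols) data.table::set(dt, j = j, value = as.logical(dt[[j]]))
    for (j in num_cols) data.table::set(dt, j = j, value = as.numeric(dt[[j]]))
    dt
  }
  demo <- rd("demo.tsv", date_cols = c("fda_dt", "event_dt"),
             lgl_cols = "event_imprecise", num_cols = c("age_years", "weight_kg"))
  drugs <- rd("drugs.tsv", date_cols = "start_dt", lgl_cols = "start_imprecise")
  reactions <- rd("reactions.tsv")
  outcomes <- rd("outcomes.tsv")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  out <- structure(list(demo = demo, drugs = drugs, reactions = reactions,
                        outcomes = outcomes), class = "faers_reports")
  attr(out, "removed") <- manifest$removed_duplicates
  out
}
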