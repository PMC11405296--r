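# Fixture builders: every test dataset is constructed in code.

# Build a faers_reports object directly from compact data.frames,
# filling typed defaults for omitted columns.
mk_reports <- function(demo, drugs = NULL, reactions = NULL, outcomes = NULL) {
  demo <- as.data.frame(demo, stringsAsFactors = FALSE)
  n <- nrow(demo)
  fill <- function(df, col, default) {
    if (!col %in% names(df))
      df[[col]] <- if (length(default) == nrow(df)) default
                   else rep(default, length.out = nrow(df))
    df
  }
  demo <- fill(demo, "caseid", demo$primaryid)
  demo <- fill(demo, "fda_dt", as.Date("2023-01-01"))
  demo <- fill(demo, "sex", "unknown")
  demo <- fill(demo, "age_years", NA_real_)
  demo <- fill(demo, "weight_kg", NA_real_)
  demo <- fill(demo, "reporter", "unknown")
  demo <- fill(demo, "country", "US")
  demo <- fill(demo, "event_dt", as.Date(NA))
  demo <- fill(demo, "event_imprecise", NA)
  empty_drugs <- data.frame(primaryid = character(0), drug_seq = character(0),
                            drug_name = character(0), role = character(0),
                            start_dt = as.Date(character(0)),
                            start_imprecise = logical(0))
  drugs <- if (is.null(drugs)) empty_drugs else {
    d <- as.data.frame(drugs, stringsAsFactors = FALSE)
    d <- fill(d, "drug_seq", "1")
    d <- fill(d, "role", "PS")
    d <- fill(d, "start_dt", as.Date(NA))
    d <- fill(d, "start_imprecise", NA)
    d$drug_name <- toupper(d$drug_name)
    d
  }
  reactions <- if (is.null(reactions))
    data.frame(primaryid = character(0), pt = character(0))
  else as.data.frame(reactions, stringsAsFactors = FALSE)
  outcomes <- if (is.null(outcomes))
    data.frame(primaryid = character(0), outc_cod = character(0))
  else as.data.frame(outcomes, stringsAsFactors = FALSE)
  structure(list(demo = data.table::as.data.table(demo),
                 drugs = data.table::as.data.table(drugs),
                 reactions = data.table::as.data.table(reactions),
                 outcomes = data.table::as.data.table(outcomes)),
            class = "faers_reports")
}

# Random report set: n reports, one suspect drug each, Poisson PT multiplicity.
random_fixture <- function(seed, n = 200, n_drugs = 6, n_pts = 20, lambda = 2) {
  set.seed(seed)
  pid <- as.character(seq_len(n) + 7000)
  drug <- sprintf("DRUG%02d", sample.int(n_drugs, n, replace = TRUE))
  k <- pmax(1L, rpois(n, lambda))
  rx <- data.frame(primaryid = rep(pid, k),
                   pt = sprintf("PT%02d", sample.int(n_pts, sum(k), replace = TRUE)))
  rx <- unique(rx)
  mk_reports(
    demo = data.frame(primaryid = pid,
                      sex = sample(c("F", "M", "unknown"), n, replace = TRUE)),
    drugs = data.frame(primaryid = pid, drug_name = drug, role = "PS"),
    reactions = rx
  )
}

# Exhaustive double-loop 2x2 count: the independent oracle for
# build_contingency / disproportionality.
brute_contingency <- function(universe, target_ids, event) {
  ev <- tolower(trimws(event))
  a <- b <- c_ <- d <- 0L
  for (pid in universe$demo$primaryid) {
    pts <- tolower(trimws(universe$reactions$pt[universe$reactions$primaryid == pid]))
    has <- ev %in% pts
    tgt <- pid %in% target_ids
    if (tgt && has) a <- a + 1L
    else if (tgt) b <- b + 1L
    else if (has) c_ <- c_ + 1L
    else d <- d + 1L
  }
  list(a = a, b = b, c = c_, d = d)
}

# Write a parser fixture: list of tables, each a character vector of
# raw "$"-delimited lines (header first). Returns named file paths.
write_quarter_fixture <- function(dir, tables) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tn in names(tables)) {
    p <- file.path(dir, paste0(tn, ".txt"))
    writeLines(tables[[tn]], p)
    paths[tn] <- p
  }
  paths
}
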