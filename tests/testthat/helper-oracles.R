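# Independent brute-force oracles. These deliberately re-derive results by
# different means than the package code paths they check.

# Character-by-character scan for registry identifiers: walk every position,
# read "NCT", then count the maximal digit run; accept only runs of exactly 8.
oracle_scan_nct <- function(text) {
  found <- character()
  for (s in text) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(chars)
    i <- 1L
    while (i <= n - 2L) {
      if (toupper(paste(chars[i:(i + 2L)], collapse = "")) == "NCT") {
        j <- i + 3L
        while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
        run <- j - (i + 3L)
        if (run == 8L) {
          found <- c(found, toupper(paste(chars[i:(j - 1L)], collapse = "")))
        }
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  sort(unique(found))
}

# Set-theoretic query oracle: materialize the set of matching citation rows
# for every term, then combine with union/intersection. Tokenization is
# re-implemented here (regmatches on word runs) rather than shared.
oracle_query_rows <- function(query, citations) {
  tokens_of <- function(i) {
    txt <- tolower(paste(citations$title[i], citations$abstract[i]))
    toks <- regmatches(txt, gregexpr("[^[:space:]]+", txt))[[1]]
    toks <- sub("^[[:punct:]]+", "", sub("[[:punct:]]+$", "", toks))
    toks[nzchar(toks)]
  }
  set_of <- function(i, field) {
    col <- c(mesh = "mesh_terms", publication_type = "publication_types",
             subheading = "subheadings")[[field]]
    tolower(citations[[col]][[i]])
  }
  rows <- seq_len(nrow(citations))
  recurse <- function(node) {
    if (node$op == "term") {
      hit <- vapply(rows, function(i) {
        if (node$field == "title_abstract") {
          toks <- tokens_of(i)
          if (isTRUE(node$truncated)) any(startsWith(toks, tolower(node$text)))
          else tolower(node$text) %in% toks
        } else {
          tolower(node$text) %in% set_of(i, node$field)
        }
      }, logical(1))
      rows[hit]
    } else if (node$op == "and") {
      Reduce(intersect, lapply(node$children, recurse), rows)
    } else {
      Reduce(union, lapply(node$children, recurse), integer())
    }
  }
  sort(recurse(query))
}

# Direct re-statement of the five trial-level predicates, written against
# raw year/month integers instead of the package's date class.
oracle_trial_eligible <- function(trial, as_of_year, as_of_month) {
  pd_ym <- function(p) {
    if (is.na(p)) NULL else c(trialaudit::pd_year(p), trialaudit::pd_month(p))
  }
  comp <- pd_ym(trial$completion_date)
  if (is.null(comp)) comp <- pd_ym(trial$primary_completion_date)
  window_ok <- !is.null(comp) &&
    ((as_of_year * 12 + as_of_month) - (comp[1] * 12 + comp[2])) > 24 &&
    (comp[1] > 2006 || (comp[1] == 2006 && comp[2] >= 1))
  ok <- c(
    study_type = identical(tolower(trial$study_type), "interventional"),
    status = identical(tolower(trial$overall_status), "completed"),
    completion_window = window_ok,
    phase = tolower(trial$phase) %in%
      tolower(c("Phase 2", "Phase 2/Phase 3", "Phase 3", "Phase 4", "N/A")),
    no_disposition = !isTRUE(trial$has_results_disposition)
  )
  list(eligible = all(ok),
       first_failing = if (all(ok)) NA_character_ else names(ok)[!ok][1])
}
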