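#' @importFrom rlang %||%
NULL

# Registry sponsor classes are coarse: industry, NIH, US Fed, other.
.sponsor_class_levels <- c("industry", "NIH", "US Fed", "other")

#' Map a raw registry agency class to the audit's four sponsor classes
#'
#' The registry's `agency_class` element takes values such as `"Industry"`,
#' `"NIH"`, `"U.S. Fed"` or `"Other"`. Anything outside the three named
#' funder categories maps to `"other"`; a raw value not seen in the public
#' registry vocabulary additionally raises a warning so corpus oddities
#' surface in logs.
#'
#' @param raw Character vector of raw `agency_class` values (`NA` allowed).
#' @return Character vector over `c("industry", "NIH", "US Fed", "other")`.
#' @export
map_sponsor_class <- function(raw) {
  known <- c("industry" = "industry", "nih" = "NIH", "u.s. fed" = "US Fed",
             "other" = "other")
  key <- tolower(trimws(raw %||% NA_character_))
  out <- unname(known[key])
  unknown <- is.na(out) & !is.na(raw)
  if (any(unknown)) {
    warning(sprintf("unknown agency class %s mapped to \"other\"",
                    paste(dQuote(unique(raw[unknown]), q = FALSE), collapse = ", ")),
            call. = FALSE)
  }
  out[is.na(out)] <- "other"
  out
}

.nct_pattern <- "^NCT[0-9]{8}$"

xml_text1 <- function(doc, xpath) {
  node <- xml2::xml_find_first(doc, xpath)
  if (inherits(node, "xml_missing")) return(NA_character_)
  txt <- trimws(xml2::xml_text(node))
  if (!nzchar(txt)) NA_character_ else txt
}

#' Parse one registry XML study record
#'
#' Reads a single full-study-record document in the 2016-era public registry
#' dialect (`clinical_study` root with `id_info/nct_id`, `study_type`,
#' `overall_status`, `phase`, `completion_date`, `primary_completion_date`,
#' `lead_sponsor/agency`, `lead_sponsor/agency_class`, `enrollment`,
#' `firstreceived_results_date`, `firstreceived_results_disposition_date`).
#' Optional elements that are absent become `NA`; the two results flags are
#' `TRUE` exactly when the corresponding date tag is present and non-empty.
#'
#' @param x An `xml2` document, an XML string, or a path to an XML file.
#' @return A one-row tibble (a trial record) with columns `nct_id`,
#'   `study_type`, `overall_status`, `phase`, `completion_date`,
#'   `primary_completion_date`, `lead_sponsor_name`, `sponsor_class`,
#'   `enrollment`, `has_registry_results`, `has_results_disposition`.
#' @seealso [load_registry()], [write_trial_xml()]
#' @export
parse_trial_xml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  root <- xml2::xml_root(doc)
  nct_id <- xml_text1(root, ".//id_info/nct_id") %||% NA_character_
  if (is.na(nct_id)) nct_id <- xml_text1(root, ".//nct_id")
  if (is.na(nct_id) || !grepl(.nct_pattern, nct_id)) {
    stop_parse_error(
      sprintf("missing or invalid nct_id (%s)",
              if (is.na(nct_id)) "absent" else dQuote(nct_id, q = FALSE)),
      field = "nct_id", record = nct_id
    )
  }
  pd_or_na <- function(xpath, field) {
    txt <- xml_text1(root, xpath)
    if (is.na(txt)) partial_date(NA_integer_, NA_integer_)
    else parse_partial_date(txt, field = field, record = nct_id)
  }
  enrollment_txt <- xml_text1(root, "./enrollment")
  enrollment <- if (is.na(enrollment_txt)) NA_integer_ else {
    v <- suppressWarnings(as.integer(enrollment_txt))
    if (is.na(v) || v < 0L) {
      stop_parse_error(sprintf("invalid enrollment %s in record %s",
                               dQuote(enrollment_txt, q = FALSE), nct_id),
                       field = "enrollment", record = nct_id, value = enrollment_txt)
    }
    v
  }
  tibble::tibble(
    nct_id = nct_id,
    study_type = xml_text1(root, "./study_type"),
    overall_status = xml_text1(root, "./overall_status"),
    phase = xml_text1(root, "./phase"),
    completion_date = pd_or_na("./completion_date", "completion_date"),
    primary_completion_date = pd_or_na("./primary_completion_date",
                                       "primary_completion_date"),
    lead_sponsor_name = xml_text1(root, "./lead_sponsor/agency"),
    sponsor_class = map_sponsor_class(xml_text1(root, "./lead_sponsor/agency_class")),
    enrollment = enrollment,
    has_registry_results = !is.na(xml_text1(root, "./firstreceived_results_date")),
    has_results_disposition = !is.na(xml_text1(root, "./firstreceived_results_disposition_date"))
  )
}

#' Load a directory of registry XML records
#'
#' Parses every `*.xml` file in `dir` (one trial per file) into a trial
#' table. Files are visited in lexicographic filename order; when two files
#' carry the same `nct_id`, the first wins and later ones are logged as
#' duplicates. Unparseable files are skipped and logged rather than aborting
#' the load.
#'
#' @param dir Directory containing per-trial XML record files.
#' @param log_path Optional path; when given, the parse log is written there
#'   as JSON lines (one event per line).
#' @return A list with `trials` (tibble of trial records, one row per unique
#'   parseable trial) and `log` (tibble with columns `file`, `nct_id`,
#'   `event`, `detail`; events are `"parse_error"` and `"duplicate"`).
#' @export
load_registry <- function(dir, log_path = NULL) {
  if (!dir.exists(dir)) stop(sprintf("registry directory %s does not exist", dir))
  files <- list.files(dir, pattern = "\\.xml$", full.names = FALSE)
  if (length(files) == 0L) stop(sprintf("registry directory %s contains no XML files", dir))
  files <- sort(files, method = "radix")
  rows <- vector("list", length(files))
  log <- list()
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(files)) {
    f <- files[i]
    rec <- tryCatch(parse_trial_xml(file.path(dir, f)), error = function(e) e)
    if (inherits(rec, "error")) {
      log[[length(log) + 1L]] <- tibble::tibble(
        file = f, nct_id = NA_character_, event = "parse_error",
        detail = conditionMessage(rec))
      next
    }
    id <- rec$nct_id
    if (!is.null(seen[[id]])) {
      log[[length(log) + 1L]] <- tibble::tibble(
        file = f, nct_id = id, event = "duplicate",
        detail = sprintf("nct_id already loaded from %s", seen[[id]]))
      next
    }
    seen[[id]] <- f
    rows[[i]] <- rec
  }
  trials <- dplyr::bind_rows(rows)
  log <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(file = character(), nct_id = character(),
                   event = character(), detail = character())
  if (!is.null(log_path)) write_jsonl(log, log_path)
  list(trials = trials, log = log)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

format_registry_date <- function(pd) {
  if (is.na(pd)) return(NA_character_)
  y <- pd_year(pd); m <- pd_month(pd); d <- pd_day(pd)
  if (is.na(d)) sprintf("%s %d", month.name[m], y)
  else sprintf("%s %d, %d", month.name[m], d, y)
}

#' Serialize a trial record to the registry XML dialect
#'
#' Writes one trial record as a `clinical_study` document using the same
#' element names [parse_trial_xml()] reads, so that serialize-then-parse is
#' an identity on records. Dates are emitted in the registry's prose style
#' (`"June 2010"`, `"January 1, 2006"`). Optional fields that are `NA` are
#' omitted; the boolean results flags are emitted as presence/absence of
#' their date tags.
#'
#' @param trial A one-row trial tibble as returned by [parse_trial_xml()].
#' @param path File path to write; the XML string is also returned invisibly.
#' @return The XML document as a character string, invisibly.
#' @export
write_trial_xml <- function(trial, path = NULL) {
  stopifnot(nrow(trial) == 1L)
  el <- function(tag, value) {
    if (is.na(value)) character() else sprintf("  <%s>%s</%s>", tag, xml_escape(value), tag)
  }
  raw_class <- c(industry = "Industry", NIH = "NIH", `US Fed` = "U.S. Fed",
                 other = "Other")[[trial$sponsor_class]]
  lines <- c(
    "<clinical_study>",
    "  <id_info>",
    sprintf("    <nct_id>%s</nct_id>", trial$nct_id),
    "  </id_info>",
    el("study_type", trial$study_type),
    el("overall_status", trial$overall_status),
    el("phase", trial$phase),
    el("completion_date", format_registry_date(trial$completion_date)),
    el("primary_completion_date", format_registry_date(trial$primary_completion_date)),
    "  <lead_sponsor>",
    sprintf("    <agency>%s</agency>", xml_escape(trial$lead_sponsor_name)),
    sprintf("    <agency_class>%s</agency_class>", raw_class),
    "  </lead_sponsor>",
    el("enrollment", if (is.na(trial$enrollment)) NA_character_ else
      as.character(trial$enrollment)),
    if (trial$has_registry_results)
      "  <firstreceived_results_date>January 1, 2016</firstreceived_results_date>"
    else character(),
    if (trial$has_results_disposition)
      "  <firstreceived_results_disposition_date>January 1, 2016</firstreceived_results_disposition_date>"
    else character(),
    "</clinical_study>"
  )
  out <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' Write a trial table as a registry directory
#'
#' One XML file per trial, named `<nct_id>.xml`, in the dialect of
#' [write_trial_xml()].
#'
#' @param trials Trial tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(trials))) {
    write_trial_xml(trials[i, ], file.path(dir, paste0(trials$nct_id[i], ".xml")))
  }
  invisible(dir)
}

write_jsonl <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE, null = "null",
                                na = "null"),
               con, useBytes = TRUE)
  }
  invisible(path)
}
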