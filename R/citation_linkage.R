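.citation_cols <- c("pmid", "title", "abstract", "pub_date", "mesh_terms",
                    "publication_types", "subheadings", "secondary_ids")

#' Read a citation corpus from JSON lines
#'
#' One citation per line, with fields `pmid`, `title`, `abstract`,
#' `pub_date` (a date string), and the array fields `mesh_terms`,
#' `publication_types`, `subheadings`, `secondary_ids`. Missing array fields
#' become empty sets; a missing abstract becomes the empty string.
#'
#' @param path Path to a `.jsonl` file.
#' @return A citation tibble: `pmid` (character), `title`, `abstract`,
#'   `pub_date` (`partial_date`), and the four set fields as list-columns of
#'   character vectors.
#' @export
read_citations <- function(path) {
  if (!file.exists(path)) stop(sprintf("citation file %s does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  as_set <- function(x) as.character(x %||% character())
  cits <- tibble::tibble(
    pmid = vapply(recs, function(r) as.character(r$pmid), character(1)),
    title = vapply(recs, function(r) as.character(r$title %||% ""), character(1)),
    abstract = vapply(recs, function(r) as.character(r$abstract %||% ""), character(1)),
    pub_date = parse_partial_date(
      vapply(recs, function(r) as.character(r$pub_date), character(1)),
      field = "pub_date"),
    mesh_terms = lapply(recs, function(r) as_set(r$mesh_terms)),
    publication_types = lapply(recs, function(r) as_set(r$publication_types)),
    subheadings = lapply(recs, function(r) as_set(r$subheadings)),
    secondary_ids = lapply(recs, function(r) as_set(r$secondary_ids))
  )
  if (anyDuplicated(cits$pmid)) {
    stop(sprintf("duplicate pmid(s) in %s: %s", path,
                 paste(unique(cits$pmid[duplicated(cits$pmid)]), collapse = ", ")))
  }
  cits
}

#' Write a citation corpus as JSON lines
#'
#' Inverse of [read_citations()]: fixed key order, one citation per line.
#'
#' @param citations Citation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_citations <- function(citations, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(citations))) {
    rec <- list(
      pmid = citations$pmid[i],
      title = citations$title[i],
      abstract = citations$abstract[i],
      pub_date = format(citations$pub_date[i]),
      mesh_terms = citations$mesh_terms[[i]],
      publication_types = citations$publication_types[[i]],
      subheadings = citations$subheadings[[i]],
      secondary_ids = citations$secondary_ids[[i]]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read citations from a PubMed XML export
#'
#' Adapter for the standard `PubmedArticleSet` citation export. Maps
#' `ArticleTitle`/`AbstractText`, the article `PubDate`, MeSH descriptor and
#' qualifier names, publication types, and ClinicalTrials.gov accession
#' numbers from `DataBankList` into the citation table of [read_citations()].
#'
#' @param path Path to a PubMed XML file.
#' @return A citation tibble.
#' @export
read_pubmed_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  if (length(arts) == 0L) stop(sprintf("no PubmedArticle records in %s", path))
  one <- function(a) {
    txt <- function(xp) {
      n <- xml2::xml_find_all(a, xp)
      paste(trimws(xml2::xml_text(n)), collapse = " ")
    }
    set <- function(xp) trimws(xml2::xml_text(xml2::xml_find_all(a, xp)))
    y <- txt(".//Article/Journal/JournalIssue/PubDate/Year")
    m <- txt(".//Article/Journal/JournalIssue/PubDate/Month")
    d <- txt(".//Article/Journal/JournalIssue/PubDate/Day")
    date_txt <- if (nzchar(d)) sprintf("%s %s, %s", m, d, y)
      else if (nzchar(m)) sprintf("%s %s", m, y)
      else sprintf("%s-01", y)  # year-only dates floor to January
    accession <- set(".//DataBankList/DataBank[DataBankName='ClinicalTrials.gov']/AccessionNumberList/AccessionNumber")
    tibble::tibble(
      pmid = txt(".//MedlineCitation/PMID"),
      title = txt(".//Article/ArticleTitle"),
      abstract = txt(".//Article/Abstract/AbstractText"),
      pub_date = parse_partial_date(date_txt, field = "PubDate"),
      mesh_terms = list(set(".//MeshHeadingList/MeshHeading/DescriptorName")),
      publication_types = list(set(".//PublicationTypeList/PublicationType")),
      subheadings = list(set(".//MeshHeadingList/MeshHeading/QualifierName")),
      secondary_ids = list(accession)
    )
  }
  dplyr::bind_rows(lapply(arts, one))
}

#' Extract registry identifiers from free text
#'
#' Finds every case-insensitive occurrence of `NCT` followed by exactly
#' eight digits; a run of nine or more digits after `NCT` is not an
#' identifier and yields no match. Results are upper-cased, de-duplicated
#' and sorted.
#'
#' @param text Character vector; matches are pooled across elements.
#' @return Character vector of distinct registry identifiers.
#' @examples
#' extract_nct_ids("Registered as NCT01234567 (nct01234567).")
#' extract_nct_ids("NCT123456789 is not an identifier")
#' @export
extract_nct_ids <- function(text) {
  if (length(text) == 0L) return(character())
  text <- text[!is.na(text)]
  hits <- regmatches(text, gregexpr("(?i)NCT[0-9]{8}(?![0-9])", text, perl = TRUE))
  sort(unique(toupper(unlist(hits))))
}

# ---- Fielded boolean queries ------------------------------------------------

.query_fields <- c("title_abstract", "mesh", "publication_type", "subheading")

#' Build fielded boolean query trees
#'
#' A query is a finite tree of `query_term()` leaves combined with
#' `query_and()` / `query_or()`. Each leaf carries a field tag:
#' `title_abstract` terms match whitespace-delimited, case-insensitive,
#' punctuation-stripped tokens of title plus abstract (with optional prefix
#' truncation, PubMed's `term*`); `mesh`, `publication_type` and
#' `subheading` terms match set membership, case-insensitively.
#'
#' @param text Term text (a token or prefix for `title_abstract`; a full
#'   entry for the set fields).
#' @param field One of `"title_abstract"`, `"mesh"`, `"publication_type"`,
#'   `"subheading"`.
#' @param truncated If `TRUE`, the term matches any token with this prefix.
#' @param ... Child nodes for `query_and()` / `query_or()`.
#' @return A `fielded_query` node.
#' @seealso [therapy_query()], [evaluate_query()]
#' @export
query_term <- function(text, field = .query_fields, truncated = FALSE) {
  field <- match.arg(field)
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  structure(list(op = "term", text = text, field = field, truncated = truncated),
            class = "fielded_query")
}

#' @rdname query_term
#' @export
query_and <- function(...) {
  children <- list(...)
  stopifnot(length(children) >= 1L,
            all(vapply(children, inherits, logical(1), "fielded_query")))
  structure(list(op = "and", children = children), class = "fielded_query")
}

#' @rdname query_term
#' @export
query_or <- function(...) {
  children <- list(...)
  stopifnot(length(children) >= 1L,
            all(vapply(children, inherits, logical(1), "fielded_query")))
  structure(list(op = "or", children = children), class = "fielded_query")
}

#' @export
format.fielded_query <- function(x, ...) {
  if (x$op == "term") {
    f <- c(title_abstract = "Title/Abstract", mesh = "MeSH",
           publication_type = "Publication Type", subheading = "Subheading")[[x$field]]
    sprintf("\"%s%s\"[%s]", x$text, if (x$truncated) "*" else "", f)
  } else {
    sprintf("(%s)", paste(vapply(x$children, format, character(1)),
                          collapse = sprintf(" %s ", toupper(x$op))))
  }
}

#' @export
print.fielded_query <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' The validated PubMed therapy clinical-query filters
#'
#' The standard sensitive ("broad") and specific ("narrow") treatment-study
#' search strategies, expressed as fielded query trees over a local citation
#' record (no MeSH-tree explosion: terms match the record's own entries).
#'
#' Broad: `(clinical[tiab] AND trial[tiab]) OR "clinical trials as
#' topic"[MeSH] OR "clinical trial"[pt] OR random*[tiab] OR "random
#' allocation"[MeSH] OR "therapeutic use"[sh]`.
#' Narrow: `"randomized controlled trial"[pt] OR (randomized[tiab] AND
#' controlled[tiab] AND trial[tiab])`.
#'
#' @param variant `"broad"` (default) or `"narrow"`.
#' @return A `fielded_query`.
#' @export
therapy_query <- function(variant = c("broad", "narrow")) {
  variant <- match.arg(variant)
  if (variant == "broad") {
    query_or(
      query_and(query_term("clinical", "title_abstract"),
                query_term("trial", "title_abstract")),
      query_term("clinical trials as topic", "mesh"),
      query_term("clinical trial", "publication_type"),
      query_term("random", "title_abstract", truncated = TRUE),
      query_term("random allocation", "mesh"),
      query_term("therapeutic use", "subheading")
    )
  } else {
    query_or(
      query_term("randomized controlled trial", "publication_type"),
      query_and(query_term("randomized", "title_abstract"),
                query_term("controlled", "title_abstract"),
                query_term("trial", "title_abstract"))
    )
  }
}

#' Tokenize title/abstract text for query matching
#'
#' Lower-cases, splits on whitespace, and strips leading/trailing
#' punctuation from each token; empty tokens are dropped. No stemming.
#'
#' @param text Character vector; tokens are pooled.
#' @return Character vector of tokens.
#' @export
tokenize_text <- function(text) {
  text <- text[!is.na(text)]
  toks <- unlist(strsplit(tolower(paste(text, collapse = " ")), "[[:space:]]+"))
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

#' Evaluate a fielded query against one citation
#'
#' @param query A `fielded_query`.
#' @param citation A one-row citation tibble or a list with fields `title`,
#'   `abstract`, `mesh_terms`, `publication_types`, `subheadings`.
#' @return `TRUE` if the citation satisfies the query.
#' @export
evaluate_query <- function(query, citation) {
  stopifnot(inherits(query, "fielded_query"))
  get_set <- function(field) {
    x <- citation[[field]]
    if (is.list(x)) x <- x[[1]] %||% character()
    tolower(as.character(x))
  }
  tokens <- tokenize_text(c(as.character(citation$title),
                            as.character(citation$abstract)))
  sets <- list(
    mesh = get_set("mesh_terms"),
    publication_type = get_set("publication_types"),
    subheading = get_set("subheadings")
  )
  eval_node <- function(node) {
    switch(node$op,
      term = {
        if (node$field == "title_abstract") {
          if (node$truncated) any(startsWith(tokens, tolower(node$text)))
          else tolower(node$text) %in% tokens
        } else {
          tolower(node$text) %in% sets[[node$field]]
        }
      },
      and = all(vapply(node$children, eval_node, logical(1))),
      or = any(vapply(node$children, eval_node, logical(1))),
      stop(sprintf("unknown query node op %s", dQuote(node$op, q = FALSE)))
    )
  }
  eval_node(query)
}

# ---- Candidate matching and screens ----------------------------------------

#' Index a citation corpus by mentioned registry identifier
#'
#' Builds the long table of (trial, citation) candidate links over a whole
#' corpus: a citation is a candidate for a trial when the trial's `nct_id`
#' appears among the citation's secondary-source accessions
#' (`route = "secondary_id"`) or in its title/abstract text
#' (`route = "text"`). A citation matching through both carries the
#' `secondary_id` route.
#'
#' @param citations Citation tibble.
#' @return Tibble with `nct_id`, `pmid`, `route`, one row per matched pair.
#' @export
citation_nct_index <- function(citations) {
  n <- nrow(citations)
  if (n == 0L) {
    return(tibble::tibble(nct_id = character(), pmid = character(),
                          route = character()))
  }
  sec <- lapply(citations$secondary_ids, function(ids) {
    ids <- toupper(ids)
    unique(ids[grepl(.nct_pattern, ids)])
  })
  txt_all <- regmatches(
    paste(citations$title, citations$abstract),
    gregexpr("(?i)NCT[0-9]{8}(?![0-9])", paste(citations$title, citations$abstract),
             perl = TRUE))
  txt <- lapply(txt_all, function(h) unique(toupper(h)))
  n_sec <- lengths(sec); n_txt <- lengths(txt)
  long <- tibble::tibble(
    nct_id = c(unlist(sec), unlist(txt)),
    pmid = c(rep(citations$pmid, n_sec), rep(citations$pmid, n_txt)),
    route = c(rep("secondary_id", sum(n_sec)), rep("text", sum(n_txt)))
  )
  # secondary_id wins when a pair matches via both routes
  long <- long[order(long$nct_id, long$pmid,
                     match(long$route, c("secondary_id", "text")),
                     method = "radix"), ]
  long[!duplicated(long[c("nct_id", "pmid")]), ]
}

#' Candidate results publications for one trial
#'
#' @param trial One-row trial tibble.
#' @param citations Citation tibble.
#' @return Tibble with `pmid` and `route` for every citation mentioning the
#'   trial's registry identifier.
#' @export
candidate_citations <- function(trial, citations) {
  idx <- citation_nct_index(citations)
  idx <- idx[idx$nct_id == trial$nct_id, c("pmid", "route")]
  tibble::as_tibble(idx)
}

#' Publication-timing screen
#'
#' A candidate passes when it was not published before the trial's
#' completion, compared at month precision: publication in the completion
#' month itself passes ("before" is strict).
#'
#' @param pub_date,completion `partial_date` vectors (recycled).
#' @return `"pass"`/`"fail"` character vector.
#' @export
screen_post_completion <- function(pub_date, completion) {
  ifelse(!(pub_date < completion), "pass", "fail")
}

#' Protocol-paper screen
#'
#' Fails any citation whose title contains the contiguous substring
#' `"study protocol"`, case-insensitively. Only the title is consulted.
#'
#' @param title Character vector of titles.
#' @return `"pass"`/`"fail"` character vector.
#' @export
screen_not_protocol <- function(title) {
  ifelse(grepl("study protocol", tolower(title), fixed = TRUE), "fail", "pass")
}

#' Link trials to screened results publications
#'
#' For every (eligible) trial, finds candidate citations by registry-ID
#' match and applies the three screens: publication not before completion,
#' title not a protocol announcement, and the therapy clinical-query filter.
#' A candidate is accepted when every evaluated screen passes. Trials with
#' no effective completion date get `post_completion = "not_evaluated"`,
#' which does not block acceptance (the condition cannot be checked).
#'
#' @param trials Trial tibble (typically the eligible set).
#' @param citations Citation tibble.
#' @param variant Therapy filter variant, `"broad"` or `"narrow"`.
#' @param config Optional [audit_config()]; supplies `variant` and the
#'   completion-field precedence when given.
#' @return Evidence tibble: `nct_id`, `pmid`, `route`, the three screen
#'   columns (`"pass"`/`"fail"`/`"not_evaluated"`), and `accepted`.
#' @export
link_trials <- function(trials, citations, variant = c("broad", "narrow"),
                        config = NULL) {
  if (!is.null(config)) {
    variant <- config$therapy_variant
    precedence <- config$completion_precedence
  } else {
    variant <- match.arg(variant)
    precedence <- "completion_date"
  }
  idx <- citation_nct_index(citations)
  idx <- idx[idx$nct_id %in% trials$nct_id, ]
  if (nrow(idx) == 0L) {
    return(tibble::tibble(nct_id = character(), pmid = character(),
                          route = character(), post_completion = character(),
                          not_protocol = character(), therapy_filter = character(),
                          accepted = logical()))
  }
  query <- therapy_query(variant)
  # therapy screen is per-citation; evaluate once per distinct candidate pmid
  pmids <- unique(idx$pmid)
  crows <- match(pmids, citations$pmid)
  therapy_by_pmid <- stats::setNames(vapply(crows, function(i) {
    if (evaluate_query(query, citations[i, ])) "pass" else "fail"
  }, character(1)), pmids)
  completion <- effective_completion_date(trials, precedence)
  trow <- match(idx$nct_id, trials$nct_id)
  crow <- match(idx$pmid, citations$pmid)
  comp <- completion[trow]
  pub <- citations$pub_date[crow]
  post <- ifelse(is.na(comp), "not_evaluated",
                 screen_post_completion(pub, comp))
  out <- tibble::tibble(
    nct_id = idx$nct_id,
    pmid = idx$pmid,
    route = idx$route,
    post_completion = post,
    not_protocol = screen_not_protocol(citations$title[crow]),
    therapy_filter = unname(therapy_by_pmid[idx$pmid]),
    accepted = post != "fail" &
      screen_not_protocol(citations$title[crow]) == "pass" &
      unname(therapy_by_pmid[idx$pmid]) == "pass"
  )
  out[order(out$nct_id, out$pmid, method = "radix"), ]
}

#' Link one trial
#'
#' @inheritParams link_trials
#' @param trial One-row trial tibble.
#' @return Evidence tibble for this trial; see [link_trials()].
#' @export
link_trial <- function(trial, citations, variant = c("broad", "narrow")) {
  link_trials(trial, citations, variant)
}
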