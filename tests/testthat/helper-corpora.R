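# Builders for hand-crafted records used across test files.

make_trial <- function(nct_id = "NCT00000001",
                       study_type = "Interventional",
                       overall_status = "Completed",
                       phase = "Phase 3",
                       completion_date = partial_date(2010, 6),
                       primary_completion_date = partial_date(NA_integer_, NA_integer_),
                       lead_sponsor_name = "Acme Pharma",
                       sponsor_class = "industry",
                       enrollment = 100L,
                       has_registry_results = FALSE,
                       has_results_disposition = FALSE) {
  tibble::tibble(
    nct_id = nct_id, study_type = study_type, overall_status = overall_status,
    phase = phase, completion_date = completion_date,
    primary_completion_date = primary_completion_date,
    lead_sponsor_name = lead_sponsor_name, sponsor_class = sponsor_class,
    enrollment = enrollment, has_registry_results = has_registry_results,
    has_results_disposition = has_results_disposition
  )
}

make_citation <- function(pmid = "1",
                          title = "Randomized controlled trial of X",
                          abstract = "",
                          pub_date = partial_date(2012, 5),
                          mesh_terms = character(),
                          publication_types = c("Randomized Controlled Trial",
                                                "Clinical Trial"),
                          subheadings = character(),
                          secondary_ids = character()) {
  tibble::tibble(
    pmid = pmid, title = title, abstract = abstract, pub_date = pub_date,
    mesh_terms = list(mesh_terms), publication_types = list(publication_types),
    subheadings = list(subheadings), secondary_ids = list(secondary_ids)
  )
}

# Random citation corpus over a small vocabulary, for query-oracle and
# linkage property tests.
random_citations <- function(n, seed) {
  set.seed(seed)
  vocab <- c("clinical", "trial", "randomized", "randomised", "controlled",
             "random", "study", "cohort", "survey", "placebo", "outcomes",
             "therapy", "protocol", "patients", "review")
  mesh_pool <- c("Clinical Trials as Topic", "Random Allocation", "Humans",
                 "Neoplasms", "Diabetes Mellitus")
  type_pool <- c("Clinical Trial", "Randomized Controlled Trial",
                 "Journal Article", "Review", "Comment")
  sub_pool <- c("therapeutic use", "adverse effects", "epidemiology")
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_citation(
      pmid = as.character(i),
      title = paste(sample(vocab, sample(2:6, 1), replace = TRUE), collapse = " "),
      abstract = paste(sample(vocab, sample(0:10, 1), replace = TRUE), collapse = " "),
      pub_date = partial_date(sample(2006:2015, 1), sample(1:12, 1)),
      mesh_terms = sample(mesh_pool, sample(0:3, 1)),
      publication_types = sample(type_pool, sample(0:2, 1)),
      subheadings = sample(sub_pool, sample(0:2, 1))
    )
  }))
}

# Random fielded-query AST of bounded depth, for the evaluator-vs-oracle
# equivalence property.
random_query <- function(depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vocab <- c("clinical", "trial", "randomized", "rand", "stud", "placebo",
             "zzz-absent", "therapy")
  mesh_pool <- c("Clinical Trials as Topic", "Random Allocation", "Humans",
                 "Absent Heading")
  type_pool <- c("Clinical Trial", "Randomized Controlled Trial", "Review")
  sub_pool <- c("therapeutic use", "adverse effects")
  build <- function(d) {
    if (d <= 1L || stats::runif(1) < 0.35) {
      field <- sample(c("title_abstract", "mesh", "publication_type",
                        "subheading"), 1)
      text <- switch(field,
                     title_abstract = sample(vocab, 1),
                     mesh = sample(mesh_pool, 1),
                     publication_type = sample(type_pool, 1),
                     subheading = sample(sub_pool, 1))
      query_term(text, field,
                 truncated = field == "title_abstract" && stats::runif(1) < 0.4)
    } else {
      k <- sample(2:3, 1)
      children <- lapply(seq_len(k), function(i) build(d - 1L))
      if (stats::runif(1) < 0.5) do.call(query_and, children)
      else do.call(query_or, children)
    }
  }
  build(depth)
}
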