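test_that("registry identifiers are extracted by the 8-digit rule", {
  expect_equal(extract_nct_ids("Registered as NCT01234567."), "NCT01234567")
  expect_equal(extract_nct_ids("nct00000001 and NCT00000001"), "NCT00000001")
  expect_equal(extract_nct_ids("NCT123456789"), character())  # nine digits
  expect_equal(extract_nct_ids("NCT1234567"), character())    # seven digits
  expect_equal(extract_nct_ids(c("see NCT00000002", "and nct00000003 too")),
               c("NCT00000002", "NCT00000003"))
  expect_equal(extract_nct_ids(character()), character())
})

test_that("extraction agrees with a character-scan oracle on random text", {
  set.seed(31)
  pieces <- c("NCT", "0123456", "01234567", "012345678", " ", ",", "x",
              "nct", "(NCT00000001)", "trial")
  for (rep in 1:100) {
    s <- paste(sample(pieces, sample(3:12, 1), replace = TRUE), collapse = "")
    expect_equal(extract_nct_ids(s), oracle_scan_nct(s), label = s)
  }
})

test_that("candidate citations report the secondary-id route with priority", {
  trial <- make_trial("NCT01234567")
  corpus <- dplyr::bind_rows(
    make_citation("1", secondary_ids = "NCT01234567"),
    make_citation("2", abstract = "Registered: NCT01234567."),
    make_citation("3", abstract = "Registered: nct01234567.",
                  secondary_ids = "NCT01234567"),
    make_citation("4", abstract = "Unrelated NCT09999999 mention.")
  )
  cand <- candidate_citations(trial, corpus)
  expect_equal(cand$route[match(c("1", "2", "3"), cand$pmid)],
               c("secondary_id", "text", "secondary_id"))
  expect_false("4" %in% cand$pmid)
  expect_equal(nrow(candidate_citations(make_trial("NCT07777777"), corpus)), 0L)
})

test_that("adding an unrelated citation never removes an existing match", {
  trial <- make_trial("NCT01234567")
  corpus <- make_citation("1", secondary_ids = "NCT01234567")
  before <- candidate_citations(trial, corpus)
  after <- candidate_citations(trial, dplyr::bind_rows(
    corpus, make_citation("9", title = "Random unrelated review")))
  expect_true(all(before$pmid %in% after$pmid))
  # and corpus order does not matter
  shuffled <- candidate_citations(trial, dplyr::bind_rows(
    make_citation("9", title = "Random unrelated review"), corpus))
  expect_setequal(after$pmid, shuffled$pmid)
})

test_that("publication-timing screen treats same-month publication as pass", {
  expect_equal(screen_post_completion(partial_date(2012, 5), partial_date(2012, 5)),
               "pass")
  expect_equal(screen_post_completion(partial_date(2012, 4), partial_date(2012, 5)),
               "fail")
  expect_equal(screen_post_completion(partial_date(2013, 1), partial_date(2012, 5)),
               "pass")
})

test_that("protocol screen matches the contiguous title substring only", {
  expect_equal(screen_not_protocol("Treatment of X: study protocol for a randomised trial"),
               "fail")
  expect_equal(screen_not_protocol("A Study Protocol announcement"), "fail")
  expect_equal(screen_not_protocol("Study of protocol deviations in surgery"),
               "pass")
  # abstract mentions do not matter: the rule is title-only
  ev <- link_trial(make_trial("NCT01234567"),
                   make_citation("1", abstract = "Our study protocol (NCT01234567) ...",
                                 pub_date = partial_date(2012, 1)),
                   variant = "broad")
  expect_equal(ev$not_protocol, "pass")
})

test_that("the built-in therapy filters behave as published", {
  broad <- therapy_query("broad")
  narrow <- therapy_query("narrow")
  ct <- make_citation("1", title = "An observational cohort",
                      publication_types = "Clinical Trial")
  expect_true(evaluate_query(broad, ct))
  rct <- make_citation("2", title = "An intervention evaluation",
                       publication_types = "Randomized Controlled Trial")
  expect_true(evaluate_query(narrow, rct))
  empty <- make_citation("3", title = "", abstract = "",
                         publication_types = character())
  expect_false(evaluate_query(broad, empty))
  expect_false(evaluate_query(narrow, empty))
  # truncation: random* matches randomised/randomized tokens
  expect_true(evaluate_query(broad, make_citation(
    "4", title = "A randomised comparison", publication_types = character())))
  # comment failing both variants
  expect_false(evaluate_query(broad, make_citation(
    "5", title = "Comment on recent findings",
    publication_types = "Comment")))
})

test_that("query evaluation equals the set-theoretic oracle on random corpora", {
  for (seed in 1:12) {
    corpus <- random_citations(n = 40, seed = 1000 + seed)
    queries <- c(lapply(1:6, function(i) random_query(sample(2:4, 1))),
                 list(therapy_query("broad"), therapy_query("narrow")))
    for (q in queries) {
      mine <- which(vapply(seq_len(nrow(corpus)), function(i)
        evaluate_query(q, corpus[i, ]), logical(1)))
      expect_equal(mine, oracle_query_rows(q, corpus), label = format(q))
    }
  }
})

test_that("link_trial screens candidates and accepts only full passes", {
  trial <- make_trial("NCT01234567", completion_date = partial_date(2012, 5))
  corpus <- dplyr::bind_rows(
    make_citation("10", pub_date = partial_date(2013, 2),
                  secondary_ids = "NCT01234567"),
    make_citation("11", title = "Treatment of X: study protocol for a randomized controlled trial",
                  abstract = "Registered as NCT01234567.",
                  pub_date = partial_date(2013, 2)),
    make_citation("12", title = "Randomized controlled trial, early report",
                  pub_date = partial_date(2011, 1),
                  secondary_ids = "NCT01234567"),
    make_citation("13", title = "Comment on recent findings",
                  abstract = "Discussion of NCT01234567.",
                  pub_date = partial_date(2013, 8),
                  publication_types = "Comment")
  )
  ev <- link_trial(trial, corpus)
  ev <- ev[match(c("10", "11", "12", "13"), ev$pmid), ]
  expect_equal(ev$accepted, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(ev$not_protocol[2], "fail")
  expect_equal(ev$post_completion[3], "fail")
  expect_equal(ev$therapy_filter[4], "fail")
  # each rejected decoy fails exactly its own screen
  screens <- cbind(ev$post_completion, ev$not_protocol, ev$therapy_filter)
  expect_equal(rowSums(screens == "fail"), c(0, 1, 1, 1))
})

test_that("a missing completion date leaves the timing screen unevaluated", {
  trial <- make_trial("NCT01234567",
                      completion_date = partial_date(NA_integer_, NA_integer_))
  ev <- link_trial(trial, make_citation("1", pub_date = partial_date(2011, 1),
                                        secondary_ids = "NCT01234567"))
  expect_equal(ev$post_completion, "not_evaluated")
  expect_true(ev$accepted)
})

test_that("citation corpora round-trip through JSON lines", {
  corpus <- dplyr::bind_rows(
    make_citation("1", title = "A \"quoted\" title", abstract = "",
                  mesh_terms = c("Humans", "Neoplasms"),
                  secondary_ids = "NCT00000001"),
    make_citation("2", pub_date = partial_date(2012, 5, 14))
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_citations(corpus, path)
  back <- read_citations(path)
  expect_equal(back$pmid, corpus$pmid)
  expect_equal(back$title, corpus$title)
  expect_equal(format(back$pub_date), format(corpus$pub_date))
  expect_equal(back$mesh_terms, corpus$mesh_terms)
  expect_equal(back$secondary_ids, corpus$secondary_ids)
  # duplicate pmids violate the corpus invariant
  write_citations(dplyr::bind_rows(corpus, corpus[1, ]), path)
  expect_error(read_citations(path), "duplicate pmid")
})

test_that("the PubMed XML adapter maps the standard export fields", {
  xml <- '<?xml version="1.0"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>101</PMID>
      <Article>
        <Journal><JournalIssue><PubDate><Year>2013</Year><Month>Feb</Month></PubDate></JournalIssue></Journal>
        <ArticleTitle>Randomized controlled trial of X</ArticleTitle>
        <Abstract><AbstractText>Results for NCT01234567.</AbstractText></Abstract>
      </Article>
      <MeshHeadingList>
        <MeshHeading><DescriptorName>Humans</DescriptorName></MeshHeading>
        <MeshHeading><DescriptorName>Neoplasms</DescriptorName><QualifierName>drug therapy</QualifierName></MeshHeading>
      </MeshHeadingList>
    </MedlineCitation>
    <PubmedData/>
    <Article/>
    <PublicationTypeList><PublicationType>Randomized Controlled Trial</PublicationType></PublicationTypeList>
    <DataBankList>
      <DataBank><DataBankName>ClinicalTrials.gov</DataBankName>
        <AccessionNumberList><AccessionNumber>NCT01234567</AccessionNumber></AccessionNumberList>
      </DataBank>
    </DataBankList>
  </PubmedArticle>
</PubmedArticleSet>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  cit <- read_pubmed_xml(path)
  expect_equal(cit$pmid, "101")
  expect_equal(format(cit$pub_date), "2013-02")
  expect_equal(cit$mesh_terms[[1]], c("Humans", "Neoplasms"))
  expect_equal(cit$subheadings[[1]], "drug therapy")
  expect_equal(cit$secondary_ids[[1]], "NCT01234567")
  expect_equal(cit$publication_types[[1]], "Randomized Controlled Trial")
})
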