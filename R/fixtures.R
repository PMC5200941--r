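#' Declare a sponsor profile for fixture generation
#'
#' @param name Lead sponsor name (exact string used in grouping).
#' @param class Sponsor class: `"industry"`, `"NIH"`, `"US Fed"`, `"other"`.
#' @param n_trials Number of eligible-by-construction trials to generate.
#' @param unreported_rate Fraction of this sponsor's trials planted as
#'   unreported; realized exactly by count (`round` half-up of
#'   `unreported_rate * n_trials`), not sampled.
#' @param n_unreported Alternative to `unreported_rate`: the exact count.
#' @return A `sponsor_profile` list.
#' @export
sponsor_profile <- function(name, class, n_trials, unreported_rate = NULL,
                            n_unreported = NULL) {
  stopifnot(is.character(name), nzchar(name),
            class %in% .sponsor_class_levels,
            n_trials >= 1L)
  if (is.null(n_unreported)) {
    stopifnot(!is.null(unreported_rate), unreported_rate >= 0, unreported_rate <= 1)
    n_unreported <- floor(unreported_rate * n_trials + 0.5)
  }
  stopifnot(n_unreported >= 0L, n_unreported <= n_trials)
  structure(list(name = name, class = class, n_trials = as.integer(n_trials),
                 n_unreported = as.integer(n_unreported)),
            class = "sponsor_profile")
}

#' Specify a synthetic audit corpus
#'
#' Describes a registry + citation corpus pair with planted ground truth:
#' how many trials each sponsor runs and how many of them are unreported,
#' how reported trials disseminate (structured registry results vs. a
#' results paper), which identifier route each results paper uses, and how
#' many decoy citations of each kind to plant.
#'
#' Default probabilities are the generator's standing study conditions:
#' `p_registry_results = 0.2` (roughly the observed compliance rate with
#' mandatory registry results posting), `p_text_only = 0.015` (the observed
#' share of citations carrying a registry ID only in title/abstract text,
#' not in the secondary-source field), and modest decoy rates so screened-out
#' citation types are well represented without dominating the corpus.
#'
#' @param sponsor_profiles List of [sponsor_profile()] objects.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param p_registry_results Probability a reported trial posts structured
#'   registry results (and then gets no results paper).
#' @param p_text_only Probability a results paper carries the registry ID
#'   only in its title/abstract, not in its secondary-source IDs.
#' @param p_protocol_decoy,p_precompletion_decoy,p_commentary_decoy
#'   Per-trial probabilities of planting a protocol paper, a pre-completion
#'   paper, and a commentary/editorial decoy.
#' @param n_noise_citations Unrelated citations carrying no valid registry
#'   identifier.
#' @param date_window Length-2 `partial_date`: completion months are drawn
#'   uniformly from this window, which must lie entirely inside the audit's
#'   eligibility window relative to `as_of`.
#' @param as_of The audit as-of month the corpus is built for.
#' @param include_ineligible Also plant one trial per eligibility failure
#'   mode plus a sub-threshold sponsor (see [ineligible_block()]).
#' @return A validated `fixture_spec` object.
#' @export
fixture_spec <- function(sponsor_profiles,
                         seed = 1L,
                         p_registry_results = 0.2,
                         p_text_only = 0.015,
                         p_protocol_decoy = 0.15,
                         p_precompletion_decoy = 0.10,
                         p_commentary_decoy = 0.15,
                         n_noise_citations = 25L,
                         date_window = c(partial_date(2006, 2), partial_date(2014, 6)),
                         as_of = partial_date(2016, 10),
                         include_ineligible = TRUE) {
  if (inherits(sponsor_profiles, "sponsor_profile")) {
    sponsor_profiles <- list(sponsor_profiles)
  }
  stopifnot(length(sponsor_profiles) >= 1L,
            all(vapply(sponsor_profiles, inherits, logical(1), "sponsor_profile")))
  nms <- vapply(sponsor_profiles, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("fixture_spec: duplicate sponsor profile names")
  probs <- c(p_registry_results, p_text_only, p_protocol_decoy,
             p_precompletion_decoy, p_commentary_decoy)
  if (any(probs < 0 | probs > 1)) stop("fixture_spec: probabilities must lie in [0, 1]")
  stopifnot(inherits(date_window, "partial_date"), length(date_window) == 2L,
            !anyNA(date_window), !(date_window[2] < date_window[1]))
  if (is.character(as_of)) as_of <- parse_partial_date(as_of, field = "as_of")
  if (months_between(date_window[2], as_of) <= 24L ||
      date_window[1] < partial_date(2006, 1)) {
    stop("fixture_spec: date_window must lie inside the eligibility window ",
         "(completion >= 2006-01 and more than 24 months before as_of)")
  }
  structure(
    list(sponsor_profiles = sponsor_profiles,
         n_trials = sum(vapply(sponsor_profiles, `[[`, integer(1), "n_trials")),
         seed = as.integer(seed),
         p_registry_results = p_registry_results,
         p_text_only = p_text_only,
         p_protocol_decoy = p_protocol_decoy,
         p_precompletion_decoy = p_precompletion_decoy,
         p_commentary_decoy = p_commentary_decoy,
         n_noise_citations = as.integer(n_noise_citations),
         date_window = date_window,
         as_of = as_of,
         include_ineligible = isTRUE(include_ineligible)),
    class = "fixture_spec"
  )
}

pd_from_month_index <- function(idx, day = NA_integer_) {
  year <- (idx - 1L) %/% 12L
  partial_date(year, idx - year * 12L, day)
}

pd_month_index <- function(pd) {
  pd_year(pd) * 12L + pd_month(pd)
}

.condition_pool <- c("chronic migraine", "type 2 diabetes", "major depression",
                     "rheumatoid arthritis", "advanced melanoma", "asthma",
                     "atrial fibrillation", "chronic heart failure")
.agent_pool <- c("AX-101", "BR-204", "CT-330", "DV-412", "EM-515", "FN-626",
                 "GL-737", "HK-848")

results_paper_title <- function(agent, condition) {
  sprintf("Randomized controlled trial of %s versus placebo in %s", agent, condition)
}

#' Plant one trial per eligibility failure mode
#'
#' Emits the ineligible exemplars used to exercise every arm of the filter
#' cascade: an observational study, a terminated study, a too-recent
#' completion, a pre-2006 completion, a phase-1 study, a study with a
#' results-disposition filing, and a block of otherwise-eligible trials run
#' by a sponsor too small to clear the 30-trial volume threshold.
#'
#' @param spec A `fixture_spec`.
#' @param start_id Integer; registry identifiers are assigned sequentially
#'   from this number.
#' @return List with `trials` (trial tibble) and `truth` (tibble `nct_id`,
#'   `eligible`, `first_failing`).
#' @export
ineligible_block <- function(spec, start_id = 900001L) {
  mk_id <- function(k) sprintf("NCT%08d", start_id + k - 1L)
  base <- function(nct_id, sponsor = "Ineligible Exemplars Consortium") {
    tibble::tibble(
      nct_id = nct_id, study_type = "Interventional",
      overall_status = "Completed", phase = "Phase 3",
      completion_date = partial_date(2010, 6),
      primary_completion_date = partial_date(NA_integer_, NA_integer_),
      lead_sponsor_name = sponsor, sponsor_class = "other",
      enrollment = 50L, has_registry_results = FALSE,
      has_results_disposition = FALSE)
  }
  t1 <- base(mk_id(1)); t1$study_type <- "Observational"
  t2 <- base(mk_id(2)); t2$overall_status <- "Terminated"
  t3 <- base(mk_id(3))
  t3$completion_date <- pd_from_month_index(pd_month_index(spec$as_of) - 12L)
  t4 <- base(mk_id(4)); t4$completion_date <- partial_date(2005, 12)
  t5 <- base(mk_id(5)); t5$phase <- "Phase 1"
  t6 <- base(mk_id(6)); t6$has_results_disposition <- TRUE
  n_small <- 3L
  small <- dplyr::bind_rows(lapply(seq_len(n_small), function(k) {
    base(mk_id(6L + k), sponsor = "Boutique Research Collective")
  }))
  trials <- dplyr::bind_rows(t1, t2, t3, t4, t5, t6, small)
  truth <- tibble::tibble(
    nct_id = trials$nct_id,
    eligible = FALSE,
    first_failing = c("study_type", "status", "completion_window",
                      "completion_window", "phase", "no_disposition",
                      rep("sponsor_volume", n_small))
  )
  list(trials = trials, truth = truth)
}

#' Generate a synthetic registry + citation corpus with planted ground truth
#'
#' Deterministically (given `spec$seed`) emits a registry directory in the
#' XML dialect of [write_trial_xml()], a citation corpus in the JSON-lines
#' dialect of [read_citations()], and the planted ground truth. Per-sponsor
#' unreported counts are realized exactly; each reported trial either posts
#' registry results (probability `p_registry_results`) or receives exactly
#' one accepted-by-construction results paper whose identifier route is
#' text-only with probability `p_text_only` and secondary-source otherwise.
#' Decoy citations (protocol, pre-completion, commentary) are constructed so
#' that exactly one linkage screen rejects them.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory; receives `registry/`, `citations.jsonl`,
#'   `ground_truth_trials.csv`, `ground_truth_decoys.csv`.
#' @return Invisibly, a list: `registry_dir`, `citations_path`, `trials`,
#'   `citations`, and `truth` (list of tibbles `trials` and `decoys`).
#' @export
generate_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  widx <- pd_month_index(spec$date_window)
  phases <- c("Phase 2", "Phase 2/Phase 3", "Phase 3", "Phase 4", "N/A")

  trial_rows <- list()
  truth_rows <- list()
  cit_rows <- list()
  decoy_rows <- list()
  nct_counter <- 0L
  pmid_counter <- 20000000L
  next_nct <- function() { nct_counter <<- nct_counter + 1L; sprintf("NCT%08d", nct_counter) }
  next_pmid <- function() { pmid_counter <<- pmid_counter + 1L; as.character(pmid_counter) }

  citation <- function(pmid, title, abstract, pub_date, types,
                       mesh = character(), sub = character(),
                       secondary = character()) {
    tibble::tibble(pmid = pmid, title = title, abstract = abstract,
                   pub_date = pub_date, mesh_terms = list(mesh),
                   publication_types = list(types), subheadings = list(sub),
                   secondary_ids = list(secondary))
  }

  # Draw order per sponsor profile (documented and fixed): trial attributes,
  # then the exact-count unreported selection, then per-trial dissemination
  # and decoy draws in trial order.
  for (prof in spec$sponsor_profiles) {
    n <- prof$n_trials
    phase <- sample(phases, n, replace = TRUE)
    comp_idx <- sample(seq(widx[1], widx[2]), n, replace = TRUE)
    has_day <- stats::runif(n) < 0.3
    comp_day <- ifelse(has_day, sample(1:28, n, replace = TRUE), NA_integer_)
    enrollment <- sample(20:500, n, replace = TRUE)
    unreported <- rep(FALSE, n)
    if (prof$n_unreported > 0L) {
      unreported[sample.int(n, prof$n_unreported)] <- TRUE
    }
    for (i in seq_len(n)) {
      nct <- next_nct()
      comp <- pd_from_month_index(comp_idx[i], comp_day[i])
      agent <- .agent_pool[(nct_counter %% length(.agent_pool)) + 1L]
      cond <- .condition_pool[(nct_counter %% length(.condition_pool)) + 1L]
      via_registry <- FALSE
      route <- "none"
      if (!unreported[i]) {
        via_registry <- stats::runif(1) < spec$p_registry_results
        if (via_registry) {
          route <- "registry"
        } else {
          text_only <- stats::runif(1) < spec$p_text_only
          route <- if (text_only) "text" else "secondary_id"
          pub <- pd_from_month_index(comp_idx[i] + sample(0:18, 1))
          abstract <- if (text_only) {
            sprintf("Efficacy and safety results in %s. ClinicalTrials.gov number %s.",
                    cond, nct)
          } else {
            sprintf("Efficacy and safety results of %s in %s.", agent, cond)
          }
          cit_rows[[length(cit_rows) + 1L]] <- citation(
            next_pmid(), results_paper_title(agent, cond), abstract, pub,
            types = c("Journal Article", "Randomized Controlled Trial",
                      "Clinical Trial"),
            mesh = c("Humans"),
            secondary = if (text_only) character() else nct)
        }
      }
      if (stats::runif(1) < spec$p_protocol_decoy) {
        pub <- pd_from_month_index(comp_idx[i] + sample(1:12, 1))
        pm <- next_pmid()
        cit_rows[[length(cit_rows) + 1L]] <- citation(
          pm, sprintf("Efficacy of %s in %s: study protocol for a randomized controlled trial",
                      agent, cond),
          sprintf("Design of an ongoing evaluation of %s.", agent), pub,
          types = c("Journal Article", "Randomized Controlled Trial"),
          secondary = nct)
        decoy_rows[[length(decoy_rows) + 1L]] <- tibble::tibble(
          pmid = pm, nct_id = nct, decoy_type = "protocol",
          expected_screen = "not_protocol")
      }
      if (stats::runif(1) < spec$p_precompletion_decoy) {
        pub <- pd_from_month_index(comp_idx[i] - sample(3:24, 1))
        pm <- next_pmid()
        cit_rows[[length(cit_rows) + 1L]] <- citation(
          pm, sprintf("Interim report from a randomized controlled trial of %s in %s",
                      agent, cond),
          sprintf("Early findings for %s.", agent), pub,
          types = c("Journal Article", "Randomized Controlled Trial"),
          secondary = nct)
        decoy_rows[[length(decoy_rows) + 1L]] <- tibble::tibble(
          pmid = pm, nct_id = nct, decoy_type = "precompletion",
          expected_screen = "post_completion")
      }
      if (stats::runif(1) < spec$p_commentary_decoy) {
        pub <- pd_from_month_index(comp_idx[i] + sample(1:12, 1))
        pm <- next_pmid()
        cit_rows[[length(cit_rows) + 1L]] <- citation(
          pm, sprintf("Comment on recent findings in %s", cond),
          sprintf("Editorial discussion of %s and its implications for practice.",
                  nct),
          pub, types = c("Comment"))
        decoy_rows[[length(decoy_rows) + 1L]] <- tibble::tibble(
          pmid = pm, nct_id = nct, decoy_type = "commentary",
          expected_screen = "therapy_filter")
      }
      trial_rows[[length(trial_rows) + 1L]] <- tibble::tibble(
        nct_id = nct, study_type = "Interventional",
        overall_status = "Completed", phase = phase[i],
        completion_date = comp,
        primary_completion_date = partial_date(NA_integer_, NA_integer_),
        lead_sponsor_name = prof$name, sponsor_class = prof$class,
        enrollment = enrollment[i], has_registry_results = via_registry,
        has_results_disposition = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        nct_id = nct, sponsor_name = prof$name, sponsor_class = prof$class,
        eligible = TRUE, first_failing = NA_character_,
        reported = !unreported[i], route = route,
        enrollment = enrollment[i])
    }
  }

  if (spec$n_noise_citations > 0L) {
    for (k in seq_len(spec$n_noise_citations)) {
      cond <- sample(.condition_pool, 1)
      cit_rows[[length(cit_rows) + 1L]] <- citation(
        next_pmid(), sprintf("Narrative review of management options in %s", cond),
        sprintf("A survey of practice; see also registry entry NCT%09d.",
                sample.int(1e6, 1)),  # nine digits: not a valid identifier
        pd_from_month_index(sample(seq(widx[1], widx[2]), 1)),
        types = c("Review"))
    }
  }

  trials <- dplyr::bind_rows(trial_rows)
  truth_trials <- dplyr::bind_rows(truth_rows)
  if (spec$include_ineligible) {
    blk <- ineligible_block(spec)
    trials <- dplyr::bind_rows(trials, blk$trials)
    truth_trials <- dplyr::bind_rows(
      truth_trials,
      tibble::tibble(nct_id = blk$truth$nct_id,
                     sponsor_name = blk$trials$lead_sponsor_name,
                     sponsor_class = blk$trials$sponsor_class,
                     eligible = blk$truth$eligible,
                     first_failing = blk$truth$first_failing,
                     reported = NA, route = NA_character_,
                     enrollment = blk$trials$enrollment))
  }
  citations <- dplyr::bind_rows(cit_rows)
  decoys <- if (length(decoy_rows)) dplyr::bind_rows(decoy_rows) else
    tibble::tibble(pmid = character(), nct_id = character(),
                   decoy_type = character(), expected_screen = character())

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  registry_dir <- file.path(out_dir, "registry")
  write_registry(trials, registry_dir)
  citations_path <- file.path(out_dir, "citations.jsonl")
  write_citations(citations, citations_path)
  tt <- truth_trials
  utils::write.csv(tt, file.path(out_dir, "ground_truth_trials.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(decoys, file.path(out_dir, "ground_truth_decoys.csv"),
                   row.names = FALSE, na = "")
  invisible(list(registry_dir = registry_dir, citations_path = citations_path,
                 trials = trials, citations = citations,
                 truth = list(trials = truth_trials, decoys = decoys)))
}

#' The packaged demonstration corpus specification
#'
#' A 1/10-scale corpus whose sponsor-class sizes and planted unreported
#' counts mirror a typical registry-wide audit: four classes with 880, 100,
#' 47 and 1566 eligible trials and class-level unreported counts of 239, 36,
#' 12 and 883 (about 45% unreported overall), spread over sponsors large
#' enough to clear the 30-trial volume threshold.
#'
#' @param seed Integer seed for [generate_fixtures()].
#' @return A [fixture_spec()].
#' @export
demo_fixture_spec <- function(seed = 20161020L) {
  split_count <- function(total, k) {
    base <- total %/% k
    rem <- total - base * k
    c(rep(base + 1L, rem), rep(base, k - rem))
  }
  mk <- function(prefix, class, n_sponsors, n_trials_each, n_unreported_total) {
    miss <- split_count(n_unreported_total, n_sponsors)
    lapply(seq_len(n_sponsors), function(i) {
      sponsor_profile(sprintf("%s %02d", prefix, i), class, n_trials_each,
                      n_unreported = miss[i])
    })
  }
  profiles <- c(
    mk("Meridian Pharma", "industry", 8L, 110L, 239L),
    mk("National Research Institute", "NIH", 2L, 50L, 36L),
    mk("Federal Health Agency", "US Fed", 1L, 47L, 12L),
    mk("University Hospital", "other", 9L, 174L, 883L)
  )
  fixture_spec(profiles, seed = seed)
}
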