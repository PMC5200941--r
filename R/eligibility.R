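# Trial-level filters, in the fixed cascade order. sponsor_volume is
# corpus-level and applied afterwards by filter_sponsors().
.trial_filters <- c("study_type", "status", "completion_window", "phase",
                    "no_disposition")

.default_phases <- c("Phase 2", "Phase 2/Phase 3", "Phase 3", "Phase 4", "N/A")

#' Audit run configuration
#'
#' Bundles the tunable parameters of the eligibility cascade and the
#' linkage stage. Defaults implement the audit's standard conditions:
#' interventional completed trials whose effective completion date is more
#' than 24 months before `as_of` and no earlier than January 2006, in phase
#' 2, 3, 4 or N/A (phase 1 and mixed phase-1/2 designs are excluded), with
#' no results-disposition filing, run by lead sponsors holding at least 30
#' eligible trials.
#'
#' @param as_of The audit's as-of month, a `partial_date` or a parseable
#'   date string such as `"2016-10"`.
#' @param min_sponsor_trials Minimum number of trial-level-eligible trials a
#'   lead sponsor must hold for its trials to enter the audit.
#' @param window_months Look-back window: completion must be strictly more
#'   than this many calendar months before `as_of`.
#' @param earliest_completion Earliest admissible completion month.
#' @param phase_whitelist Phases (case-insensitive) that pass the phase filter.
#' @param therapy_variant Which validated therapy clinical-query filter the
#'   linkage stage applies: `"broad"` (sensitive, the default) or `"narrow"`
#'   (specific).
#' @param completion_precedence Which completion field wins when both are
#'   present; the other is the fallback.
#' @param sponsor_normalizer Function applied to lead-sponsor names before
#'   grouping; ships as identity (sponsor identity is the exact string).
#' @return An object of class `audit_config`.
#' @export
audit_config <- function(as_of,
                         min_sponsor_trials = 30L,
                         window_months = 24L,
                         earliest_completion = partial_date(2006, 1),
                         phase_whitelist = .default_phases,
                         therapy_variant = c("broad", "narrow"),
                         completion_precedence = c("completion_date",
                                                   "primary_completion_date"),
                         sponsor_normalizer = identity) {
  if (is.character(as_of)) as_of <- parse_partial_date(as_of, field = "as_of")
  stopifnot(inherits(as_of, "partial_date"), length(as_of) == 1L, !is.na(as_of))
  if (is.character(earliest_completion)) {
    earliest_completion <- parse_partial_date(earliest_completion,
                                              field = "earliest_completion")
  }
  min_sponsor_trials <- as.integer(min_sponsor_trials)
  stopifnot(min_sponsor_trials >= 1L, window_months >= 0L)
  structure(
    list(as_of = as_of,
         min_sponsor_trials = min_sponsor_trials,
         window_months = as.integer(window_months),
         earliest_completion = earliest_completion,
         phase_whitelist = phase_whitelist,
         therapy_variant = match.arg(therapy_variant),
         completion_precedence = match.arg(completion_precedence),
         sponsor_normalizer = sponsor_normalizer),
    class = "audit_config"
  )
}

#' Effective completion date of a trial
#'
#' Returns the completion field named first in `precedence` when present,
#' otherwise the other one, otherwise `NA`. Registry records often populate
#' only one of the two completion fields; the audit treats `completion_date`
#' as authoritative by default.
#'
#' @param trials Trial tibble.
#' @param precedence `"completion_date"` (default) or
#'   `"primary_completion_date"`: the field consulted first.
#' @return A `partial_date` vector, `NA` where neither field is present.
#' @export
effective_completion_date <- function(trials,
                                      precedence = c("completion_date",
                                                     "primary_completion_date")) {
  precedence <- match.arg(precedence)
  first <- trials[[precedence]]
  second <- trials[[setdiff(c("completion_date", "primary_completion_date"),
                            precedence)]]
  out <- first
  missing <- is.na(out)
  if (any(missing)) out[missing] <- second[missing]
  out
}

#' Evaluate the trial-level filter cascade
#'
#' Applies the five trial-level filters to every trial, in the fixed order
#' `study_type`, `status`, `completion_window`, `phase`, `no_disposition`.
#' Every filter is evaluated for every trial (no short-circuiting), so the
#' output doubles as a per-filter audit trail; `first_failing` attributes
#' each ineligible trial to the first filter it fails. Missing data fails
#' the filter that needs it (a trial with no completion date fails
#' `completion_window`).
#'
#' @param trials Trial tibble.
#' @param config An [audit_config()].
#' @return A tibble with `nct_id`, one `"pass"`/`"fail"` column per filter,
#'   `eligible` (logical) and `first_failing` (`NA` when eligible).
#' @export
check_trials <- function(trials, config) {
  stopifnot(inherits(config, "audit_config"))
  pf <- function(x) ifelse(x, "pass", "fail")
  d <- effective_completion_date(trials, config$completion_precedence)
  window_ok <- !is.na(d) &
    months_between(d, config$as_of) > config$window_months &
    !(d < config$earliest_completion)
  checks <- tibble::tibble(
    nct_id = trials$nct_id,
    study_type = pf(!is.na(trials$study_type) &
                      tolower(trials$study_type) == "interventional"),
    status = pf(!is.na(trials$overall_status) &
                  tolower(trials$overall_status) == "completed"),
    completion_window = pf(window_ok),
    phase = pf(!is.na(trials$phase) &
                 tolower(trials$phase) %in% tolower(config$phase_whitelist)),
    no_disposition = pf(!trials$has_results_disposition)
  )
  fail_mat <- as.matrix(checks[.trial_filters]) == "fail"
  first_idx <- apply(fail_mat, 1L, function(r) if (any(r)) which(r)[1L] else NA_integer_)
  checks$eligible <- is.na(first_idx)
  checks$first_failing <- .trial_filters[first_idx]
  checks
}

#' Evaluate the filter cascade for a single trial
#'
#' @param trial One-row trial tibble.
#' @param as_of Audit as-of month (`partial_date` or string).
#' @param config Optional [audit_config()]; overrides `as_of` when given.
#' @return One-row decision tibble; see [check_trials()].
#' @export
check_trial <- function(trial, as_of, config = NULL) {
  if (is.null(config)) config <- audit_config(as_of)
  check_trials(trial, config)
}

#' Apply the sponsor-volume filter and assemble the filter report
#'
#' Retains trials whose lead sponsor has at least `min_trials` trials passing
#' all trial-level filters; trials of lower-volume sponsors are dropped and
#' counted under `sponsor_volume`. The report's failure counts attribute
#' each excluded trial to the first filter it failed, so
#' `n_input - n_eligible` always equals the sum of the per-filter counts.
#'
#' @param decisions Decision tibble from [check_trials()].
#' @param trials The trial tibble the decisions were computed from.
#' @param min_trials Sponsor-volume threshold (default 30).
#' @param sponsor_normalizer Function applied to sponsor names before
#'   counting; identity by default.
#' @return A list with `eligible` (tibble of retained trials) and `report`
#'   (class `filter_report`: `n_input`, `n_eligible`, and ordered per-filter
#'   failure `counts` ending in `sponsor_volume`).
#' @export
filter_sponsors <- function(decisions, trials, min_trials = 30L,
                            sponsor_normalizer = identity) {
  stopifnot(min_trials >= 1L)
  trials <- trials[match(decisions$nct_id, trials$nct_id), ]
  counts <- vapply(.trial_filters, function(f)
    sum(decisions$first_failing == f, na.rm = TRUE), integer(1))
  sponsor <- sponsor_normalizer(trials$lead_sponsor_name)
  trial_ok <- decisions$eligible
  tab <- table(sponsor[trial_ok])
  big <- names(tab)[tab >= min_trials]
  keep <- trial_ok & sponsor %in% big
  counts <- c(counts, sponsor_volume = sum(trial_ok & !keep))
  report <- structure(
    list(n_input = nrow(trials), n_eligible = sum(keep), counts = counts),
    class = "filter_report"
  )
  list(eligible = trials[keep, ], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d records in, %d eligible\n", x$n_input, x$n_eligible))
  for (f in names(x$counts)) cat(sprintf("  %-18s -%d\n", f, x$counts[[f]]))
  invisible(x)
}
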