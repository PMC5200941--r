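#' Per-trial dissemination verdicts
#'
#' Combines the two results-ascertainment routes into one verdict per trial:
#' a trial is *reported* when it has structured registry results (the
#' registry results-date tag) or at least one accepted results publication
#' from the linkage stage; otherwise it is *unreported*.
#'
#' @param trials Trial tibble (the eligible set).
#' @param evidence Evidence tibble from [link_trials()] (may cover a
#'   superset of `trials`; rows are matched by `nct_id`).
#' @return Status tibble: `nct_id`, `registry_results`, `publication`
#'   (logicals: which sources attest results), `reported`.
#' @export
ascertain_all <- function(trials, evidence) {
  acc <- evidence[evidence$accepted, , drop = FALSE]
  tibble::tibble(
    nct_id = trials$nct_id,
    registry_results = trials$has_registry_results,
    publication = trials$nct_id %in% acc$nct_id,
    reported = trials$has_registry_results | trials$nct_id %in% acc$nct_id
  )
}

#' @rdname ascertain_all
#' @param trial One-row trial tibble; `evidence` must refer to this trial.
#' @export
ascertain <- function(trial, evidence) {
  stopifnot(nrow(trial) == 1L,
            all(evidence$nct_id == trial$nct_id))
  ascertain_all(trial, evidence)
}

# Round-half-up of 100 * num/den to `decimals` places, in exact integer
# arithmetic (no binary floating-point ties): floor(s/den + 1/2) with
# s = 100 * num * 10^decimals.
round_half_up_pct <- function(num, den, decimals) {
  s <- 100 * as.numeric(num) * 10^decimals
  floor((2 * s + den) / (2 * den)) / 10^decimals
}

#' Display a percent-missing value
#'
#' Formats `100 * n_missing / n_eligible` rounded half-up on the exact
#' rational to the requested number of decimals, as used in the audit's
#' published tables (integer precision) and prose (one decimal).
#'
#' @param n_missing,n_eligible Non-negative integer vectors (recycled);
#'   `n_eligible` must be positive.
#' @param decimals 0 or 1.
#' @return Character vector like `"23%"` or `"45.2%"`.
#' @examples
#' format_percent(35, 35, 0)
#' format_percent(11714, 25927, 1)
#' @export
format_percent <- function(n_missing, n_eligible, decimals = 0L) {
  stopifnot(decimals %in% c(0L, 1L))
  args <- vctrs::vec_recycle_common(n_missing = n_missing, n_eligible = n_eligible)
  if (any(args$n_eligible <= 0)) stop("format_percent: n_eligible must be positive")
  if (any(args$n_missing < 0 | args$n_missing > args$n_eligible)) {
    stop("format_percent: n_missing must lie in [0, n_eligible]")
  }
  v <- round_half_up_pct(args$n_missing, args$n_eligible, decimals)
  sprintf(paste0("%.", decimals, "f%%"), v)
}

summarize_groups <- function(trials, statuses, group_var) {
  stopifnot(all(trials$nct_id %in% statuses$nct_id))
  joined <- dplyr::left_join(trials, statuses, by = "nct_id")
  joined$.grp <- joined[[group_var]]
  out <- joined |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(
      sponsor_class = dplyr::first(.data$sponsor_class),
      n_eligible = dplyr::n(),
      n_missing = sum(!.data$reported),
      unreported_enrollment = sum(
        ifelse(!.data$reported, dplyr::coalesce(.data$enrollment, 0L), 0L)),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_missing = 100 * .data$n_missing / .data$n_eligible)
  out
}

#' Per-sponsor audit summaries
#'
#' One row per lead sponsor over the eligible set: eligible count, count
#' missing results, percent missing (exact rational as a double; use
#' [format_percent()] for display), and the total enrollment of the
#' sponsor's unreported trials (missing enrollment counts as 0).
#'
#' @param trials Eligible trial tibble.
#' @param statuses Status tibble from [ascertain_all()] covering every trial.
#' @return Tibble with `sponsor_name`, `sponsor_class`, `n_eligible`,
#'   `n_missing`, `pct_missing`, `unreported_enrollment`, sorted by sponsor
#'   name.
#' @export
summarize_sponsors <- function(trials, statuses) {
  out <- summarize_groups(trials, statuses, "lead_sponsor_name")
  out <- dplyr::rename(out, sponsor_name = ".grp")
  out <- out[order(out$sponsor_name, method = "radix"),
             c("sponsor_name", "sponsor_class", "n_eligible", "n_missing",
               "pct_missing", "unreported_enrollment")]
  tibble::as_tibble(out)
}

#' Per-sponsor-class audit summaries
#'
#' As [summarize_sponsors()] but grouped by the registry's coarse sponsor
#' class (industry, NIH, US Fed, other). Classes with no eligible trials are
#' omitted.
#'
#' @inheritParams summarize_sponsors
#' @return Tibble with `sponsor_class`, `n_eligible`, `n_missing`,
#'   `pct_missing`, `unreported_enrollment`, in the fixed class order.
#' @export
summarize_classes <- function(trials, statuses) {
  out <- summarize_groups(trials, statuses, "sponsor_class")
  out$sponsor_class <- out$.grp
  out <- out[order(match(out$sponsor_class, .sponsor_class_levels)),
             c("sponsor_class", "n_eligible", "n_missing", "pct_missing",
               "unreported_enrollment")]
  tibble::as_tibble(out)
}

#' Rank sponsor summaries
#'
#' Stable sort of sponsor summaries by one of the audit's three ranking
#' keys, ties broken by sponsor name ascending. The default —
#' most unreported trials first — front-loads large, well-known sponsors.
#'
#' @param summaries Tibble from [summarize_sponsors()].
#' @param key `"n_missing"` (default), `"n_eligible"`, or `"pct_missing"`.
#' @param direction `"desc"` (default) or `"asc"`.
#' @return The same tibble, reordered.
#' @export
rank_sponsors <- function(summaries, key = c("n_missing", "n_eligible",
                                             "pct_missing"),
                          direction = c("desc", "asc")) {
  key <- match.arg(key)
  direction <- match.arg(direction)
  metric <- summaries[[key]]
  if (direction == "desc") metric <- -metric
  summaries[order(metric, summaries$sponsor_name, method = "radix"), ]
}

#' Concordance with an external verdict set
#'
#' Cross-tabulates this audit's per-trial verdicts against an external
#' per-trial verdict map (for example a manual publication-bias cohort),
#' over the trials present in both. Reports the four cells and each method's
#' percent-reported over the overlap.
#'
#' @param ours Status tibble from [ascertain_all()] (`nct_id`, `reported`).
#' @param theirs External verdicts: a tibble with `nct_id` and `reported`,
#'   or a named logical vector keyed by `nct_id`.
#' @return An object of class `concordance_table`: the four cells
#'   (`both_reported`, `both_unreported`, `theirs_reported_ours_not`,
#'   `theirs_unreported_ours_reported`), `overlap`, `ours_reported_pct`,
#'   `theirs_reported_pct`.
#' @export
concordance <- function(ours, theirs) {
  if (is.logical(theirs)) {
    theirs <- tibble::tibble(nct_id = names(theirs), reported = unname(theirs))
  }
  ids <- intersect(ours$nct_id, theirs$nct_id)
  if (length(ids) == 0L) stop("concordance: no overlapping trial identifiers")
  o <- ours$reported[match(ids, ours$nct_id)]
  t <- theirs$reported[match(ids, theirs$nct_id)]
  cells <- list(
    both_reported = sum(o & t),
    both_unreported = sum(!o & !t),
    theirs_reported_ours_not = sum(!o & t),
    theirs_unreported_ours_reported = sum(o & !t)
  )
  structure(
    c(cells, list(
      overlap = length(ids),
      ours_reported_pct = 100 * sum(o) / length(ids),
      theirs_reported_pct = 100 * sum(t) / length(ids)
    )),
    class = "concordance_table"
  )
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf(paste0(
    "Concordance over %d overlapping trials\n",
    "  both reported: %d   both unreported: %d\n",
    "  theirs reported / ours not: %d   theirs unreported / ours reported: %d\n",
    "  ours %% reported: %s   theirs %% reported: %s\n"),
    x$overlap, x$both_reported, x$both_unreported,
    x$theirs_reported_ours_not, x$theirs_unreported_ours_reported,
    format_percent(round(x$ours_reported_pct / 100 * x$overlap), x$overlap, 0),
    format_percent(round(x$theirs_reported_pct / 100 * x$overlap), x$overlap, 0)))
  invisible(x)
}
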