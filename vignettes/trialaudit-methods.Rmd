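---
title: "Auditing trial results reporting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing trial results reporting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialaudit)
```

## The problem and the model

Registered clinical trials are expected to make their results available —
either as structured summary results deposited on the registry, or as a
journal publication. A transparency audit asks, for every completed trial:
*can anyone actually find its results?* The unit of analysis is the trial;
the published statistic is the per-sponsor (and per-class) proportion of
eligible trials with no discoverable results.

The audit is a deterministic decision procedure, not a statistical model.
Its two substantive components are an **eligibility cascade** (which trials
are owed results) and a **results-ascertainment rule** (what counts as
discoverable results). Both err deliberately on the side of simple,
reproducible criteria: a trial whose results exist but are not findable by
registry ID is counted unreported, on the view that undiscoverable
reporting is not transparent reporting.

## Dates at month precision

Registry and citation dates are frequently month-only ("June 2010"). The
`partial_date` class stores year, month and optional day, but **all
comparisons are month-granular**: the day is parsed and round-tripped,
never compared. Consequences that follow from this choice:

* "completion more than 24 months ago" is the exact calendar-month
  difference `(y2 - y1) * 12 + (m2 - m1) > 24`, strict because of "more
  than";
* "after Jan 1 2006" becomes *completion ≥ January 2006*, since a
  month-granular date cannot distinguish Jan 1 from Jan 2;
* a publication in the *same month* as trial completion passes the
  "not published before completion" screen ("before" read strictly).

## The eligibility cascade

Filters run in a fixed order — `study_type`, `status`,
`completion_window`, `phase`, `no_disposition` — with every filter
evaluated for every trial (the per-filter trail is part of the output);
excluded trials are attributed to the *first* filter they fail, so failure
counts sum exactly to the number excluded. Missing data fails the filter
that needs it. The corpus-level `sponsor_volume` filter runs last.

Parameters (all in `audit_config()`):

| parameter | default | rationale |
|---|---|---|
| `as_of` | — (required) | the audit's reference month |
| `window_months` | 24 | grace period after completion before results are considered owed |
| `earliest_completion` | 2006-01 | registry-ID citation policy makes earlier linkage unreliable |
| `phase_whitelist` | 2, 2/3, 3, 4, N/A | phase-1 (and mixed 1/2) studies are exploratory; N/A covers device/behavioural trials |
| `min_sponsor_trials` | 30 | rankings are only informative for high-volume sponsors |
| `completion_precedence` | `completion_date` first | see below |

Three decisions here were genuinely open:

* **Completion-field precedence.** When both `completion_date` and
  `primary_completion_date` are present, the overall completion date is
  taken as authoritative and the primary completion date is the fallback.
  The choice is configurable because the opposite convention is defensible
  (primary completion is the outcome-relevant date).
* **The volume threshold is ≥ 30, not > 30.** Published per-sponsor
  rankings of this kind include sponsors with exactly 30 eligible trials,
  so the inclusive reading is used; the threshold is a parameter.
* **Sponsor identity is the exact lead-sponsor string.** No normalization
  of name variants is attempted (a `sponsor_normalizer` hook exists and
  ships as the identity). Name-variant clustering would change sponsor
  counts and therefore volume filtering; it is out of scope.

## Results ascertainment

A trial is **reported** if either route attests results:

1. **Registry results** — the structured-results date tag is present and
   non-empty.
2. **Accepted publication** — some citation carries the trial's `NCT` +
   8-digit identifier (in the secondary-source accession field, or, since
   about 1.5% of records carry it only in the text, in title/abstract) and
   survives three screens: published no earlier than the completion month;
   title not containing the substring "study protocol"; and the validated
   PubMed *therapy* clinical-query filter, which excludes commentary and
   secondary analyses.

The identifier rule is strict: `NCT` followed by *exactly* eight digits
(a nine-digit run matches nothing). A citation matching through both
routes is recorded once, with the secondary-ID route. A citation may serve
as evidence for several trials (multi-arm reports). A trial with no
effective completion date cannot be timing-screened; the screen is marked
`not_evaluated`, treated as a pass, and flagged in the run log.

### Query semantics

The therapy filters are fielded boolean trees evaluated against the local
citation record — there is no live index, so semantics had to be fixed
precisely:

* `[Title/Abstract]` terms match whitespace-delimited, case-insensitive
  tokens with leading/trailing punctuation stripped; `random*` truncation
  is prefix matching on tokens; no stemming.
* `[MeSH]`, `[Publication Type]` and `[Subheading]` terms are
  case-insensitive set membership against the record's own entries — no
  MeSH-tree explosion. This makes the evaluator strictly weaker than a
  live index for hierarchical headings, which is acceptable because the
  broad filter's redundant clauses (tokens *and* types *and* headings)
  keep it sensitive.
* The **broad** (sensitive) variant is the default; the **narrow**
  (specific) variant is selectable. Where the choice between them is
  ambiguous, the audit prefers sensitivity: a false "reported" is the
  conservative error for a tool whose findings name sponsors.

The evaluator is verified in the test suite against an independent
set-theoretic oracle (materialize each term's matching set, combine with
union/intersection) on randomized corpora and random query trees.

## Aggregation and display

Percentages are kept as exact rationals internally. Display rounding is
**round-half-up on the exact rational**, computed in integer arithmetic
(`floor((2·s + den) / (2·den))` with `s = 100·num·10^d`), never via binary
floating point — banker's rounding and float ties would otherwise disagree
with conventional table display on exact halves. Rankings are stable sorts
with alphabetical tie-break on sponsor name; the default key (most missing
trials first) front-loads large sponsors. Missing enrollment counts as
zero in unreported-enrollment sums and is logged. Concordance with an
external cohort is computed over the identifier intersection only.

## The synthetic corpus generator

`generate_fixtures()` emulates the two corpora the audit consumes, with
planted ground truth. Its defaults are the generator's standing study
conditions, chosen once:

* `p_text_only = 0.015` — the observed share of citations carrying a
  registry ID only in title/abstract text;
* `p_registry_results = 0.2` — roughly the observed compliance rate with
  mandatory registry results posting;
* decoy probabilities 0.15 / 0.10 / 0.15 (protocol / pre-completion /
  commentary) — enough decoys that every screen is exercised on any
  moderately sized corpus without dominating it;
* completion dates uniform over 2006-02 … 2014-06 for an as-of month of
  2016-10, so planted-eligible trials are eligible by construction.

Per-sponsor unreported counts are realized **exactly by count**
(round-half-up of rate × n, then sampled *which* trials), so corpus-level
prevalences are exact and worked examples reproduce to the digit; the
per-paper route choice stays Bernoulli so its frequency can be checked
statistically. Decoy titles and types come from small built-in templates
constructed so that exactly one screen rejects each decoy — protocol
papers pass timing and therapy but fail the title screen, pre-completion
papers fail only timing, commentaries fail only the therapy filter. Noise
citations carry nine-digit pseudo-identifiers that must not match. One
seeded RNG stream drives generation: sponsors in profile order, then per
trial its attributes, dissemination draws and decoy draws, then noise
citations; the generator restores the caller's RNG state.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: realistic medical text (therapy-filter
performance on real abstracts is not measured here), results papers that
omit the registry ID entirely (the audit's known false-"unreported" mode),
sponsor name variants, registry amendment histories, and PubMed indexing
latency. Recovery tests demonstrate that the *decision procedure* is
exact, not that the screens have any particular sensitivity/specificity on
real literature.

## Validation problem sizes

The test suite validates ground-truth recovery end-to-end on a generated
corpus of 5,000 planted-eligible trials (50 sponsors) plus ineligible
exemplars and ≈ 20,000 citations, which completes the on-disk load, link
and aggregation in well under a minute; oracle-equivalence runs on
randomized corpora of 200 citations with query trees of depth ≤ 4; the
demonstration corpus used by `scripts/acceptance.R` is a 1/10-scale
registry (2,593 eligible trials across four sponsor classes, about 45%
planted unreported). Determinism is checked byte-for-byte on both the
generator and the audit outputs.

## Degenerate inputs and edge policy

* Duplicate `nct_id` across registry files: the lexicographically first
  file wins; later files are logged (registry snapshots occasionally ship
  amended duplicates; the choice is arbitrary but deterministic).
* Malformed XML or an invalid/missing `nct_id`: the record is rejected and
  logged; the load continues.
* Unknown agency class: mapped to `other` with a warning.
* Duplicate PMIDs in a citation corpus violate its invariant and abort.
* `format_percent()` with zero eligible trials is an error, not `NaN`.
* An audit run with zero eligible trials exits with a diagnosis naming the
  filter report rather than writing an empty feed.

## Known limitations

The audit inherits the limits of ID-based matching: results published
without the registry identifier are invisible (false "unreported"), and a
non-results paper that carries the ID and slips the screens counts as
results (false "reported"). Probabilistic record linkage and citation
back-references from the registry are deliberately excluded — the former
as future work, the latter because such links are frequently erroneous in
practice. Sponsor-level statistics are therefore best read as a
discoverability ranking under a fixed, transparent rule, not as exact
publication rates.
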