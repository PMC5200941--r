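as_of <- partial_date(2016, 10)
cfg <- audit_config(as_of)

test_that("effective completion date prefers completion_date, then falls back", {
  both <- make_trial(completion_date = partial_date(2011, 3),
                     primary_completion_date = partial_date(2012, 7))
  expect_equal(format(effective_completion_date(both)), "2011-03")
  expect_equal(format(effective_completion_date(both, "primary_completion_date")),
               "2012-07")
  only_primary <- make_trial(completion_date = partial_date(NA_integer_, NA_integer_),
                             primary_completion_date = partial_date(2012, 7))
  expect_equal(format(effective_completion_date(only_primary)), "2012-07")
  neither <- make_trial(completion_date = partial_date(NA_integer_, NA_integer_))
  expect_true(is.na(effective_completion_date(neither)))
  expect_equal(check_trials(neither, cfg)$first_failing, "completion_window")
})

test_that("the filter cascade implements the inclusion rules", {
  ok <- check_trial(make_trial(completion_date = partial_date(2010, 6)), as_of)
  expect_true(ok$eligible)
  expect_true(is.na(ok$first_failing))

  cases <- list(
    list(trial = make_trial(study_type = "Observational"), fails = "study_type"),
    list(trial = make_trial(overall_status = "Recruiting"), fails = "status"),
    # 21 months before as_of: inside the 24-month embargo window
    list(trial = make_trial(completion_date = partial_date(2015, 1)),
         fails = "completion_window"),
    # exactly 24 months: "more than 24" is strict
    list(trial = make_trial(completion_date = partial_date(2014, 10)),
         fails = "completion_window"),
    list(trial = make_trial(completion_date = partial_date(2005, 12)),
         fails = "completion_window"),
    list(trial = make_trial(phase = "Phase 1"), fails = "phase"),
    list(trial = make_trial(phase = "Phase 1/Phase 2"), fails = "phase"),
    list(trial = make_trial(has_results_disposition = TRUE),
         fails = "no_disposition")
  )
  for (cs in cases) {
    dec <- check_trial(cs$trial, as_of)
    expect_false(dec$eligible)
    expect_equal(dec$first_failing, cs$fails)
  }
  # boundary passes: January 2006 completion, 25 months before as_of
  expect_true(check_trial(make_trial(completion_date = partial_date(2006, 1)),
                          as_of)$eligible)
  expect_true(check_trial(make_trial(completion_date = partial_date(2014, 9)),
                          as_of)$eligible)
  expect_true(check_trial(make_trial(phase = "N/A"), as_of)$eligible)
})

test_that("first_failing attributes each trial to the first failed filter", {
  t <- make_trial(study_type = "Observational", overall_status = "Recruiting",
                  phase = "Phase 1")
  expect_equal(check_trial(t, as_of)$first_failing, "study_type")
})

test_that("sponsor-volume filter keeps >=min_trials sponsors and reports counts", {
  trials <- dplyr::bind_rows(
    lapply(1:30, function(i) make_trial(sprintf("NCT%08d", i),
                                        lead_sponsor_name = "Big Sponsor")),
    lapply(31:59, function(i) make_trial(sprintf("NCT%08d", i),
                                         lead_sponsor_name = "Mid Sponsor")),
    make_trial("NCT00000099", lead_sponsor_name = "Big Sponsor",
               study_type = "Observational")
  )
  dec <- check_trials(trials, cfg)
  out <- filter_sponsors(dec, trials, min_trials = 30)
  # a sponsor with exactly 30 eligible trials is retained; 29 is not
  expect_setequal(unique(out$eligible$lead_sponsor_name), "Big Sponsor")
  expect_equal(out$report$n_eligible, 30L)
  expect_equal(unname(out$report$counts["sponsor_volume"]), 29L)
  expect_equal(unname(out$report$counts["study_type"]), 1L)
  expect_equal(out$report$n_input - out$report$n_eligible,
               sum(out$report$counts))

  # degenerate threshold: nobody is dropped for volume
  out1 <- filter_sponsors(dec, trials, min_trials = 1)
  expect_equal(out1$report$n_eligible, 59L)
  expect_equal(unname(out1$report$counts["sponsor_volume"]), 0L)
})

test_that("eligibility is monotone in the sponsor threshold and nested in filters", {
  fx <- generate_fixtures(fixture_spec(list(
    sponsor_profile("S40", "industry", 40, unreported_rate = 0.5),
    sponsor_profile("S31", "other", 31, unreported_rate = 0.2),
    sponsor_profile("S12", "NIH", 12, unreported_rate = 0.5)
  ), seed = 3), withr::local_tempdir())
  dec <- check_trials(fx$trials, cfg)
  sets <- lapply(c(1, 12, 31, 32, 40, 41), function(k) {
    filter_sponsors(dec, fx$trials, min_trials = k)$eligible$nct_id
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
  # the eligible set is a subset of every per-filter pass set
  elig <- filter_sponsors(dec, fx$trials, min_trials = 30)$eligible$nct_id
  for (f in c("study_type", "status", "completion_window", "phase",
              "no_disposition")) {
    expect_true(all(elig %in% dec$nct_id[dec[[f]] == "pass"]))
  }
})

test_that("decisions and counts are invariant to corpus order", {
  fx <- generate_fixtures(fixture_spec(list(
    sponsor_profile("A", "industry", 35, unreported_rate = 0.3),
    sponsor_profile("B", "other", 33, unreported_rate = 0.6)
  ), seed = 9), withr::local_tempdir())
  dec1 <- check_trials(fx$trials, cfg)
  perm <- sample(nrow(fx$trials))
  dec2 <- check_trials(fx$trials[perm, ], cfg)
  expect_equal(dec2[order(dec2$nct_id), ], dec1[order(dec1$nct_id), ])
  r1 <- filter_sponsors(dec1, fx$trials, 30)$report
  r2 <- filter_sponsors(dec2, fx$trials[perm, ], 30)$report
  expect_equal(r1$counts, r2$counts)
  expect_equal(r1$n_eligible, r2$n_eligible)
})

test_that("cascade decisions agree with a brute-force re-evaluation", {
  fx <- generate_fixtures(fixture_spec(list(
    sponsor_profile("A", "industry", 45, unreported_rate = 0.4),
    sponsor_profile("B", "other", 40, unreported_rate = 0.7)
  ), seed = 21), withr::local_tempdir())
  dec <- check_trials(fx$trials, cfg)
  for (i in seq_len(nrow(fx$trials))) {
    expected <- oracle_trial_eligible(fx$trials[i, ], 2016, 10)
    expect_equal(dec$eligible[i], expected$eligible)
    expect_equal(dec$first_failing[i], expected$first_failing)
  }
})
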