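test_that("SOE grades map to ordinal scores losslessly", {
  grades <- c("insufficient", "low", "moderate", "high")
  expect_identical(soe_score(grades), 1:4)
  expect_identical(soe_grade_from_score(soe_score(grades)), grades)
  expect_error(soe_score("very high"), "unknown SOE grade")
})

test_that("dataset construction enforces the flag and identity invariants", {
  expect_s3_class(toy_dataset(), "case_dataset")

  # duplicate case id
  expect_error(
    case_dataset(rbind(toy_case_row("a"), toy_case_row("a")),
                 toy_obs_row("a", "walk"), toy_outcomes()),
    "duplicate case_id")
  # unknown outcome
  expect_error(
    case_dataset(toy_case_row("a"), toy_obs_row("a", "nonesuch"),
                 toy_outcomes()),
    "unknown outcome_id")
  # duplicate (case, outcome)
  expect_error(
    case_dataset(toy_case_row("a"),
                 rbind(toy_obs_row("a", "walk"), toy_obs_row("a", "walk")),
                 toy_outcomes()),
    "duplicate \\(case_id, outcome_id\\)")
  # unreported observation with a positive flag
  expect_error(
    case_dataset(toy_case_row("a"),
                 toy_obs_row("a", "walk", reported = FALSE, mention = TRUE),
                 toy_outcomes()),
    "unreported observation")
  # dose-change flag on a benefit outcome
  expect_error(
    case_dataset(toy_case_row("a"),
                 toy_obs_row("a", "walk", irr = TRUE), toy_outcomes()),
    "irr_dose_change")
})

test_that("CSV round-trip reproduces every field and flag exactly", {
  ds <- toy_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  opath <- withr::local_tempfile(fileext = ".json")
  write_case_dataset(ds, path, outcomes_path = opath)
  back <- read_case_dataset(path, opath, provenance = ds$provenance)
  o1 <- ds$observations[order(ds$observations$case_id,
                              ds$observations$outcome_id), ]
  o2 <- back$observations[order(back$observations$case_id,
                                back$observations$outcome_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o2, o1)
  c1 <- ds$cases[order(ds$cases$case_id), ]
  c2 <- back$cases[order(back$cases$case_id), ]
  rownames(c1) <- rownames(c2) <- NULL
  expect_identical(c2, c1)
  expect_identical(back$outcomes, ds$outcomes)
})

test_that("reader reports schema and integrity errors by name", {
  ds <- toy_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_case_dataset(ds, path)

  raw <- read.csv(path, stringsAsFactors = FALSE)
  broken <- raw[, setdiff(names(raw), "reported")]
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken, p2, row.names = FALSE)
  expect_error(read_case_dataset(p2, toy_outcomes()), "reported")

  # empty file with a valid header is a legal zero-case dataset
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw[0, ], p3, row.names = FALSE)
  expect_equal(n_cases(read_case_dataset(p3, toy_outcomes())), 0)

  expect_error(read_case_dataset("no/such/file.csv", toy_outcomes()),
               "not found")
})

test_that("analysis-set filters compose conjunctively and are idempotent", {
  ds <- toy_dataset()
  # empty spec without the aggregated filter keeps everything
  keep_all <- analysis_set_spec("identity", exclude_aggregated = FALSE)
  expect_equal(n_cases(apply_analysis_set(ds, keep_all)), n_cases(ds))

  spec <- analysis_set_spec("combo", date_cutoff = "2015-12-31",
                            exclude_congress = TRUE, exclude_overlap = TRUE)
  once <- apply_analysis_set(ds, spec)
  twice <- apply_analysis_set(once, spec)
  expect_identical(twice$cases$case_id, once$cases$case_id)
  expect_lte(n_cases(once), n_cases(ds))
  # conjunction equals sequential application of the single filters
  seq_appl <- apply_analysis_set(
    apply_analysis_set(
      apply_analysis_set(ds, analysis_set_spec("d", date_cutoff = "2015-12-31")),
      analysis_set_spec("c", exclude_congress = TRUE)),
    analysis_set_spec("o", exclude_overlap = TRUE))
  expect_setequal(seq_appl$cases$case_id, once$cases$case_id)
  expect_identical(once$cases$case_id, "a")
})

test_that("packaged corpus reproduces the published case marginals", {
  ds <- mpsii_corpus()
  expect_equal(n_cases(ds), 56)

  prim <- apply_analysis_set(ds, analysis_set_spec("primary"))
  expect_equal(n_cases(prim), 44)
  expect_equal(n_publications(prim), 25)

  noc <- apply_analysis_set(ds, analysis_set_spec("no_congress"))
  expect_equal(n_cases(noc), 36)
  expect_equal(n_publications(noc), 21)

  nov <- apply_analysis_set(ds, analysis_set_spec("no_overlap"))
  expect_equal(n_cases(nov), 33)
  expect_equal(n_publications(nov), 22)

  expect_equal(count_positives(prim, "strong")$k,
               table1_counts()$k)
  expect_equal(count_positives(prim, "weak")$k,
               table2_counts()$k)
})
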