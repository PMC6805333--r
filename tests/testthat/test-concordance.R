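test_that("confusion table follows the acceptable-vs-moderate polarity", {
  outc <- mpsii_outcomes()
  ev <- classify_evidence(table1_counts())
  ct <- confusion_from_classification(ev, outc)
  expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")]),
               c(tp = 3L, fp = 0L, fn = 0L, tn = 8L))

  ev2 <- classify_evidence(table2_counts())
  ct2 <- confusion_from_classification(ev2, outc)
  expect_equal(unlist(ct2[c("tp", "fp", "fn", "tn")]),
               c(tp = 3L, fp = 2L, fn = 0L, tn = 6L))

  empty <- confusion_from_classification(ev[0, ], outc)
  expect_equal(empty$tp + empty$fp + empty$fn + empty$tn, 0L)

  expect_error(
    confusion_from_classification(
      data.frame(outcome_id = "mystery", group = "acceptable"), outc),
    "mystery")
})

test_that("Clopper-Pearson interval matches closed forms and binom.test", {
  ci <- clopper_pearson_interval(3, 3)
  expect_equal(round(ci[["lower"]], 3), 0.292)
  expect_equal(ci[["lower"]], 0.025^(1 / 3), tolerance = 1e-10)
  expect_equal(ci[["upper"]], 1)

  ci <- clopper_pearson_interval(8, 8)
  expect_equal(round(ci[["lower"]], 3), 0.631)
  expect_equal(ci[["lower"]], 0.025^(1 / 8), tolerance = 1e-10)

  expect_equal(clopper_pearson_interval(0, 10)[["lower"]], 0)

  # independent oracle on a non-degenerate case
  bt <- binom.test(7, 19)$conf.int
  ci <- clopper_pearson_interval(7, 19)
  expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-10)

  # nesting: the 99% interval contains the 95% interval
  for (x in c(1, 5, 9)) {
    i95 <- clopper_pearson_interval(x, 10, 0.95)
    i99 <- clopper_pearson_interval(x, 10, 0.99)
    expect_lte(i99[["lower"]], i95[["lower"]])
    expect_gte(i99[["upper"]], i95[["upper"]])
  }

  expect_true(all(is.na(clopper_pearson_interval(0, 0))))
})

test_that("validity indices reproduce the published 2x2 summaries", {
  perfect <- structure(list(tp = 3L, fp = 0L, fn = 0L, tn = 8L),
                       class = "confusion_table")
  v <- validity_indices(perfect)
  expect_true(all(v$estimate == 1))
  expect_equal(round(v$lower[v$index == "sensitivity"], 2), 0.29)
  expect_equal(round(v$lower[v$index == "specificity"], 2), 0.63)

  noc <- structure(list(tp = 2L, fp = 0L, fn = 1L, tn = 8L),
                   class = "confusion_table")
  v <- validity_indices(noc)
  est <- setNames(percent(v$estimate), v$index)
  expect_equal(est, c(sensitivity = 67L, specificity = 100L, ppv = 100L,
                      npv = 89L, accuracy = 91L))

  nopos <- structure(list(tp = 0L, fp = 0L, fn = 0L, tn = 5L),
                     class = "confusion_table")
  v <- validity_indices(nopos)
  expect_true(all(is.na(v$estimate[v$index %in% c("sensitivity", "ppv")])))
  expect_true(all(v$estimate[v$index %in%
                               c("specificity", "npv", "accuracy")] == 1))

  zero <- structure(list(tp = 0L, fp = 0L, fn = 0L, tn = 0L),
                    class = "confusion_table")
  expect_error(validity_indices(zero), "all-zero")
})

test_that("midranks average tie positions and sum to n(n+1)/2", {
  expect_equal(midrank(c(0, 0, 0, 1)), c(2, 2, 2, 4))
  expect_equal(midrank(c(20, 8, 6, 4, 4, 3, 2, 1, 0, 0, 0)),
               c(11, 10, 9, 7.5, 7.5, 6, 5, 4, 2, 2, 2))
  x <- c(5, 1, 4, 2, 3)
  expect_equal(midrank(x), order(order(x)))
  expect_equal(sum(midrank(runif(20) > 0.5)), 20 * 21 / 2)
})

test_that("tie-corrected Spearman reproduces the published agreement", {
  counts <- c(20, 8, 6, 4, 4, 3, 2, 1, 0, 0, 0)
  soe <- c(3, 3, 3, 2, 1, 2, 2, 2, 1, 1, 1)
  rho <- spearman_midrank(counts, soe)
  expect_equal(round(rho, 2), 0.82)
  # cross-check against the standard tie-corrected implementation
  expect_equal(rho, cor(counts, soe, method = "spearman"), tolerance = 1e-12)

  expect_equal(spearman_midrank(1:7, 1:7), 1)
  expect_equal(spearman_midrank(1:7, 7:1), -1)
  expect_true(is.na(spearman_midrank(rep(1, 5), 1:5)))

  # no ties: equals the classical shortcut formula
  set.seed(42)
  for (i in 1:10) {
    x <- sample(100, 12)
    y <- sample(100, 12)
    d <- rank(x) - rank(y)
    shortcut <- 1 - 6 * sum(d^2) / (12 * (12^2 - 1))
    expect_equal(spearman_midrank(x, y), shortcut, tolerance = 1e-12)
  }

  # invariance under strictly monotone transforms
  x <- c(0, 1, 1, 3, 7, 7, 10)
  y <- c(2, 2, 5, 4, 9, 11, 11)
  expect_equal(spearman_midrank(exp(x), y), spearman_midrank(x, y))
  expect_equal(spearman_midrank(x, 3 * y + 1), spearman_midrank(x, y))
})

test_that("Fisher-z interval reproduces the published bounds and stays inside (-1,1)", {
  counts <- c(20, 8, 6, 4, 4, 3, 2, 1, 0, 0, 0)
  soe <- c(3, 3, 3, 2, 1, 2, 2, 2, 1, 1, 1)
  ci <- fisher_z_interval(spearman_midrank(counts, soe), 11)
  expect_equal(round(unname(ci), 2), c(0.43, 0.95))

  ci0 <- fisher_z_interval(0, 100)
  expect_equal(ci0[["lower"]], -ci0[["upper"]])

  ci <- fisher_z_interval(0.9, 5)
  expect_lt(ci[["lower"]], 0.9)
  expect_gt(ci[["upper"]], 0.9)
  expect_true(all(abs(ci) < 1))

  expect_true(all(is.na(fisher_z_interval(1, 10))))
  expect_true(all(is.na(fisher_z_interval(0.5, 3))))
})

test_that("agreement_with_gold wires counts, grades and the scatter export", {
  prim <- apply_analysis_set(mpsii_corpus(), analysis_set_spec("primary"))
  ag <- agreement_with_gold(count_positives(prim, "strong"), prim$outcomes)
  expect_equal(round(ag$rho, 2), 0.82)
  expect_equal(ag$n, 11)
  expect_equal(nrow(ag$scatter), 11)
  expect_true(all(ag$scatter$soe_score %in% 1:3))
})
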