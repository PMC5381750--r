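test_that("change datasets follow the 2x2 design counting rules", {
  feats <- toy_features(n_subjects = 14)
  ds <- build_change_datasets(feats)
  expect_named(ds, c("repetition1", "repetition2"))
  for (d in ds) {
    expect_equal(sum(d$label == "positive"), 14L)
    expect_equal(sum(d$label == "negative"), 28L)
  }
  # the two datasets share their negative samples
  n1 <- ds$repetition1[ds$repetition1$label == "negative", ]
  n2 <- ds$repetition2[ds$repetition2$label == "negative", ]
  expect_equal(n1$d_peak, n2$d_peak)
  expect_equal(n1$subject, n2$subject)
  # but differ in their positives
  p1 <- ds$repetition1[ds$repetition1$label == "positive", ]
  p2 <- ds$repetition2[ds$repetition2$label == "positive", ]
  expect_false(isTRUE(all.equal(p1$d_peak, p2$d_peak)))
})

test_that("incomplete subjects are skipped; tiny cohorts error", {
  feats <- toy_features(n_subjects = 3)
  feats <- feats[!(feats$subject == "S2" & feats$state == "rested" &
                     feats$repetition == 2), ]
  expect_warning(ds <- build_change_datasets(feats), "S2")
  expect_equal(sort(unique(ds$repetition1$subject)), c("S1", "S3"))
  expect_equal(sum(ds$repetition1$label == "positive"), 2L)

  one <- toy_features(n_subjects = 1)
  expect_error(build_change_datasets(one), "at least 2")
})

test_that("delta columns agree with direct subtraction of the feature table", {
  feats <- toy_features(n_subjects = 2)
  ds <- build_change_datasets(feats, selfsim_orientation = -1,
                              angle_peak_scale = 25)
  g <- function(s, st, r) feats[feats$subject == s & feats$state == st &
                                  feats$repetition == r, ]
  pos1 <- ds$repetition1[ds$repetition1$label == "positive" &
                           ds$repetition1$subject == "S1", ]
  expect_equal(pos1$d_peak,
               g("S1", "sleep_inertia", 1)$khte_peak -
                 g("S1", "rested", 1)$khte_peak)
  expect_equal(pos1$d_median_ht,
               g("S1", "sleep_inertia", 1)$median_ht -
                 g("S1", "rested", 1)$median_ht)
  expect_equal(pos1$angle, atan2(-pos1$d_selfsim, pos1$d_peak / 25))
})

test_that("perfectly separated deltas give AUC 1 under subject hold-out", {
  withr::local_seed(27)
  n_sub <- 6
  ds <- do.call(rbind, lapply(seq_len(n_sub), function(s) data.frame(
    subject = sprintf("S%d", s),
    label = c("positive", "negative", "negative"),
    d_peak = c(10, -10, -12) + rnorm(3, 0, 0.5),
    d_selfsim = c(0.5, -0.5, -0.4) + rnorm(3, 0, 0.02)
  )))
  roc <- loo_svm_evaluate(ds)
  expect_equal(roc$auc, 1.0)
  expect_equal(sort(unique(roc$fold_assignments)),
               sort(unique(ds$subject)))
})

test_that("hold-one-subject-out never trains on the held-out subject", {
  # audited by construction: every sample's fold is its own subject,
  # so the training set for that fold excludes all of the subject's rows
  feats <- toy_features(n_subjects = 5, seed = 9)
  ds <- build_change_datasets(feats)$repetition1
  roc <- loo_svm_evaluate(ds)
  expect_identical(roc$fold_assignments, as.character(ds$subject))
  expect_equal(roc$loo_unit, "subject")
  # sample-level hold-out is available behind the flag
  roc_s <- loo_svm_evaluate(ds, loo_unit = "sample")
  expect_equal(length(unique(roc_s$fold_assignments)), nrow(ds))
})

test_that("a fold losing one class entirely is a named error", {
  ds <- data.frame(subject = c("A", "A", "B"),
                   label = c("negative", "negative", "positive"),
                   d_peak = rnorm(3), d_selfsim = rnorm(3))
  expect_error(loo_svm_evaluate(ds), "A.*lost one class")
})

test_that("pooled-score AUC equals the rank-statistic oracle", {
  withr::local_seed(31)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    s <- sample(round(rnorm(n), 2))  # ties likely
    auc <- roc_curve(s, pos)$auc
    w <- stats::wilcox.test(s[pos], s[!pos], exact = FALSE)
    expect_equal(auc, unname(w$statistic) / (sum(pos) * sum(!pos)))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::local_seed(17)
  s <- rnorm(30); pos <- rep(c(TRUE, FALSE), 15)
  a <- roc_curve(s, pos)$auc
  expect_equal(roc_curve(exp(s), pos)$auc, a)
  expect_equal(roc_curve(2 * s + 7, pos)$auc, a)
  expect_equal(roc_curve(atan(s), pos)$auc, a)
})

test_that("stump AUC picks the best orientation and handles degeneracy", {
  r <- stump_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1.0)
  expect_equal(r$orientation, 1)

  r2 <- stump_auc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 1.0)
  expect_equal(r2$orientation, -1)

  r3 <- stump_auc(rep(5, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(r3$auc, 0.5)
  expect_true(r3$degenerate)
})

test_that("stump AUC equals exhaustive threshold enumeration", {
  withr::local_seed(23)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    v <- sample(round(runif(n, 0, 5), 1))
    orc <- max(oracle_sweep_auc(v, pos), oracle_sweep_auc(-v, pos))
    expect_equal(stump_auc(v, pos)$auc, orc)
  }
})

test_that("our ROC/AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(41)
  for (i in 1:10) {
    n <- 40
    pos <- rep(c(TRUE, FALSE), each = n / 2)
    s <- rnorm(n) + pos
    ours <- roc_curve(s, pos)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(pos, s))))
    expect_equal(ours, ref)
  }
})
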