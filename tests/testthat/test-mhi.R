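test_that("MHI score is the stabilized biomarker abundance ratio", {
  wx <- worked_example_fixture()
  sc <- mhi_score(wx$table, wx$biomarkers)
  # sample WX1: numerator 0.40 + 0.30, denominator 0.05 + 0.05
  expect_equal(sc$numerator[1], 0.70)
  expect_equal(sc$denominator[1], 0.10)
  expect_equal(sc$score[1], (0.70 + 1e-6) / (0.10 + 1e-6), tolerance = 1e-12)
  expect_true(all(sc$score > 0 & is.finite(sc$score)))
  expect_true(all(sc$score[wx$labels == "ICU_E1"] > 1))
  expect_true(all(sc$score[wx$labels == "ICU_E2"] < 1))

  # all ten biomarkers absent: score pinned at exactly 1 by the stabilizer
  other <- abundance_table(matrix(c(0.6, 0.4), 1, dimnames = list("z", NULL)),
                           c("Bacteria;P;C;O;F;Ga", "Bacteria;P;C;O;F;Gb"),
                           mode = "relative")
  expect_equal(mhi_score(other, wx$biomarkers)$score, 1)
})

test_that("doubling numerator-marker mass strictly increases the score", {
  wx <- worked_example_fixture()
  counts <- round(wx$table$values * 1000)
  tab <- abundance_table(counts, wx$table$lineages, mode = "counts")
  sc0 <- mhi_score(to_relative(tab), wx$biomarkers)
  boosted <- counts
  boosted[, c("Bacteroides", "Enterobacteriaceae*")] <-
    boosted[, c("Bacteroides", "Enterobacteriaceae*")] * 2
  tab2 <- abundance_table(boosted, wx$table$lineages, mode = "counts")
  sc1 <- mhi_score(to_relative(tab2), wx$biomarkers)
  expect_true(all(sc1$score > sc0$score))
})

test_that("threshold training matches the brute-force grid sweep", {
  sep_scores <- c(2, 3, 4, 0.1, 0.2)
  sep_labels <- factor(c("ICU_E1", "ICU_E1", "ICU_E1", "ICU_E2", "ICU_E2"))
  clf <- mhi_train(sep_scores, sep_labels)
  expect_equal(clf$youden_j, 1)
  expect_equal(clf$train_sensitivity, 1)
  expect_equal(clf$train_specificity, 1)
  expect_gte(clf$threshold, min(sep_scores))
  expect_lte(clf$threshold, max(sep_scores))

  set.seed(13)
  sc <- runif(20, 0.5, 3)
  y <- factor(rep(c("ICU_E1", "ICU_E2"), 10))
  clf2 <- mhi_train(sc, y)
  # independent loop over all 1001 grid points
  grid <- min(sc) + (max(sc) - min(sc)) * (0:1000) / 1000
  best_j <- -Inf; best_t <- NA
  for (t in grid) {
    sens <- mean(sc[y == "ICU_E1"] > t)
    spec <- mean(sc[y == "ICU_E2"] <= t)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  expect_equal(clf2$threshold, best_t, tolerance = 1e-12)
  expect_equal(clf2$youden_j, best_j, tolerance = 1e-12)

  expect_error(mhi_train(rep(1, 5), factor(rep(c("ICU_E1", "ICU_E2"), c(3, 2)))),
               "zero score range")
  expect_error(mhi_train(1:5, factor(rep("ICU_E1", 5))), "both classes")
})

test_that("classification boundary: at-threshold goes to E2, just above to E1", {
  clf <- mhi_train(c(2, 3, 0.5, 0.6), factor(c("ICU_E1", "ICU_E1", "ICU_E2", "ICU_E2")))
  t0 <- clf$threshold
  calls <- predict(clf, c(at = t0, above = t0 + 1e-9, below = t0 - 1e-9))
  expect_equal(as.character(calls), c("ICU_E2", "ICU_E1", "ICU_E2"))
})

test_that("AUC equals the pairwise loop, respects invariances, and nulls at 0.5", {
  perf <- roc_auc(c(5, 6, 7, 1, 2), factor(c("ICU_E1", "ICU_E1", "ICU_E1",
                                             "ICU_E2", "ICU_E2")), n_boot = 99)
  expect_equal(perf$auc, 1)
  expect_true(perf$ci_low <= perf$auc && perf$auc <= perf$ci_high)

  for (seed in 1:10) {
    set.seed(seed)
    sc <- sample(round(runif(14, 0, 5), 1))  # duplicates force tie handling
    y <- factor(rep(c("ICU_E1", "ICU_E2"), 7))
    a <- roc_auc(sc, y, n_boot = 19, seed = seed)$auc
    expect_equal(a, oracle_auc(sc, y == "ICU_E1"), tolerance = 1e-12)
    expect_equal(roc_auc(exp(sc), y, n_boot = 19)$auc, a, tolerance = 1e-12)
  }

  set.seed(31)
  null_scores <- matrix(rnorm(60 * 30), 60)
  null_auc <- apply(null_scores, 1, function(sc)
    roc_auc(sc, factor(rep(c("ICU_E1", "ICU_E2"), 15)), n_boot = 19)$auc)
  se <- sd(null_auc) / sqrt(length(null_auc))
  expect_lt(abs(mean(null_auc) - 0.5), 3 * se + 0.02)
})

test_that("AUC point estimate agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(17)
  sc <- runif(40)
  y <- factor(rep(c("ICU_E1", "ICU_E2"), 20))
  ours <- roc_auc(sc, y, n_boot = 19)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = sc, levels = c("ICU_E2", "ICU_E1"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("split evaluation is stratified, disjoint, deterministic and accurate", {
  coh <- generate_cohort(cohort_config(), seed = 12)
  genus <- aggregate_to_rank(to_relative(coh$abundance), "genus")
  y <- factor(coh$truth$enterotype)
  names(y) <- coh$truth$sample_id
  bm <- build_biomarker_set(genus, y, seed = 3)
  ev <- mhi_evaluate(genus, y, bm, seed = 5, n_boot = 199)
  expect_length(intersect(ev$train_ids, ev$test_ids), 0)
  expect_setequal(c(ev$train_ids, ev$test_ids), coh$truth$sample_id)
  expect_equal(length(ev$train_ids), 105)  # 80% of 131, stratified
  expect_gte(ev$report$auc[ev$report$set == "testing"], 0.9)
  expect_true(all(ev$report$f1 >= 0 & ev$report$f1 <= 1))
  expect_true(all(ev$report$ci_low <= ev$report$auc &
                    ev$report$auc <= ev$report$ci_high))

  ev2 <- mhi_evaluate(genus, y, bm, seed = 5, n_boot = 199)
  expect_identical(ev$report, ev2$report)
  expect_identical(ev$classifier$threshold, ev2$classifier$threshold)
})

test_that("classifier JSON round-trips and reproduces calls", {
  wx <- worked_example_fixture()
  sc <- mhi_score(wx$table, wx$biomarkers)
  clf <- mhi_train(sc, wx$labels, biomarkers = wx$biomarkers)
  f <- withr::local_tempfile(fileext = ".json")
  write_mhi_classifier(clf, f)
  back <- read_mhi_classifier(f)
  expect_equal(back$threshold, clf$threshold)
  expect_equal(predict(back, wx$table), predict(clf, sc))
})
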