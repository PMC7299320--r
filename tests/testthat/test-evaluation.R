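scores_df <- function(pos, neg) {
  as_cv_scores(data.frame(
    patient_id = sprintf("P%03d", seq_len(length(pos) + length(neg))),
    label = c(rep("positive", length(pos)), rep("negative", length(neg))),
    score = c(pos, neg), fold = seq_len(length(pos) + length(neg)),
    stringsAsFactors = FALSE))
}

test_that("AUC equals the tie-corrected pair-counting statistic", {
  expect_equal(roc_auc(scores_df(c(0.9, 0.8), c(0.3, 0.2)))$auc, 1)
  expect_equal(roc_auc(scores_df(rep(0.5, 5), rep(0.5, 4)))$auc, 0.5)
  expect_equal(roc_auc(scores_df(c(0.8, 0.4), c(0.6, 0.2)))$auc, 0.75)
  for (s in 1:100) {
    withr::with_seed(2000 + s, {
      pos <- sample(1:6, 8, replace = TRUE)   # heavy ties
      neg <- sample(1:6, 6, replace = TRUE)
    })
    expect_equal(roc_auc(scores_df(pos, neg))$auc, oracle_auc(pos, neg))
  }
})

test_that("the ROC curve is a monotone staircase from (0,0) to (1,1)", {
  sc <- sim_scores(20, 15, 0.75, seed = 21)
  r <- roc_auc(sc)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
})

test_that("ROC analysis is invariant under strictly increasing score transforms", {
  sc <- sim_scores(30, 25, 0.8, seed = 22)
  sc2 <- sc; sc2$score <- exp(3 * sc$score)
  r1 <- roc_auc(sc); r2 <- roc_auc(sc2)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$se_delong, r2$se_delong)
  expect_equal(r1$curve[c("fpr", "tpr")], r2$curve[c("fpr", "tpr")])
})

test_that("DeLong variance matches bootstrap and the pROC reference", {
  sc <- sim_scores(52, 40, 0.8, seed = 23)
  r <- roc_auc(sc)
  pos <- sc$score[sc$label == "positive"]
  neg <- sc$score[sc$label == "negative"]
  boot <- withr::with_seed(24, vapply(1:2000, function(i) {
    oracle_auc(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
  }, numeric(1)))
  expect_lt(abs(r$se_delong^2 - var(boot)) / var(boot), 0.15)
  ref <- pROC::roc(response = sc$label, predictor = sc$score,
                   levels = c("negative", "positive"), direction = "<",
                   quiet = TRUE)
  expect_equal(r$auc, as.numeric(ref$auc), tolerance = 1e-12)
  expect_equal(r$se_delong^2, as.numeric(pROC::var(ref, method = "delong")),
               tolerance = 1e-10)
})

test_that("paired AUC comparison matches pROC, is antisymmetric, and null on self", {
  a <- sim_scores(40, 35, 0.85, seed = 25)
  b <- a
  withr::with_seed(26, b$score <- 0.7 * a$score + rnorm(75, sd = 0.8))
  self <- compare_auc(a, a)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)
  cmp <- compare_auc(a, b)
  rev <- compare_auc(b, a)
  expect_equal(cmp$z, -rev$z)
  expect_equal(cmp$p_value, rev$p_value)
  expect_equal(sign(cmp$z), sign(cmp$auc_a - cmp$auc_b))
  ra <- pROC::roc(a$label, a$score, levels = c("negative", "positive"),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(b$label, b$score, levels = c("negative", "positive"),
                  direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(abs(cmp$z), abs(as.numeric(ref$statistic)), tolerance = 1e-10)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-10)
  # patient mismatch is rejected for paired comparisons
  b2 <- b; b2$patient_id[1] <- "other"
  expect_error(compare_auc(a, b2), "identical patients")
})

test_that("clearly different classifiers are almost always distinguished", {
  hits <- vapply(1:20, function(s) {
    good <- sim_scores(52, 40, 0.9, seed = 2700 + s)
    null <- good
    null$score <- withr::with_seed(2800 + s, rnorm(92))
    compare_auc(good, null)$p_value < 0.05
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("the Youden operating point reproduces known confusion counts", {
  perfect <- operating_point(scores_df(c(0.9, 0.8), c(0.3, 0.2)))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  # constructed cohort: TP 42, FN 10, TN 34, FP 6
  sc <- scores_df(c(rep(1, 42), rep(0, 10)), c(rep(1, 6), rep(0, 34)))
  op <- operating_point(sc)
  expect_equal(op$tp, 42); expect_equal(op$fn, 10)
  expect_equal(op$tn, 34); expect_equal(op$fp, 6)
  expect_equal(round(100 * op$sensitivity, 2), 80.77)
  expect_equal(round(100 * op$specificity, 2), 85.00)
  expect_equal(round(100 * op$accuracy, 2), 82.61)
  # all-tied scores: everything is called positive at the single threshold
  tied <- operating_point(scores_df(rep(1, 5), rep(1, 3)))
  expect_equal(tied$sensitivity, 1)
  expect_equal(tied$specificity, 0)
  expect_equal(tied$accuracy, 5 / 8)
})

test_that("the evaluation report has the phase-by-classifier structure", {
  sets <- list()
  for (ph in c("pre", "post", "subtraction"))
    for (cl in c("lra", "qda", "svm"))
      sets[[paste(ph, cl, sep = "_")]] <-
        as_cv_scores(sim_scores(15, 12, 0.8,
                                seed = nchar(ph) * 100 + nchar(cl)),
                     classifier = cl, phase = ph)
  rep1 <- run_report(sets)
  expect_equal(nrow(rep1$performance), 9)
  expect_named(rep1$comparisons, c("pre", "post", "subtraction"))
  m <- rep1$comparisons$subtraction
  expect_equal(dim(m), c(3, 3))
  expect_true(all(is.na(diag(m))))
  expect_equal(m[1, 2], m[2, 1])       # symmetric p-values
  rep2 <- run_report(sets)
  expect_identical(rep1, rep2)         # regeneration is deterministic
})
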