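#' @keywords internal
# DeLong structural components of an empirical AUC.
# v10[i]: placement of positive i among negatives; v01[j]: converse.
delong_components <- function(pos, neg) {
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

delong_var <- function(comp) {
  m <- length(comp$v10); n <- length(comp$v01)
  stats::var(comp$v10) / m + stats::var(comp$v01) / n
}

# 95% CI for the AUC treated as a proportion of concordant pairs with an
# effective pair count matched to the DeLong variance (Clopper-Pearson
# with continuous counts); an approximation of a binomial exact interval.
binomial_exact_ci <- function(auc, var_delong, n_pairs, level = 0.95) {
  a <- (1 - level) / 2
  n_eff <- if (is.finite(var_delong) && var_delong > 0)
    auc * (1 - auc) / var_delong else n_pairs
  if (!is.finite(n_eff) || n_eff <= 0) n_eff <- n_pairs
  x <- auc * n_eff
  lo <- if (x <= 0) 0 else stats::qbeta(a, x, n_eff - x + 1)
  hi <- if (x >= n_eff) 1 else stats::qbeta(1 - a, x + 1, n_eff - x)
  c(lo, hi)
}

#' Empirical ROC curve and AUC with DeLong standard error
#'
#' The AUC equals the tie-corrected Mann-Whitney statistic
#' `U / (n_pos * n_neg)` (ties contribute 1/2); its standard error comes
#' from the DeLong structural-components estimator, and the 95% CI from a
#' binomial exact (Clopper-Pearson) construction on an effective number
#' of concordant pairs matched to the DeLong variance.
#'
#' @param scores a `cv_scores` data frame, or any data frame with
#'   columns `score` and `label` (`"positive"`/`"negative"`).
#' @return an object of class `roc_result`: `curve` (data frame of
#'   threshold, fpr, tpr), `auc`, `se_delong`, `ci95`, `n_pos`, `n_neg`,
#'   and the DeLong components.
#' @export
roc_auc <- function(scores) {
  stopifnot(all(c("score", "label") %in% names(scores)))
  if (anyNA(scores$score))
    stop("roc_auc: scores contain missing values")
  pos <- scores$score[scores$label == "positive"]
  neg <- scores$score[scores$label == "negative"]
  if (!length(pos) || !length(neg))
    stop("roc_auc: both classes required")
  thr <- c(Inf, sort(unique(scores$score), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  comp <- delong_components(pos, neg)
  v <- delong_var(comp)
  structure(list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = comp$auc, se_delong = sqrt(v),
                 ci95 = binomial_exact_ci(comp$auc, v,
                                          length(pos) * length(neg)),
                 n_pos = length(pos), n_neg = length(neg),
                 components = comp),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (SE %.3f, 95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$se_delong, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Operating point of a classifier by the Youden index
#'
#' Chooses the threshold maximizing sensitivity + specificity - 1 over
#' all observed scores (a sample is called positive when its score is at
#' or above the threshold); ties prefer the higher specificity.
#'
#' @param scores a `cv_scores` data frame (columns `score`, `label`).
#' @return list with `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
operating_point <- function(scores) {
  pos <- scores$score[scores$label == "positive"]
  neg <- scores$score[scores$label == "negative"]
  thr <- sort(unique(scores$score))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  if (length(best) > 1) best <- best[which.max(spec[best])]
  t <- thr[best]
  tp <- sum(pos >= t); fn <- sum(pos < t)
  tn <- sum(neg < t); fp <- sum(neg >= t)
  list(threshold = t,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(scores$score),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Paired (or unpaired) z-test between two correlated AUCs
#'
#' DeLong covariance of the two AUCs from the shared structural
#' components; `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov)` with a
#' two-sided normal p-value. Paired comparison requires identical patient
#' sets.
#'
#' @param a,b `cv_scores` data frames (paired: same patients).
#' @param paired logical (default `TRUE`).
#' @return list with `auc_a`, `auc_b`, `covariance`, `z`, `p_value`,
#'   `paired`.
#' @export
compare_auc <- function(a, b, paired = TRUE) {
  if (paired) {
    if (!setequal(a$patient_id, b$patient_id))
      stop("compare_auc: paired comparison requires identical patients")
    b <- b[match(a$patient_id, b$patient_id), ]
    if (!identical(a$label, b$label))
      stop("compare_auc: labels disagree between score sets")
  }
  ca <- delong_components(a$score[a$label == "positive"],
                          a$score[a$label == "negative"])
  cb <- delong_components(b$score[b$label == "positive"],
                          b$score[b$label == "negative"])
  va <- delong_var(ca); vb <- delong_var(cb)
  cv <- if (paired) {
    stats::cov(ca$v10, cb$v10) / length(ca$v10) +
      stats::cov(ca$v01, cb$v01) / length(ca$v01)
  } else 0
  se2 <- va + vb - 2 * cv
  d <- ca$auc - cb$auc
  z <- if (se2 > 0) d / sqrt(se2) else 0
  p <- if (se2 > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(d == 0)
  list(auc_a = ca$auc, auc_b = cb$auc, covariance = cv, z = z,
       p_value = p, paired = paired)
}

#' Performance report across phases and classifiers
#'
#' Builds the per-model performance table (AUC, DeLong SE, 95% CI,
#' Youden-point sensitivity/specificity/accuracy) and, per phase, the
#' pairwise z-test p-value matrix between the classifiers' AUCs.
#'
#' @param scores_list named list of `cv_scores` objects (names are
#'   informational; phase and classifier are read from attributes).
#' @return an object of class `evaluation_report`: `performance` (data
#'   frame) and `comparisons` (named list of p-value matrices per phase).
#' @export
run_report <- function(scores_list) {
  stopifnot(length(scores_list) >= 1)
  perf <- do.call(rbind, lapply(scores_list, function(s) {
    r <- roc_auc(s)
    op <- operating_point(s)
    data.frame(phase = attr(s, "phase"), classifier = attr(s, "classifier"),
               auc = r$auc, se = r$se_delong,
               ci_lo = r$ci95[1], ci_hi = r$ci95[2],
               sensitivity = op$sensitivity, specificity = op$specificity,
               accuracy = op$accuracy, stringsAsFactors = FALSE)
  }))
  rownames(perf) <- NULL
  comparisons <- list()
  for (ph in unique(perf$phase)) {
    ss <- scores_list[vapply(scores_list, function(s)
      identical(attr(s, "phase"), ph), logical(1))]
    cls <- vapply(ss, function(s) attr(s, "classifier"), character(1))
    m <- matrix(NA_real_, length(ss), length(ss),
                dimnames = list(cls, cls))
    if (length(ss) > 1)
      for (i in seq_along(ss)) for (j in seq_along(ss))
        if (i != j) m[i, j] <- compare_auc(ss[[i]], ss[[j]])$p_value
    comparisons[[ph]] <- m
  }
  structure(list(performance = perf, comparisons = comparisons),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Classifier performance (LOOCV):\n")
  p <- x$performance
  p$auc <- sprintf("%.3f", p$auc)
  p$se <- sprintf("%.3f", p$se)
  p$ci <- sprintf("(%.3f, %.3f)", x$performance$ci_lo, x$performance$ci_hi)
  p$sensitivity <- sprintf("%.2f%%", 100 * x$performance$sensitivity)
  p$specificity <- sprintf("%.2f%%", 100 * x$performance$specificity)
  p$accuracy <- sprintf("%.2f%%", 100 * x$performance$accuracy)
  print(p[, c("phase", "classifier", "auc", "se", "ci",
              "sensitivity", "specificity", "accuracy")], row.names = FALSE)
  for (ph in names(x$comparisons)) {
    if (all(is.na(x$comparisons[[ph]]))) next
    cat(sprintf("\nPairwise AUC z-test p-values (%s):\n", ph))
    m <- format(round(x$comparisons[[ph]], 4))
    m[is.na(x$comparisons[[ph]])] <- "/"
    print(m, quote = FALSE)
  }
  invisible(x)
}
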