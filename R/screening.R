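#' Screening configuration
#'
#' @param alpha_normality significance level of the per-group normality
#'   gate (default 0.05): the t branch is taken only when both groups
#'   pass.
#' @param alpha_screen significance level below which a feature is kept.
#' @return an object of class `screening_config`.
#' @export
screening_config <- function(alpha_normality = 0.05, alpha_screen = 0.05) {
  stopifnot(alpha_normality > 0, alpha_normality < 1,
            alpha_screen > 0, alpha_screen <= 1)
  structure(list(alpha_normality = alpha_normality,
                 alpha_screen = alpha_screen),
            class = "screening_config")
}

# p-value of the Lilliefors-corrected KS statistic, from the published
# Dallal & Wilkinson (1986) approximation with the Stephens (1974)
# refinement in the upper tail. Vectorized over D for fixed n.
lilliefors_p <- function(D, n) {
  if (n > 100) {
    Kd <- D * (n / 100)^0.49
    nd <- 100
  } else {
    Kd <- D
    nd <- n
  }
  p <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
             2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
             0.974598 / sqrt(nd) + 1.67997 / nd)
  hi <- which(p > 0.1)
  if (length(hi)) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D[hi]
    p[hi] <- ifelse(KK <= 0.302, 1,
             ifelse(KK <= 0.5,
                    2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
                      138.55152 * KK^3 + 81.218052 * KK^4,
             ifelse(KK <= 0.9,
                    -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
                      94.029866 * KK^3 - 32.355711 * KK^4,
             ifelse(KK <= 1.31,
                    6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
                      12.234627 * KK^3 + 2.423045 * KK^4,
                    0))))
  }
  pmin(pmax(p, 0), 1)
}

#' Kolmogorov-Smirnov normality test with Lilliefors correction
#'
#' One-sample KS test against a normal distribution with mean and
#' standard deviation estimated from the sample; the p-value uses the
#' Lilliefors correction for the estimated parameters. A zero-variance
#' sample is maximally non-normal: p = 0, flagged degenerate.
#'
#' @param x numeric sample, n >= 4.
#' @return list with `statistic` (D), `p.value`, `degenerate`.
#' @export
ks_normal <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("ks_normal: need n >= 4")
  s <- stats::sd(x)
  if (s == 0)
    return(list(statistic = NA_real_, p.value = 0, degenerate = TRUE))
  z <- stats::pnorm((sort(x) - mean(x)) / s)
  i <- seq_len(n)
  D <- max(i / n - z, z - (i - 1) / n)
  list(statistic = D, p.value = lilliefors_p(D, n), degenerate = FALSE)
}

# Pooled-variance two-sided Student t test (closed form).
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (sp2 == 0)
    return(list(statistic = 0, p.value = if (mean(x) == mean(y)) 1 else 0))
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, p.value = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# Two-sided Mann-Whitney U test: exact via the null U distribution when
# n1*n2 <= exact_limit and there are no ties, otherwise the normal
# approximation with tie and continuity corrections.
mann_whitney <- function(x, y, exact_limit = 400) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- rle(sort(c(x, y)))$lengths
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= exact_limit) {
    Umin <- min(U, n1 * n2 - U)
    p <- min(1, 2 * stats::pwilcox(Umin, n1, n2))
    return(list(statistic = U, p.value = p, method = "exact"))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_n <- ties[ties > 1]
  sig2 <- n1 * n2 / 12 *
    ((n + 1) - sum(tie_n^3 - tie_n) / (n * (n - 1)))
  if (sig2 <= 0)
    return(list(statistic = U, p.value = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  list(statistic = U, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

# Lean kept-set computation used inside cross-validation folds: same
# gate and tests as compare_feature, without record construction.
screen_kept_fast <- function(X, pos_idx, neg_idx, cfg) {
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[pos_idx, j]; y <- X[neg_idx, j]
    if (!all(is.finite(x)) || !all(is.finite(y))) next
    both_normal <- ks_normal(x)$p.value >= cfg$alpha_normality &&
      ks_normal(y)$p.value >= cfg$alpha_normality
    p <- if (both_normal) pooled_t(x, y)$p.value
         else mann_whitney(x, y)$p.value
    keep[j] <- p < cfg$alpha_screen
  }
  colnames(X)[keep]
}

summarize_group <- function(x, normal) {
  if (normal)
    sprintf("%.3f±%.3f", mean(x), stats::sd(x))
  else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.3f (%.3f-%.3f)", q[2], q[1], q[3])
  }
}

#' Univariate comparison of one feature between the two FISH groups
#'
#' Runs the Lilliefors-corrected KS normality test on each group; if both
#' pass at `alpha_normality` a pooled-variance Student t test is used,
#' otherwise a two-sided Mann-Whitney U test. Summaries are mean +/- sd
#' on the t branch and median (IQR) otherwise.
#'
#' @param pos,neg feature values of the positive / negative group (each
#'   n >= 4).
#' @param cfg a `screening_config`.
#' @param name feature name to record.
#' @return one-row data frame (a feature screening record).
#' @export
compare_feature <- function(pos, neg, cfg = screening_config(),
                            name = NA_character_) {
  if (length(pos) < 4 || length(neg) < 4)
    stop("compare_feature: both groups need n >= 4")
  if (!all(is.finite(pos)) || !all(is.finite(neg))) {
    # feature undefined for some patients (e.g. wavelet depth sentinel):
    # unusable downstream, recorded but never kept
    return(data.frame(feature = name, normal_pos = NA, normal_neg = NA,
                      test_used = "none", statistic = NA_real_,
                      p_value = NA_real_, kept = FALSE,
                      summary_positive = NA_character_,
                      summary_negative = NA_character_,
                      stringsAsFactors = FALSE))
  }
  kp <- ks_normal(pos); kn <- ks_normal(neg)
  normal_pos <- kp$p.value >= cfg$alpha_normality
  normal_neg <- kn$p.value >= cfg$alpha_normality
  both_normal <- normal_pos && normal_neg
  res <- if (both_normal) pooled_t(pos, neg) else mann_whitney(pos, neg)
  data.frame(feature = name,
             normal_pos = normal_pos, normal_neg = normal_neg,
             test_used = if (both_normal) "t" else "mann_whitney",
             statistic = res$statistic, p_value = res$p.value,
             kept = res$p.value < cfg$alpha_screen,
             summary_positive = summarize_group(pos, both_normal),
             summary_negative = summarize_group(neg, both_normal),
             stringsAsFactors = FALSE)
}

#' Feature table
#'
#' Patients x features container with the binary FISH label.
#'
#' @param features numeric matrix (patients x features) with column names.
#' @param labels character vector, `"positive"` / `"negative"`.
#' @param patient_ids optional patient identifiers.
#' @param phase optional phase tag.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(features, labels, patient_ids = NULL,
                          phase = NA_character_) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels),
            all(labels %in% c("positive", "negative")),
            ncol(features) == 0L || !is.null(colnames(features)),
            !anyDuplicated(colnames(features)))
  if (is.null(patient_ids)) patient_ids <- sprintf("P%03d", seq_along(labels))
  structure(list(features = features, labels = labels,
                 patient_ids = patient_ids, phase = phase),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d patients (%d pos / %d neg) x %d features%s\n",
              nrow(x$features), sum(x$labels == "positive"),
              sum(x$labels == "negative"), ncol(x$features),
              if (is.na(x$phase)) "" else paste0(", phase ", x$phase)))
  invisible(x)
}

#' Screen all features of a cohort table
#'
#' One screening record per feature; the kept set is every feature with
#' `p < alpha_screen` (no multiple-testing correction, matching raw
#' univariate screening practice; apply [stats::p.adjust()] to the
#' `p_value` column for a corrected variant).
#'
#' @param tab a `feature_table` containing both classes.
#' @param cfg a `screening_config`.
#' @return data frame of records with attribute `"kept"` (character
#'   vector of kept feature names).
#' @export
screen_table <- function(tab, cfg = screening_config()) {
  stopifnot(inherits(tab, "feature_table"))
  pos <- tab$labels == "positive"
  if (!any(pos) || all(pos)) stop("screen_table: both classes required")
  recs <- lapply(colnames(tab$features), function(f)
    compare_feature(tab$features[pos, f], tab$features[!pos, f], cfg,
                    name = f))
  out <- do.call(rbind, recs)
  attr(out, "kept") <- out$feature[out$kept]
  out
}

#' Association test for a 2x2 contingency table
#'
#' Pearson chi-square without continuity correction when every expected
#' count is at least 5, otherwise Fisher's exact test (two-sided).
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list with `method`, `statistic` (chi-square or `NA`),
#'   `p_value` and `expected`.
#' @export
contingency_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)), all(counts >= 0),
            all(counts == round(counts)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("contingency_test: zero margin")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (all(expected >= 5)) {
    ht <- stats::chisq.test(counts, correct = FALSE)
    list(method = "chi_square", statistic = unname(ht$statistic),
         p_value = ht$p.value, expected = expected)
  } else {
    ht <- stats::fisher.test(counts)
    list(method = "fisher_exact", statistic = NA_real_,
         p_value = ht$p.value, expected = expected)
  }
}

#' Min-max standardization of a feature table to [0, 1]
#'
#' Each feature is scaled to the unit interval; constant features map to
#' 0.5 and are listed in the `"constant_features"` attribute.
#'
#' @param tab a `feature_table`.
#' @return a `feature_table` with scaled features.
#' @export
standardize_unit_interval <- function(tab) {
  stopifnot(inherits(tab, "feature_table"))
  X <- tab$features
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  const <- hi == lo
  span <- ifelse(const, 1, hi - lo)
  Xs <- sweep(sweep(X, 2, lo), 2, span, "/")
  Xs[, const] <- 0.5
  out <- feature_table(Xs, tab$labels, tab$patient_ids, tab$phase)
  attr(out, "constant_features") <- colnames(X)[const]
  out
}
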