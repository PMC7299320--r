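#' Classifier specification
#'
#' @param kind `"lra"` (unpenalized logistic regression), `"qda"`
#'   (Gaussian quadratic discriminant with a covariance ridge), or
#'   `"svm"` (support vector machine).
#' @param svm_kernel `"rbf"` (default) or `"linear"`.
#' @param svm_C SVM cost parameter (default 1).
#' @param svm_gamma `"scale"` (1 / (p * var(X)), the scale rule) or a
#'   fixed positive value; RBF kernel only.
#' @param qda_epsilon relative ridge added to each class covariance,
#'   `epsilon * trace(S)/p * I` (default 1e-6).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("lra", "qda", "svm"),
                            svm_kernel = c("rbf", "linear"),
                            svm_C = 1, svm_gamma = "scale",
                            qda_epsilon = 1e-6) {
  kind <- match.arg(kind)
  svm_kernel <- match.arg(svm_kernel)
  stopifnot(svm_C > 0)
  structure(list(kind = kind, svm_kernel = svm_kernel, svm_C = svm_C,
                 svm_gamma = svm_gamma, qda_epsilon = qda_epsilon),
            class = "classifier_spec")
}

# Gaussian quadratic discriminant with an epsilon covariance ridge;
# returns the equal-prior posterior probability of the positive class for
# x_new. Equal priors (rather than training-fold proportions) avoid the
# stratification bias of pooled leave-one-out scores: the held-out
# patient's class is always the minority of its training fold, and a
# prevalence-weighted prior systematically depresses its score.
qda_score <- function(X, yb, x_new, epsilon) {
  p <- ncol(X)
  score_class <- function(Xc) {
    mu <- colMeans(Xc)
    S <- stats::cov(Xc)
    tr <- sum(diag(S))
    ridge <- if (tr > 0) epsilon * tr / p else 1e-8
    S <- S + diag(ridge, p)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) stop("qda_score: singular class covariance")
    d <- backsolve(ch, x_new - mu, transpose = TRUE)
    logdet <- 2 * sum(log(diag(ch)))
    -0.5 * (sum(d^2) + logdet)
  }
  lp <- score_class(X[yb == 1L, , drop = FALSE])
  ln <- score_class(X[yb == 0L, , drop = FALSE])
  1 / (1 + exp(ln - lp))
}

fit_score_one <- function(X_tr, yb_tr, x_new, spec) {
  switch(spec$kind,
    lra = {
      df <- as.data.frame(X_tr)
      fit <- suppressWarnings(
        stats::glm(yb_tr ~ ., data = df, family = stats::binomial(),
                   control = stats::glm.control(maxit = 50)))
      nd <- as.data.frame(matrix(x_new, 1, dimnames = list(NULL, colnames(X_tr))))
      lp <- unname(suppressWarnings(stats::predict(fit, nd, type = "link")))
      # remove the training-fold prior log-odds so that out-of-fold
      # scores are comparable across folds (pooled-LOOCV stratification
      # bias correction)
      prev <- mean(yb_tr)
      stats::plogis(lp - log(prev / (1 - prev)))
    },
    qda = qda_score(X_tr, yb_tr, x_new, spec$qda_epsilon),
    svm = {
      yf <- factor(ifelse(yb_tr == 1L, "positive", "negative"),
                   levels = c("positive", "negative"))
      gamma <- if (identical(spec$svm_gamma, "scale")) {
        v <- stats::var(as.numeric(X_tr))
        if (v > 0) 1 / (ncol(X_tr) * v) else 1 / ncol(X_tr)
      } else spec$svm_gamma
      fit <- e1071::svm(X_tr, yf,
                        kernel = if (spec$svm_kernel == "rbf") "radial"
                                 else "linear",
                        cost = spec$svm_C, gamma = gamma, scale = FALSE)
      pr <- stats::predict(fit, matrix(x_new, 1), decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # orient the margin so larger means more positive
      if (grepl("^negative", colnames(attr(pr, "decision.values"))[1]))
        dv <- -dv
      unname(dv)
    },
    stop("unknown classifier kind"))
}

#' Leave-one-out cross-validated classifier scores
#'
#' For each patient, the classifier is trained on all remaining patients
#' (features standardized with training-fold statistics) and the held-out
#' patient receives a continuous score: the predicted positive-class
#' probability for LRA and QDA, the signed margin for SVM. In
#' `leakage_safe` mode, univariate screening and LASSO selection are
#' re-run inside every fold on the training patients only; in `paper`
#' mode the caller passes the already-selected feature columns and only
#' the classifier is cross-validated (the sequential design classically
#' used with a screen-then-model description, optimistic on null data).
#'
#' @param tab a `feature_table`. In paper mode, its columns are the
#'   selected features; in leakage_safe mode, the full candidate set.
#' @param spec a `classifier_spec`.
#' @param mode `"paper"` or `"leakage_safe"`.
#' @param screening a `screening_config` (leakage_safe mode).
#' @param k_folds,seed LASSO cross-validation parameters
#'   (leakage_safe mode).
#' @return an object of class `cv_scores`: data frame with columns
#'   `patient_id`, `label`, `score`, `fold`, plus attributes
#'   `classifier`, `phase`, `mode`.
#' @export
fit_predict_loocv <- function(tab, spec = classifier_spec("lra"),
                              mode = c("paper", "leakage_safe"),
                              screening = screening_config(),
                              k_folds = 10L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(tab, "feature_table"), inherits(spec, "classifier_spec"))
  X <- tab$features
  yb <- as.integer(tab$labels == "positive")
  n <- nrow(X)
  if (n < 4 || sum(yb) < 2 || sum(1 - yb) < 2)
    stop("fit_predict_loocv: need n >= 4 with >= 2 per class")
  # features undefined for any patient (e.g. reduced wavelet depth) are
  # unusable for modeling; defined-ness depends only on mask geometry,
  # never on labels, so this costs no cross-validation integrity
  usable <- which(apply(is.finite(X), 2, all))
  scores <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    stopifnot(!(i %in% tr))            # structural leakage check
    X_tr <- X[tr, , drop = FALSE]
    y_tr <- yb[tr]
    if (length(unique(y_tr)) < 2)
      stop(sprintf("fit_predict_loocv: class absent from training fold %d", i))
    cols <- colnames(X_tr)
    if (mode == "leakage_safe") {
      kept <- screen_kept_fast(X_tr[, usable, drop = FALSE],
                               which(y_tr == 1L), which(y_tr == 0L),
                               screening)
      sel <- if (length(kept))
        lasso_select(X_tr[, kept, drop = FALSE], y_tr,
                     k_folds = k_folds, seed = seed)
      else NULL
      cols <- if (is.null(sel)) character(0) else names(sel$nonzero_features)
    }
    if (length(cols)) {
      # a feature constant within this training fold carries no
      # information and would produce undefined coefficients
      sd_tr <- apply(X_tr[, cols, drop = FALSE], 2, stats::sd)
      cols <- cols[sd_tr > 0]
    }
    if (length(cols) == 0L) {
      # no usable features: constant non-informative score (a per-fold
      # training prevalence would anti-correlate with the held-out label
      # under LOOCV and bias the AUC to 0)
      scores[i] <- 0.5
      next
    }
    Xs <- X_tr[, cols, drop = FALSE]
    mu <- colMeans(Xs)
    sdv <- apply(Xs, 2, stats::sd); sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(Xs, 2, mu), 2, sdv, "/")
    x_new <- (X[i, cols] - mu) / sdv
    scores[i] <- fit_score_one(Xs, y_tr, x_new, spec)
  }
  out <- data.frame(patient_id = tab$patient_ids, label = tab$labels,
                    score = scores, fold = seq_len(n),
                    stringsAsFactors = FALSE)
  structure(out, class = c("cv_scores", "data.frame"),
            classifier = spec$kind, phase = tab$phase, mode = mode)
}
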