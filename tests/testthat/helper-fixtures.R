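# Programmatic fixtures shared across test files.

# Random fully-masked quantized ROI with few gray levels.
rand_qroi <- function(nr = 6, nc = 6, levels = 8, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(sample(0:(levels - 1), nr * nc, replace = TRUE), nr, nc)
  })
  structure(list(grid = g, mask = matrix(TRUE, nr, nc),
                 n_levels = as.integer(levels),
                 params = list(mu = NA, sigma = NA, n_bits = NA,
                               degenerate = FALSE)),
            class = "quantized_roi")
}

# Quantized ROI from an explicit integer matrix (full mask).
qroi_from <- function(g, levels = max(g) + 1L) {
  structure(list(grid = g, mask = matrix(TRUE, nrow(g), ncol(g)),
                 n_levels = as.integer(levels),
                 params = list(mu = NA, sigma = NA, n_bits = NA,
                               degenerate = FALSE)),
            class = "quantized_roi")
}

rand_mask <- function(nr = 8, nc = 8, p = 0.5, seed = 1) {
  withr::with_seed(seed, matrix(stats::runif(nr * nc) < p, nr, nc))
}

# Binormal out-of-fold scores with a given true AUC.
sim_scores <- function(n_pos = 52, n_neg = 40, auc = 0.8, seed = 1) {
  mu <- sqrt(2) * stats::qnorm(auc)
  withr::with_seed(seed, {
    data.frame(
      patient_id = sprintf("P%03d", seq_len(n_pos + n_neg)),
      label = c(rep("positive", n_pos), rep("negative", n_neg)),
      score = c(stats::rnorm(n_pos, mu), stats::rnorm(n_neg)),
      fold = seq_len(n_pos + n_neg), stringsAsFactors = FALSE)
  })
}

as_cv_scores <- function(df, classifier = "lra", phase = "subtraction",
                         mode = "paper") {
  structure(df, class = c("cv_scores", "data.frame"),
            classifier = classifier, phase = phase, mode = mode)
}

# Small feature table with pure-noise columns and an optional shifted one.
noise_table <- function(n_pos = 26, n_neg = 20, p = 10, shift = 0, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm((n_pos + n_neg) * p), n_pos + n_neg, p,
                dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
    labels <- c(rep("positive", n_pos), rep("negative", n_neg))
    if (shift != 0) X[labels == "positive", 1] <- X[labels == "positive", 1] + shift
    feature_table(X, labels)
  })
}

# Small phantom configuration for fast end-to-end tests.
small_phantom <- function(n_pos = 12, n_neg = 8, seed = 1, ...) {
  phantom_config(n_positive = n_pos, n_negative = n_neg,
                 image_size = c(64, 64), lesion_radius_range = c(9, 13),
                 seed = seed, ...)
}
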