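#' First-order histogram features
#'
#' Mean, variance, skewness and kurtosis of the masked gray levels.
#' Moments use the population (denominator `n`) convention; skewness is
#' the third standardized moment and kurtosis the excess kurtosis, both
#' defined as 0 for a zero-variance region.
#'
#' @param q a `quantized_roi`.
#' @return named numeric vector `c(Mean, Variance, Skewness, Kurtosis)`.
#' @export
histogram_features <- function(q) {
  v <- as.numeric(roi_levels(q))
  if (length(v) < 2L) stop("histogram_features: need >= 2 masked pixels")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) {
    sk <- 0; ku <- 0
  } else {
    sk <- mean((v - m)^3) / m2^1.5
    ku <- mean((v - m)^4) / m2^2 - 3
  }
  c(Mean = m, Variance = m2, Skewness = sk, Kurtosis = ku)
}

#' Full texture feature vector of one quantized ROI
#'
#' Concatenates the four feature families in canonical order: 4 histogram
#' + 380 GLCM + 44 GRLM + 60 DWT = 488 named values under the default
#' configurations.
#'
#' @param q a `quantized_roi`.
#' @param glcm_cfg,grlm_cfg,dwt_cfg family configurations.
#' @return named numeric vector.
#' @export
extract_features <- function(q, glcm_cfg = glcm_config(),
                             grlm_cfg = grlm_config(),
                             dwt_cfg = dwt_config()) {
  c(histogram_features(q),
    glcm_features(q, glcm_cfg),
    grlm_features(q, grlm_cfg),
    dwt_features(q, dwt_cfg))
}

#' Per-phase texture extraction for one patient
#'
#' @param pre_q,post_q,sub_q quantized ROIs of the pre-contrast,
#'   post-contrast and subtraction phases (same lesion mask).
#' @param glcm_cfg,grlm_cfg,dwt_cfg family configurations.
#' @return named list of three feature vectors
#'   (`pre`, `post`, `subtraction`).
#' @export
extract_all <- function(pre_q, post_q, sub_q,
                        glcm_cfg = glcm_config(),
                        grlm_cfg = grlm_config(),
                        dwt_cfg = dwt_config()) {
  phases <- list(pre = pre_q, post = post_q, subtraction = sub_q)
  lapply(stats::setNames(names(phases), names(phases)), function(ph) {
    tryCatch(
      extract_features(phases[[ph]], glcm_cfg, grlm_cfg, dwt_cfg),
      error = function(e)
        stop(sprintf("extract_all [%s phase]: %s", ph, conditionMessage(e)),
             call. = FALSE))
  })
}
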