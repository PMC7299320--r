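#' DWT extraction configuration
#'
#' Four-level separable 2D wavelet decomposition with periodic boundary
#' extension, for the Haar, Daubechies-2 and Symlet-4 orthonormal
#' wavelets. Per level and wavelet, five values are emitted: the
#' normalized energies of the three detail subbands (codes `HH` =
#' horizontal, `DH` = vertical, `HD` = diagonal), the normalized energy
#' of the approximation, and the mean of the approximation coefficients.
#'
#' @param wavelets character vector among `"haar"`, `"db2"`, `"sym4"`.
#' @param n_levels decomposition depth (default 4).
#' @return an object of class `dwt_config`.
#' @export
dwt_config <- function(wavelets = c("haar", "db2", "sym4"), n_levels = 4L) {
  stopifnot(all(wavelets %in% c("haar", "db2", "sym4")), n_levels >= 1)
  structure(list(wavelets = wavelets, n_levels = as.integer(n_levels)),
            class = "dwt_config")
}

# Orthonormal scaling (lowpass) filters; standard published coefficients.
wavelet_filter <- function(name) {
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2  = c(0.48296291314453416, 0.83651630373780790,
             0.22414386804201339, -0.12940952255126037),
    sym4 = c(0.03222310060404270, -0.01260396726203783,
             -0.09921954357684722, 0.29785779560527736,
             0.80373875180591614, 0.49761866763201545,
             -0.02963552764599851, -0.07576571478927333),
    stop("wavelet_filter: unknown wavelet ", name))
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)     # quadrature mirror highpass
  list(h = h, g = g)
}

# One analysis step along the first dimension with periodic extension.
# x has an even number of rows; returns list(lo, hi), each nrow(x)/2 rows.
dwt_step_rows <- function(x, h, g) {
  n <- nrow(x)
  stopifnot(n %% 2 == 0)
  half <- n / 2L
  lo <- matrix(0, half, ncol(x))
  hi <- matrix(0, half, ncol(x))
  base <- 2L * (seq_len(half) - 1L)       # 0-based start of each window
  for (m in seq_along(h)) {
    idx <- ((base + m - 1L) %% n) + 1L
    lo <- lo + h[m] * x[idx, , drop = FALSE]
    hi <- hi + g[m] * x[idx, , drop = FALSE]
  }
  list(lo = lo, hi = hi)
}

#' One level of separable 2D wavelet analysis (periodic extension)
#'
#' @param x numeric matrix with even dimensions.
#' @param wavelet `"haar"`, `"db2"` or `"sym4"`.
#' @return list with approximation `LL` and detail subbands `horizontal`
#'   (rows lowpass / columns highpass), `vertical` (rows highpass /
#'   columns lowpass) and `diagonal` (both highpass).
#' @export
dwt2 <- function(x, wavelet = "haar") {
  f <- wavelet_filter(wavelet)
  rows <- dwt_step_rows(x, f$h, f$g)
  lo_c <- dwt_step_rows(t(rows$lo), f$h, f$g)   # columns of the row-lowpass
  hi_c <- dwt_step_rows(t(rows$hi), f$h, f$g)
  list(LL = t(lo_c$lo), horizontal = t(lo_c$hi),
       vertical = t(hi_c$lo), diagonal = t(hi_c$hi))
}

dwt_subband_codes <- c(horizontal = "HH", vertical = "DH", diagonal = "HD")

#' Wavelet subband features of a quantized ROI
#'
#' The masked bounding box is extracted, outside-mask pixels are filled
#' with the masked mean, and the box is padded (same fill) to a multiple
#' of `2^n_levels` so that every level has even dimensions under periodic
#' extension. Subband energies are normalized by the total energy of the
#' padded image. If the bounding box is too small for the requested
#' depth, the depth is reduced with a warning and the missing levels are
#' reported as `NA`.
#'
#' @param q a `quantized_roi`.
#' @param cfg a `dwt_config`.
#' @return named numeric vector, `5 * n_levels` values per wavelet
#'   (60 under the defaults).
#' @export
dwt_features <- function(q, cfg = dwt_config()) {
  stopifnot(any(q$mask))
  rr <- range(which(rowSums(q$mask) > 0))
  cc <- range(which(colSums(q$mask) > 0))
  box <- q$grid[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  fill <- mean(q$grid[q$mask])
  box[is.na(box)] <- fill
  box <- box * 1.0
  n_levels <- cfg$n_levels
  eff <- min(n_levels, floor(log2(min(dim(box)))))
  if (eff < 1) {
    warning("dwt_features: mask bounding box too small for any level")
    eff <- 0L
  } else if (eff < n_levels) {
    warning(sprintf("dwt_features: reducing depth from %d to %d levels",
                    n_levels, eff))
  }
  if (eff > 0) {
    unit <- 2L^eff
    pad_to <- function(n) as.integer(ceiling(n / unit) * unit)
    padded <- matrix(fill, pad_to(nrow(box)), pad_to(ncol(box)))
    padded[seq_len(nrow(box)), seq_len(ncol(box))] <- box
    e0 <- sum(padded^2)
  }
  out <- numeric(0)
  for (w in cfg$wavelets) {
    vals <- rep(NA_real_, 5L * n_levels)
    nms <- character(5L * n_levels)
    for (lev in seq_len(n_levels))
      nms[(5 * (lev - 1) + 1):(5 * lev)] <-
        sprintf("%s %s_%d", w, c("HH", "DH", "HD", "LL", "LLmean"), lev)
    if (eff > 0) {
      cur <- padded
      for (lev in seq_len(eff)) {
        dec <- dwt2(cur, w)
        vals[5 * (lev - 1) + 1:5] <- c(sum(dec$horizontal^2) / e0,
                                       sum(dec$vertical^2) / e0,
                                       sum(dec$diagonal^2) / e0,
                                       sum(dec$LL^2) / e0,
                                       mean(dec$LL))
        cur <- dec$LL
      }
    }
    names(vals) <- nms
    out <- c(out, vals)
  }
  out
}
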