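#' Construct a 2D slice image
#'
#' Lightweight container for one grayscale axial slice of a dynamic
#' contrast-enhanced MRI exam. Intensities are arbitrary finite reals
#' (MR signal is not calibrated); the pipeline's own normalization maps
#' them to gray levels later.
#'
#' @param grid numeric matrix of pixel intensities (rows x cols, >= 2x2).
#' @param phase one of `"pre"`, `"post"`, `"subtraction"`.
#' @param patient_id character scalar identifying the patient.
#' @param pixel_spacing optional pixel spacing in mm (informational).
#' @return an object of class `slice_image`.
#' @export
slice_image <- function(grid, phase = c("pre", "post", "subtraction"),
                        patient_id = "unknown", pixel_spacing = NULL) {
  phase <- match.arg(phase)
  grid <- as.matrix(grid)
  if (nrow(grid) < 2L || ncol(grid) < 2L)
    stop("slice_image: grid must be at least 2x2")
  if (!all(is.finite(grid)))
    stop("slice_image: grid contains non-finite values")
  structure(list(grid = grid, phase = phase, patient_id = patient_id,
                 pixel_spacing = pixel_spacing),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> patient %s, phase %s, %d x %d\n",
              x$patient_id, x$phase, nrow(x$grid), ncol(x$grid)))
  invisible(x)
}

#' @export
dim.slice_image <- function(x) dim(x$grid)

#' Pixel-wise subtraction image
#'
#' Computes the contrast-uptake image `post - pre` used for lesion
#' delineation; enhancing tissue appears bright.
#'
#' @param post post-contrast `slice_image`.
#' @param pre pre-contrast `slice_image`.
#' @return a `slice_image` with phase `"subtraction"`.
#' @export
subtract_images <- function(post, pre) {
  stopifnot(inherits(post, "slice_image"), inherits(pre, "slice_image"))
  if (!identical(dim(post$grid), dim(pre$grid)))
    stop("subtract_images: shape mismatch")
  if (!identical(post$patient_id, pre$patient_id))
    stop("subtract_images: patient mismatch")
  slice_image(post$grid - pre$grid, phase = "subtraction",
              patient_id = post$patient_id,
              pixel_spacing = post$pixel_spacing)
}

#' Normalize and quantize masked lesion pixels
#'
#' Masked intensities are clipped to `mu +/- 3 sigma` (mean and standard
#' deviation computed over the masked pixels of the phase being analyzed)
#' and that interval is mapped linearly onto integer gray levels
#' `0 .. 2^n_bits - 1` by flooring, with the top edge mapping to the
#' maximum level. A zero-variance region is degenerate: all masked pixels
#' are set to the middle level `2^(n_bits - 1)` and flagged.
#'
#' @param image a `slice_image`.
#' @param mask logical matrix, same shape, `TRUE` inside the lesion.
#' @param n_bits bit depth of the quantization (default 8).
#' @return an object of class `quantized_roi` with fields `grid` (integer
#'   levels inside the mask, `NA` outside), `mask`, `n_levels` and
#'   `params` (`mu`, `sigma`, `n_bits`, `degenerate`).
#' @export
normalize_quantize <- function(image, mask, n_bits = 8L) {
  stopifnot(inherits(image, "slice_image"), is.logical(mask))
  if (!identical(dim(image$grid), dim(mask)))
    stop("normalize_quantize: mask shape mismatch")
  if (!any(mask)) stop("normalize_quantize: empty mask")
  n_bits <- as.integer(n_bits)
  if (n_bits < 1L || n_bits > 16L)
    stop("normalize_quantize: n_bits must be in 1..16")
  n_levels <- 2L^n_bits
  vals <- image$grid[mask]
  mu <- mean(vals)
  sigma <- stats::sd(vals)
  out <- matrix(NA_integer_, nrow(mask), ncol(mask))
  degenerate <- !is.finite(sigma) || sigma == 0
  if (degenerate) {
    out[mask] <- as.integer(n_levels / 2L)
  } else {
    lo <- mu - 3 * sigma
    hi <- mu + 3 * sigma
    v <- pmin(pmax(vals, lo), hi)
    lev <- floor((v - lo) / (hi - lo) * n_levels)
    lev[lev >= n_levels] <- n_levels - 1L
    out[mask] <- as.integer(lev)
  }
  structure(list(grid = out, mask = mask, n_levels = n_levels,
                 params = list(mu = mu, sigma = sigma, n_bits = n_bits,
                               degenerate = degenerate)),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %d x %d, %d masked pixels, %d levels%s\n",
              nrow(x$grid), ncol(x$grid), sum(x$mask), x$n_levels,
              if (isTRUE(x$params$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

# Masked gray levels as an integer vector.
roi_levels <- function(q) q$grid[q$mask]
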