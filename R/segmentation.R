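#' Region-of-interest polygon
#'
#' The operator-drawn seed region around a lesion, as an ordered list of
#' `(row, col)` vertices in pixel coordinates. The polygon is assumed
#' simple (non-self-intersecting); this is not verified geometrically.
#'
#' @param vertices numeric matrix with two columns (row, col), >= 3 rows.
#' @return an object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("roi_polygon: need >= 3 (row, col) vertices")
  if (!all(is.finite(vertices)))
    stop("roi_polygon: non-finite vertex")
  dimnames(vertices) <- list(NULL, c("row", "col"))
  structure(list(vertices = vertices), class = "roi_polygon")
}

#' Rasterize an ROI polygon to a pixel mask
#'
#' @param roi an `roi_polygon`.
#' @param dims image dimensions `c(rows, cols)`.
#' @return logical matrix, `TRUE` for pixel centers inside the polygon.
#' @export
roi_to_mask <- function(roi, dims) {
  stopifnot(inherits(roi, "roi_polygon"), length(dims) == 2L)
  v <- roi$vertices
  if (any(v[, 1] < 1 - 0.5) || any(v[, 1] > dims[1] + 0.5) ||
      any(v[, 2] < 1 - 0.5) || any(v[, 2] > dims[2] + 0.5))
    stop("roi_to_mask: ROI extends outside the image")
  rr <- floor(max(1, min(v[, 1]))):ceiling(min(dims[1], max(v[, 1])))
  cc <- floor(max(1, min(v[, 2]))):ceiling(min(dims[2], max(v[, 2])))
  pts <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  inside <- mgcv::in.out(rbind(v, v[1, , drop = FALSE]), pts)
  m <- matrix(FALSE, dims[1], dims[2])
  m[pts[inside, , drop = FALSE]] <- TRUE
  m
}

#' Otsu threshold of an intensity sample
#'
#' Histogram-based threshold maximizing the between-class variance
#' `w0 * w1 * (m0 - m1)^2`. The histogram uses `n_bins` equal-width bins
#' over the observed min-max range; candidate thresholds are the interior
#' bin edges and ties are broken toward the lowest qualifying threshold.
#' Pixels at or above the returned threshold are foreground.
#'
#' @param pixels numeric vector of intensities (>= 2 values, >= 2 distinct).
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold intensity (a bin edge).
#' @export
otsu_threshold <- function(pixels, n_bins = 256L) {
  pixels <- as.numeric(pixels)
  pixels <- pixels[is.finite(pixels)]
  if (length(pixels) < 2L) stop("otsu_threshold: need >= 2 pixels")
  lo <- min(pixels); hi <- max(pixels)
  if (lo == hi) stop("otsu_threshold: constant input (degenerate)")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(pixels, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  s <- numeric(n_bins)
  s[sort(unique(bin))] <- rowsum(pixels, bin)[, 1]  # per-bin intensity sums
  n <- length(pixels); total <- sum(pixels)
  c0 <- cumsum(cnt)[-n_bins]          # counts below each interior edge
  s0 <- cumsum(s)[-n_bins]
  valid <- c0 > 0 & c0 < n
  w0 <- c0 / n; w1 <- 1 - w0
  m0 <- s0 / c0; m1 <- (total - s0) / (n - c0)
  sb <- ifelse(valid, w0 * w1 * (m0 - m1)^2, -Inf)
  k <- which.max(sb)                  # which.max returns first (lowest) maximizer
  edges[k + 1L]
}

#' Largest eight-connected foreground component
#'
#' Diagonal neighbors are connected. When several components tie in size,
#' the one whose first pixel appears earliest in raster (row, col) order
#' is returned.
#'
#' @param mask logical matrix.
#' @return logical matrix retaining only the largest component.
#' @export
largest_component8 <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("largest_component8: empty mask")
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  next_label <- 0L
  best_label <- 0L; best_size <- -1L
  stack <- integer(sum(mask))
  # scan in raster (row-major) order so the first pixel of each component
  # is well defined for tie-breaking
  for (r in seq_len(nr)) for (co in seq_len(nc)) {
    if (!mask[r, co] || labels[r, co] != 0L) next
    next_label <- next_label + 1L
    size <- 0L
    top <- 1L
    stack[1L] <- (co - 1L) * nr + r
    labels[r, co] <- next_label
    while (top > 0L) {
      idx <- stack[top]; top <- top - 1L
      size <- size + 1L
      ri <- ((idx - 1L) %% nr) + 1L
      ci <- ((idx - 1L) %/% nr) + 1L
      for (dr in -1L:1L) for (dc in -1L:1L) {
        if (dr == 0L && dc == 0L) next
        r2 <- ri + dr; c2 <- ci + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        if (mask[r2, c2] && labels[r2, c2] == 0L) {
          labels[r2, c2] <- next_label
          top <- top + 1L
          stack[top] <- (c2 - 1L) * nr + r2
        }
      }
    }
    if (size > best_size) { best_size <- size; best_label <- next_label }
  }
  labels == best_label
}

#' Morphology parameters for lesion cleanup
#'
#' @param erosion_radius radius in pixels of the erosion element (default 2).
#' @param dilation_radius radius in pixels of the dilation element (default 2).
#' @param structuring_element `"disk"` or `"square"`.
#' @return an object of class `morphology_params`.
#' @export
morphology_params <- function(erosion_radius = 2L, dilation_radius = 2L,
                              structuring_element = c("disk", "square")) {
  structuring_element <- match.arg(structuring_element)
  stopifnot(erosion_radius >= 0, dilation_radius >= 0)
  structure(list(erosion_radius = as.integer(erosion_radius),
                 dilation_radius = as.integer(dilation_radius),
                 structuring_element = structuring_element),
            class = "morphology_params")
}

make_kernel <- function(radius, shape) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L,
                     shape = if (shape == "disk") "disc" else "box")
}

erode_mask <- function(mask, radius, shape = "disk") {
  if (radius == 0L) return(mask)
  EBImage::erode(mask * 1, make_kernel(radius, shape)) > 0.5
}

dilate_mask <- function(mask, radius, shape = "disk") {
  if (radius == 0L) return(mask)
  EBImage::dilate(mask * 1, make_kernel(radius, shape)) > 0.5
}

#' Semi-automatic lesion segmentation on a subtraction image
#'
#' Reproduces the four-step delineation used for contrast-enhancing
#' lesions: (1) restrict to the interior of the operator ROI, (2) Otsu
#' threshold on the ROI pixels with foreground above the threshold,
#' (3) morphological erosion followed by extraction of the largest
#' eight-connected component, (4) morphological dilation. The result is
#' clipped to the ROI so dilation cannot leak outside the drawn region.
#'
#' @param subtraction a `slice_image` (normally the subtraction phase).
#' @param roi an `roi_polygon` around the lesion.
#' @param params a `morphology_params` object.
#' @return logical lesion mask (single eight-connected component before
#'   dilation; clipped to the ROI).
#' @export
segment_lesion <- function(subtraction, roi, params = morphology_params()) {
  stopifnot(inherits(subtraction, "slice_image"))
  roi_mask <- roi_to_mask(roi, dim(subtraction$grid))
  if (!any(roi_mask)) stop("segment_lesion: ROI contains no pixels")
  thr <- otsu_threshold(subtraction$grid[roi_mask])
  binary <- roi_mask & (subtraction$grid >= thr)
  if (!any(binary))
    stop("segment_lesion: no foreground above the Otsu threshold")
  eroded <- erode_mask(binary, params$erosion_radius,
                       params$structuring_element)
  if (!any(eroded))
    stop(sprintf(paste0("segment_lesion: mask collapsed after erosion ",
                        "(radius %d, %d foreground pixels before erosion)"),
                 params$erosion_radius, sum(binary)))
  core <- largest_component8(eroded)
  dilated <- dilate_mask(core, params$dilation_radius,
                         params$structuring_element)
  dilated & roi_mask
}

#' Transfer a lesion mask to a co-registered phase
#'
#' The phases of one exam are assumed already aligned, so the contour
#' found on the subtraction image is reused verbatim.
#'
#' @param mask logical lesion mask.
#' @param target a `slice_image` of the same shape.
#' @return the mask, unchanged, with the target phase recorded in the
#'   `"phase"` attribute.
#' @export
transfer_mask <- function(mask, target) {
  stopifnot(is.logical(mask), inherits(target, "slice_image"))
  if (!identical(dim(mask), dim(target$grid)))
    stop("transfer_mask: shape mismatch")
  out <- mask
  attr(out, "phase") <- target$phase
  out
}

#' Dice overlap between two binary masks
#'
#' @param a,b logical matrices of equal shape.
#' @return Dice coefficient `2|a & b| / (|a| + |b|)`.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
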