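#' GRLM extraction configuration
#'
#' Run-length matrices are computed along four directions at unit step
#' (the standard 0/45/90/135 degree rakes). Runs are maximal sequences of
#' equal gray level along the direction and are truncated wherever the
#' mask is interrupted.
#'
#' @param n_levels number of gray levels of the quantized ROI.
#' @return an object of class `grlm_config`.
#' @export
grlm_config <- function(n_levels = 256L) {
  structure(list(n_levels = as.integer(n_levels),
                 directions = c("0", "45", "90", "135")),
            class = "grlm_config")
}

grlm_feature_names <- c("RLN", "GLN", "LRE", "SRE", "FIR", "LGRE", "HGRE",
                        "SRLGE", "SRHGE", "LRLGE", "LRHGE")

# Lines of the masked gray-level image along one rake direction.
# Returns a list of integer vectors with NA at unmasked pixels.
grlm_lines <- function(g, direction) {
  nr <- nrow(g); nc <- ncol(g)
  switch(direction,
    "0"   = lapply(seq_len(nr), function(r) g[r, ]),
    "90"  = lapply(seq_len(nc), function(cc) g[, cc]),
    "45"  = lapply(2:(nr + nc), function(s) {   # anti-diagonals r + c = s
      r <- max(1L, s - nc):min(nr, s - 1L)
      g[cbind(r, s - r)]
    }),
    "135" = lapply((1L - nc):(nr - 1L), function(dlt) { # diagonals r - c = dlt
      r <- max(1L, 1L + dlt):min(nr, nc + dlt)
      g[cbind(r, r - dlt)]
    }),
    stop("grlm_lines: unknown direction"))
}

#' Gray level run-length matrix along one direction
#'
#' @param q a `quantized_roi`.
#' @param direction one of `"0"`, `"45"`, `"90"`, `"135"` (degrees).
#' @return data frame with columns `level` (0-based gray level), `len`
#'   (run length) and `count`.
#' @export
grlm <- function(q, direction = c("0", "45", "90", "135")) {
  direction <- match.arg(direction)
  if (!any(q$mask)) stop("grlm: empty mask")
  lev <- integer(0); len <- integer(0)
  for (v in grlm_lines(q$grid, direction)) {
    # NA (outside mask) breaks runs; encode as an impossible level
    r <- rle(ifelse(is.na(v), -1L, as.integer(v)))
    keep <- r$values >= 0L
    lev <- c(lev, r$values[keep])
    len <- c(len, r$lengths[keep])
  }
  key <- paste(lev, len)
  cnt <- table(key)
  parts <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
  data.frame(level = as.integer(parts[, 1]), len = as.integer(parts[, 2]),
             count = as.integer(cnt))
}

# The 11 run-length statistics from one run matrix. Gray levels enter the
# low/high-gray emphases 1-based so that level 0 stays finite.
grlm_stats <- function(rm, n_pixels) {
  cnt <- rm$count; l <- rm$len; g1 <- rm$level + 1
  nr <- sum(cnt)
  c(RLN   = sum(as.numeric(rowsum(cnt, l))^2) / nr,
    GLN   = sum(as.numeric(rowsum(cnt, g1))^2) / nr,
    LRE   = sum(cnt * l^2) / nr,
    SRE   = sum(cnt / l^2) / nr,
    FIR   = nr / n_pixels,
    LGRE  = sum(cnt / g1^2) / nr,
    HGRE  = sum(cnt * g1^2) / nr,
    SRLGE = sum(cnt / (g1^2 * l^2)) / nr,
    SRHGE = sum(cnt * g1^2 / l^2) / nr,
    LRLGE = sum(cnt * l^2 / g1^2) / nr,
    LRHGE = sum(cnt * g1^2 * l^2) / nr)
}

#' All GRLM texture features of a quantized ROI
#'
#' Eleven run-length statistics per direction, four directions: 44 named
#' values (`"RLN_0"`, ..., `"LRHGE_135"`).
#'
#' @param q a `quantized_roi`.
#' @param cfg a `grlm_config`.
#' @return named numeric vector of length 44.
#' @export
grlm_features <- function(q, cfg = grlm_config()) {
  n_pixels <- sum(q$mask)
  out <- numeric(0)
  for (dir in cfg$directions) {
    st <- grlm_stats(grlm(q, dir), n_pixels)
    names(st) <- sprintf("%s_%s", grlm_feature_names, dir)
    out <- c(out, st[sprintf("%s_%s", grlm_feature_names, dir)])
  }
  out
}
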