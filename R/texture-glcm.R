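#' GLCM extraction configuration
#'
#' Defaults follow the pipeline's inventory: four distances (1..4 pixels)
#' in four directions, expressed as raw pixel offsets `(drow, dcol)`:
#' `(0, d)`, `(-d, d)`, `(-d, 0)`, `(-d, -d)`. Feature names carry the
#' offsets themselves (e.g. `"S(0,1) CON"`) because angle labels are
#' convention-dependent. A per-distance directional mean of every feature
#' is appended, giving 19 features x 4 distances x (4 directions + mean)
#' = 380 values.
#'
#' @param distances integer vector of pixel distances (default `1:4`).
#' @param directions list of unit `(drow, dcol)` offsets.
#' @param n_levels number of gray levels the quantized ROI uses.
#' @param symmetric logical; accumulate each pair in both orders.
#' @param include_directional_mean logical; append per-distance means.
#' @return an object of class `glcm_config`.
#' @export
glcm_config <- function(distances = 1:4,
                        directions = list(c(0L, 1L), c(-1L, 1L),
                                          c(-1L, 0L), c(-1L, -1L)),
                        n_levels = 256L, symmetric = TRUE,
                        include_directional_mean = TRUE) {
  stopifnot(all(distances >= 1),
            all(vapply(directions, function(d) any(d != 0), logical(1))))
  structure(list(distances = as.integer(distances), directions = directions,
                 n_levels = as.integer(n_levels), symmetric = symmetric,
                 include_directional_mean = include_directional_mean),
            class = "glcm_config")
}

glcm_feature_names <- c("ACOR", "CON", "COR", "CP", "CS", "DIS", "ASM",
                        "ENT", "IDM", "MP", "SOS", "SA", "SV", "SE",
                        "DV", "DE", "IMC", "IDN", "IDMN")

#' Gray level co-occurrence matrix at one offset
#'
#' Counts ordered pairs `(level at p, level at p + offset)` over all pixel
#' pairs whose two ends both lie inside the mask, optionally adds the
#' transpose (symmetric GLCM), and normalizes to sum one. The matrix is
#' returned sparsely as a data frame of occupied cells.
#'
#' @param q a `quantized_roi`.
#' @param offset integer `(drow, dcol)` displacement.
#' @param symmetric logical; if `TRUE` each pair also counts reversed.
#' @return data frame with columns `i`, `j` (gray levels, 0-based) and
#'   `p` (probability), with attribute `n_levels`.
#' @export
glcm <- function(q, offset, symmetric = TRUE) {
  stopifnot(inherits(q, "quantized_roi"), length(offset) == 2L)
  g <- q$grid
  nr <- nrow(g); nc <- ncol(g)
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  if (dr == 0L && dc == 0L) stop("glcm: offset must be non-zero")
  r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
  if (r1 > r2 || c1 > c2)
    stop("glcm: no valid pixel pairs for this offset")
  a <- g[r1:r2, c1:c2, drop = FALSE]
  b <- g[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop("glcm: no valid pixel pairs inside the mask for this offset")
  i <- a[ok]; j <- b[ok]
  if (symmetric) {
    tmp <- i; i <- c(i, j); j <- c(j, tmp)
  }
  G <- q$n_levels
  key <- i * G + j
  cnt <- table(key)                      # named counts by key
  k <- as.numeric(names(cnt))
  out <- data.frame(i = k %/% G, j = k %% G,
                    p = as.numeric(cnt) / sum(cnt))
  attr(out, "n_levels") <- G
  out
}

# All 19 co-occurrence statistics from one sparse normalized GLCM.
# Entropies use the natural logarithm; degenerate denominators
# (zero marginal variance / zero marginal entropy) yield 0.
glcm_stats <- function(cells) {
  G <- attr(cells, "n_levels")
  i <- cells$i; j <- cells$j; p <- cells$p
  px <- rowsum(p, i); ui <- as.numeric(rownames(px)); px <- px[, 1]
  py <- rowsum(p, j); uj <- as.numeric(rownames(py)); py <- py[, 1]
  mx <- sum(ui * px); my <- sum(uj * py)
  sx <- sqrt(sum((ui - mx)^2 * px)); sy <- sqrt(sum((uj - my)^2 * py))
  acor <- sum(i * j * p)
  d2 <- (i - j)^2
  con <- sum(d2 * p)
  cor <- if (sx * sy > 0) (acor - mx * my) / (sx * sy) else 0
  cp <- sum((i + j - mx - my)^4 * p)
  cs <- sum((i + j - mx - my)^3 * p)
  dis <- sum(abs(i - j) * p)
  asm <- sum(p^2)
  ent <- -sum(p * log(p))
  idm <- sum(p / (1 + d2))
  mp <- max(p)
  sos <- sum((i - mx)^2 * p)
  psum <- rowsum(p, i + j); ks <- as.numeric(rownames(psum)); psum <- psum[, 1]
  sa <- sum(ks * psum)
  sv <- sum((ks - sa)^2 * psum)
  se <- -sum(psum * log(psum))
  pdif <- rowsum(p, abs(i - j)); kd <- as.numeric(rownames(pdif)); pdif <- pdif[, 1]
  md <- sum(kd * pdif)
  dv <- sum((kd - md)^2 * pdif)
  de <- -sum(pdif * log(pdif))
  hx <- -sum(px * log(px)); hy <- -sum(py * log(py))
  lx <- log(px)                          # names: character gray levels
  ly <- log(py)
  hxy1 <- -sum(p * (lx[as.character(i)] + ly[as.character(j)]))
  imc <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  idn <- sum(p / (1 + abs(i - j) / G))
  idmn <- sum(p / (1 + d2 / G^2))
  c(ACOR = acor, CON = con, COR = cor, CP = cp, CS = cs, DIS = dis,
    ASM = asm, ENT = ent, IDM = idm, MP = mp, SOS = sos, SA = sa,
    SV = sv, SE = se, DV = dv, DE = de, IMC = imc, IDN = idn, IDMN = idmn)
}

#' All GLCM texture features of a quantized ROI
#'
#' Computes the 19 co-occurrence statistics for every configured distance
#' and direction, then (by default) appends their per-distance arithmetic
#' mean across the four directions, yielding 380 named values under the
#' default configuration.
#'
#' @param q a `quantized_roi`.
#' @param cfg a `glcm_config`.
#' @return named numeric vector.
#' @export
glcm_features <- function(q, cfg = glcm_config()) {
  out <- numeric(0)
  for (d in cfg$distances) {
    block <- matrix(NA_real_, length(cfg$directions),
                    length(glcm_feature_names))
    for (k in seq_along(cfg$directions)) {
      off <- cfg$directions[[k]] * d
      st <- glcm_stats(glcm(q, off, symmetric = cfg$symmetric))
      block[k, ] <- st
      names(st) <- sprintf("S(%d,%d) %s", off[1], off[2],
                           glcm_feature_names)
      out <- c(out, st)
    }
    if (cfg$include_directional_mean) {
      m <- colMeans(block)
      names(m) <- sprintf("S(%d,mean) %s", d, glcm_feature_names)
      out <- c(out, m)
    }
  }
  out
}
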