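# Independent brute-force oracles used to validate the package's
# implementations. Deliberately written with naive loops and direct
# formulas, sharing no code with the implementation.

# Exhaustive Otsu: try every interior bin edge as a threshold and compute
# the between-class variance directly from the pixel partition.
oracle_otsu <- function(pixels, n_bins = 256L) {
  lo <- min(pixels); hi <- max(pixels)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  best <- -Inf; best_t <- NA
  for (t in edges[2:n_bins]) {
    below <- pixels[pixels < t]; above <- pixels[pixels >= t]
    if (!length(below) || !length(above)) next
    w0 <- length(below) / length(pixels); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(below) - mean(above))^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
  }
  best_t
}

# Flood-fill labeling with an explicit coordinate queue (8-connectivity),
# returning the largest component (raster-order tie-break).
oracle_largest8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  best <- NULL; best_size <- -1
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!mask[r, cc] || seen[r, cc]) next
    comp <- matrix(FALSE, nr, nc)
    queue <- list(c(r, cc)); seen[r, cc] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      comp[p[1], p[2]] <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
    if (sum(comp) > best_size) { best_size <- sum(comp); best <- comp }
  }
  best
}

# Dense GLCM by an explicit pixel-pair loop, then the 19 statistics by
# direct textbook formulas over the dense matrix.
oracle_glcm_features <- function(q, offset, symmetric = TRUE) {
  g <- q$grid; G <- q$n_levels
  M <- matrix(0, G, G)
  nr <- nrow(g); nc <- ncol(g)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    r2 <- r + offset[1]; c2 <- cc + offset[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    if (is.na(g[r, cc]) || is.na(g[r2, c2])) next
    M[g[r, cc] + 1, g[r2, c2] + 1] <- M[g[r, cc] + 1, g[r2, c2] + 1] + 1
  }
  if (symmetric) M <- M + t(M)
  stopifnot(sum(M) > 0)
  P <- M / sum(M)
  iv <- 0:(G - 1)
  px <- rowSums(P); py <- colSums(P)
  mx <- sum(iv * px); my <- sum(iv * py)
  sx <- sqrt(sum((iv - mx)^2 * px)); sy <- sqrt(sum((iv - my)^2 * py))
  II <- matrix(iv, G, G); JJ <- t(II)
  ent0 <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  psum <- sapply(0:(2 * G - 2), function(k) sum(P[II + JJ == k]))
  pdif <- sapply(0:(G - 1), function(k) sum(P[abs(II - JJ) == k]))
  sa <- sum((0:(2 * G - 2)) * psum)
  md <- sum((0:(G - 1)) * pdif)
  hxy1 <- { pp <- outer(px, py); ok <- P > 0 & pp > 0
            -sum(P[ok] * log(pp[ok])) }
  hx <- ent0(px); hy <- ent0(py)
  c(ACOR = sum(II * JJ * P),
    CON = sum((II - JJ)^2 * P),
    COR = if (sx * sy > 0) (sum(II * JJ * P) - mx * my) / (sx * sy) else 0,
    CP = sum((II + JJ - mx - my)^4 * P),
    CS = sum((II + JJ - mx - my)^3 * P),
    DIS = sum(abs(II - JJ) * P),
    ASM = sum(P^2),
    ENT = ent0(P),
    IDM = sum(P / (1 + (II - JJ)^2)),
    MP = max(P),
    SOS = sum((II - mx)^2 * P),
    SA = sa,
    SV = sum(((0:(2 * G - 2)) - sa)^2 * psum),
    SE = ent0(psum),
    DV = sum(((0:(G - 1)) - md)^2 * pdif),
    DE = ent0(pdif),
    IMC = if (max(hx, hy) > 0) (ent0(P) - hxy1) / max(hx, hy) else 0,
    IDN = sum(P / (1 + abs(II - JJ) / G)),
    IDMN = sum(P / (1 + (II - JJ)^2 / G^2)))
}

# AUC by explicit concordant/tied pair counting.
oracle_auc <- function(pos, neg) {
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p by enumeration of all label assignments.
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  U_of <- function(idx) {
    r <- rank(all_v)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- U_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  Uall <- apply(combos, 2, U_of)
  mean(pmin(Uall, n1 * n2 - Uall) <= min(obs, n1 * n2 - obs) + 1e-9)
}

# Fisher's exact two-sided p (point-probability method) by full
# hypergeometric enumeration.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square statistic by the closed form.
oracle_chisq_stat <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
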