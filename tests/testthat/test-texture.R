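test_that("histogram moments follow the population (n-denominator) convention", {
  qc <- make_fixture("constant", c(4, 4))
  expect_equal(unname(histogram_features(qc)),
               c(128, 0, 0, 0))
  # symmetric two-point distribution
  g <- matrix(c(rep(0L, 8), rep(255L, 8)), 4, 4)
  h <- histogram_features(qroi_from(g, 256))
  expect_equal(unname(h["Mean"]), 127.5)
  expect_equal(unname(h["Variance"]), 127.5^2)
  expect_equal(unname(h["Skewness"]), 0)
  expect_equal(unname(h["Kurtosis"]), -2)  # two-point excess kurtosis
  # direct arithmetic
  g2 <- matrix(c(0L, 0L, 0L, 255L), 2, 2)
  expect_equal(unname(histogram_features(qroi_from(g2, 256))["Mean"]), 63.75)
})

test_that("co-occurrence matrices match hand counts and normalize to one", {
  q2 <- make_fixture("constant", c(2, 2))
  P <- glcm(q2, c(0, 1))
  expect_equal(nrow(P), 1)
  expect_equal(P$p, 1)
  expect_equal(P$i, P$j)

  qc <- make_fixture("checkerboard", c(4, 4), levels = 2)
  Pc <- glcm(qc, c(0, 1), symmetric = TRUE)
  # 12 horizontal pairs, all dissimilar: P(0,1) = P(1,0) = 0.5
  expect_equal(Pc$p[order(Pc$i)], c(0.5, 0.5))
  expect_setequal(paste(Pc$i, Pc$j), c("0 1", "1 0"))
  st <- texomri:::glcm_stats(Pc)
  expect_equal(unname(st["CON"]), 1)
  expect_equal(unname(st["ASM"]), 0.5)

  qr <- rand_qroi(7, 7, 8, seed = 42)
  expect_equal(sum(glcm(qr, c(-2, 1))$p), 1)
  # thin mask with no valid pairs errors
  thin <- qroi_from(matrix(0:3, 1, 4), 8)
  expect_error(glcm(thin, c(-1, 0)), "pairs")
})

test_that("every GLCM feature equals the brute-force pair-loop oracle", {
  cfg <- glcm_config(n_levels = 8)
  for (s in 1:20) {
    q <- rand_qroi(6, 6, 8, seed = 400 + s)
    for (d in 1:4) for (dir in cfg$directions) {
      off <- dir * d
      got <- texomri:::glcm_stats(glcm(q, off, symmetric = TRUE))
      want <- oracle_glcm_features(q, off, symmetric = TRUE)
      expect_equal(got, want, tolerance = 1e-10,
                   info = sprintf("seed %d offset (%d,%d)", s, off[1], off[2]))
    }
  }
})

test_that("GLCM directional features permute consistently under 90-degree rotation", {
  q <- rand_qroi(8, 8, 8, seed = 77)
  rot <- qroi_from(t(q$grid[nrow(q$grid):1, ]), 8)  # clockwise rotation
  fv <- glcm_features(q, glcm_config(n_levels = 8))
  fr <- glcm_features(rot, glcm_config(n_levels = 8))
  # displacement (dr,dc) maps to (dc,-dr); symmetric GLCM identifies +/- offsets
  for (d in 1:4) for (f in texomri:::glcm_feature_names) {
    expect_equal(fv[[sprintf("S(0,%d) %s", d, f)]],
                 fr[[sprintf("S(-%d,0) %s", d, f)]], tolerance = 1e-12)
    expect_equal(fv[[sprintf("S(-%d,%d) %s", d, d, f)]],
                 fr[[sprintf("S(-%d,-%d) %s", d, d, f)]], tolerance = 1e-12)
    # the directional mean is rotation-invariant
    expect_equal(fv[[sprintf("S(%d,mean) %s", d, f)]],
                 fr[[sprintf("S(%d,mean) %s", d, f)]], tolerance = 1e-12)
  }
})

test_that("directional-mean GLCM features equal the mean of the four directions", {
  q <- rand_qroi(7, 7, 8, seed = 5)
  fv <- glcm_features(q, glcm_config(n_levels = 8))
  for (d in 1:4) for (f in texomri:::glcm_feature_names) {
    dirs <- c(fv[[sprintf("S(0,%d) %s", d, f)]],
              fv[[sprintf("S(-%d,%d) %s", d, d, f)]],
              fv[[sprintf("S(-%d,0) %s", d, f)]],
              fv[[sprintf("S(-%d,-%d) %s", d, d, f)]])
    expect_identical(fv[[sprintf("S(%d,mean) %s", d, f)]], mean(dirs))
  }
})

test_that("run-length features follow closed forms and conserve pixel mass", {
  # single row of identical values: one run of length N
  N <- 9L
  row_q <- qroi_from(matrix(3L, 1, N), 8)
  st <- texomri:::grlm_stats(grlm(row_q, "0"), N)
  expect_equal(unname(st["LRE"]), N^2)
  expect_equal(unname(st["SRE"]), 1 / N^2)
  expect_equal(unname(st["FIR"]), 1 / N)
  # checkerboard along 0 and 90 degrees: all runs have length one
  qc <- make_fixture("checkerboard", c(4, 4), levels = 2)
  for (dir in c("0", "90")) {
    stc <- texomri:::grlm_stats(grlm(qc, dir), 16)
    expect_equal(unname(stc["SRE"]), 1)
    expect_equal(unname(stc["LRE"]), 1)
    expect_equal(unname(stc["FIR"]), 1)
  }
  # conservation: sum(count * length) = masked pixels, every direction
  for (s in 1:25) {
    q <- rand_qroi(7, 6, 4, seed = 500 + s)
    q$mask <- rand_mask(7, 6, 0.7, seed = 600 + s)
    q$grid[!q$mask] <- NA_integer_
    if (!any(q$mask)) next
    for (dir in c("0", "45", "90", "135")) {
      rm <- grlm(q, dir)
      expect_equal(sum(rm$count * rm$len), sum(q$mask))
    }
  }
})

test_that("wavelet subband energies satisfy Parseval for all three filters", {
  withr::with_seed(8, x <- matrix(rnorm(32 * 32), 32, 32))
  for (w in c("haar", "db2", "sym4")) {
    cur <- x; detail <- 0
    for (lev in 1:4) {
      d <- dwt2(cur, w)
      detail <- detail + sum(d$horizontal^2) + sum(d$vertical^2) +
        sum(d$diagonal^2)
      cur <- d$LL
    }
    expect_equal(detail + sum(cur^2), sum(x^2), tolerance = 1e-8)
  }
})

test_that("constant images put all wavelet energy into the approximation", {
  q <- make_fixture("constant", c(16, 16))
  fv <- dwt_features(q)
  for (w in c("haar", "db2", "sym4")) for (lev in 1:4) {
    expect_equal(fv[[sprintf("%s HH_%d", w, lev)]], 0, tolerance = 1e-20)
    expect_equal(fv[[sprintf("%s DH_%d", w, lev)]], 0, tolerance = 1e-20)
    expect_equal(fv[[sprintf("%s HD_%d", w, lev)]], 0, tolerance = 1e-20)
  }
  expect_equal(fv[["haar LL_4"]], 1, tolerance = 1e-12)
  expect_equal(fv[["haar LLmean_1"]], 2 * 128, tolerance = 1e-12)
})

test_that("a single impulse distributes first-level Haar energy equally", {
  q <- make_fixture("impulse", c(16, 16))
  fv <- dwt_features(q, dwt_config("haar"))
  # hand filtering of the 2x2 block holding the impulse of height v:
  # each subband coefficient is +/- v/2, so each subband carries v^2/4
  expect_equal(fv[["haar HH_1"]], 0.25, tolerance = 1e-12)
  expect_equal(fv[["haar DH_1"]], 0.25, tolerance = 1e-12)
  expect_equal(fv[["haar HD_1"]], 0.25, tolerance = 1e-12)
  expect_equal(fv[["haar LL_1"]], 0.25, tolerance = 1e-12)
})

test_that("small masks reduce wavelet depth with a warning and NA sentinels", {
  q <- rand_qroi(6, 6, 8, seed = 3)
  expect_warning(fv <- dwt_features(q, dwt_config("haar")), "reducing")
  expect_true(all(is.na(fv[sprintf("haar %s_%d", c("HH", "DH", "HD"), 3)])))
  expect_false(anyNA(fv[sprintf("haar %s_1", c("HH", "DH", "HD"))]))
})

test_that("the default inventory has 488 uniquely named features per phase", {
  q <- rand_qroi(20, 20, 256, seed = 10)
  fv <- extract_features(q)
  expect_length(fv, 488)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_identical(fv, extract_features(rand_qroi(20, 20, 256, seed = 10)))
  out <- extract_all(q, q, q)
  expect_named(out, c("pre", "post", "subtraction"))
  expect_identical(out$pre, out$subtraction)
  # stage errors are tagged with the offending phase
  thin <- qroi_from(matrix(rep(0:3, 2), 1, 8), 256)
  expect_error(extract_all(q, q, thin), "subtraction phase")
})
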