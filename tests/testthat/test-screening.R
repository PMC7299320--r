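test_that("Lilliefors-corrected KS test calibrates on normal and skewed samples", {
  withr::with_seed(1, x <- rnorm(500))
  expect_gte(ks_normal(x)$p.value, 0.05)
  withr::with_seed(2, y <- rexp(500))
  expect_lt(ks_normal(y)$p.value, 0.05)
  kc <- ks_normal(rep(5, 10))
  expect_equal(kc$p.value, 0)
  expect_true(kc$degenerate)
  expect_error(ks_normal(c(1, 2, 3)), "n >= 4")
})

test_that("the in-package Lilliefors test agrees with the nortest reference", {
  for (s in 1:20) {
    withr::with_seed(700 + s, x <- rnorm(15 + s * 7, sd = 1 + s / 5)^
                       (if (s %% 2) 1 else 2))
    got <- ks_normal(x)
    ref <- nortest::lillie.test(x)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("group comparison picks the gated test and matches exact references", {
  # identical non-normal groups: U = n1 n2 / 2 and p = 1
  withr::with_seed(3, z <- rexp(20)^2)
  rec <- compare_feature(z, z, name = "f")
  expect_identical(rec$test_used, "mann_whitney")
  expect_equal(rec$statistic, 200)
  expect_equal(rec$p_value, 1)
  # enumeration example: {4,5,6} vs {1,2,3}
  mw <- texomri:::mann_whitney(c(4, 5, 6), c(1, 2, 3))
  expect_equal(mw$statistic, 9)
  expect_equal(mw$p.value, 0.1)
  expect_equal(mw$p.value, oracle_mw_exact_p(c(4, 5, 6), c(1, 2, 3)))
  # identical normal groups: t = 0, p = 1
  withr::with_seed(4, g <- rnorm(20))
  rec2 <- compare_feature(g, g, name = "f")
  expect_identical(rec2$test_used, "t")
  expect_equal(rec2$statistic, 0)
  expect_equal(rec2$p_value, 1)
})

test_that("the pooled t statistic equals the textbook formula", {
  pt_ <- texomri:::pooled_t(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(pt_$statistic, -sqrt(3), tolerance = 1e-12)
  expect_equal(pt_$p.value, 2 * pt(-sqrt(3), 6), tolerance = 1e-12)
  ref <- t.test(c(1, 2, 3, 4), c(2, 4, 6, 8), var.equal = TRUE)
  expect_equal(pt_$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(pt_$p.value, ref$p.value, tolerance = 1e-12)
})

test_that("Mann-Whitney normal approximation tracks the exact null closely", {
  for (s in 1:30) {
    withr::with_seed(800 + s, { x <- rnorm(8); y <- rnorm(8) })
    pe <- texomri:::mann_whitney(x, y)$p.value                 # exact branch
    pa <- texomri:::mann_whitney(x, y, exact_limit = 0)$p.value
    # the continuity-corrected normal approximation deviates by slightly
    # more than 0.01 for mid-range p at n = 8; immaterial for decisions
    expect_lte(abs(pe - pa), 0.015)
  }
  # exact branch agrees with full enumeration on tiny samples
  for (s in 1:5) {
    withr::with_seed(900 + s, { x <- rnorm(4); y <- rnorm(5) })
    expect_equal(texomri:::mann_whitney(x, y)$p.value,
                 oracle_mw_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("rank-based screening is invariant to monotone feature transforms", {
  withr::with_seed(5, { x <- rexp(30); y <- rexp(25) * 1.5 })
  p1 <- compare_feature(x, y, name = "f")
  p2 <- compare_feature(x^3, y^3, name = "f")  # strictly monotone map
  expect_identical(p1$test_used, "mann_whitney")
  expect_equal(p1$p_value, p2$p_value)
  expect_equal(p1$statistic, p2$statistic)
})

test_that("screening keeps exactly the sub-threshold features and flags NAs", {
  tab <- noise_table(p = 8, seed = 6)
  scr <- screen_table(tab, screening_config(alpha_screen = 1))
  expect_true(all(scr$kept))            # alpha = 1 keeps everything defined
  expect_identical(attr(scr, "kept"), scr$feature)
  expect_true(all(scr$kept == (scr$p_value < 1)))
  # a feature with any undefined value is recorded but never kept
  tab2 <- noise_table(p = 4, seed = 7)
  tab2$features[3, 2] <- NA
  scr2 <- screen_table(tab2)
  expect_identical(scr2$test_used[2], "none")
  expect_false(scr2$kept[2])
  # single-class tables are rejected
  bad <- feature_table(tab$features[1:26, ], rep("positive", 26))
  expect_error(screen_table(bad), "both classes")
})

test_that("a three-pooled-sd shift is detected in every replicate", {
  hits <- vapply(1:20, function(s) {
    tab <- noise_table(p = 10, shift = 3, seed = 1000 + s)
    "f01" %in% attr(screen_table(tab), "kept")
  }, logical(1))
  expect_true(all(hits))
})

test_that("contingency tests choose the branch by expected counts", {
  ht <- contingency_test(matrix(c(10, 10, 10, 10), 2))
  expect_identical(ht$method, "chi_square")
  expect_equal(ht$statistic, 0)
  expect_equal(ht$p_value, 1)
  # small expected counts trigger Fisher; p matches full enumeration
  tabf <- matrix(c(1, 8, 8, 1), 2)
  htf <- contingency_test(tabf)
  expect_identical(htf$method, "fisher_exact")
  expect_equal(htf$p_value, oracle_fisher_p(tabf), tolerance = 1e-12)
  # chi-square branch equals the closed form
  tab2 <- matrix(c(20, 15, 10, 25), 2)
  ht2 <- contingency_test(tab2)
  expect_equal(ht2$statistic, oracle_chisq_stat(tab2), tolerance = 1e-12)
  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("receptor-status style tables reproduce the expected significance", {
  er <- matrix(c(24, 28, 35, 5), 2)    # strongly associated
  expect_lt(contingency_test(er)$p_value, 0.001)
  ki67 <- matrix(c(41, 11, 28, 12), 2) # not associated
  expect_gt(contingency_test(ki67)$p_value, 0.05)
})

test_that("unit-interval standardization is exact, idempotent and flags constants", {
  X <- cbind(a = c(2, 4, 6), b = c(0, 0.25, 1), cst = c(3, 3, 3))
  tab <- feature_table(X, c("positive", "negative", "positive"))
  out <- standardize_unit_interval(tab)
  expect_equal(unname(out$features[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(out$features[, "b"]), c(0, 0.25, 1))  # unchanged
  expect_equal(unname(out$features[, "cst"]), rep(0.5, 3))
  expect_identical(attr(out, "constant_features"), "cst")
  expect_equal(standardize_unit_interval(out)$features, out$features)
})

test_that("the in-fold fast screening path reproduces the full record decisions", {
  for (s in 1:3) {
    tab <- noise_table(n_pos = 15, n_neg = 12, p = 30, shift = 1.2,
                       seed = 1100 + s)
    # mix in skewed columns so both test branches are exercised
    tab$features[, 11:20] <- exp(tab$features[, 11:20])
    kept_full <- attr(screen_table(tab), "kept")
    kept_fast <- texomri:::screen_kept_fast(
      tab$features, which(tab$labels == "positive"),
      which(tab$labels == "negative"), screening_config())
    expect_identical(sort(kept_full), sort(kept_fast))
  }
})
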