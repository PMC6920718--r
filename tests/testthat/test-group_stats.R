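# Pointwise t-tests, significance banding, normality screening and
# normalized summary tables.

mk_profiles <- function(m) {
  grid <- 59 + seq_len(ncol(m))
  lapply(seq_len(nrow(m)), function(i)
    structure(data.frame(percent = grid, value = m[i, ]),
              class = c("morph_profile", "data.frame")))
}

test_that("pointwise t-test agrees with stats::t.test exactly", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  pa <- mk_profiles(matrix(a, 4, 3))
  pb <- mk_profiles(matrix(b, 4, 3))
  gr <- ttest_profile(pa, pb)
  oracle <- t.test(a, b, var.equal = TRUE)
  expect_equal(gr$t[1], unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(gr$p[1], oracle$p.value, tolerance = 1e-12)
  expect_equal(gr$t[1], -1.095445, tolerance = 1e-6)
  expect_equal(gr$p[1], 0.3153336, tolerance = 1e-6)
  expect_equal(gr$se_a[1], sd(a) / sqrt(4), tolerance = 1e-12)
  # Welch option against the oracle too
  grw <- ttest_profile(pa, pb, welch = TRUE)
  ow <- t.test(a, b)
  expect_equal(grw$p[1], ow$p.value, tolerance = 1e-12)
})

test_that("identical groups give zero differences and p = 1", {
  m <- matrix(rnorm(4 * 41), 4, 41)
  gr <- ttest_profile(mk_profiles(m), mk_profiles(m))
  expect_equal(gr$diff, rep(0, 41))
  expect_equal(gr$p, rep(1, 41))
  expect_true(all(gr$band == "NS"))
})

test_that("swapping groups negates t and diff, preserves p", {
  set.seed(3)
  A <- matrix(rnorm(5 * 41, 10), 5, 41)
  B <- matrix(rnorm(6 * 41, 10.5), 6, 41)
  g1 <- ttest_profile(mk_profiles(A), mk_profiles(B))
  g2 <- ttest_profile(mk_profiles(B), mk_profiles(A))
  expect_equal(g1$t, -g2$t, tolerance = 1e-12)
  expect_equal(g1$diff, -g2$diff, tolerance = 1e-12)
  expect_equal(g1$p, g2$p, tolerance = 1e-12)
})

test_that("degenerate zero-variance points are flagged, p in (0, 1]", {
  A <- matrix(5, 3, 2); B <- matrix(c(5, 5, 5, 7, 7, 7), 3, 2)
  gr <- ttest_profile(mk_profiles(A), mk_profiles(B))
  expect_equal(gr$p[1], 1)
  expect_gt(gr$p[2], 0)
  expect_lt(gr$p[2], 1e-10)
  expect_true(all(gr$degenerate))
})

test_that("significance bands follow the half-open cutpoints exactly", {
  p <- c(1, 0.05, 0.049999, 0.01, 0.009999, 0.001, 0.0009999, 1e-4,
         0.99e-4, 5e-5)
  expect_equal(as.character(band_classify(p)),
               c("NS", "NS", "p05", "p05", "p01", "p01", "p001", "p001",
                 "p0001", "p0001"))
  expect_error(band_classify(0), "0, 1")
  expect_error(band_classify(1.2), "0, 1")
  # banding is a monotone step function of p
  ps <- sort(runif(200, 1e-6, 1))
  expect_true(all(diff(as.integer(band_classify(ps))) <= 0))
})

test_that("normality screen flags degenerate and bimodal samples", {
  set.seed(5)
  res <- normality_screen(list(normal = rnorm(20, 10, 1),
                               flat = rep(3, 8),
                               bimodal = c(rep(0, 4), rep(100, 4)),
                               tiny = c(1, 2, 3)))
  expect_false(res$flagged[res$group == "normal"])
  expect_true(res$flagged[res$group == "flat"])
  expect_true(res$flagged[res$group == "bimodal"])
  expect_match(res$note[res$group == "tiny"], "n < 4")
  # nominal level: 8 normal draws rarely flagged
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    normality_screen(list(g = rnorm(8)))$flagged
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("null simulation rejects at close to the nominal 5% level", {
  set.seed(17)
  grid <- seq(60, 100, 1)
  base <- data.frame(percent = grid, value = 0.3)
  hits <- 0; total <- 0
  for (rep in 1:300) {
    sim <- simulate_groups(base, NULL, n_per_group = 8, noise_cv = 0.1,
                           seed = rep)
    gr <- ttest_profile(sim_profiles(sim, "value", "Control"),
                        sim_profiles(sim, "value", "SCI"))
    hits <- hits + sum(gr$p < 0.05)
    total <- total + nrow(gr)
  }
  rate <- hits / total
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})

test_that("normalized tables recover an imposed deficit with stars", {
  set.seed(23)
  a <- data.frame(bv_tv = rnorm(8, 0.30, 0.03),
                  tb_th = rnorm(8, 0.09, 0.009),
                  zero = rep(0, 8))
  b <- data.frame(bv_tv = rnorm(8, 0.30 * 0.43, 0.013),
                  tb_th = rnorm(8, 0.09, 0.009),
                  zero = rep(0, 8))
  tab <- normalized_group_table(a, b)
  expect_equal(tab$norm_control, c(1, 1, NA))
  bv <- tab[tab$parameter == "bv_tv", ]
  expect_lt(abs(bv$norm_test - 0.43), 0.05)
  expect_match(bv$stars, "\\*")
  expect_equal(tab$flag[tab$parameter == "zero"], "zero-control-mean")
  same <- normalized_group_table(a["bv_tv"], a["bv_tv"])
  expect_equal(same$norm_test, 1)
  expect_equal(same$stars, "")
})

test_that("significant bands require contiguous runs", {
  gr <- data.frame(percent = 60:80, p = 1)
  gr$p[c(5, 10, 11, 12, 18)] <- 0.001
  bands <- significant_bands(gr)
  expect_equal(nrow(bands), 1)            # isolated points are not bands
  expect_equal(bands$lo_percent, 69)
  expect_equal(bands$hi_percent, 71)
})
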