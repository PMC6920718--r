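# Profile interpolation, Trabecular Extent and group difference profiles.

native_table <- function(percent, value)
  data.frame(percent = percent, value = value)

test_that("cubic interpolation reproduces constants and linear trends", {
  x <- seq(60, 100, by = 0.02)
  tab <- native_table(x, rep(5, length(x)))
  pr <- build_profile(tab, "value", grid = seq(60, 100, 1))
  expect_equal(pr$value, rep(5, 41))
  tab2 <- native_table(x, 0.3 * x - 7)
  pr2 <- build_profile(tab2, "value", grid = seq(60, 100, 1))
  expect_equal(pr2$value, 0.3 * seq(60, 100, 1) - 7, tolerance = 1e-9)
})

test_that("interpolation tracks a sinusoid to under 1e-3 of its amplitude", {
  x <- seq(60, 100, by = 0.02)
  f <- function(p) sin(p / 3)
  pr <- build_profile(native_table(x, f(x)), "value", grid = seq(60, 100, 1))
  expect_lt(max(abs(pr$value - f(seq(60, 100, 1)))), 1e-3)
})

test_that("grid values at native positions equal the native values", {
  x <- seq(60, 100, by = 0.25)
  y <- cos(x / 5) + x / 50
  pr <- build_profile(native_table(x, y), "value", grid = x[seq(1, 161, 8)])
  expect_equal(pr$value, y[seq(1, 161, 8)], tolerance = 1e-9)
})

test_that("no extrapolation beyond the covered native range", {
  x <- seq(62, 95, by = 0.1)
  expect_error(build_profile(native_table(x, x), "value",
                             grid = seq(60, 100, 1)), "out-of-range")
  expect_error(build_profile(native_table(x, x), "missing_col"),
               "missing_col")
})

test_that("Tb.E reproduces the linear-profile hand solution", {
  # BA/TA linear from 0.40 at 91% down to 0 at 71%, L = 36.81 mm
  pct <- seq(60, 100, by = 0.02)
  ba <- pmax(0, pmin(0.40, 0.02 * (pct - 71)))
  te <- trabecular_extent(pct, ba, 36.81, reference_percent = 91)
  expect_equal(te$tbe_mm[te$threshold == 0.30], (91 - 86) / 100 * 36.81,
               tolerance = 1e-6)
  expect_equal(te$tbe_mm[te$threshold == 0.30], 1.8405, tolerance = 1e-4)
  expect_equal(te$tbe_mm[te$threshold == 0], 7.362, tolerance = 0.007)
  expect_false(any(te$censored))
  # mm and percent terms convert exactly by L/100
  expect_equal(te$tbe_mm, (91 - te$crossing_percent) * 36.81 / 100,
               tolerance = 1e-12)
})

test_that("unreached thresholds are censored, high thresholds give zero", {
  pct <- seq(60, 91, by = 0.1)
  te <- trabecular_extent(pct, rep(0.5, length(pct)), 36.81,
                          reference_percent = 91)
  t30 <- te[te$threshold == 0.30, ]
  expect_true(t30$censored)
  expect_equal(t30$tbe_mm, (91 - 60) / 100 * 36.81, tolerance = 1e-9)
  # threshold above the value at the reference level
  te2 <- trabecular_extent(pct, rep(0.2, length(pct)), 36.81, 91,
                           thresholds = c(0.30))
  expect_equal(te2$tbe_mm, 0)
  expect_equal(te2$flag, "below-at-reference")
})

test_that("Tb.E is monotone in threshold and matches a brute-force scan", {
  brute_first_crossing <- function(pct, v, ref, thr) {
    o <- order(pct, decreasing = TRUE)
    pct <- pct[o]; v <- v[o]
    keep <- pct <= ref
    pct <- pct[keep]; v <- v[keep]
    for (k in seq_along(v)) {
      if (v[k] <= thr) {
        if (v[k] == thr || k == 1) return(pct[k])
        t <- (v[k - 1] - thr) / (v[k - 1] - v[k])
        return(pct[k - 1] + t * (pct[k] - pct[k - 1]))
      }
    }
    NA
  }
  set.seed(11)
  for (rep in 1:100) {
    pct <- seq(60, 95, by = 0.05)
    peak <- runif(1, 0.31, 0.6)
    drop_at <- runif(1, 62, 90)
    v <- peak * pmin(1, pmax(0, (pct - drop_at) / (95 - drop_at)))
    v <- rev(cummax(rev(v)))  # monotone non-decreasing in percent
    te <- trabecular_extent(pct, v, 30, reference_percent = 95)
    expect_true(all(diff(te$tbe_mm) >= -1e-12))  # thresholds 0.3 -> 0
    for (thr in c(0.30, 0.10)) {
      bf <- brute_first_crossing(pct, v, 95, thr)
      got <- te$crossing_percent[te$threshold == thr]
      if (!is.na(bf)) expect_equal(got, bf, tolerance = 1e-9)
    }
  }
})

test_that("Tb.E_Abs reaches the most proximal positive sample", {
  pct <- seq(60, 95, by = 0.5)
  v <- rep(0, length(pct))
  v[pct >= 70] <- 0.2
  v[pct >= 62 & pct <= 63] <- 0.05   # isolated distal island of bone
  te <- trabecular_extent(pct, v, 10, reference_percent = 95)
  expect_equal(attr(te, "tbe_abs_mm"), (95 - 62) / 100 * 10)
  expect_gte(attr(te, "tbe_abs_mm"), te$tbe_mm[te$threshold == 0])
})

test_that("difference profiles subtract group means pointwise", {
  g <- seq(60, 100, 1)
  mk <- function(v) structure(data.frame(percent = g, value = v),
                              class = c("morph_profile", "data.frame"))
  a <- list(mk(rep(1, 41)), mk(rep(3, 41)))
  expect_equal(difference_profile(a, a)$diff, rep(0, 41))
  b <- lapply(a, function(p) mk(p$value + 0.5))
  d <- difference_profile(a, b)
  expect_equal(d$diff, rep(-0.5, 41))
  expect_true(all(d$sign == "negative"))
  bad <- list(mk(rep(1, 41)))
  bad[[1]]$percent <- g + 0.5
  expect_error(difference_profile(a, bad), "grid")
})
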