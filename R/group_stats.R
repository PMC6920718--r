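# Statistical layer: normality screening, pointwise two-sample t-tests along
# the percent grid, significance banding, and control-normalized summary
# tables.

#' Normality screening of per-group samples
#'
#' Runs Anderson-Darling and Lilliefors (Kolmogorov-Smirnov with estimated
#' parameters) normality tests on each group and flags a group when either
#' test rejects at the 0.05 level. Degenerate samples (zero spread) are
#' flagged without testing; groups below the minimum size are skipped with a
#' flag.
#'
#' @param samples Named list of numeric vectors, one per group.
#' @param alpha Rejection level (default 0.05).
#' @return Data frame: group, n, p_ad, p_ks, flagged, note.
#' @export
normality_screen <- function(samples, alpha = 0.05) {
  rows <- lapply(names(samples), function(g) {
    x <- samples[[g]]
    n <- length(x)
    if (n < 4)
      return(data.frame(group = g, n = n, p_ad = NA_real_, p_ks = NA_real_,
                        flagged = NA, note = "skipped: n < 4"))
    if (stats::sd(x) == 0)
      return(data.frame(group = g, n = n, p_ad = NA_real_, p_ks = NA_real_,
                        flagged = TRUE, note = "degenerate: zero variance"))
    p_ad <- if (n >= 8) nortest::ad.test(x)$p.value else NA_real_
    p_ks <- if (n >= 5) nortest::lillie.test(x)$p.value else NA_real_
    note <- if (n < 8) "AD needs n >= 8; KS only" else ""
    flagged <- any(c(p_ad, p_ks) < alpha, na.rm = TRUE)
    data.frame(group = g, n = n, p_ad = p_ad, p_ks = p_ks, flagged = flagged,
               note = note)
  })
  do.call(rbind, rows)
}

#' Significance band of a p-value
#'
#' Half-open bands matching the heat-map convention: NS for p >= .05,
#' then .05 > p >= .01, .01 > p >= .001, .001 > p >= .0001, and p < .0001.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Factor with levels NS, p05, p01, p001, p0001.
#' @export
band_classify <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("validation error: p-values must lie in (0, 1]")
  b <- ifelse(p >= 0.05, "NS",
       ifelse(p >= 0.01, "p05",
       ifelse(p >= 0.001, "p01",
       ifelse(p >= 0.0001, "p001", "p0001"))))
  factor(b, levels = c("NS", "p05", "p01", "p001", "p0001"))
}

# Vectorized classic (equal-variance) or Welch two-sample t-test over the
# columns of two matrices (rows = specimens, cols = grid points).
ttest_matrix <- function(A, B, welch = FALSE) {
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(ma))
  }
  t <- (ma - mb) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  p[degen & ma == mb] <- 1
  p[degen & ma != mb] <- .Machine$double.xmin
  t[degen & ma == mb] <- 0
  list(t = t, p = p, df = df, mean_a = ma, mean_b = mb,
       se_a = sqrt(va / na), se_b = sqrt(vb / nb), degenerate = degen)
}

#' Pointwise two-sample t-tests along the percent grid
#'
#' Classic Student's t-test for independent samples (equal variances) at each
#' grid point, with means, standard errors (SD/sqrt(n)), signed differences,
#' p-values and significance bands. No multiple-testing correction is applied
#' across grid points by default, matching the pointwise heat-map convention;
#' Holm adjustment is available via \code{adjust}.
#'
#' @param profiles_a,profiles_b Lists of \code{morph_profile}s on a shared
#'   grid (group a is the reference/control).
#' @param welch Use the Welch (unequal variance) test instead.
#' @param adjust "none" (default) or "holm" across grid points.
#' @return A \code{group_result} data frame: percent, mean_a, mean_b, se_a,
#'   se_b, diff, t, p, band, degenerate; attributes n_a, n_b.
#' @export
ttest_profile <- function(profiles_a, profiles_b, welch = FALSE,
                          adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  to_matrix <- function(ps) {
    g <- ps[[1]]$percent
    for (p in ps)
      if (!isTRUE(all.equal(p$percent, g)))
        stop("validation error: profiles are not on a shared grid")
    m <- vapply(ps, function(p) p$value, numeric(length(g)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(g))
    list(grid = g, m = t(m))
  }
  a <- to_matrix(profiles_a); b <- to_matrix(profiles_b)
  if (!isTRUE(all.equal(a$grid, b$grid)))
    stop("validation error: groups are on different grids")
  if (nrow(a$m) < 2 || nrow(b$m) < 2)
    stop("validation error: need at least 2 specimens per group")
  r <- ttest_matrix(a$m, b$m, welch = welch)
  p <- r$p
  if (adjust == "holm") p <- stats::p.adjust(p, method = "holm")
  out <- data.frame(percent = a$grid, mean_a = r$mean_a, mean_b = r$mean_b,
                    se_a = r$se_a, se_b = r$se_b,
                    diff = r$mean_a - r$mean_b, t = r$t, p = p,
                    band = band_classify(p), degenerate = r$degenerate)
  attr(out, "n_a") <- nrow(a$m)
  attr(out, "n_b") <- nrow(b$m)
  class(out) <- c("group_result", "data.frame")
  out
}

#' Maximal significant bands of a group result
#'
#' A significant band is a maximal run of at least \code{min_run} consecutive
#' grid points with p below \code{alpha}; isolated single points are not
#' reported as bands.
#'
#' @param result A \code{group_result}.
#' @param alpha Significance level.
#' @param min_run Minimum run length constituting a band.
#' @return Data frame: lo_percent, hi_percent, n_points.
#' @export
significant_bands <- function(result, alpha = 0.05, min_run = 2) {
  sig <- result$p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  data.frame(lo_percent = result$percent[starts[keep]],
             hi_percent = result$percent[ends[keep]],
             n_points = r$lengths[keep])
}

#' Control-normalized group summary table
#'
#' Normalizes each parameter by the control-group mean and attaches Student
#' t-test significance stars, the bar-chart style summary used for VOI-level
#' 3D parameters.
#'
#' @param metrics_a Data frame of per-specimen parameter values for the
#'   control group (one column per parameter, one row per specimen).
#' @param metrics_b Same for the comparison group.
#' @return Data frame: parameter, mean_control, norm_control, norm_test,
#'   se_norm_control, se_norm_test, p, stars, flag. Parameters whose control
#'   mean is zero are skipped with a flag.
#' @export
normalized_group_table <- function(metrics_a, metrics_b) {
  params <- intersect(names(metrics_a), names(metrics_b))
  params <- params[vapply(params, function(p) is.numeric(metrics_a[[p]]),
                          logical(1))]
  rows <- lapply(params, function(pn) {
    xa <- metrics_a[[pn]]; xb <- metrics_b[[pn]]
    ma <- mean(xa)
    if (ma == 0)
      return(data.frame(parameter = pn, mean_control = 0,
                        norm_control = NA_real_, norm_test = NA_real_,
                        se_norm_control = NA_real_, se_norm_test = NA_real_,
                        p = NA_real_, stars = "", flag = "zero-control-mean"))
    p <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      if (mean(xb) == ma) 1 else .Machine$double.xmin
    } else stats::t.test(xa, xb, var.equal = TRUE)$p.value
    stars <- if (p < 0.0001) "****" else if (p < 0.001) "***"
             else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
    data.frame(parameter = pn, mean_control = ma, norm_control = 1,
               norm_test = mean(xb) / ma,
               se_norm_control = stats::sd(xa) / sqrt(length(xa)) / ma,
               se_norm_test = stats::sd(xb) / sqrt(length(xb)) / ma,
               p = p, stars = stars, flag = "")
  })
  do.call(rbind, rows)
}

#' Plot a two-group profile comparison with a p-band strip
#'
#' Mean +/- SE curves for both groups with the pointwise significance bands
#' rendered as a colour strip underneath (heat-map style). Requires ggplot2.
#'
#' @param result A \code{group_result} from \code{\link{ttest_profile}}.
#' @param parameter Axis label for the parameter.
#' @return A ggplot object.
#' @export
plot_profile_comparison <- function(result, parameter = "value") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
  band_cols <- c(NS = "black", p05 = "blue", p01 = "green3",
                 p001 = "yellow3", p0001 = "red")
  ymin <- min(result$mean_a - result$se_a, result$mean_b - result$se_b)
  yrange <- diff(range(result$mean_a, result$mean_b))
  strip_y <- ymin - 0.08 * max(yrange, 1e-12)
  ggplot2::ggplot(result, ggplot2::aes(x = .data$percent)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_a - .data$se_a,
                                      ymax = .data$mean_a + .data$se_a),
                         fill = "blue", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_b - .data$se_b,
                                      ymax = .data$mean_b + .data$se_b),
                         fill = "red", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_a), colour = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_b), colour = "red") +
    ggplot2::geom_tile(ggplot2::aes(y = strip_y, fill = .data$band),
                       height = 0.05 * max(yrange, 1e-12)) +
    ggplot2::scale_fill_manual(values = band_cols, drop = FALSE) +
    ggplot2::labs(x = "percent bone length", y = parameter, fill = "p band") +
    ggplot2::theme_minimal()
}
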