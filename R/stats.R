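#' Least-squares regression with standard error of estimate
#'
#' Ordinary least squares of y on x with the Pearson correlation and the
#' standard error of estimate SEE = sqrt(sum(residual^2) / (n - 2)), the
#' summary conventionally reported in method-comparison studies.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return an object of class \code{lvq_regression} with \code{slope},
#'   \code{intercept}, \code{r}, \code{see}, \code{n} and a
#'   \code{degenerate} flag (TRUE when y has zero variance, in which case
#'   r is reported as 0 rather than NaN).
#' @export
linreg_see <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("regression needs at least 3 pairs")
  if (stats::var(x) == 0) stop("zero variance in x: slope undefined")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  degenerate <- stats::var(y) == 0
  r <- if (degenerate) 0 else stats::cor(x, y)
  see <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r = r, see = see, n = n, degenerate = degenerate),
            class = "lvq_regression")
}

#' @export
print.lvq_regression <- function(x, ...) {
  cat(sprintf("y = %.4g x + %.4g   (r = %.3f, SEE = %.3g, n = %d%s)\n",
              x$slope, x$intercept, x$r, x$see, x$n,
              if (x$degenerate) ", degenerate: constant y" else ""))
  invisible(x)
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences are oriented a - b (a = test method, b = reference). In
#' percent mode each difference is divided by the pairwise average,
#' (a - b) / ((a + b) / 2) * 100. Limits of agreement are the mean
#' difference plus or minus 1.96 standard deviations (n - 1 denominator).
#'
#' @param a,b paired numeric vectors, n >= 2.
#' @param mode \code{"absolute"} or \code{"percent"}.
#' @return an object of class \code{bland_altman} with \code{bias},
#'   \code{sd}, \code{loa_low}, \code{loa_high}, the per-pair
#'   \code{differences} and \code{means}.
#' @export
bland_altman <- function(a, b, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("paired vectors differ in length")
  if (length(a) < 2) stop("Bland-Altman needs at least 2 pairs")
  avg <- (a + b) / 2
  d <- if (mode == "percent") {
    if (any(avg == 0)) stop("zero-average pair: percent difference undefined")
    (a - b) / avg * 100
  } else a - b
  bias <- mean(d); s <- stats::sd(d)
  structure(list(mode = mode, bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 differences = d, means = avg, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  unit <- if (x$mode == "percent") "%" else ""
  cat(sprintf("Bland-Altman (%s): bias %.3g%s +/- 1.96 SD [%.3g, %.3g]%s, n = %d\n",
              x$mode, x$bias, unit, x$loa_low, x$loa_high, unit, x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  unit <- if (x$mode == "percent") " (%)" else ""
  graphics::plot(x$means, x$differences, pch = 16,
                 xlab = "mean of pair", ylab = paste0("difference", unit), ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = "red")
  invisible(x)
}

#' Quadratically weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordinal scores with quadratic weights
#' w_ij = 1 - (i - j)^2 / (k - 1)^2: kappa = (p_o - p_e) / (1 - p_e) with
#' weighted observed and expected agreement proportions.
#'
#' @param table an [agreement_table()] or square count matrix with total
#'   greater than zero.
#' @return an object of class \code{kappa_result} with \code{kappa},
#'   \code{observed_agreement}, \code{expected_agreement}, \code{n}.
#' @export
weighted_kappa <- function(table) {
  m <- unclass(as.matrix(table))
  if (nrow(m) != ncol(m)) stop("agreement table must be square")
  n <- sum(m)
  if (n <= 0) stop("agreement table is empty")
  k <- nrow(m)
  d <- outer(seq_len(k), seq_len(k), `-`)
  w <- 1 - d^2 / (k - 1)^2
  e <- outer(rowSums(m), colSums(m)) / n
  po <- sum(w * m) / n
  pe <- sum(w * e) / n
  if (abs(1 - pe) < 1e-12)
    stop("undefined kappa: expected agreement is 1 (all mass in one cell)")
  structure(list(kappa = (po - pe) / (1 - pe), weights = "quadratic",
                 observed_agreement = po, expected_agreement = pe, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Weighted kappa (quadratic weights): %.3f  (p_o = %.4f, p_e = %.4f, n = %d)\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$n))
  invisible(x)
}

#' Variance-ratio (F) test for dispersions of two difference samples
#'
#' The statistic is the ratio of the larger to the smaller sample variance
#' (so F >= 1 by construction) and the two-sided p-value doubles the upper
#' tail of the F distribution with the matching degrees of freedom.
#'
#' @param d1,d2 numeric vectors of differences, each of length >= 2.
#' @return an object of class \code{variance_ratio} with \code{f},
#'   \code{df1}, \code{df2}, \code{p}.
#' @export
variance_ratio_test <- function(d1, d2) {
  if (length(d1) < 2 || length(d2) < 2) stop("each sample needs >= 2 values")
  v1 <- stats::var(d1); v2 <- stats::var(d2)
  if (v1 == 0 && v2 == 0) stop("zero variance in both samples")
  if (v1 >= v2) {
    f <- v1 / v2; df1 <- length(d1) - 1; df2 <- length(d2) - 1
  } else {
    f <- v2 / v1; df1 <- length(d2) - 1; df2 <- length(d1) - 1
  }
  p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  structure(list(f = f, df1 = df1, df2 = df2, p = p),
            class = "variance_ratio")
}

#' @export
print.variance_ratio <- function(x, ...) {
  cat(sprintf("Variance ratio F(%d, %d) = %.3g, two-sided p = %.4g\n",
              x$df1, x$df2, x$f, x$p))
  invisible(x)
}

# Dunn's multiple-comparison z tests on joint ranks, with tie correction
.dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- factor(groups)
  rk <- rank(values)
  N <- length(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  g <- levels(groups)
  pairs <- utils::combn(g, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[a] + 1 / n_g[b]))
    z[i] <- (mean_rank[a] - mean_rank[b]) / se
    p[i] <- 2 * stats::pnorm(abs(z[i]), lower.tail = FALSE)
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p = p, p_adjusted = stats::p.adjust(p, p_adjust))
}

#' Rank-based hypothesis tests used in method comparison
#'
#' Thin, uniform interface over the standard rank tests: the Friedman test
#' for repeated measurements (matrix input, subjects in rows), the
#' Kruskal-Wallis test and Dunn's multiple comparisons for grouped data,
#' and the Wilcoxon matched-pairs signed-rank test. Friedman,
#' Kruskal-Wallis and Wilcoxon delegate to the corresponding tests in
#' \pkg{stats}; Dunn's z tests are computed from joint ranks with tie
#' correction and Bonferroni adjustment.
#'
#' @param x for \code{"friedman"}: a numeric matrix (subjects x
#'   conditions); for \code{"kruskal_wallis"} and \code{"dunn"}: a numeric
#'   vector of values; for \code{"wilcoxon_signed_rank"}: the first member
#'   of each pair.
#' @param y second member of each pair (Wilcoxon only).
#' @param groups group labels (Kruskal-Wallis and Dunn only).
#' @param kind which test to run.
#' @param p_adjust multiplicity adjustment for Dunn's comparisons.
#' @return list with \code{kind}, \code{statistic}, \code{p_value} and,
#'   for Dunn, a \code{comparisons} data frame (statistic and p are then
#'   those of the most significant comparison after adjustment).
#' @export
rank_tests <- function(x, y = NULL, groups = NULL,
                       kind = c("friedman", "kruskal_wallis",
                                "wilcoxon_signed_rank", "dunn"),
                       p_adjust = "bonferroni") {
  kind <- match.arg(kind)
  if (kind == "friedman") {
    ht <- stats::friedman.test(as.matrix(x))
    if (is.nan(ht$statistic)) { # every row fully tied: no evidence at all
      warning("ties-only degenerate input; Friedman statistic set to 0")
      ht$statistic <- 0; ht$p.value <- 1
    }
  } else if (kind == "kruskal_wallis") {
    if (is.null(groups)) stop("kruskal_wallis needs 'groups'")
    ht <- stats::kruskal.test(x, factor(groups))
  } else if (kind == "wilcoxon_signed_rank") {
    if (is.null(y)) stop("wilcoxon_signed_rank needs paired 'y'")
    ht <- stats::wilcox.test(x, y, paired = TRUE)
  } else {
    if (is.null(groups)) stop("dunn needs 'groups'")
    cmp <- .dunn_test(x, groups, p_adjust)
    best <- which.min(cmp$p_adjusted)
    return(list(kind = kind, statistic = cmp$z[best],
                p_value = cmp$p_adjusted[best], comparisons = cmp))
  }
  list(kind = kind, statistic = unname(ht$statistic),
       p_value = ht$p.value, method = ht$method)
}
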