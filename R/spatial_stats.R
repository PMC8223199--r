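# False-positive control: per-pixel Pearson correlation of candidate
# parent/adduct pairs, two-sided tests, Bonferroni correction, Storey
# q-values, and cutoff screens.

#' Pearson correlation of candidate pairs across pixels
#'
#' For each pair row, computes the Pearson correlation between the parent
#' and adduct ion images over all pixels.  Zeros are data: pixels where a
#' peak was not detected contribute intensity 0, because co-absence is
#' spatial information (set `pixels = "either_nonzero"` to restrict each
#' pair to pixels where at least one member is detected).  The two-sided
#' p-value comes from the t statistic `r*sqrt((n-2)/(1-r^2))` with n-2
#' degrees of freedom.  Constant intensity vectors have undefined r,
#' reported as `NA` with p = 1.
#'
#' @param m An [msi_matrix()] whose row indices the pair table refers to.
#' @param pairs A pair table with `parent_index`, `adduct_index` columns.
#' @param pixels `"all"` (default) or `"either_nonzero"`.
#' @param chunk_size Pairs processed per block (memory control).
#' @return `pairs` with added columns `r`, `p`, `n_pixels`.
#' @export
correlate_pairs <- function(m, pairs, pixels = c("all", "either_nonzero"),
                            chunk_size = 20000) {
  pixels <- match.arg(pixels)
  X <- m$values
  n <- ncol(X)
  if (n < 3L) stop("Pearson test undefined for fewer than 3 pixels")
  if (nrow(pairs)) {
    if (max(pairs$parent_index, pairs$adduct_index) > nrow(X) ||
        min(pairs$parent_index, pairs$adduct_index) < 1L)
      stop("pair indices outside the intensity matrix")
  }
  r <- numeric(nrow(pairs)); np <- rep.int(n, nrow(pairs))
  if (pixels == "all") {
    mu <- rowMeans(X)
    Xc <- X - mu
    ss <- rowSums(Xc^2)
    idx <- seq_len(nrow(pairs))
    for (block in split(idx, ceiling(idx / chunk_size))) {
      i <- pairs$parent_index[block]; j <- pairs$adduct_index[block]
      cross <- rowSums(Xc[i, , drop = FALSE] * Xc[j, , drop = FALSE])
      denom <- sqrt(ss[i] * ss[j])
      r[block] <- ifelse(denom > 0, cross / denom, NA_real_)
    }
  } else {
    for (k in seq_len(nrow(pairs))) {
      a <- X[pairs$parent_index[k], ]; b <- X[pairs$adduct_index[k], ]
      keep <- a > 0 | b > 0
      np[k] <- sum(keep)
      r[k] <- if (np[k] >= 3 && stats::sd(a[keep]) > 0 && stats::sd(b[keep]) > 0)
        stats::cor(a[keep], b[keep]) else NA_real_
    }
  }
  r <- pmin(1, pmax(-1, r))
  p <- .pearson_pvalue(r, np)
  out <- pairs
  out$r <- r; out$p <- p; out$n_pixels <- np
  out
}

.pearson_pvalue <- function(r, n) {
  p <- rep(1, length(r))
  ok <- !is.na(r) & n > 2
  one <- ok & abs(r) >= 1
  p[one] <- 0
  mid <- ok & abs(r) < 1
  tstat <- r[mid] * sqrt((n[mid] - 2) / (1 - r[mid]^2))
  p[mid] <- 2 * stats::pt(-abs(tstat), df = n[mid] - 2)
  p
}

#' Bonferroni screen
#'
#' Multiplies each p-value by the number of tested pairs (capped at 1) and
#' rejects pairs with corrected p >= alpha.  A positive correlation is also
#' required: the test is for co-localization, so `r <= 0` (or undefined r)
#' fails regardless of p.
#'
#' @param pairs A correlated pair table (columns `r`, `p`).
#' @param alpha Significance level (default 0.05).
#' @param m_tests Number of tests for the correction; defaults to
#'   `nrow(pairs)`.
#' @return `pairs` with added columns `p_bonferroni`, `passed_bonferroni`.
#' @export
bonferroni_screen <- function(pairs, alpha = 0.05, m_tests = nrow(pairs)) {
  pairs$p_bonferroni <- pmin(1, m_tests * pairs$p)
  pairs$passed_bonferroni <- !is.na(pairs$r) & pairs$r > 0 &
    pairs$p_bonferroni < alpha
  pairs
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the p-value distribution on the
#' lambda grid 0.05, 0.10, ..., 0.95 with a cubic smoother extrapolated to
#' lambda = 1, then converts p-values to q-values by the step-up rule
#' `q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)` (capped at 1).
#' With pi0 fixed at 1 this reduces exactly to Benjamini-Hochberg.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param pi0 Optional fixed null proportion; estimated when `NULL`.
#' @param lambda Grid for the pi0 estimate.
#' @return List with `qvalues`, `pi0`, `lambda`, `pi0_lambda`.
#' @export
storey_qvalues <- function(p, pi0 = NULL,
                           lambda = seq(0.05, 0.95, by = 0.05)) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  pi0_lambda <- NULL
  if (is.null(pi0)) {
    if (m < 10L) {
      warning("fewer than 10 p-values: fixing pi0 at 1")
      pi0 <- 1
    } else {
      pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l),
                           numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
      # bound to [0, 1]; an estimate of 0 (everything signal) is legitimate
      pi0 <- min(max(stats::predict(fit, x = 1)$y, 0), 1)
    }
  }
  if (m == 0L)
    return(list(qvalues = numeric(0), pi0 = pi0, lambda = lambda,
                pi0_lambda = pi0_lambda))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  rk <- rank(p, ties.method = "max")
  q <- pmin(1, cummin(pi0 * m * p[o] / rk[o]))[ro]
  list(qvalues = q, pi0 = pi0, lambda = lambda, pi0_lambda = pi0_lambda)
}

#' q-value screen
#'
#' Adds Storey q-values and keeps pairs with q below the cutoff (default
#' 1e-7) and positive correlation.
#'
#' @param pairs A correlated pair table (columns `r`, `p`).
#' @param q_cutoff Keep pairs with `q < q_cutoff`.
#' @param pi0 Optional fixed pi0 (see [storey_qvalues()]).
#' @return `pairs` with added columns `q`, `passed_qvalue`.
#' @export
qvalue_screen <- function(pairs, q_cutoff = 1e-7, pi0 = NULL) {
  qv <- storey_qvalues(pairs$p, pi0 = pi0)
  pairs$q <- qv$qvalues
  pairs$passed_qvalue <- !is.na(pairs$r) & pairs$r > 0 &
    pairs$q < q_cutoff
  attr(pairs, "pi0") <- qv$pi0
  pairs
}

#' Correlation-coefficient screen
#'
#' Keeps pairs with r strictly greater than `r_min`; undefined r
#' (constant-intensity peaks) fails.
#'
#' @param pairs A correlated pair table (column `r`).
#' @param r_min Cutoff (the study settings of interest are 0.1 and 0.3).
#' @return `pairs` with added column `passed_rcut`.
#' @export
filter_correlation <- function(pairs, r_min = 0.1) {
  pairs$passed_rcut <- !is.na(pairs$r) & pairs$r > r_min
  pairs
}

#' Apply all false-positive screens
#'
#' Computes the Bonferroni, q-value, and correlation-cutoff screens and
#' sets `passed` to the chosen one.
#'
#' @param pairs A correlated pair table (from [correlate_pairs()]).
#' @param screen Which screen decides `passed`: `"rcut"` (default),
#'   `"bonferroni"`, or `"qvalue"`.
#' @param alpha Bonferroni significance level.
#' @param q_cutoff q-value cutoff.
#' @param r_min Correlation cutoff.
#' @return `pairs` with all screen columns plus `passed` and a
#'   `screen_used` attribute.
#' @export
screen_pairs <- function(pairs, screen = c("rcut", "bonferroni", "qvalue"),
                         alpha = 0.05, q_cutoff = 1e-7, r_min = 0.1) {
  screen <- match.arg(screen)
  pairs <- bonferroni_screen(pairs, alpha = alpha)
  pairs <- qvalue_screen(pairs, q_cutoff = q_cutoff)
  pairs <- filter_correlation(pairs, r_min = r_min)
  pairs$passed <- switch(screen,
                         rcut = pairs$passed_rcut,
                         bonferroni = pairs$passed_bonferroni,
                         qvalue = pairs$passed_qvalue)
  attr(pairs, "screen_used") <- screen
  pairs
}
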