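# Dataset conditioning: ppm tolerance models, peak binning, intensity /
# frequency / top-N filters, and matrix-blank subtraction.

#' ppm mass-tolerance model
#'
#' Relative mass accuracy used throughout matching.  For a single mass m the
#' tolerance is `p*m`.  For a pair (parent, adduct) the per-peak
#' uncertainties are propagated: in `"quadrature"` mode (default)
#' `p*sqrt(mA^2 + mB^2)`, in `"linear"` mode the more permissive
#' `p*(mA + mB)`.
#'
#' @param ppm Mass accuracy in parts per million (e.g. `5`).
#' @param mode Pair-tolerance propagation: `"quadrature"` or `"linear"`.
#' @return A `tol_model` object.
#' @export
tol_model <- function(ppm = 5, mode = c("quadrature", "linear")) {
  mode <- match.arg(mode)
  if (!is.numeric(ppm) || length(ppm) != 1L || ppm <= 0)
    stop("'ppm' must be a single positive number")
  structure(list(ppm = ppm, p = ppm * 1e-6, mode = mode),
            class = "tol_model")
}

#' @export
print.tol_model <- function(x, ...) {
  cat(sprintf("Tolerance model: %g ppm, %s pair propagation\n",
              x$ppm, x$mode))
  invisible(x)
}

.as_tol <- function(t) {
  if (inherits(t, "tol_model")) return(t)
  if (is.numeric(t) && length(t) == 1L) return(tol_model(t))
  stop("'tol' must be a tol_model or a ppm value")
}

#' Mass tolerance for a parent/adduct pair
#'
#' @param tol A [tol_model()] (or a ppm value).
#' @param mA,mB Parent and adduct masses (Da).
#' @return Tolerance in Da (vectorized over `mA`, `mB`).
#' @export
pair_tolerance <- function(tol, mA, mB) {
  tol <- .as_tol(tol)
  if (any(mA <= 0) || any(mB <= 0)) stop("masses must be positive")
  switch(tol$mode,
         quadrature = tol$p * sqrt(mA^2 + mB^2),
         linear     = tol$p * (mA + mB))
}

#' Mass tolerance for a single peak
#'
#' @inheritParams pair_tolerance
#' @param m Mass (Da).
#' @return `p * m` in Da.
#' @export
single_tolerance <- function(tol, m) {
  tol <- .as_tol(tol)
  if (any(m < 0)) stop("masses must be non-negative")
  tol$p * m
}

# Single-linkage clustering of a sorted m/z vector: consecutive peaks whose
# gap is below the width (evaluated at the heavier peak for ppm widths) join
# one cluster.  Returns integer cluster ids (1-based, ascending).
.cluster_sorted_mz <- function(mz, width, unit = c("ppm", "mda")) {
  unit <- match.arg(unit)
  n <- length(mz)
  if (n == 0L) return(integer(0))
  gaps <- diff(mz)
  thr <- if (unit == "ppm") width * 1e-6 * mz[-1] else rep(width * 1e-3, n - 1L)
  cumsum(c(1L, as.integer(gaps >= thr)))
}

#' Merge peaks closer than a bin width
#'
#' Greedy ascending single-linkage merge: consecutive peaks on the sorted
#' m/z axis whose gap is below the width (ppm widths scale with the heavier
#' peak's m/z; mDa widths are absolute) join one cluster.  Each cluster's
#' m/z is the summary-intensity-weighted centroid and its per-pixel
#' intensities are summed, so total intensity per pixel is conserved and no
#' two output peaks lie within the width.
#'
#' @param m An [msi_matrix()].
#' @param width Bin width, in units given by `unit`.
#' @param unit `"ppm"` (default) or `"mda"`.
#' @return A binned [msi_matrix()].
#' @export
bin_peaks <- function(m, width, unit = c("ppm", "mda")) {
  unit <- match.arg(unit)
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("'width' must be a single positive number")
  if (!inherits(m, "msi_matrix")) stop("'m' must be an msi_matrix")
  if (length(m$mz) <= 1L) return(m)
  cl <- .cluster_sorted_mz(m$mz, width, unit)
  if (max(cl) == length(m$mz)) return(m)
  w <- apply(m$values, 1, max)
  w[w <= 0] <- 1e-12
  groups <- split(seq_along(m$mz), cl)
  centr <- vapply(groups, function(ii) sum(m$mz[ii] * w[ii]) / sum(w[ii]),
                  numeric(1))
  vals <- rowsum(m$values, group = cl, reorder = TRUE)
  msi_matrix(centr, vals, m$coords)
}

#' Intensity-threshold filter
#'
#' Keeps peaks whose dataset maximum intensity is at least `fraction` of the
#' reference intensity: by default the global maximum single-pixel intensity
#' of the dataset (`reference = "global_max"`), alternatively the maximum of
#' the mean spectrum (`"mean_spectrum"`).  Equality is kept.
#'
#' @param m An [msi_matrix()].
#' @param fraction Threshold fraction in (0, 1), e.g. `5e-4` for 0.05%.
#' @param reference Which reference intensity the fraction applies to.
#' @return A filtered [msi_matrix()].
#' @export
filter_intensity <- function(m, fraction = 5e-4,
                             reference = c("global_max", "mean_spectrum")) {
  reference <- match.arg(reference)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie strictly between 0 and 1")
  peak_max <- apply(m$values, 1, max)
  ref <- switch(reference,
                global_max = max(peak_max),
                mean_spectrum = max(rowMeans(m$values)))
  keep <- peak_max >= fraction * ref
  .subset_peaks(m, keep)
}

#' Pixel-frequency filter
#'
#' Keeps peaks detected (nonzero) in at least `ceiling(min_fraction *
#' n_pixels)` pixels.
#'
#' @param m An [msi_matrix()].
#' @param min_fraction Minimum fraction of pixels in `[0, 1]` (default 1%).
#' @return A filtered [msi_matrix()].
#' @export
filter_frequency <- function(m, min_fraction = 0.01) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction < 0 || min_fraction > 1)
    stop("'min_fraction' must lie in [0, 1]")
  need <- ceiling(min_fraction * ncol(m$values))
  keep <- rowSums(m$values > 0) >= need
  .subset_peaks(m, keep)
}

#' Top-N intensity filter
#'
#' Keeps the `n` peaks with the highest summed-over-pixels intensity; ties
#' are broken deterministically in favour of the lower m/z.
#'
#' @param m An [msi_matrix()].
#' @param n Number of peaks to retain (e.g. 4000).
#' @return A filtered [msi_matrix()].
#' @export
filter_topn <- function(m, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count")
  if (length(m$mz) <= n) return(m)
  tot <- rowSums(m$values)
  o <- order(-tot, m$mz)
  keep <- sort(o[seq_len(n)])
  .subset_peaks(m, seq_along(m$mz) %in% keep)
}

.subset_peaks <- function(m, keep) {
  msi_matrix(m$mz[keep], m$values[keep, , drop = FALSE], m$coords)
}

#' Subtract a matrix-blank peak list
#'
#' Removes every sample peak lying within [single_tolerance()] (evaluated at
#' the sample peak's m/z) of any blank-list peak -- the control for matrix
#' cluster ions measured on matrix-only slides.
#'
#' @param sample A [peaklist()] or [msi_matrix()].
#' @param blank A [peaklist()] of matrix-only peaks.
#' @param tol A [tol_model()] or ppm value (default 5 ppm).
#' @return A list with elements `kept` (same type as `sample`), `removed`
#'   (data frame of removed m/z and the matched blank m/z), `n_removed`,
#'   `n_kept`.
#' @export
subtract_blank <- function(sample, blank, tol = tol_model(5)) {
  tol <- .as_tol(tol)
  smz <- if (inherits(sample, "msi_matrix")) sample$mz else sample$mz
  n_in <- length(smz)
  bmz <- sort(blank$mz)
  if (length(bmz) == 0L) {
    matched <- rep(FALSE, n_in)
    nearest <- rep(NA_real_, n_in)
  } else {
    # nearest blank peak via findInterval on the sorted blank axis
    idx <- findInterval(smz, bmz)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(bmz))
    d_lo <- abs(smz - bmz[lo]); d_hi <- abs(smz - bmz[hi])
    nearest <- ifelse(d_lo <= d_hi, bmz[lo], bmz[hi])
    matched <- abs(smz - nearest) <= single_tolerance(tol, smz)
  }
  kept <- if (inherits(sample, "msi_matrix"))
    .subset_peaks(sample, !matched)
  else
    structure(as.data.frame(sample)[!matched, , drop = FALSE],
              class = c("peaklist", "data.frame"))
  if (inherits(kept, "data.frame")) rownames(kept) <- NULL
  list(kept = kept,
       removed = data.frame(mz = smz[matched],
                            blank_mz = nearest[matched]),
       n_removed = sum(matched),
       n_kept = n_in - sum(matched))
}
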