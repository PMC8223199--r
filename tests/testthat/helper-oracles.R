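# Shared fixtures and independent brute-force oracles used across the suite.
# Oracles are written as plain loops from the definitions, independent of
# the package's vectorized implementations.

# small intensity matrix on a 1-row raster
toy_matrix <- function(mz, values) {
  values <- matrix(values, nrow = length(mz))
  msi_matrix(mz, values, data.frame(x = seq_len(ncol(values)), y = 1L))
}

rand_matrix <- function(n_peaks, n_pixels, mz_range = c(100, 1000)) {
  mz <- sort(runif(n_peaks, mz_range[1], mz_range[2]))
  while (any(diff(mz) == 0)) mz <- sort(runif(n_peaks, mz_range[1], mz_range[2]))
  vals <- matrix(rexp(n_peaks * n_pixels), n_peaks)
  vals[runif(length(vals)) < 0.3] <- 0
  msi_matrix(mz, vals, data.frame(x = seq_len(n_pixels), y = 1L))
}

# single-linkage clustering of sorted m/z by repeated merging until no gap
# is below the width (same gap rule as the package: width evaluated at the
# heavier peak for ppm units)
oracle_cluster <- function(mz, width, unit) {
  n <- length(mz)
  if (n == 0) return(integer(0))
  id <- 1L
  out <- integer(n); out[1] <- 1L
  for (i in seq_len(n - 1L)) {
    thr <- if (unit == "ppm") width * 1e-6 * mz[i + 1] else width * 1e-3
    if (mz[i + 1] - mz[i] >= thr) id <- id + 1L
    out[i + 1] <- id
  }
  out
}

oracle_bin <- function(m, width, unit) {
  cl <- oracle_cluster(m$mz, width, unit)
  k <- max(cl)
  mz <- numeric(k)
  vals <- matrix(0, k, ncol(m$values))
  for (g in seq_len(k)) {
    ii <- which(cl == g)
    w <- vapply(ii, function(i) max(m$values[i, ]), numeric(1))
    if (all(w <= 0)) w <- rep(1, length(ii))
    mz[g] <- sum(m$mz[ii] * w) / sum(w)
    for (i in ii) vals[g, ] <- vals[g, ] + m$values[i, ]
  }
  list(mz = mz, values = vals)
}

oracle_pairs <- function(mz) {
  out <- list()
  for (i in seq_along(mz)) for (j in seq_along(mz)) {
    if (mz[j] > mz[i])
      out[[length(out) + 1L]] <- c(i, j, mz[i], mz[j], mz[j] - mz[i])
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("parent_index", "adduct_index", "parent_mz", "adduct_mz",
                 "delta")
  df[order(df$parent_mz, df$adduct_mz), ]
}

oracle_match <- function(pairs, registry, ppm, mode = "quadrature") {
  hits <- list()
  for (k in seq_len(nrow(pairs))) {
    tol <- if (mode == "quadrature")
      ppm * 1e-6 * sqrt(pairs$parent_mz[k]^2 + pairs$adduct_mz[k]^2)
    else ppm * 1e-6 * (pairs$parent_mz[k] + pairs$adduct_mz[k])
    for (e in seq_len(nrow(registry))) {
      if (abs(pairs$delta[k] - registry$delta_mass[e]) <= tol)
        hits[[length(hits) + 1L]] <- c(k, e)
    }
  }
  if (!length(hits)) return(matrix(integer(0), 0, 2))
  do.call(rbind, hits)
}

oracle_subtract <- function(sample_mz, blank_mz, ppm) {
  removed <- logical(length(sample_mz))
  for (i in seq_along(sample_mz)) {
    for (b in blank_mz) {
      if (abs(sample_mz[i] - b) <= ppm * 1e-6 * sample_mz[i]) {
        removed[i] <- TRUE
        break
      }
    }
  }
  removed
}

oracle_topn <- function(m, n) {
  tot <- rowSums(m$values)
  o <- order(-tot, m$mz)
  sort(m$mz[o[seq_len(min(n, length(m$mz)))]])
}
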