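# The core of the method: all-pairs mass differences, the delta-mass
# histogram, adduct-registry matching, and per-type counting.

#' All-pairs mass differences
#'
#' One row per unordered pair of peaks, oriented heavier-minus-lighter so
#' `delta > 0` always, in deterministic order (by parent m/z, then adduct
#' m/z).  For n peaks the table has exactly n(n-1)/2 rows.
#'
#' The table contract is logical, not a materialization mandate: for large
#' peak lists supply `chunk_fun` to stream the pairs in blocks of parent
#' peaks without holding the full table in memory (the function is called
#' once per block with a pair-table chunk; `build_pairs` then returns
#' `NULL`).
#'
#' @param peaks A [peaklist()] (or anything with an `mz` column/element).
#' @param chunk_fun Optional callback receiving successive pair-table
#'   chunks.
#' @param chunk_size Approximate number of rows per chunk.
#' @return A `pair_table` data frame with columns `parent_index`,
#'   `adduct_index`, `parent_mz`, `adduct_mz`, `delta` (or `NULL` when
#'   streaming).
#' @export
build_pairs <- function(peaks, chunk_fun = NULL, chunk_size = 1e6) {
  mz <- sort(as.numeric(peaks$mz))
  n <- length(mz)
  empty <- data.frame(parent_index = integer(0), adduct_index = integer(0),
                      parent_mz = numeric(0), adduct_mz = numeric(0),
                      delta = numeric(0))
  if (n < 2L) {
    warning("fewer than 2 peaks: no pairs to build")
    return(structure(empty, class = c("pair_table", "data.frame")))
  }
  make_block <- function(is) {
    counts <- n - is
    i <- rep.int(is, counts)
    j <- sequence(counts, from = is + 1L)
    data.frame(parent_index = i, adduct_index = j,
               parent_mz = mz[i], adduct_mz = mz[j],
               delta = mz[j] - mz[i])
  }
  if (!is.null(chunk_fun)) {
    start <- 1L
    while (start < n) {
      size <- 0L; end <- start - 1L
      while (end < n - 1L && size < chunk_size) {
        end <- end + 1L
        size <- size + (n - end)
      }
      chunk_fun(structure(make_block(start:end),
                          class = c("pair_table", "data.frame")))
      start <- end + 1L
    }
    return(invisible(NULL))
  }
  structure(make_block(seq_len(n - 1L)),
            class = c("pair_table", "data.frame"))
}

#' Histogram of mass differences
#'
#' Fixed-width bins from 0 up to the largest delta.  The abundant bins of
#' this histogram reveal the dominant adduct chemistry of a dataset (e.g. a
#' tall bin at 136.016 Da flags DHB-H2O adducts).
#'
#' @param pairs A pair table from [build_pairs()].
#' @param binwidth Bin width in Da (default 0.005).
#' @return A `delta_histogram` object (list with `breaks`, `counts`,
#'   `mids`, `binwidth`, `n_pairs`).
#' @export
delta_histogram <- function(pairs, binwidth = 0.005) {
  if (!is.numeric(binwidth) || length(binwidth) != 1L || binwidth <= 0)
    stop("'binwidth' must be a single positive number")
  d <- pairs$delta
  if (length(d) == 0L) {
    return(structure(list(breaks = numeric(0), counts = integer(0),
                          mids = numeric(0), binwidth = binwidth,
                          n_pairs = 0L),
                     class = "delta_histogram"))
  }
  k <- pmin(floor(d / binwidth) + 1L, ceiling(max(d) / binwidth))
  nbin <- max(k)
  counts <- tabulate(k, nbins = nbin)
  breaks <- seq(0, by = binwidth, length.out = nbin + 1L)
  structure(list(breaks = breaks, counts = counts,
                 mids = breaks[-1] - binwidth / 2,
                 binwidth = binwidth, n_pairs = length(d)),
            class = "delta_histogram")
}

#' Most populated delta-mass bins
#'
#' @param h A [delta_histogram()].
#' @param k Number of bins to return.
#' @return Data frame of `center`, `count` for the `k` most populated bins
#'   (ties broken by lower center).
#' @export
top_bins <- function(h, k = 10) {
  if (length(h$counts) == 0L)
    return(data.frame(center = numeric(0), count = integer(0)))
  o <- order(-h$counts, h$mids)
  o <- o[seq_len(min(k, sum(h$counts > 0)))]
  data.frame(center = h$mids[o], count = h$counts[o])
}

#' @export
print.delta_histogram <- function(x, ...) {
  cat(sprintf(
    "Mass-difference histogram: %d pairs, %d bins of %.4g Da\n",
    x$n_pairs, length(x$counts), x$binwidth))
  if (x$n_pairs > 0) {
    cat("Top bins:\n")
    print(top_bins(x, 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.delta_histogram <- function(x, xlim = NULL, ...) {
  graphics::plot(x$mids, x$counts, type = "h", xlab = expression(Delta*m~(Da)),
                 ylab = "pair count", xlim = xlim, ...)
  invisible(x)
}

#' Match pair mass differences against an adduct registry
#'
#' Keeps pair rows whose delta lies within the pair-propagated tolerance of
#' some registry entry's mass shift, annotated with the entry name and the
#' signed error.  A row whose delta matches several registry entries is
#' emitted once per entry with `ambiguous = TRUE` (resolution is a
#' downstream, MS2-level question).
#'
#' @param pairs A pair table from [build_pairs()].
#' @param registry An [adduct_registry()].
#' @param tol A [tol_model()] or ppm value.
#' @return The matching subset of `pairs` with added columns `adduct_name`,
#'   `registry_delta`, `error_da`, `error_ppm`, `ambiguous`.
#' @export
match_adducts <- function(pairs, registry, tol = tol_model(5)) {
  tol <- .as_tol(tol)
  if (!nrow(registry)) stop("empty adduct registry")
  out <- vector("list", nrow(registry))
  if (nrow(pairs)) {
    tolvec <- pair_tolerance(tol, pairs$parent_mz, pairs$adduct_mz)
    for (e in seq_len(nrow(registry))) {
      err <- pairs$delta - registry$delta_mass[e]
      hit <- which(abs(err) <= tolvec)
      if (length(hit)) {
        blk <- pairs[hit, , drop = FALSE]
        blk$adduct_name <- registry$name[e]
        blk$registry_delta <- registry$delta_mass[e]
        blk$error_da <- err[hit]
        blk$error_ppm <- err[hit] / blk$delta * 1e6
        out[[e]] <- blk
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    res <- data.frame(parent_index = integer(0), adduct_index = integer(0),
                      parent_mz = numeric(0), adduct_mz = numeric(0),
                      delta = numeric(0), adduct_name = character(0),
                      registry_delta = numeric(0), error_da = numeric(0),
                      error_ppm = numeric(0), ambiguous = logical(0))
    return(structure(res, class = c("pair_table", "data.frame")))
  }
  res <- do.call(rbind, out)
  key <- paste(res$parent_index, res$adduct_index)
  res$ambiguous <- key %in% key[duplicated(key)]
  res <- res[order(res$parent_mz, res$adduct_mz, res$adduct_name), ,
             drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("pair_table", "data.frame"))
}

#' Count matched adducts by type
#'
#' Tabulates matched (optionally screened) pairs per adduct type and
#' expresses each count as a fraction of the total peak count.  The default
#' unit counts distinct peaks appearing as the adduct member of at least one
#' row; `"pairs"` counts rows.
#'
#' @param matched A matched pair table (see [match_adducts()]); if a
#'   `passed` column is present only passing rows are counted.
#' @param total_peaks Denominator: total number of peaks in the dataset.
#' @param unit `"distinct_adduct_peaks"` (default) or `"pairs"`.
#' @return Data frame of `adduct_name`, `n_pairs`,
#'   `n_distinct_adduct_peaks`, `count`, `fraction`.
#' @export
count_by_type <- function(matched, total_peaks,
                          unit = c("distinct_adduct_peaks", "pairs")) {
  unit <- match.arg(unit)
  if (!is.numeric(total_peaks) || total_peaks < 1)
    stop("'total_peaks' must be >= 1")
  types <- unique(matched$adduct_name)
  use <- if ("passed" %in% names(matched)) matched[matched$passed, , drop = FALSE]
         else matched
  n_pairs <- vapply(types, function(tp) sum(use$adduct_name == tp), integer(1))
  n_dist <- vapply(types, function(tp)
    length(unique(use$adduct_index[use$adduct_name == tp])), integer(1))
  count <- if (unit == "pairs") n_pairs else n_dist
  out <- data.frame(adduct_name = types, n_pairs = n_pairs,
                    n_distinct_adduct_peaks = n_dist, count = count,
                    fraction = count / total_peaks)
  out <- out[order(out$adduct_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a pair table as TSV
#'
#' @param pairs A pair table.
#' @param path TSV file path.
#' @return `read_pairs_tsv` returns a `pair_table` data frame.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pairs_tsv
#' @export
read_pairs_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df, class = c("pair_table", "data.frame"))
}
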