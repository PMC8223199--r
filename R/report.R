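# Reporting: per-adduct-type summary tables, annotated mean spectra, and
# ion-image extraction.

#' Per-adduct-type summary table
#'
#' Tabulates screened pairs by adduct type as counts and fractions of the
#' total peak number (the per-platform summary of a dataset's adduct
#' composition).
#'
#' @param pairs A matched and screened pair table (passing rows are those
#'   with the chosen screen column `TRUE`).
#' @param total_peaks Denominator peak count.  By convention the
#'   post-preprocessing, pre-blank-subtraction peak count.
#' @param screen Which screen's flags to use: `"rcut"`, `"bonferroni"`,
#'   `"qvalue"`, or `"passed"` (whatever [screen_pairs()] selected).
#' @param unit Counting unit, see [count_by_type()].
#' @return Data frame with columns `adduct_name`, `n_pairs`,
#'   `n_distinct_adduct_peaks`, `fraction_of_total_peaks`, `screen_used`.
#' @export
summarize_adducts <- function(pairs, total_peaks,
                              screen = c("rcut", "bonferroni", "qvalue",
                                         "passed"),
                              unit = c("distinct_adduct_peaks", "pairs")) {
  screen <- match.arg(screen)
  unit <- match.arg(unit)
  col <- if (screen == "passed") "passed" else paste0("passed_", screen)
  if (!col %in% names(pairs))
    stop("screen column '", col, "' not present; run screen_pairs() first")
  use <- pairs
  use$passed <- pairs[[col]]
  tab <- count_by_type(use, total_peaks, unit = unit)
  data.frame(adduct_name = tab$adduct_name, n_pairs = tab$n_pairs,
             n_distinct_adduct_peaks = tab$n_distinct_adduct_peaks,
             fraction_of_total_peaks = tab$fraction,
             screen_used = screen)
}

#' Annotated mean spectrum
#'
#' The dataset mean spectrum with every peak that appears as the adduct
#' member of at least one passing pair flagged by adduct type -- the
#' "which part of my spectrum is adducts" view.
#'
#' @param m An [msi_matrix()].
#' @param pairs A matched and screened pair table whose indices refer to
#'   `m`; rows with `passed == TRUE` (or all rows if no `passed` column)
#'   are used.
#' @return An `annotated_spectrum` data frame with columns `mz`,
#'   `mean_intensity`, `adduct` (type name or `NA`).
#' @export
annotate_spectrum <- function(m, pairs) {
  spec <- data.frame(mz = m$mz, mean_intensity = rowMeans(m$values),
                     adduct = NA_character_)
  use <- if ("passed" %in% names(pairs)) pairs[pairs$passed, , drop = FALSE]
         else pairs
  if (nrow(use)) {
    for (k in seq_len(nrow(use))) {
      i <- use$adduct_index[k]
      spec$adduct[i] <- if (is.na(spec$adduct[i])) use$adduct_name[k]
        else paste(unique(c(strsplit(spec$adduct[i], ";")[[1]],
                            use$adduct_name[k])), collapse = ";")
    }
  }
  structure(spec, class = c("annotated_spectrum", "data.frame"))
}

#' @export
plot.annotated_spectrum <- function(x, ...) {
  flagged <- !is.na(x$adduct)
  graphics::plot(x$mz, x$mean_intensity, type = "h", col = "grey40",
                 xlab = "m/z", ylab = "mean intensity", ...)
  if (any(flagged))
    graphics::segments(x$mz[flagged], 0, x$mz[flagged],
                       x$mean_intensity[flagged], col = "red")
  invisible(x)
}

#' Extract an ion image
#'
#' Per-pixel summed intensity of all peaks within a ppm window around a
#' target m/z, rendered on the raster without interpolation.
#'
#' @param m An [msi_matrix()].
#' @param mz Target m/z (Da), within the axis range.
#' @param tol_ppm Half-width of the m/z window in ppm (default 2.5).
#' @return An `ion_image`: numeric matrix of dimension (width, height)
#'   indexed `[x, y]`, with attributes `mz` and `tol_ppm`.
#' @export
ion_image <- function(m, mz, tol_ppm = 2.5) {
  if (mz < min(m$mz) - 1 || mz > max(m$mz) + 1)
    stop("target m/z outside the dataset axis range")
  win <- tol_ppm * 1e-6 * mz
  sel <- abs(m$mz - mz) <= win
  width <- max(m$coords$x); height <- max(m$coords$y)
  img <- matrix(0, nrow = width, ncol = height)
  if (!any(sel)) {
    warning(sprintf("no peak within %.3g ppm of m/z %.4f", tol_ppm, mz))
  } else {
    v <- colSums(m$values[sel, , drop = FALSE])
    img[cbind(m$coords$x, m$coords$y)] <- v
  }
  structure(img, class = c("ion_image", "matrix"),
            mz = mz, tol_ppm = tol_ppm)
}

#' @export
plot.ion_image <- function(x, col = grDevices::hcl.colors(64, "viridis"),
                           ...) {
  graphics::image(seq_len(nrow(x)), seq_len(ncol(x)), unclass(x),
                  col = col, xlab = "x", ylab = "y", useRaster = TRUE,
                  main = sprintf("m/z %.4f (+/- %.3g ppm)",
                                 attr(x, "mz"), attr(x, "tol_ppm")), ...)
  invisible(x)
}

#' Write an ion image to disk
#'
#' Writes the numeric image as TSV (the authoritative output) and,
#' optionally, a PNG rendering.
#'
#' @param img An [ion_image()].
#' @param path Output TSV path.
#' @param png Optional PNG path.
#' @return `path`, invisibly.
#' @export
write_ion_image <- function(img, path, png = NULL) {
  utils::write.table(unclass(img), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(png)) {
    grDevices::png(png, width = 480, height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(img)
  }
  invisible(path)
}
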