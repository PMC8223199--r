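# Containers and readers/writers for MSI data: dataset-level peak lists,
# peaks x pixels intensity matrices, CSV/TSV text formats, and imzML.

#' Dataset-level peak list
#'
#' Ordered m/z values with one non-negative summary intensity each (by
#' convention the maximum single-pixel intensity; see
#' [collapse_to_peaklist()]).
#'
#' @param mz Numeric vector of m/z values (Da), all positive and distinct.
#' @param intensity Non-negative summary intensity per peak.
#' @return A `peaklist` data frame with columns `mz`, `intensity`, sorted by
#'   m/z.
#' @export
peaklist <- function(mz, intensity = rep(0, length(mz))) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(intensity) != length(mz))
    stop("'intensity' must have one value per m/z")
  if (anyNA(mz) || any(!is.finite(mz))) stop("m/z values must be finite")
  if (any(mz <= 0)) stop("m/z values must be positive")
  if (anyNA(intensity) || any(intensity < 0))
    stop("intensities must be non-negative")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (any(diff(mz) == 0))
    stop("duplicate m/z values; merge them first (see bin_peaks)")
  structure(data.frame(mz = mz, intensity = intensity),
            class = c("peaklist", "data.frame"))
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("Peak list: %d peaks, m/z %.4f-%.4f\n", nrow(x),
              if (nrow(x)) min(x$mz) else NA, if (nrow(x)) max(x$mz) else NA))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6), row.names = FALSE)
  invisible(x)
}

#' Peaks-by-pixels intensity matrix
#'
#' The central MSI container: an m/z axis, a dense peaks x pixels intensity
#' matrix (zeros mean "not detected in that pixel"), and integer pixel
#' coordinates in imzML convention (1-based).
#'
#' @param mz Numeric m/z axis (Da), positive, distinct; rows are sorted by
#'   m/z on construction.
#' @param values Numeric matrix, `length(mz)` rows x `nrow(coords)` columns,
#'   all values >= 0.
#' @param coords Data frame with integer columns `x`, `y`, one row per
#'   pixel, unique.
#' @return An `msi_matrix` object (list with elements `mz`, `values`,
#'   `coords`).
#' @export
msi_matrix <- function(mz, values, coords) {
  mz <- as.numeric(mz)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  coords <- as.data.frame(coords)
  if (!all(c("x", "y") %in% names(coords)))
    stop("'coords' needs columns x and y")
  coords <- data.frame(x = as.integer(coords$x), y = as.integer(coords$y))
  if (nrow(values) != length(mz))
    stop("'values' must have one row per m/z")
  if (ncol(values) != nrow(coords))
    stop("'values' must have one column per pixel")
  if (anyNA(mz) || any(mz <= 0)) stop("m/z values must be positive and finite")
  if (anyDuplicated(coords)) stop("pixel coordinates must be unique")
  if (anyNA(values) || any(values < 0))
    stop("intensities must be non-negative")
  o <- order(mz)
  mz <- mz[o]; values <- values[o, , drop = FALSE]
  if (any(diff(mz) == 0))
    stop("duplicate m/z values; merge them first (see bin_peaks)")
  dimnames(values) <- NULL
  structure(list(mz = mz, values = values, coords = coords),
            class = "msi_matrix")
}

#' @export
print.msi_matrix <- function(x, ...) {
  cat(sprintf("MSI intensity matrix: %d peaks x %d pixels\n",
              length(x$mz), nrow(x$coords)))
  cat(sprintf("  m/z range %.4f-%.4f; raster x %d-%d, y %d-%d\n",
              min(x$mz), max(x$mz), min(x$coords$x), max(x$coords$x),
              min(x$coords$y), max(x$coords$y)))
  invisible(x)
}

#' @export
dim.msi_matrix <- function(x) c(length(x$mz), nrow(x$coords))

n_peaks <- function(x) {
  if (inherits(x, "msi_matrix")) length(x$mz) else nrow(x)
}

#' Collapse an intensity matrix to a dataset-level peak list
#'
#' @param m An [msi_matrix()].
#' @param summary Per-peak summary over pixels: `"max"` (default), `"mean"`,
#'   or `"sum"`.
#' @return A [peaklist()].
#' @export
collapse_to_peaklist <- function(m, summary = c("max", "mean", "sum")) {
  summary <- match.arg(summary)
  if (!inherits(m, "msi_matrix")) stop("'m' must be an msi_matrix")
  if (length(m$mz) == 0L) stop("empty intensity matrix")
  s <- switch(summary,
              max  = apply(m$values, 1, max),
              mean = rowMeans(m$values),
              sum  = rowSums(m$values))
  peaklist(m$mz, s)
}

.pixel_names <- function(coords) sprintf("x%d_y%d", coords$x, coords$y)

#' Write / read an intensity matrix as CSV
#'
#' Default orientation: first column `mz`, remaining columns one pixel each,
#' named `x<i>_y<j>`.  `transpose = TRUE` reads/writes the transposed layout
#' (one row per pixel, columns named by m/z).
#'
#' @param m An [msi_matrix()].
#' @param path CSV file path.
#' @param transpose Use the pixels-as-rows layout.
#' @return `read_intensity_csv` returns an [msi_matrix()];
#'   `write_intensity_csv` returns `path` invisibly.
#' @export
write_intensity_csv <- function(m, path, transpose = FALSE) {
  if (!transpose) {
    df <- data.frame(mz = m$mz, m$values, check.names = FALSE)
    names(df) <- c("mz", .pixel_names(m$coords))
  } else {
    df <- data.frame(pixel = .pixel_names(m$coords), t(m$values),
                     check.names = FALSE)
    names(df) <- c("pixel", format(m$mz, digits = 15, trim = TRUE))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.parse_pixel_headers <- function(h) {
  ok <- grepl("^x-?[0-9]+_y-?[0-9]+$", h)
  if (all(ok)) {
    data.frame(x = as.integer(sub("^x(-?[0-9]+)_y.*$", "\\1", h)),
               y = as.integer(sub("^.*_y(-?[0-9]+)$", "\\1", h)))
  } else {
    warning("pixel headers not in x<i>_y<j> form; assigning sequential coordinates")
    data.frame(x = seq_along(h), y = rep(1L, length(h)))
  }
}

#' @rdname write_intensity_csv
#' @export
read_intensity_csv <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("intensity CSV needs at least two columns")
  if (!transpose) {
    mz <- suppressWarnings(as.numeric(df[[1]]))
    if (anyNA(mz))
      stop("non-numeric m/z value at data row ", which(is.na(mz))[1])
    vals <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "double")
    if (anyNA(vals)) {
      idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric intensity at data row %d, column '%s'",
                   idx[1], colnames(vals)[idx[2]]))
    }
    coords <- .parse_pixel_headers(names(df)[-1])
  } else {
    mz <- suppressWarnings(as.numeric(names(df)[-1]))
    if (anyNA(mz)) stop("transposed CSV header must contain numeric m/z values")
    vals <- t(as.matrix(df[, -1, drop = FALSE]))
    storage.mode(vals) <- "double"
    if (anyNA(vals)) {
      idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric intensity for m/z row %d, pixel %d",
                   idx[1], idx[2]))
    }
    coords <- .parse_pixel_headers(as.character(df[[1]]))
  }
  if (anyDuplicated(mz))
    stop("duplicate m/z rows in CSV; bin the data first (see bin_peaks)")
  msi_matrix(mz, vals, coords)
}

#' Write / read a peak list as TSV
#'
#' Two tab-separated columns, `mz` and `intensity`, with a header row.
#'
#' @param p A [peaklist()].
#' @param path TSV file path.
#' @return `read_peaklist_tsv` returns a [peaklist()].
#' @export
write_peaklist_tsv <- function(p, path) {
  utils::write.table(as.data.frame(p)[, c("mz", "intensity")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaklist_tsv
#' @export
read_peaklist_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("peak-list TSV must have columns mz and intensity")
  peaklist(df$mz, df$intensity)
}

# ---- imzML ------------------------------------------------------------

# Minimal imzML support for centroided data: the XML index plus the binary
# .ibd companion (16-byte UUID header, then little-endian float arrays).
# Continuous mode shares one m/z axis across pixels; processed mode stores a
# spectrum per pixel and is aligned onto a common axis by binning on read.

.imzml_ibd_path <- function(path) {
  p <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(p, path)) p <- paste0(path, ".ibd")
  p
}

#' Write an intensity matrix as imzML
#'
#' Writes a centroided imzML/ibd pair with 64-bit float arrays.  In
#' `"continuous"` mode the m/z axis is stored once and every pixel stores a
#' full intensity vector; in `"processed"` mode each pixel stores only its
#' nonzero peaks.
#'
#' @param m An [msi_matrix()].
#' @param path Output `.imzML` path (the `.ibd` companion is written next to
#'   it).
#' @param mode `"continuous"` or `"processed"`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(m, path, mode = c("continuous", "processed")) {
  mode <- match.arg(mode)
  ibd <- .imzml_ibd_path(path)
  uuid <- "41646475-6374-4d53-4921-6d7a496d6700"
  uuid_bytes <- as.raw(c(0x41, 0x64, 0x64, 0x75, 0x63, 0x74, 0x4d, 0x53,
                         0x49, 0x21, 0x6d, 0x7a, 0x49, 0x6d, 0x67, 0x00))
  con <- file(ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid_bytes, con)
  offset <- 16
  npix <- nrow(m$coords)
  specs <- vector("list", npix)
  if (mode == "continuous") {
    mz_off <- offset; mz_len <- length(m$mz)
    writeBin(as.double(m$mz), con, size = 8, endian = "little")
    offset <- offset + 8 * mz_len
    for (i in seq_len(npix)) {
      v <- m$values[, i]
      specs[[i]] <- list(x = m$coords$x[i], y = m$coords$y[i],
                         mz_off = mz_off, mz_len = mz_len,
                         int_off = offset, int_len = length(v))
      writeBin(as.double(v), con, size = 8, endian = "little")
      offset <- offset + 8 * length(v)
    }
  } else {
    for (i in seq_len(npix)) {
      keep <- m$values[, i] > 0
      mzv <- m$mz[keep]; v <- m$values[keep, i]
      mz_off <- offset
      writeBin(as.double(mzv), con, size = 8, endian = "little")
      offset <- offset + 8 * length(mzv)
      int_off <- offset
      writeBin(as.double(v), con, size = 8, endian = "little")
      offset <- offset + 8 * length(v)
      specs[[i]] <- list(x = m$coords$x[i], y = m$coords$y[i],
                         mz_off = mz_off, mz_len = length(mzv),
                         int_off = int_off, int_len = length(v))
    }
  }
  mode_acc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
  mode_name <- paste0(mode)
  cv <- function(acc, name, value = NULL) {
    ref <- if (startsWith(acc, "IMS")) "IMS" else "MS"
    if (is.null(value))
      sprintf('<cvParam cvRef="%s" accession="%s" name="%s"/>', ref, acc, name)
    else
      sprintf('<cvParam cvRef="%s" accession="%s" name="%s" value="%s"/>',
              ref, acc, name, value)
  }
  spec_xml <- vapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, s$mz_len),
      cv("MS:1000127", "centroid spectrum"),
      '<scanList count="1"><scan>',
      cv("IMS:1000050", "position x", s$x),
      cv("IMS:1000051", "position y", s$y),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      cv("MS:1000514", "m/z array"), cv("MS:1000523", "64-bit float"),
      cv("IMS:1000102", "external offset", s$mz_off),
      cv("IMS:1000103", "external array length", s$mz_len),
      cv("IMS:1000104", "external encoded length", 8L * s$mz_len),
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      cv("MS:1000515", "intensity array"), cv("MS:1000523", "64-bit float"),
      cv("IMS:1000102", "external offset", s$int_off),
      cv("IMS:1000103", "external array length", s$int_len),
      cv("IMS:1000104", "external encoded length", 8L * s$int_len),
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    cv("MS:1000579", "MS1 spectrum"),
    cv(mode_acc, mode_name),
    cv("IMS:1000080", "universally unique identifier",
       paste0("{", uuid, "}")),
    '</fileContent></fileDescription>',
    sprintf('<run id="run1"><spectrumList count="%d">', npix),
    paste0(spec_xml, collapse = ""),
    '</spectrumList></run></mzML>\n')
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

.xml_cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, sprintf(".//*[local-name()='cvParam'][@accession='%s']", accession))
  if (inherits(p, "xml_missing")) return(NA_character_)
  xml2::xml_attr(p, "value")
}

.xml_has_cv <- function(node, accession) {
  !inherits(xml2::xml_find_first(
    node, sprintf(".//*[local-name()='cvParam'][@accession='%s']", accession)),
    "xml_missing")
}

#' Read an imzML dataset
#'
#' Reads a centroided imzML/ibd pair into an [msi_matrix()].  Continuous
#' files map directly onto the shared m/z axis; processed files are aligned
#' onto a common axis by merging peaks closer than `bin_ppm` (see
#' [bin_peaks()] for the merge rule).
#'
#' @param path Path to the `.imzML` file; the `.ibd` must sit next to it.
#' @param bin_ppm Bin width (ppm) used to align processed-mode spectra.
#' @return An [msi_matrix()].
#' @export
read_imzml <- function(path, bin_ppm = 5) {
  if (!file.exists(path)) stop("file not found: ", path)
  ibd <- .imzml_ibd_path(path)
  if (!file.exists(ibd))
    stop("missing binary companion file: ", ibd)
  doc <- xml2::read_xml(path)
  filecontent <- xml2::xml_find_first(doc, "//*[local-name()='fileContent']")
  continuous <- .xml_has_cv(filecontent, "IMS:1000030")
  processed <- .xml_has_cv(filecontent, "IMS:1000031")
  if (!continuous && !processed)
    stop("imzML file declares neither continuous nor processed binary mode")
  if (.xml_has_cv(filecontent, "MS:1000128"))
    stop("profile-mode imzML is not supported; centroid the data first")
  spectra <- xml2::xml_find_all(doc, "//*[local-name()='spectrum']")
  if (!length(spectra)) stop("imzML file contains no spectra")
  if (any(vapply(spectra, .xml_has_cv, logical(1), "MS:1000128")))
    stop("profile-mode spectra found; centroid the data first")
  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  read_array <- function(offset, len, size) {
    if (len == 0L) return(numeric(0))
    seek(con, where = offset, origin = "start")
    readBin(con, what = "double", n = len, size = size, endian = "little")
  }
  info <- lapply(spectra, function(sp) {
    x <- as.integer(.xml_cv_value(sp, "IMS:1000050"))
    y <- as.integer(.xml_cv_value(sp, "IMS:1000051"))
    arrays <- xml2::xml_find_all(sp, ".//*[local-name()='binaryDataArray']")
    out <- list(x = x, y = y)
    for (a in arrays) {
      size <- if (.xml_has_cv(a, "MS:1000521")) 4L else 8L
      off <- as.numeric(.xml_cv_value(a, "IMS:1000102"))
      len <- as.integer(.xml_cv_value(a, "IMS:1000103"))
      slot <- if (.xml_has_cv(a, "MS:1000514")) "mz" else "int"
      out[[slot]] <- list(off = off, len = len, size = size)
    }
    out
  })
  coords <- data.frame(x = vapply(info, `[[`, integer(1), "x"),
                       y = vapply(info, `[[`, integer(1), "y"))
  if (continuous) {
    a <- info[[1]]$mz
    mz <- read_array(a$off, a$len, a$size)
    vals <- matrix(0, nrow = length(mz), ncol = length(info))
    for (i in seq_along(info)) {
      b <- info[[i]]$int
      v <- read_array(b$off, b$len, b$size)
      if (length(v) != length(mz))
        stop("continuous imzML with inconsistent array lengths")
      vals[, i] <- v
    }
    return(msi_matrix(mz, vals, coords))
  }
  # processed mode: gather all spectra, merge onto a common axis
  all_mz <- list(); all_int <- list(); all_pix <- list()
  for (i in seq_along(info)) {
    mzv <- read_array(info[[i]]$mz$off, info[[i]]$mz$len, info[[i]]$mz$size)
    v <- read_array(info[[i]]$int$off, info[[i]]$int$len, info[[i]]$int$size)
    all_mz[[i]] <- mzv; all_int[[i]] <- v
    all_pix[[i]] <- rep.int(i, length(mzv))
  }
  mzv <- unlist(all_mz); v <- unlist(all_int); pix <- unlist(all_pix)
  if (!length(mzv))
    return(msi_matrix(numeric(0), matrix(0, 0, length(info)), coords))
  o <- order(mzv)
  mzv <- mzv[o]; v <- v[o]; pix <- pix[o]
  cl <- .cluster_sorted_mz(mzv, width = bin_ppm, unit = "ppm")
  k <- max(cl)
  w <- v
  w[w <= 0] <- min(w[w > 0], 1) * 1e-9  # weight guard for all-zero clusters
  centr <- vapply(split(seq_along(mzv), cl), function(ii)
    sum(mzv[ii] * w[ii]) / sum(w[ii]), numeric(1))
  vals <- matrix(0, nrow = k, ncol = length(info))
  for (r in seq_along(mzv)) vals[cl[r], pix[r]] <- vals[cl[r], pix[r]] + v[r]
  msi_matrix(centr, vals, coords)
}
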