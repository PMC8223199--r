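# Seeded synthetic MALDI-MSI generator: planted parent/adduct pairs with
# shared spatial patterns, matrix-cluster background, uncorrelated noise
# peaks, and ground truth.  The pipeline's offline test bed.

#' Specification for a synthetic MSI dataset
#'
#' Defaults describe the reference simulation used throughout the test
#' suite: a 32 x 32 raster with 20 tissue-localized parent ions, each
#' planted with a DHB-H2O matrix adduct at 30% of the parent intensity,
#' multiplicative log-normal pixel noise of CV 0.2 on the adduct images,
#' 1 ppm mass jitter, 30 spatially uncorrelated noise peaks, and 12
#' matrix-cluster peaks spread near-uniformly over the slide.  Isotope
#' companions can be planted too via `registry_subset = c("13C",
#' "DHB-H2O")`.
#'
#' @param width,height Raster size in pixels.
#' @param n_parents Number of parent ions.
#' @param registry_subset Names of [default_registry()] entries planted as
#'   adducts of every parent.
#' @param adduct_yield Adduct intensity as a fraction of the parent image.
#' @param pixel_noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise applied to adduct images (0 = noise-free).
#' @param mz_jitter_ppm Uniform per-peak mass error half-width in ppm.
#' @param n_background Number of spatially uncorrelated noise peaks.
#' @param n_matrix_peaks Number of matrix-cluster peaks (also emitted as
#'   the blank peak list).
#' @param mz_range m/z range (Da) peaks are drawn from.
#' @param matrix_compound MALDI matrix whose registry the planted adduct
#'   names refer to.
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(width = 32, height = 32, n_parents = 20,
                       registry_subset = "DHB-H2O",
                       adduct_yield = 0.3, pixel_noise_cv = 0.2,
                       mz_jitter_ppm = 1, n_background = 30,
                       n_matrix_peaks = 12, mz_range = c(100, 1000),
                       matrix_compound = "DHB", seed = 1) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_parents = as.integer(n_parents),
               registry_subset = registry_subset,
               adduct_yield = adduct_yield,
               pixel_noise_cv = pixel_noise_cv,
               mz_jitter_ppm = mz_jitter_ppm,
               n_background = as.integer(n_background),
               n_matrix_peaks = as.integer(n_matrix_peaks),
               mz_range = as.numeric(mz_range),
               matrix_compound = matrix_compound,
               seed = as.integer(seed))
  stopifnot(spec$width >= 1, spec$height >= 1,
            spec$width * spec$height >= 3,
            spec$n_parents >= 0, spec$n_background >= 0,
            spec$n_matrix_peaks >= 0,
            spec$adduct_yield > 0, spec$adduct_yield <= 1,
            spec$pixel_noise_cv >= 0, spec$mz_jitter_ppm >= 0,
            length(spec$mz_range) == 2, diff(spec$mz_range) > 0)
  structure(spec, class = "synth_spec")
}

# draw an m/z away from existing peaks; collisions closer than 4x the
# absolute jitter are re-drawn
.draw_mz <- function(lo, hi, existing, jitter_ppm, attempts = 100) {
  for (k in seq_len(attempts)) {
    mz <- stats::runif(1, lo, hi)
    gap <- 4 * jitter_ppm * 1e-6 * mz
    if (!length(existing) || all(abs(existing - mz) > gap)) return(mz)
  }
  stop("could not place an m/z value without collision after ",
       attempts, " attempts")
}

.jitter_mz <- function(mz, jitter_ppm) {
  if (jitter_ppm == 0) return(mz)
  mz * (1 + stats::runif(length(mz), -jitter_ppm, jitter_ppm) * 1e-6)
}

# 2-D Gaussian blob on the raster, truncated to zero below 0.5% of its
# peak so tissue-localized ions have true zeros outside the structure
.gaussian_blob <- function(width, height, peak) {
  cx <- stats::runif(1, 1, width); cy <- stats::runif(1, 1, height)
  sigma <- stats::runif(1, max(1.5, width / 16), max(2.5, width / 6))
  g <- expand.grid(x = seq_len(width), y = seq_len(height))
  v <- peak * exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * sigma^2))
  v[v < 0.005 * peak] <- 0
  list(values = v, cx = cx, cy = cy, sigma = sigma)
}

# multiplicative log-normal noise with mean 1 and the given CV
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic MSI dataset
#'
#' Every parent ion receives a smooth spatial pattern (2-D Gaussian blob
#' with random center and width, peak intensity log-uniform over two
#' decades).  Each planted adduct's noise-free image is `adduct_yield`
#' times the parent image, multiplied by i.i.d. log-normal noise of CV
#' `pixel_noise_cv`.  Matrix-cluster peaks get spatially near-uniform
#' images (uniform level with 5% noise) and are also emitted as the blank
#' peak list; background peaks get spatially uncorrelated per-pixel
#' log-normal intensities.  All m/z values are jittered by up to
#' `mz_jitter_ppm`; the output is fully reproducible from `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return List with `matrix` (an [msi_matrix()]), `truth` (data frame of
#'   planted `parent_mz`, `adduct_mz`, `adduct_name`), `blank` (a
#'   [peaklist()] of the matrix peaks), `parent_mz`, `background_mz`,
#'   `matrix_mz`, `blob` (per-parent blob parameters), and `spec`.
#' @export
generate_msi <- function(spec = synth_spec()) {
  if (!inherits(spec, "synth_spec")) stop("'spec' must be a synth_spec")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  registry <- default_registry(spec$matrix_compound)
  planted <- registry[registry$name %in% spec$registry_subset, , drop = FALSE]
  if (length(spec$registry_subset) && nrow(planted) < length(spec$registry_subset))
    stop("registry_subset names not in the default registry: ",
         paste(setdiff(spec$registry_subset, registry$name), collapse = ", "))
  npix <- spec$width * spec$height
  lo <- spec$mz_range[1]; hi <- spec$mz_range[2]
  max_delta <- if (nrow(planted)) max(planted$delta_mass) else 0
  parent_hi <- max(lo + 1, hi - max_delta - 1)

  mz_all <- numeric(0)
  mz_list <- list(); img_list <- list()
  truth <- data.frame(parent_mz = numeric(0), adduct_mz = numeric(0),
                      adduct_name = character(0))
  blob_info <- data.frame(parent_mz = numeric(0), cx = numeric(0),
                          cy = numeric(0), sigma = numeric(0),
                          peak = numeric(0))
  add_peak <- function(mz, img) {
    mz_list[[length(mz_list) + 1L]] <<- mz
    img_list[[length(img_list) + 1L]] <<- img
    mz_all <<- c(mz_all, mz)
  }

  for (i in seq_len(spec$n_parents)) {
    pm <- .draw_mz(lo, parent_hi, mz_all, spec$mz_jitter_ppm)
    # reserve the planted adduct positions too
    am <- pm + planted$delta_mass
    if (length(mz_all) &&
        any(vapply(am, function(a)
          any(abs(mz_all - a) <= 4 * spec$mz_jitter_ppm * 1e-6 * a),
          logical(1)))) {
      # adduct position collides: redraw the parent a few times
      tries <- 0
      repeat {
        pm <- .draw_mz(lo, parent_hi, mz_all, spec$mz_jitter_ppm)
        am <- pm + planted$delta_mass
        ok <- !any(vapply(am, function(a)
          any(abs(mz_all - a) <= 4 * spec$mz_jitter_ppm * 1e-6 * a),
          logical(1)))
        tries <- tries + 1
        if (ok || tries >= 100)
          break
      }
      if (!ok) stop("could not place parent/adduct m/z without collision")
    }
    peak <- 10^stats::runif(1, 3, 5)
    blob <- .gaussian_blob(spec$width, spec$height, peak)
    pm_j <- .jitter_mz(pm, spec$mz_jitter_ppm)
    add_peak(pm_j, blob$values)
    blob_info <- rbind(blob_info,
                       data.frame(parent_mz = pm_j, cx = blob$cx,
                                  cy = blob$cy, sigma = blob$sigma,
                                  peak = peak))
    for (a in seq_len(nrow(planted))) {
      am_j <- .jitter_mz(pm + planted$delta_mass[a], spec$mz_jitter_ppm)
      img <- spec$adduct_yield * blob$values *
        .ln_noise(npix, spec$pixel_noise_cv)
      add_peak(am_j, img)
      truth <- rbind(truth,
                     data.frame(parent_mz = pm_j, adduct_mz = am_j,
                                adduct_name = planted$name[a]))
    }
  }

  matrix_mz <- numeric(0)
  for (i in seq_len(spec$n_matrix_peaks)) {
    mm <- .draw_mz(lo, hi, mz_all, spec$mz_jitter_ppm)
    level <- 10^stats::runif(1, 3.5, 5.5)
    img <- level * (1 + stats::runif(npix, -0.05, 0.05))
    mm_j <- .jitter_mz(mm, spec$mz_jitter_ppm)
    add_peak(mm_j, img)
    matrix_mz <- c(matrix_mz, mm_j)
  }

  background_mz <- numeric(0)
  for (i in seq_len(spec$n_background)) {
    bm <- .draw_mz(lo, hi, mz_all, spec$mz_jitter_ppm)
    med <- 10^stats::runif(1, 2.5, 4.5)
    img <- med * stats::rlnorm(npix, 0, 1)
    bm_j <- .jitter_mz(bm, spec$mz_jitter_ppm)
    add_peak(bm_j, img)
    background_mz <- c(background_mz, bm_j)
  }

  coords <- expand.grid(x = seq_len(spec$width), y = seq_len(spec$height))
  vals <- do.call(rbind, lapply(img_list, as.numeric))
  mzv <- unlist(mz_list)
  m <- msi_matrix(mzv, vals, coords)
  blank <- if (length(matrix_mz)) {
    idx <- match(sort(matrix_mz), m$mz)
    peaklist(m$mz[idx], apply(m$values[idx, , drop = FALSE], 1, max))
  } else peaklist(numeric(0), numeric(0))
  truth <- truth[order(truth$parent_mz, truth$adduct_mz), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(matrix = m, truth = truth, blank = blank,
                 parent_mz = sort(blob_info$parent_mz),
                 background_mz = sort(background_mz),
                 matrix_mz = sort(matrix_mz),
                 blob = blob_info, spec = spec),
            class = "synth_msi")
}

#' @export
print.synth_msi <- function(x, ...) {
  cat(sprintf(
    "Synthetic MSI dataset (seed %d): %d x %d pixels, %d peaks\n",
    x$spec$seed, x$spec$width, x$spec$height, length(x$matrix$mz)))
  cat(sprintf("  %d parents, %d planted adduct pairs, %d matrix, %d background\n",
              x$spec$n_parents, nrow(x$truth), x$spec$n_matrix_peaks,
              x$spec$n_background))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the intensity matrix as CSV and imzML, the ground truth and the
#' blank peak list as TSV, and the generator settings as a plain-text
#' config.
#'
#' @param x A dataset from [generate_msi()] (or a [synth_spec()], which is
#'   generated first).
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_fixture <- function(x, dir) {
  if (inherits(x, "synth_spec")) x <- generate_msi(x)
  if (!inherits(x, "synth_msi")) stop("'x' must be a synth_spec or synth_msi")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(matrix_csv = file.path(dir, "intensity_matrix.csv"),
             imzml = file.path(dir, "dataset.imzML"),
             truth = file.path(dir, "ground_truth.tsv"),
             blank = file.path(dir, "blank_peaklist.tsv"),
             config = file.path(dir, "synth_spec.txt"))
  write_intensity_csv(x$matrix, files[["matrix_csv"]])
  write_imzml(x$matrix, files[["imzml"]])
  utils::write.table(x$truth, files[["truth"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_peaklist_tsv(x$blank, files[["blank"]])
  sp <- x$spec
  lines <- vapply(names(sp), function(k)
    paste0(k, "=", paste(format(sp[[k]], digits = 15), collapse = ",")),
    character(1))
  writeLines(lines, files[["config"]])
  invisible(files)
}
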