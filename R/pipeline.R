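# In-memory composition of the whole workflow: condition -> blank-subtract
# -> all-pairs mass differences -> registry matching -> spatial correlation
# -> false-positive screens -> summary.

#' Run the full adduct-screening pipeline
#'
#' @param m An [msi_matrix()].
#' @param blank Optional matrix-blank [peaklist()]; when given, matching
#'   sample peaks are removed before pair building.
#' @param registry An [adduct_registry()] (default: built-in DHB set).
#' @param tol A [tol_model()] or ppm value.
#' @param screen,alpha,q_cutoff,r_min See [screen_pairs()].
#' @param binwidth Delta-mass histogram bin width (Da).
#' @param unit Counting unit for the summary, see [count_by_type()].
#' @param intensity_fraction,freq_min,top_n Optional conditioning filters
#'   applied in this order before blank subtraction (see
#'   [filter_intensity()], [filter_frequency()], [filter_topn()]).
#' @param bin_width_ppm,bin_width_mda Optional peak binning applied first.
#' @return An `adduct_analysis` list: `matrix` (processed), `peaks`,
#'   `pairs` (matched + screened), `histogram`, `summary`, `total_peaks`
#'   (post-conditioning, pre-blank-subtraction denominator),
#'   `blank_report`, and the settings used.
#' @export
run_adduct_pipeline <- function(m, blank = NULL,
                                registry = default_registry("DHB"),
                                tol = tol_model(5),
                                screen = c("rcut", "bonferroni", "qvalue"),
                                alpha = 0.05, q_cutoff = 1e-7, r_min = 0.1,
                                binwidth = 0.005,
                                unit = c("distinct_adduct_peaks", "pairs"),
                                intensity_fraction = NULL, freq_min = NULL,
                                top_n = NULL, bin_width_ppm = NULL,
                                bin_width_mda = NULL) {
  screen <- match.arg(screen)
  unit <- match.arg(unit)
  tol <- .as_tol(tol)
  if (!is.null(bin_width_ppm)) m <- bin_peaks(m, bin_width_ppm, "ppm")
  if (!is.null(bin_width_mda)) m <- bin_peaks(m, bin_width_mda, "mda")
  if (!is.null(intensity_fraction)) m <- filter_intensity(m, intensity_fraction)
  if (!is.null(freq_min)) m <- filter_frequency(m, freq_min)
  if (!is.null(top_n)) m <- filter_topn(m, top_n)
  total_peaks <- length(m$mz)
  blank_report <- NULL
  if (!is.null(blank)) {
    sb <- subtract_blank(m, blank, tol)
    m <- sb$kept
    blank_report <- sb[c("removed", "n_removed", "n_kept")]
  }
  peaks <- collapse_to_peaklist(m, "max")
  pairs <- build_pairs(peaks)
  hist <- delta_histogram(pairs, binwidth)
  matched <- match_adducts(pairs, registry, tol)
  if (nrow(matched)) {
    matched <- correlate_pairs(m, matched)
    matched <- screen_pairs(matched, screen = screen, alpha = alpha,
                            q_cutoff = q_cutoff, r_min = r_min)
  } else {
    matched$r <- numeric(0); matched$p <- numeric(0)
    matched$passed <- logical(0)
  }
  summary <- if (nrow(matched))
    summarize_adducts(matched, total_peaks, screen = "passed", unit = unit)
  else
    data.frame(adduct_name = character(0), n_pairs = integer(0),
               n_distinct_adduct_peaks = integer(0),
               fraction_of_total_peaks = numeric(0),
               screen_used = character(0))
  structure(list(matrix = m, peaks = peaks, pairs = matched,
                 histogram = hist, summary = summary,
                 total_peaks = total_peaks, blank_report = blank_report,
                 registry = registry, tol = tol, screen = screen,
                 settings = list(alpha = alpha, q_cutoff = q_cutoff,
                                 r_min = r_min, binwidth = binwidth,
                                 unit = unit)),
            class = "adduct_analysis")
}

#' @export
print.adduct_analysis <- function(x, ...) {
  cat(sprintf("Adduct analysis: %d peaks (%d before blank subtraction)\n",
              length(x$matrix$mz), x$total_peaks))
  if (!is.null(x$blank_report))
    cat(sprintf("  blank subtraction removed %d peaks, kept %d\n",
                x$blank_report$n_removed, x$blank_report$n_kept))
  cat(sprintf("  %d matched pair rows, %d passing the '%s' screen\n",
              nrow(x$pairs), sum(x$pairs$passed), x$screen))
  if (nrow(x$summary)) {
    cat("Per-type summary:\n")
    print(x$summary, row.names = FALSE)
  }
  invisible(x)
}

#' Score recovery of planted adduct pairs
#'
#' Compares the passing pairs of an analysis against a synthetic ground
#' truth.  A truth pair is recovered when some passing row has both member
#' m/z within `match_ppm` of it; a passing (distinct) pair is a true
#' positive under the same rule.
#'
#' @param analysis An `adduct_analysis` (or a screened pair table).
#' @param truth Ground-truth data frame with `parent_mz`, `adduct_mz`
#'   (see [generate_msi()]).
#' @param match_ppm Matching tolerance in ppm.
#' @return List with `sensitivity`, `precision`, `n_truth`, `n_detected`,
#'   `n_true_positive`.
#' @export
evaluate_recovery <- function(analysis, truth, match_ppm = 5) {
  pairs <- if (inherits(analysis, "adduct_analysis")) analysis$pairs
           else analysis
  pass <- pairs[pairs$passed, , drop = FALSE]
  # distinct detected pairs (a row per registry entry can duplicate a pair)
  det <- unique(pass[, c("parent_mz", "adduct_mz")])
  tolp <- match_ppm * 1e-6
  is_tp <- function(pm, am)
    any(abs(truth$parent_mz - pm) <= tolp * pm &
        abs(truth$adduct_mz - am) <= tolp * am)
  tp_flags <- if (nrow(det))
    mapply(is_tp, det$parent_mz, det$adduct_mz) else logical(0)
  recovered <- if (nrow(truth))
    vapply(seq_len(nrow(truth)), function(i)
      nrow(det) > 0 &&
        any(abs(det$parent_mz - truth$parent_mz[i]) <=
              tolp * truth$parent_mz[i] &
            abs(det$adduct_mz - truth$adduct_mz[i]) <=
              tolp * truth$adduct_mz[i]),
      logical(1)) else logical(0)
  list(sensitivity = if (nrow(truth)) mean(recovered) else NA_real_,
       precision = if (nrow(det)) mean(tp_flags) else NA_real_,
       n_truth = nrow(truth), n_detected = nrow(det),
       n_true_positive = sum(tp_flags))
}
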