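---
title: "Screening MALDI-MSI data for matrix and alkali adducts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening MALDI-MSI data for matrix and alkali adducts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adductscreen)
```

## The problem

MALDI mass spectrometry imaging (MSI) acquires one mass spectrum per raster
pixel over a sample. A large share of the peaks in such spectra are not
distinct metabolites but *adducts*: the same molecule detected with an
attached sodium or potassium, a 13C isotope companion, or — specific to
MALDI — an attached matrix molecule such as DHB (2,5-dihydroxybenzoic acid)
or CHCA (alpha-cyano-4-hydroxycinnamic acid), frequently after loss of
water. Treating those peaks as independent compounds inflates peak counts
and produces false annotations, because a matrix adduct shift (e.g. C7H4O3,
136.016 Da) is indistinguishable by exact mass from a genuine chemical
difference between two metabolites.

`adductscreen` detects and quantifies such adducts from the data alone
using two orthogonal signals:

1. **Mass differences.** An adduct sits at a characteristic, exactly
   computable mass offset from its parent ion. Computing the mass
   difference of *every* pair of peaks and matching the differences
   against a registry of known offsets nominates candidate parent/adduct
   pairs.
2. **Spatial co-localization.** A true adduct is made from its parent
   wherever the parent is, so the two ion images should be positively
   correlated across pixels. Candidate pairs that are not co-localized are
   rejected as chance mass matches.

## The candidate-generation model

For peaks with masses $m_A < m_B$ the pair is a candidate for registry
entry $k$ with exact shift $\Delta_k$ when

$$|\,(m_B - m_A) - \Delta_k\,| \le p\,\sqrt{m_A^2 + m_B^2},$$

where $p$ is the relative mass accuracy of the dataset (default 5 ppm,
i.e. $p = 5\times10^{-6}$). The quadrature form propagates the two
independent per-peak uncertainties $p\,m_A$ and $p\,m_B$; a linear mode
$p\,(m_A + m_B)$ is available as a strictly more permissive alternative.
Quadrature is the default because it is the standard error-propagation
form and the tighter of the two defensible readings.

Every registry shift is *derived*, never hand-entered: entries are stored
as net formula changes (`"C7H4O3"`, `"NaH-1"`, `"[13C]C-1"`) and their
masses computed from a bundled table of monoisotopic isotope masses
(6+ decimals). Protonation adds the proton mass (H atom minus electron,
1.0072765 Da), which reproduces published lipid ion m/z values such as
PC(36:1) [M+H]+ at 788.616 to the printed precision. The built-in registry
covers the 13C companion, Na-for-H and K-for-H exchanges, DHB, DHB-H2O and
its 2x/3x oligomers, CHCA, CHCA with an additional sodium, and an
*implausible control* (107Ag-H, 105.897 Da): silver has no biological role,
so its detection rate estimates the chance-match floor. Further entries
load from a plain CSV (`name,formula,category`).

## The spatial screen

For each candidate pair the Pearson correlation $r$ between the two ion
images is computed over all pixels, with the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. Three screens are
computed side by side:

* **Bonferroni**: reject when $\min(1, m\,p) \ge \alpha$ with
  $\alpha = 0.05$ and $m$ the number of tested pairs;
* **Storey q-values**: reject when $q \ge 10^{-7}$;
* **correlation cutoff**: reject when $r \le r_{\min}$ (0.1 or 0.3 are the
  settings of practical interest).

All screens additionally require $r > 0$: the hypothesis is
co-localization, and a negatively correlated pair is not an adduct no
matter how significant. Zeros count as data — a pixel where a peak was not
detected contributes intensity 0, since co-absence is itself spatial
evidence (a mask restricting each pair to pixels where at least one member
is detected is available via `pixels = "either_nonzero"`).

The q-value implementation follows Storey's smoother method: $\hat\pi_0$
is estimated on the grid $\lambda = 0.05, 0.10, \dots, 0.95$ as
$\#\{p_i > \lambda\}/(m(1-\lambda))$, a cubic smoothing spline (3 df) is
extrapolated to $\lambda = 1$, and the estimate is bounded to $[0, 1]$.
With $\pi_0 = 1$ the q-values reduce exactly to Benjamini–Hochberg, which
the test suite asserts against `p.adjust`. A $\hat\pi_0$ of 0 is accepted
silently: in a matched-candidate set in which essentially every pair is a
real adduct it is the honest estimate.

## Dataset conditioning

The conditioning steps mirror common MSI preprocessing, each with an
explicit, testable rule:

* `bin_peaks()` — greedy ascending single-linkage merge of peaks closer
  than a width (ppm widths scale with the heavier peak's m/z; mDa widths
  are absolute). Merged m/z is the maximum-intensity-weighted centroid;
  per-pixel intensities are summed, so total intensity per pixel is
  conserved and no two output peaks lie within the width.
* `filter_intensity()` — keep peaks whose dataset maximum is at least a
  fraction (default 0.05%) of the reference intensity. "Maximum ion
  intensity" of a dataset is ambiguous between the global maximum
  single-pixel intensity and the maximum of the mean spectrum; both are
  implemented, global maximum is the default, and equality is kept (the
  threshold is a ">=").
* `filter_frequency()` — keep peaks detected in at least
  `ceiling(f * n_pixels)` pixels (default 1%). Ceiling, because 1% of 150
  pixels must mean at least 2 pixels, not 1.5.
* `filter_topn()` — keep the N most intense peaks by summed intensity,
  ties broken toward lower m/z for determinism.
* `subtract_blank()` — remove every sample peak within `p*m` of any peak
  in a matrix-only blank list, the direct control for matrix *cluster*
  ions (pure-matrix signals, as opposed to matrix *adducts* of analytes).

All filters are idempotent and commute with pixel reordering; both
properties are asserted in the tests.

## The synthetic test bed

Real MSI datasets are hundreds of megabytes and live in external archives,
so the package carries a seeded generator (`synth_spec()`,
`generate_msi()`) that emulates exactly the structure the method exploits:

* each **parent** ion gets a smooth spatial pattern — a 2-D Gaussian blob
  with random center and width, peak intensity log-uniform over two
  decades, truncated to zero below 0.5% of its peak so tissue-localized
  ions have true zeros off-structure;
* each planted **adduct** image is `adduct_yield` (default 0.3) times its
  parent image, multiplied by i.i.d. log-normal noise with unit mean and
  CV `pixel_noise_cv` (default 0.2). Multiplicative log-normal noise,
  rather than additive Gaussian, keeps intensities positive and
  heteroscedastic like real ion counts, and keeps the planted correlation
  analytically tractable: the suite checks the realized parent–adduct
  correlation against an independent Monte-Carlo of the same noise model;
* **matrix-cluster** peaks are spatially near-uniform (uniform level with
  5% noise) — matrix covers the whole slide — and are also emitted as the
  blank peak list;
* **background** peaks are spatially uncorrelated per-pixel log-normal
  noise, the "unstructured chemical noise" class that the correlation
  screens must reject;
* all m/z values are jittered by up to `mz_jitter_ppm` (default 1 ppm),
  and positions colliding within 4x the jitter are re-drawn.

The defaults (32 x 32 pixels, 20 parents, DHB-H2O adducts at yield 0.3,
noise CV 0.2, 30 background peaks, 12 matrix peaks, m/z 100–1000) are the
reference conditions for the end-to-end tests: the full pipeline
(blank-subtract, pair building, registry matching, correlation, r > 0.1)
must recover planted pairs with sensitivity and precision at least 0.9,
and the tallest non-isotope bin of the mass-difference histogram must be
the one containing 136.016 Da. For the screen-behavior checks a noise CV
of 0.45 is used, which under this blob-intensity model puts the planted
parent–adduct correlation at about 0.9 at 1024 pixels; there at least 95%
of planted pairs must clear r > 0.3 while at least 99% of mass-matched
background pairs fall to the Bonferroni screen.

What the generator does *not* emulate — and what green tests therefore do
not certify about real data: ionization suppression and other
matrix/analyte interactions, isotope envelopes beyond a single 13C
companion, spatial autocorrelation of noise (pixels are treated as
independent samples, in the screens as well as in the generator), mass
drift across the acquisition, and detector saturation.

## Numerical and design choices

* **Histogram bin width** 0.005 Da by default: narrow enough to separate
  the DHB shift (154.027) from neighboring organic deltas in the relevant
  mass range, wide enough that 1 ppm jitter rarely splits a population
  across bins; configurable.
* **Ambiguous matches** (one delta, several registry entries within
  tolerance) are all reported, flagged `ambiguous = TRUE`, never resolved:
  exact mass alone cannot distinguish them; that is MS2 territory.
* **Counting unit** for summaries: distinct peaks appearing as the adduct
  member of at least one passing pair (default), or raw pair counts. The
  distinct-peak unit avoids double-counting a peak that mass-matches two
  parents.
* **Summary denominator**: the post-conditioning, pre-blank-subtraction
  peak count by default, switchable, since the "fraction of total peaks"
  depends on whether matrix clusters are inside the denominator.
* **Degenerate inputs**: fewer than 2 peaks gives an empty pair table with
  a warning; constant ion images give `r = NA`, p = 1, and fail every
  screen; an empty blank list is the identity subtraction; fewer than 10
  p-values fixes pi0 at 1 with a warning.
* **Pair-table scale**: 10^4 peaks imply 5x10^7 pairs; `build_pairs()`
  therefore supports chunked streaming through a callback, so the full
  table never needs to be materialized.
* **Problem sizes in the tests** (32 x 32 rasters, up to 1000 peaks, 100
  random oracle instances per operation, 10^4 p-values, 10^5 Monte-Carlo
  samples) were chosen as the smallest sizes at which every property is
  non-trivially exercised on a single CPU.

## Workflow

```{r example, eval = FALSE}
d <- generate_msi(synth_spec(seed = 1))          # or read_imzml() / read_intensity_csv()
res <- run_adduct_pipeline(d$matrix, blank = d$blank, r_min = 0.1)
res$summary                                      # per-adduct-type fractions
top_bins(res$histogram, 5)                       # dominant mass differences
evaluate_recovery(res, d$truth)                  # vs. planted ground truth
plot(ion_image(d$matrix, d$parent_mz[1]))        # spatial distribution
```

The same steps are exposed as shell subcommands (`simulate`, `preprocess`,
`blank-subtract`, `massdiff`, `match`, `correlate`, `screen`, `summarize`,
`ion-image`, `run-all`) through the installed script in
`system.file("cli", "adductscreen.R", package = "adductscreen")`; `run-all`
is the literal composition of the stepwise handlers, so stepwise and
one-shot runs produce byte-identical files.

## Known limitations

* Positive-ion mode and singly charged ions only; average (abundance-
  weighted) masses are out of scope.
* The imzML reader/writer covers centroided continuous and processed
  files with external binary arrays — the common interchange case — not
  the full imzML surface (compressed arrays, profile spectra).
* Registry defaults cover the adduct chemistry named above; site- or
  matrix-specific transformations should be supplied via the CSV loader
  rather than guessed at.
* Correlation screens treat pixels as exchangeable; strong spatial
  autocorrelation makes the nominal p-values optimistic, which is one
  reason the correlation-cutoff screen is reported alongside the
  significance-based ones.
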