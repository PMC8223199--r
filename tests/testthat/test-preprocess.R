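# Tolerance models, binning, conditioning filters, blank subtraction.

test_that("pair and single tolerances follow the ppm model", {
  tq <- tol_model(5, "quadrature")
  tl <- tol_model(5, "linear")
  expect_equal(pair_tolerance(tl, 1000, 1000), 0.01)
  expect_equal(pair_tolerance(tq, 1000, 1000), 5e-6 * sqrt(2e6))
  expect_equal(single_tolerance(tq, 200), 0.001)
  expect_equal(single_tolerance(tq, 0), 0)
  expect_equal(single_tolerance(tq, 400), 2 * single_tolerance(tq, 200))
  # tolerance vanishes with the mass accuracy
  expect_lt(pair_tolerance(tol_model(1e-6), 500, 600), 1e-8)
  # monotone increasing in mass
  expect_true(all(diff(pair_tolerance(tq, seq(100, 900, 100), 1000)) > 0))
  expect_error(tol_model(0), "positive")
})

test_that("bin_peaks merges within the width and conserves intensity", {
  m <- toy_matrix(c(500.0000, 500.0020), c(1, 2, 3, 4))
  b <- bin_peaks(m, 5, "ppm")   # width 0.0025 at m/z 500
  expect_equal(length(b$mz), 1)
  expect_equal(colSums(b$values), colSums(m$values))

  m2 <- toy_matrix(c(500.0000, 500.0100), c(1, 2, 3, 4))
  expect_equal(length(bin_peaks(m2, 5, "ppm")$mz), 2)

  # merged m/z is the max-intensity-weighted centroid
  m3 <- toy_matrix(c(100.000, 100.0002), c(1, 3))
  b3 <- bin_peaks(m3, 5, "ppm")
  expect_equal(b3$mz, (100.000 * 1 + 100.0002 * 3) / 4)
})

test_that("bin_peaks equals the brute-force single-linkage merge", {
  set.seed(101)
  for (k in 1:20) {
    m <- rand_matrix(200, 4, mz_range = c(100, 101))  # dense -> many merges
    for (spec in list(c(5, NA), c(20, NA), c(NA, 1))) {
      if (is.na(spec[2])) { width <- spec[1]; unit <- "ppm" }
      else { width <- spec[2]; unit <- "mda" }
      got <- bin_peaks(m, width, unit)
      want <- oracle_bin(m, width, unit)
      expect_equal(got$mz, want$mz, tolerance = 1e-12)
      expect_equal(got$values, want$values, tolerance = 1e-12)
      # idempotence and per-pixel conservation
      expect_equal(colSums(got$values), colSums(m$values))
    }
  }
})

test_that("intensity filter keeps the boundary and respects the reference", {
  m <- toy_matrix(c(100, 200, 300), c(1e6, 500, 499, 0, 0, 0))
  f <- filter_intensity(m, 5e-4)
  expect_equal(f$mz, c(100, 200))  # 500 = threshold kept, 499 dropped
  expect_error(filter_intensity(m, 0), "between")
  expect_error(filter_intensity(m, 1), "between")
  # near-1 fraction keeps only the top peak
  expect_equal(filter_intensity(m, 0.999)$mz, 100)
  # mean-spectrum reference is the permissive alternative
  expect_gte(length(filter_intensity(m, 5e-4, "mean_spectrum")$mz), 2)
})

test_that("frequency filter applies a ceiling pixel-count threshold", {
  mk <- function(n_pixels, n_hit) {
    v <- matrix(0, 2, n_pixels)
    v[1, seq_len(n_hit)] <- 1
    v[2, ] <- 1
    msi_matrix(c(100, 200), v, data.frame(x = seq_len(n_pixels), y = 1))
  }
  expect_equal(length(filter_frequency(mk(100, 1), 0.01)$mz), 2)   # 1 >= ceil(1)
  expect_equal(length(filter_frequency(mk(1000, 9), 0.01)$mz), 1)  # 9 < 10
  m <- mk(100, 1)
  expect_equal(filter_frequency(m, 0)$mz, m$mz)  # identity at 0
})

test_that("top-N filter equals brute-force sort-and-take", {
  set.seed(202)
  m <- rand_matrix(50, 5)
  expect_equal(filter_topn(m, 50)$mz, m$mz)
  expect_equal(filter_topn(m, 1)$mz, m$mz[which.max(rowSums(m$values))])
  for (k in 1:20) {
    mm <- rand_matrix(sample(10:80, 1), 4)
    n <- sample(1:15, 1)
    expect_equal(filter_topn(mm, n)$mz, oracle_topn(mm, n))
  }
  # deterministic tie-break: lower m/z wins
  mt <- toy_matrix(c(100, 200, 300), rep(1, 3))
  expect_equal(filter_topn(mt, 2)$mz, c(100, 200))
})

test_that("filters are idempotent and commute with pixel reordering", {
  set.seed(303)
  m <- rand_matrix(60, 8)
  ops <- list(function(x) filter_intensity(x, 0.05),
              function(x) filter_frequency(x, 0.3),
              function(x) filter_topn(x, 20),
              function(x) bin_peaks(x, 200, "ppm"))
  perm <- sample(8)
  mp <- msi_matrix(m$mz, m$values[, perm], m$coords[perm, ])
  for (op in ops) {
    once <- op(m)
    expect_equal(op(once)$mz, once$mz)
    expect_equal(op(once)$values, once$values)
    expect_equal(op(mp)$mz, once$mz)  # same peaks kept under reordering
  }
})

test_that("blank subtraction removes exactly the in-tolerance peaks", {
  s <- peaklist(c(100.0000, 200.0000))
  b <- peaklist(200.00005)
  out <- subtract_blank(s, b, tol_model(5))
  expect_equal(out$kept$mz, 100)
  expect_equal(out$n_removed, 1)
  expect_equal(out$removed$blank_mz, 200.00005)

  out0 <- subtract_blank(s, peaklist(numeric(0)))
  expect_equal(out0$kept$mz, s$mz)
  expect_equal(out0$n_removed, 0)
})

test_that("blank subtraction equals the brute-force all-pairs check", {
  set.seed(404)
  for (k in 1:25) {
    smz <- sort(runif(60, 100, 110))
    bmz <- sort(c(sample(smz, 10) * (1 + runif(10, -3e-6, 3e-6)),
                  runif(20, 100, 110)))
    s <- peaklist(smz)
    b <- peaklist(bmz)
    out <- subtract_blank(s, b, tol_model(5))
    removed <- oracle_subtract(smz, bmz, 5)
    expect_equal(out$kept$mz, smz[!removed])
    expect_equal(out$n_removed + out$n_kept, length(smz))
    # survivors share no peak with the blank within tolerance
    expect_equal(subtract_blank(out$kept, b, tol_model(5))$n_removed, 0)
  }
})

test_that("blank subtraction works on intensity matrices too", {
  m <- toy_matrix(c(100, 200, 300), rep(1, 6))
  out <- subtract_blank(m, peaklist(c(200.0000002, 555)), tol_model(5))
  expect_s3_class(out$kept, "msi_matrix")
  expect_equal(out$kept$mz, c(100, 300))
  expect_equal(ncol(out$kept$values), 2)
})
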