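# All-pairs mass differences, the delta-mass histogram, registry matching,
# and per-type counting.

test_that("build_pairs enumerates every unordered pair, heavier minus lighter", {
  p <- build_pairs(peaklist(c(100, 200, 336.016)))
  expect_equal(nrow(p), 3)
  expect_equal(sort(p$delta), c(100, 136.016, 236.016))
  expect_true(all(p$delta > 0))
  expect_equal(nrow(build_pairs(peaklist(c(50, 60)))), 1)
  expect_warning(p0 <- build_pairs(peaklist(100)), "fewer than 2")
  expect_equal(nrow(p0), 0)
  # deterministic ordering by parent then adduct m/z
  p <- build_pairs(peaklist(c(3, 1, 2) * 100))
  expect_equal(p$parent_mz, c(100, 100, 200))
  expect_equal(p$adduct_mz, c(200, 300, 300))
})

test_that("build_pairs matches the brute-force double loop", {
  set.seed(11)
  for (n in c(2, 5, 23, 60)) {
    mz <- sort(runif(n, 100, 1000))
    got <- build_pairs(peaklist(mz))
    want <- oracle_pairs(mz)
    expect_equal(nrow(got), n * (n - 1) / 2)
    expect_equal(got$parent_mz, want$parent_mz)
    expect_equal(got$adduct_mz, want$adduct_mz)
    expect_equal(got$delta, want$delta)
  }
})

test_that("chunked streaming reproduces the full pair table", {
  mz <- sort(runif(80, 100, 500))
  full <- build_pairs(peaklist(mz))
  chunks <- list()
  res <- build_pairs(peaklist(mz),
                     chunk_fun = function(ch) chunks[[length(chunks) + 1]] <<- ch,
                     chunk_size = 500)
  expect_null(res)
  expect_gt(length(chunks), 1)
  streamed <- do.call(rbind, chunks)
  expect_equal(as.data.frame(streamed), as.data.frame(full))
})

test_that("delta histogram bins pair differences from zero", {
  pairs <- data.frame(delta = c(1.0, 1.0004, 2.0))
  h <- delta_histogram(pairs, 0.005)
  expect_equal(sum(h$counts), 3)
  occ <- h$counts[h$counts > 0]
  expect_equal(sort(occ), c(1, 2))
  tb <- top_bins(h, 1)
  expect_equal(tb$count, 2)
  expect_true(abs(tb$center - 1.0) < 0.005)

  h0 <- delta_histogram(data.frame(delta = numeric(0)))
  expect_equal(h0$n_pairs, 0)
  expect_equal(length(h0$counts), 0)
  expect_equal(nrow(top_bins(h0)), 0)
})

test_that("match_adducts annotates in-tolerance pairs", {
  reg <- default_registry("DHB")
  pairs <- build_pairs(peaklist(c(788.6164, 924.6324)))
  m <- match_adducts(pairs, reg, tol_model(5))
  expect_equal(nrow(m), 1)
  expect_equal(m$adduct_name, "DHB-H2O")
  expect_lt(abs(m$error_da), 1e-3)

  pairs <- build_pairs(peaklist(c(100, 101.00336)))
  m <- match_adducts(pairs, reg, tol_model(5))
  expect_equal(m$adduct_name, "13C")
})

test_that("match_adducts equals a brute-force scan on random instances", {
  set.seed(22)
  reg <- default_registry("DHB")
  for (k in 1:15) {
    mz <- sort(c(runif(25, 100, 900),
                 runif(15, 100, 700) + sample(reg$delta_mass, 15, TRUE)))
    pairs <- build_pairs(peaklist(mz))
    for (mode in c("quadrature", "linear")) {
      got <- match_adducts(pairs, reg, tol_model(5, mode))
      want <- oracle_match(pairs, reg, 5, mode)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        want_keys <- sort(paste(pairs$parent_mz[want[, 1]],
                                pairs$adduct_mz[want[, 1]],
                                reg$name[want[, 2]]))
        got_keys <- sort(paste(got$parent_mz, got$adduct_mz, got$adduct_name))
        expect_equal(got_keys, want_keys)
      }
    }
  }
})

test_that("matching is monotone in tolerance and registry size", {
  set.seed(33)
  mz <- sort(runif(150, 100, 1000))
  pairs <- build_pairs(peaklist(mz))
  reg <- default_registry("DHB")
  key <- function(m) paste(m$parent_index, m$adduct_index, m$adduct_name)
  m5 <- match_adducts(pairs, reg, tol_model(5))
  m20 <- match_adducts(pairs, reg, tol_model(20))
  expect_true(all(key(m5) %in% key(m20)))
  sub <- structure(reg[reg$category == "matrix", ],
                   class = c("adduct_registry", "data.frame"))
  msub <- match_adducts(pairs, sub, tol_model(20))
  expect_true(all(key(msub) %in% key(m20)))
})

test_that("ambiguous deltas are reported once per matching entry", {
  reg <- suppressWarnings(
    adduct_registry(c("a", "b"), c("C2H4", "[13C]CH3"), "custom"))
  pairs <- build_pairs(peaklist(c(100, 100 + monoisotopic_mass("C2H4"))))
  m <- match_adducts(pairs, reg, tol_model(50))
  expect_equal(nrow(m), 2)
  expect_true(all(m$ambiguous))
})

test_that("count_by_type supports distinct-peak and pair units", {
  matched <- data.frame(
    parent_index = c(1, 2, 3, 4), adduct_index = c(5, 6, 7, 7),
    parent_mz = 1:4, adduct_mz = 5:8, delta = 1,
    adduct_name = c("DHB-H2O", "DHB-H2O", "DHB-H2O", "DHB-H2O"))
  tab <- count_by_type(matched, total_peaks = 10)
  expect_equal(tab$fraction, 0.3)  # peaks 5,6,7 -> 3 of 10
  tab2 <- count_by_type(matched, 10, unit = "pairs")
  expect_equal(tab2$fraction, 0.4)
  # a passed column restricts the counts
  matched$passed <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(count_by_type(matched, 10)$fraction, 0.2)
})

test_that("pair tables round-trip through TSV", {
  pairs <- match_adducts(build_pairs(peaklist(c(100, 101.00336, 236.016))),
                         default_registry("DHB"), tol_model(5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pairs_tsv(pairs, f)
  back <- read_pairs_tsv(f)
  expect_equal(back$adduct_name, pairs$adduct_name)
  expect_equal(back$delta, pairs$delta, tolerance = 1e-9)
})
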