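# Formula parsing, monoisotopic masses, protonated ions, and the adduct
# registry.

test_that("formula parsing handles counts, signs, isotopes, and errors", {
  f <- parse_formula("C7H4O3")
  expect_equal(unclass(f)[c("C", "H", "O")], c(C = 7, H = 4, O = 3))
  expect_length(parse_formula(""), 0)
  f <- parse_formula("NaH-1")
  expect_equal(unclass(f)[["Na"]], 1)
  expect_equal(unclass(f)[["H"]], -1)
  f <- parse_formula("[13C]C-1")
  expect_equal(unclass(f)[["[13C]"]], 1)
  expect_equal(unclass(f)[["C"]], -1)
  # repeated symbols accumulate; zero counts vanish
  expect_equal(unclass(parse_formula("CHC"))[["C"]], 2)
  expect_length(parse_formula("CC-1"), 0)
  expect_error(parse_formula("Xx2"), "unknown element")
  expect_error(parse_formula("C7h4"), "position")
  expect_error(parse_formula("[13Q]"), "unknown element|position")
})

test_that("formula formatting round-trips through the parser", {
  cases <- c("C7H4O3", "C44H86NO8P", "NaH-1", "[13C]C-1", "[107Ag]H-1",
             "H-2O-1", "C10H7NO3Na")
  sorted <- function(f) {
    x <- unclass(f)
    x[order(names(x))]
  }
  for (txt in cases) {
    f <- parse_formula(txt)
    expect_equal(sorted(parse_formula(format(f))), sorted(f), info = txt)
    expect_equal(monoisotopic_mass(parse_formula(format(f))),
                 monoisotopic_mass(f), info = txt)
  }
})

test_that("mass is additive over formula arithmetic", {
  set.seed(42)
  syms <- c("C", "H", "N", "O", "P", "Na", "K", "S", "Cl")
  for (k in 1:25) {
    a <- parse_formula(paste0(sample(syms, 3), sample(1:9, 3), collapse = ""))
    b <- parse_formula(paste0(sample(syms, 3), sample(-4:4, 3), collapse = ""))
    expect_equal(monoisotopic_mass(a + b),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-12)
    expect_equal(monoisotopic_mass(a - b),
                 monoisotopic_mass(a) - monoisotopic_mass(b),
                 tolerance = 1e-12)
  }
})

test_that("monoisotopic masses reproduce reference values", {
  expect_equal(round(monoisotopic_mass("C7H4O3"), 3), 136.016)
  expect_equal(round(monoisotopic_mass("H2O"), 3), 18.011)
  expect_equal(monoisotopic_mass(""), 0)
  expect_equal(round(monoisotopic_mass("C7H6O4") - monoisotopic_mass("H2O"), 3),
               136.016)
  expect_error(monoisotopic_mass(structure(c(Zz = 1), class = "mol_formula")),
               "Zz")
})

test_that("protonated ion m/z uses the proton (not H-atom) mass", {
  expect_equal(round(ion_mz("C44H86NO8P"), 3), 788.616)
  expect_equal(round(ion_mz("C42H80NO7P"), 3), 742.575)
  expect_equal(round(ion_mz("C7H4O3"), 2), 137.02)
  expect_lt(proton_mass(), monoisotopic_mass("H"))
  expect_equal(proton_mass(), 1.00727646, tolerance = 1e-7)
  expect_error(ion_mz("C6H12O6", charge = 2), "singly charged")
  expect_error(ion_mz("CH-2"), "non-negative")
})

test_that("default registries carry formula-derived mass shifts", {
  for (mx in c("DHB", "CHCA", "none")) {
    reg <- default_registry(mx)
    expect_false(anyDuplicated(reg$name) > 0)
    expect_true(all(reg$delta_mass > 0))
    # every shift is recomputable from its formula
    expect_equal(reg$delta_mass,
                 vapply(reg$formula, function(f) monoisotopic_mass(f),
                        numeric(1), USE.NAMES = FALSE))
    expect_true("Ag107-H" %in% reg$name)
    expect_equal(round(reg$delta_mass[reg$name == "Ag107-H"], 3), 105.897)
    expect_equal(round(reg$delta_mass[reg$name == "13C"], 3), 1.003)
  }
  dhb <- default_registry("DHB")
  expect_equal(round(dhb$delta_mass[dhb$name == "DHB-H2O"], 3), 136.016)
  expect_equal(round(dhb$delta_mass[dhb$name == "DHB"], 3), 154.027)
  expect_equal(round(dhb$delta_mass[dhb$name == "2(DHB-H2O)"], 3), 272.032)
  chca <- default_registry("CHCA")
  expect_equal(round(chca$delta_mass[chca$name == "CHCA"], 2), 189.04)
  expect_equal(round(chca$delta_mass[chca$name == "CHCA+Na"], 3), 212.032)
  expect_false(any(default_registry("none")$category == "matrix"))
  wl <- default_registry("DHB", include_water_loss = TRUE)
  expect_equal(round(wl$delta_mass[wl$name == "-H2O"], 3), -18.011)
})

test_that("registry CSV loading derives masses and replaces duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment line", "name,formula,category",
               "waterloss,H-2O-1,custom"), path)
  reg <- load_registry(path)
  expect_equal(round(reg$delta_mass, 3), -18.011)

  writeLines("name,formula,category", path)
  expect_equal(nrow(load_registry(path)), 0)

  writeLines(c("name,formula,category", "DHB-H2O,C7H4O3,matrix"), path)
  base <- default_registry("DHB")
  expect_warning(merged <- load_registry(path, base = base), "replacing")
  expect_equal(nrow(merged), nrow(base))
  expect_equal(sum(merged$name == "DHB-H2O"), 1)

  writeLines(c("name,formula,category", "bad,Qq9,custom"), path)
  expect_error(load_registry(path), "row 1")
})

test_that("near-degenerate registry entries trigger a warning", {
  expect_warning(adduct_registry(c("a", "b"), c("C2H4", "C2H4"),
                                 c("custom", "custom")),
                 "1e-4")
  expect_error(adduct_registry(c("a", "a"), c("C2H4", "CO")), "duplicate")
})

test_that("the shipped example registry CSV loads", {
  path <- system.file("extdata", "example_registry.csv",
                      package = "adductscreen")
  reg <- load_registry(path)
  expect_equal(nrow(reg), 2)
  expect_equal(round(reg$delta_mass[reg$name == "waterloss"], 3), -18.011)
  expect_equal(round(reg$delta_mass[reg$name == "2x13C"], 3), 2.007)
})
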