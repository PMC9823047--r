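test_that("monoisotopic and anion masses follow the atomic constants", {
  expect_identical(monoisotopic_mass(formula_cho(0, 0, 0)), 0)
  # benzoic acid, hand-summed from the monoisotopic atomic masses
  expect_equal(monoisotopic_mass("C7H6O2"), 122.03678, tolerance = 1e-7)
  # one 13C substitution adds exactly (13.00335483507 - 12)
  expect_equal(monoisotopic_mass(formula_cho(7, 6, 2, 1)), 123.04013,
               tolerance = 1e-7)
  expect_equal(monoisotopic_mass(formula_cho(7, 6, 2, 1)) -
                 monoisotopic_mass("C7H6O2"), 13.00335483507 - 12)
  # anion m/z = mass + electron mass, for any formula
  for (f in list(formula_cho(7, 5, 2), formula_cho(18, 25, 5),
                 formula_cho(10, 9, 4, 4))) {
    expect_equal(anion_mz(f) - monoisotopic_mass(f), 0.00054857990)
  }
})

test_that("the diagnostic trio m/z values come out of the constants", {
  expect_equal(round(anion_mz("C7H5O2"), 4), 121.0295)
  expect_equal(round(anion_mz("C8H3O3"), 4), 147.0088)
  expect_equal(round(anion_mz("C8H5O4"), 4), 165.0193)
})

test_that("RDBE is evaluated on the reconstructed neutral", {
  expect_equal(rdbe_neutral("C10H9O4"), 6)  # monoethyl phthalate anion
  expect_equal(rdbe_neutral("C6H5O"), 4)
  expect_equal(rdbe_neutral("C18H25O5"), 6)
})

test_that("formula strings round-trip through Hill notation", {
  for (s in c("C10H10O4", "C7H5O2", "C6[13C]4H10O4", "CH4O10")) {
    expect_identical(format(parse_formula(s)), s)
  }
  f <- parse_formula("C6[13C]4H10O4")
  expect_equal(f$n_carbon, 10L)
  expect_equal(f$n_carbon13, 4L)
  expect_error(parse_formula("C6H5N"), "only C, H, O")
  expect_error(formula_cho(2, 4, 1, 3), "n_carbon13")
})

test_that("formula enumeration honors the elemental restrictions", {
  hits <- enumerate_formulas(321.1709)
  expect_true("C18H25O5" %in% hits$formula)
  expect_true(all(abs(hits$ppm_error) <= 5))
  expect_true(all(hits$rdbe >= 6 & hits$rdbe <= 12))
  expect_true(all(hits$n_hydrogen %% 2 == 1))  # even-electron neutral
  # the 121.0295 fragment violates c_min = 8 and o_min = 4
  expect_equal(nrow(enumerate_formulas(121.0295)), 0)
  # results are sorted by |ppm error|
  expect_true(!is.unsorted(abs(hits$ppm_error)))
})

test_that("enumeration agrees with a pruning-free brute force", {
  # independent oracle: full triple scan of the constraint grid with its own
  # mass arithmetic
  brute <- function(mz_obs) {
    out <- character(0)
    for (nc in 8:30) for (nh in 6:60) for (no in 4:10) {
      if (nh %% 2 == 0) next                     # even-electron neutral
      m <- nc * 12 + nh * 1.00782503207 + no * 15.99491461956 + 0.00054857990
      if (abs((m - mz_obs) / mz_obs * 1e6) > 5) next
      r <- nc - (nh + 1) / 2 + 1
      if (r < 6 || r > 12) next
      out <- c(out, sprintf("C%d|H%d|O%d", nc, nh, no))
    }
    sort(out)
  }
  set.seed(42)
  for (mz_obs in runif(40, 150, 800)) {
    got <- enumerate_formulas(mz_obs)
    got_keys <- sort(sprintf("C%d|H%d|O%d", got$n_carbon, got$n_hydrogen,
                             got$n_oxygen))
    expect_identical(got_keys, brute(mz_obs))
  }
})

test_that("panel [M-H]- ions enumerate to their own formula at rank 1", {
  panel <- default_panel()
  nat <- panel[!panel$labelled & !panel$is_decoy, ]
  for (i in seq_len(nrow(nat))) {
    hits <- enumerate_formulas(nat$mz[i])
    expect_gt(nrow(hits), 0)
    ion <- parse_formula(nat$formula[i])
    expect_equal(hits$n_carbon[1], ion$n_carbon)
    expect_equal(hits$n_hydrogen[1], ion$n_hydrogen - 1L)
    expect_equal(hits$n_oxygen[1], ion$n_oxygen)
    expect_equal(hits$ppm_error[1], 0, tolerance = 1e-9)
  }
})
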