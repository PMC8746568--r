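test_that("adduct m/z applies atom deltas with electron correction", {
  # proton = H - e-, sodiated = Na - e-
  expect_equal(adduct_mz(754.23203, "[M+Na]+"), 777.22125, tolerance = 1e-5)
  expect_equal(adduct_mz(224.06847, "[M+H]+"), 225.07575, tolerance = 1e-5)
  expect_equal(adduct_mz(100, "[M+H]+") - 100, 1.00727646, tolerance = 1e-7)
  expect_equal(100 - adduct_mz(100, "[M-H]-"), 1.00727646, tolerance = 1e-7)
  expect_equal(adduct_mz(100, "[M+Na]+") - 100, 22.98922070, tolerance = 1e-7)
  expect_error(adduct_mz(100, "[M+K]+"), "supported")
})

test_that("neutral mass deduction inverts adduct m/z for every adduct", {
  for (ad in supported_adducts()) {
    for (m in c(100.0, 224.06847, 754.23203)) {
      expect_equal(neutral_mass_from_adduct(adduct_mz(m, ad), ad), m,
                   tolerance = 1e-9)
    }
  }
  expect_equal(neutral_mass_from_adduct(777.22101, "[M+Na]+"), 754.23179,
               tolerance = 1e-5)
  expect_equal(neutral_mass_from_adduct(753.22528, "[M-H]-"), 754.23256,
               tolerance = 1e-5)
  # the typographic minus sign used in print is accepted
  expect_equal(neutral_mass_from_adduct(753.22528, "[M−H]−"),
               754.23256, tolerance = 1e-5)
})

test_that("ppm error has the fixed measured-minus-theoretical sign", {
  theo <- adduct_mz(monoisotopic_mass("C34H42O19"), "[M+Na]+")
  expect_equal(ppm_error(777.22101, theo), -0.309, tolerance = 0.002)
  expect_equal(ppm_error(123.4, 123.4), 0)
  theo9 <- adduct_mz(monoisotopic_mass("C16H20O8"), "[M+H]+")
  expect_equal(theo9, 341.12309, tolerance = 1e-5)
  expect_equal(ppm_error(341.12158, theo9), -4.438, tolerance = 0.005)
  # antisymmetric to first order, strictly monotone in the measured value
  expect_equal(ppm_error(100.0001, 100), -ppm_error(100, 100.0001),
               tolerance = 1e-3)
  expect_true(ppm_error(100.0002, 100) > ppm_error(100.0001, 100))
})

test_that("nominal shifts recover the printed integer mass differences", {
  expect_identical(nominal_shift(777.22101, 571.16290), 206L)
  expect_identical(nominal_shift(5.0, 5.0), 0L)
  expect_identical(nominal_shift(777.22101, 735.17440), 42L)
})

test_that("computed ppm errors reproduce the printed positive-mode values", {
  fx <- cached_fixture()
  printed <- c(M0_pos = -0.309, M1_pos = -0.773, M2_pos = -0.529,
               M3_pos = -0.553, M6_pos = -0.485, M7_pos = -0.222,
               M9_pos = -4.438, M12_pos = 0.456, M13_pos = -0.338,
               M18_pos = 0.5040)
  for (fid in names(printed)) {
    row <- fx$features[fx$features$feature_id == fid, ]
    theo <- adduct_mz(monoisotopic_mass(row$formula), row$adduct)
    expect_lt(abs(ppm_error(row$mz, theo) - printed[[fid]]), 0.01,
              label = paste("ppm mismatch at", fid))
  }
})

test_that("every fixture row sits within 7 ppm of its composition, all but one within 5", {
  fx <- cached_fixture()
  pp <- vapply(seq_len(nrow(fx$features)), function(i) {
    row <- fx$features[i, ]
    ppm_error(row$mz, adduct_mz(monoisotopic_mass(row$formula), row$adduct))
  }, numeric(1))
  expect_true(all(abs(pp) <= 7))
  over5 <- fx$features$feature_id[abs(pp) > 5]
  expect_identical(over5, "M14_neg")
})
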