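# independent mass table for the summation oracles, typed in by hand
.h <- 1.0078250319; .c <- 12; .n <- 14.0030740; .o <- 15.9949146
.na <- 22.9897693

test_that("formula parsing handles implicit counts and repeats", {
  expect_equal(unclass(parse_formula("CH4")), c(C = 1L, H = 4L),
               ignore_attr = TRUE)
  f <- parse_formula("C27H40N2O4")
  expect_equal(as.integer(f[c("C", "H", "N", "O")]), c(27L, 40L, 2L, 4L))
  expect_equal(unclass(parse_formula("CH3CH3")), c(C = 2L, H = 6L),
               ignore_attr = TRUE)
  expect_error(parse_formula("C27H40Xx2"), class = "chemocomp_data_error")
  expect_error(parse_formula("C27H40N0"), class = "chemocomp_data_error")
  expect_error(parse_formula(""), class = "chemocomp_validation_error")
})

test_that("monoisotopic masses match independent summation", {
  expect_identical(monoisotopic_mass("C"), 12)
  expect_equal(monoisotopic_mass("C9H19O2"),
               9 * .c + 19 * .h + 2 * .o, tolerance = 1e-12)
  expect_equal(round(monoisotopic_mass("C9H19O2"), 4), 159.1385)
  expect_equal(monoisotopic_mass("C27H40N2O4"),
               27 * .c + 40 * .h + 2 * .n + 4 * .o, tolerance = 1e-12)
  expect_equal(round(monoisotopic_mass("C27H40N2O4"), 4), 456.2988)
})

test_that("monoisotopic mass is additive over formula union", {
  expect_equal(monoisotopic_mass("C6H12O6"),
               monoisotopic_mass("C3H6O3") + monoisotopic_mass("C3H6O3"),
               tolerance = 1e-12)
  expect_equal(monoisotopic_mass("C27H40N2O4"),
               monoisotopic_mass("C18H26N2O2") +
                 monoisotopic_mass("C9H14O2"), tolerance = 1e-12)
})

test_that("adduct m/z follows the electron-corrected ion equation", {
  # sodiated ion of the C27H40N2O4 metabolite, electron-corrected
  expect_equal(round(adduct_mz("C27H40N2O4", "[M+Na]+"), 4), 479.2880)
  # a pre-parsed formula object gives the same answer as its string
  expect_equal(adduct_mz(parse_formula("C27H40N2O4"), "[M+Na]+"),
               adduct_mz("C27H40N2O4", "[M+Na]+"))
  # protonated 2-methyloctanoic acid as a plain atomic sum (no electron)
  expect_equal(round(adduct_mz("C9H18O2", "[M+H]+",
                               electron_correction = FALSE), 4), 159.1385)
  # definitional: neutral mass + proton mass without correction
  M <- 250.123
  expect_equal(adduct_mz(M, "[M+H]+", electron_correction = FALSE),
               M + 1.0078250319, tolerance = 1e-12)
  # toggling the correction moves m/z by exactly z*m_e/|z|
  for (a in c("[M+H]+", "[M+Na]+", "[M+2H]2+", "[M-H]-")) {
    on <- adduct_mz(M, a, electron_correction = TRUE)
    off <- adduct_mz(M, a, electron_correction = FALSE)
    expect_equal(abs(on - off), 0.000549 / 1, tolerance = 1e-6,
                 label = a)
  }
  # doubly charged: half the mass plus a proton each
  expect_equal(adduct_mz(M, "[M+2H]2+", electron_correction = FALSE),
               (M + 2 * 1.0078250319) / 2, tolerance = 1e-12)
  expect_error(adduct_mz(M, list(delta = 1, charge = 0)),
               class = "chemocomp_validation_error")
  expect_error(adduct_mz(M, "[M+Xe]+"), class = "chemocomp_usage_error")
})

test_that("ring-and-double-bond equivalents follow C + 1 + (N - H - X)/2", {
  expect_equal(rdbe("C27H40N2O4"), 9)
  expect_equal(rdbe("CH4"), 0)
  expect_equal(rdbe("C9H14N2O2"), 4)
  expect_equal(rdbe("C6H6"), 4)          # benzene
  # alkanes are saturated; each ring or double bond adds exactly 1
  for (n in c(1, 5, 12))
    expect_equal(rdbe(sprintf("C%dH%d", n, 2 * n + 2)), 0)
  expect_equal(rdbe("C6H12") - rdbe("C6H14"), 1)
  # halogens count like hydrogen
  expect_equal(rdbe("C2H3Cl"), 1)
})

test_that("reference matching annotates the correct adduct", {
  x <- matrix(c(10, 20), nrow = 2,
              dimnames = list(c("s1", "s2"), "479.2880@12.40"))
  tab <- bucket_table(x)
  refs <- data.frame(name = "doscadenamide-like", formula = "C27H40N2O4",
                     neutral_mass = NA_real_)
  refs$adducts <- list(c("[M+H]+", "[M+Na]+"))
  res <- match_reference(tab, refs, mz_tol = 0.01)
  expect_equal(nrow(res$annotations), 1)
  expect_equal(res$annotations$adduct, "[M+Na]+")
  expect_lt(abs(res$annotations$delta), 0.01)
  expect_length(res$not_dereplicated, 0)
})

test_that("an empty reference set leaves every feature undereplicated", {
  x <- matrix(1:4, nrow = 2,
              dimnames = list(c("s1", "s2"),
                              c("300.0000@5.00", "457.7850@12.40")))
  tab <- bucket_table(x)
  refs <- data.frame(name = character(0), formula = character(0),
                     neutral_mass = numeric(0))
  refs$adducts <- list()
  res <- match_reference(tab, refs, mz_tol = 0.01)
  expect_equal(nrow(res$annotations), 0)
  expect_setequal(res$not_dereplicated, colnames(tab))
})

test_that("reference matching is exact at zero tolerance and monotone", {
  theo <- adduct_mz("C27H40N2O4", "[M+Na]+")
  keys <- c(sprintf("%.4f@%.2f", round(theo, 4), 12.4), "479.3100@12.40")
  x <- matrix(c(1, 1, 1, 1), nrow = 2,
              dimnames = list(c("s1", "s2"), keys))
  tab <- bucket_table(x)
  refs <- data.frame(name = "cmpd", formula = "C27H40N2O4",
                     neutral_mass = NA_real_)
  refs$adducts <- list("[M+Na]+")
  strict <- match_reference(tab, refs, mz_tol = 0)
  expect_equal(nrow(strict$annotations), 0)   # key rounded to 4 dp != exact
  narrow <- match_reference(tab, refs, mz_tol = 0.001)
  wide <- match_reference(tab, refs, mz_tol = 0.05)
  expect_true(all(narrow$annotations$feature_key %in%
                    wide$annotations$feature_key))
  expect_equal(nrow(narrow$annotations), 1)
  expect_equal(nrow(wide$annotations), 2)
})

test_that("reference CSV validates the formula/mass alternative", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,formula,neutral_mass,adducts",
               "a,C27H40N2O4,,[M+H]+;[M+Na]+",
               "b,,456.2988,[M+Na]+"), path)
  refs <- read_reference_csv(path)
  expect_equal(nrow(refs), 2)
  expect_equal(refs$adducts[[1]], c("[M+H]+", "[M+Na]+"))
  writeLines(c("name,formula,neutral_mass,adducts",
               "bad,C2H6,100.1,[M+H]+"), path)
  expect_error(read_reference_csv(path),
               class = "chemocomp_validation_error")
  writeLines(c("name,formula,neutral_mass,adducts", "bad,,,"), path)
  expect_error(read_reference_csv(path),
               class = "chemocomp_validation_error")
})

test_that("fragment matching supports hydrogen rearrangements", {
  # core-fragment series of the doscadenamide-type fragmentation
  obs <- data.frame(mz = c(321.2171, 303.1901, 168.1016),
                    intensity = c(100, 50, 80))
  cand <- data.frame(label = c("loss_side_chain", "loss_amine_too",
                               "core"),
                     mass = c(321.217, 303.183, 168.102))
  hits <- match_fragments(obs, cand, mz_tol = 0.01, max_h_shifts = 0)
  expect_equal(nrow(hits), 3)
  expect_true(all(hits$h_shift == 0))
  expect_true(all(abs(hits$delta) <= 0.01))

  # empty observed list yields no matches
  none <- match_fragments(obs[0, ], cand, mz_tol = 0.01)
  expect_equal(nrow(none), 0)

  # candidate one hydrogen heavier matches with h_shift = -1
  obs2 <- data.frame(mz = 200.000, intensity = 1)
  cand2 <- data.frame(label = "x", mass = 200.000 + 1.007825)
  expect_equal(nrow(match_fragments(obs2, cand2, 0.001, 0)), 0)
  hit <- match_fragments(obs2, cand2, 0.001, 1)
  expect_equal(hit$h_shift, -1)
  expect_equal(hit$matched_mz, 200.000)
  # the smallest |k| wins when several shifts would match
  obs3 <- data.frame(mz = c(200.000, 201.007825), intensity = c(1, 1))
  hit3 <- match_fragments(obs3, data.frame(label = "y", mass = 201.007825),
                          0.01, 2)
  expect_equal(hit3$h_shift, 0)
})
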