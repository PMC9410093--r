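test_that("residue and peptide masses match published values", {
  res <- residue_masses("mono")
  # three published monoisotopic residue masses
  expect_equal(res[["G"]], 57.02146, tolerance = 1e-7)
  expect_equal(res[["W"]], 186.07931, tolerance = 1e-7)
  expect_equal(res[["R"]], 156.10111, tolerance = 1e-7)
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-6)
  expect_equal(peptide_mass("GG"), 132.05349, tolerance = 1e-6)
  # average masses are systematically heavier for multi-isotope residues
  expect_gt(peptide_mass("WR", kind = "avg"), peptide_mass("WR"))
})

test_that("modification deltas shift masses by the catalogue values", {
  s <- "FDSLGGGSFLG"
  expect_equal(peptide_mass(s, "amidation") - peptide_mass(s), -0.98402,
               tolerance = 1e-9)
  expect_equal(peptide_mass("QAAA", "pyroglu") - peptide_mass("QAAA"),
               -17.02655, tolerance = 1e-9)
  expect_equal(peptide_mass("AMA", c("oxidation", "oxidation")) -
                 peptide_mass("AMA"), 2 * 15.99491, tolerance = 1e-9)
  expect_error(peptide_mass("AAA", "nosuchmod"), "unknown modification")
})

test_that("mass additivity: mass(AB) = mass(A) + mass(B) - water", {
  set.seed(11)
  for (i in 1:20) {
    a <- random_peptide(sample(1:12, 1))
    b <- random_peptide(sample(1:12, 1))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("fragment ions reproduce hand-computed b/a/y values", {
  ions <- fragment_ions("GA")
  get <- function(se, ix) ions$mz[ions$series == se & ions$index == ix]
  expect_equal(get("b", 1), 58.02874, tolerance = 1e-5)
  expect_equal(get("y", 1), 90.05495, tolerance = 1e-5)
  expect_equal(get("b", 1) + residue_masses()[["A"]], 129.06585,
               tolerance = 1e-5)
  expect_equal(get("a", 1), get("b", 1) - 27.99491, tolerance = 1e-6)
  expect_error(fragment_ions("G"), "at least 2")
})

test_that("b/y complementarity holds to 1e-9 Da and mods land on one series", {
  set.seed(12)
  for (i in 1:10) {
    s <- random_peptide(sample(2:15, 1))
    ions <- fragment_ions(s)
    n <- nchar(s)
    mono <- peptide_mass(s)
    b <- ions$mz[ions$series == "b"][order(ions$index[ions$series == "b"])]
    y <- ions$mz[ions$series == "y"][order(ions$index[ions$series == "y"])]
    expect_equal(b + rev(y), rep(mono + 2 * 1.007276, n - 1),
                 tolerance = 1e-9)
  }
  # C-terminal amidation shifts y ions only
  plain <- fragment_ions("GASILV")
  amid <- fragment_ions("GASILV", cterm_mods = "amidation")
  expect_equal(amid$mz[amid$series == "b"], plain$mz[plain$series == "b"])
  expect_equal(amid$mz[amid$series == "y"],
               plain$mz[plain$series == "y"] - 0.98402, tolerance = 1e-9)
  # a site modification shifts b_i only once the site is spanned
  ox <- fragment_ions("GMSILV", site_mods = data.frame(name = "oxidation",
                                                       pos = 2))
  pl <- fragment_ions("GMSILV")
  expect_equal(ox$mz[ox$series == "b" & ox$index == 1],
               pl$mz[pl$series == "b" & pl$index == 1])
  expect_equal(ox$mz[ox$series == "b" & ox$index == 2],
               pl$mz[pl$series == "b" & pl$index == 2] + 15.99491,
               tolerance = 1e-9)
})

test_that("doubly charged ions follow (m + zH)/z", {
  ions <- fragment_ions("GASILV", max_charge = 2)
  b1 <- ions[ions$series == "b" & ions$index == 3, ]
  expect_equal(b1$mz[b1$charge == 2],
               (b1$mz[b1$charge == 1] + 1.007276) / 2, tolerance = 1e-9)
})

test_that("variant enumeration covers pyroglutamate and Met oxidation states", {
  expect_equal(nrow(enumerate_variants("AMAA")), 3L)    # none/ox/diox
  expect_equal(nrow(enumerate_variants("QAAA")), 2L)    # +/- pyroglu
  expect_equal(nrow(enumerate_variants("AAAA")), 1L)
  expect_equal(nrow(enumerate_variants("QMAMA")), 2L * 9L)
  v <- enumerate_variants("AMAA")
  base <- v$neutral_mono[v$mods == ""]
  expect_equal(sort(v$neutral_mono - base), c(0, 15.99491, 31.98983),
               tolerance = 1e-9)
  # amidation is fixed, not variable
  va <- enumerate_variants("FDSLGGGSFLG", amidated = TRUE)
  expect_equal(nrow(va), 1L)
  expect_equal(va$neutral_mono, peptide_mass("FDSLGGGSFLG", "amidation"),
               tolerance = 1e-9)
  # alkylated samples carry fixed carbamidomethyl-Cys
  vc <- enumerate_variants("ACCA", alkylated = TRUE)
  expect_equal(vc$neutral_mono, peptide_mass("ACCA") + 2 * 57.02146,
               tolerance = 1e-9)
})

test_that("library building expands variants and keeps names", {
  pep <- data.frame(sequence = c("AMAA", "QAAA", "AMAA"),
                    amidated = c(FALSE, FALSE, FALSE),
                    pyroglu = c(FALSE, TRUE, FALSE),
                    name = c("n1", "n2", "n1"))
  lib <- build_peptide_library(pep)
  expect_equal(nrow(lib), 5L)  # 3 ox states + 2 pyroglu states, dups dropped
  expect_setequal(unique(lib$peptide_name), c("n1", "n2"))
  expect_warning(build_peptide_library(pep[0, ]), "empty")
})
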