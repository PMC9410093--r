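test_that("spectrum constructor enforces range and sorting", {
  sp <- spectrum("s1", level = 1, mz = c(900, 800), intensity = c(1, 2))
  expect_equal(sp$peaks$mz, c(800, 900))
  expect_error(spectrum("s2", level = 1, mz = 500), "instrument range")
  expect_error(spectrum("s3", level = 2, mz = 500), "precursor_mz")
  # fragment peaks below 700 Da are legal on level 2
  sp2 <- spectrum("s4", level = 2, precursor_mz = 1000, mz = c(120, 900))
  expect_equal(nrow(sp2$peaks), 2L)
  expect_error(spectrum("s5", level = 1, mz = 800, intensity = -1),
               "negative")
})

test_that("MGF writer/reader round-trips spectra", {
  sps <- list(
    spectrum("a1", tissue = "MNG", level = 2, precursor_mz = 1056.5,
             mz = c(175.119, 905.43), intensity = c(10, 20)),
    spectrum("a2", tissue = "OL", level = 1, mz = c(800.1, 1200.2),
             intensity = c(5, 6)))
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sps, f)
  back <- read_mgf(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$id, "a1")
  expect_equal(back[[1]]$tissue, "MNG")
  expect_equal(back[[1]]$level, 2L)
  expect_equal(back[[1]]$precursor_mz, 1056.5, tolerance = 1e-6)
  expect_equal(back[[1]]$peaks$mz, sps[[1]]$peaks$mz, tolerance = 1e-6)
  expect_equal(back[[2]]$level, 1L)
})

test_that("plain peak lists load as level-1 spectra", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# mz intensity", "800.5 12", "1200.25 3"), f)
  sp <- read_peaklist(f, id = "pl", tissue = "OvG")
  expect_equal(sp$level, 1L)
  expect_equal(sp$peaks$mz, c(800.5, 1200.25))
})

test_that("precursor matching returns signed ppm error within tolerance", {
  mh_ga <- peptide_mh("GA")
  expect_equal(mh_ga, 147.07641, tolerance = 1e-5)
  ppm <- match_precursor(147.0770, mh_ga)
  expect_equal(ppm, (147.0770 - mh_ga) / mh_ga * 1e6, tolerance = 1e-9)
  expect_equal(round(ppm), 4)
  expect_equal(match_precursor(1000, 1000), 0)
  expect_true(is.na(match_precursor(147.11, mh_ga)))   # ~228 ppm
  # symmetric tolerance: obs = theo * (1 + eps) matches iff |eps| <= tol
  for (eps in c(-199e-6, 199e-6)) {
    expect_false(is.na(match_precursor(1000 * (1 + eps), 1000, 200)))
  }
  expect_true(is.na(match_precursor(1000 * (1 + 201e-6), 1000, 200)))
})

test_that("greedy fragment matching is one-peak-one-ion", {
  ions <- fragment_ions("FDSLGGGSFLG", series = c("b", "y"))
  sp <- spectrum("full", level = 2, precursor_mz = peptide_mh("FDSLGGGSFLG"),
                 mz = ions$mz, intensity = rep(1, nrow(ions)))
  m <- match_fragments(sp, ions)
  expect_equal(nrow(m), nrow(ions))           # complete series: all matched
  expect_true(all(abs(m$delta_mz) < 1e-9))
  empty <- spectrum("none", level = 2, precursor_mz = 1000)
  expect_equal(nrow(match_fragments(empty, ions)), 0L)
  # two ions cannot claim one peak
  two <- data.frame(series = "b", index = 1:2, charge = 1,
                    mz = c(500.0, 500.2))
  one_peak <- spectrum("p", level = 2, precursor_mz = 1000, mz = 500.1)
  expect_equal(nrow(match_fragments(one_peak, two)), 1L)
  expect_error(match_fragments(spectrum("l1", level = 1, mz = 800), ions),
               "level-2")
})

test_that("binomial-tail score equals exact enumeration and is monotone", {
  expect_equal(score_psm(0, 10, 100, 1000, 0.6), 0)
  # fixed small case (n_theoretical 10, n_matched 5, p = 0.01) against the
  # brute-force tail sum; n_peaks chosen so n_peaks * 2 * tol / range = 0.01
  expect_equal(score_psm(5, 10, 25 / 3, 1000, 0.6),
               -log10(brute_binom_tail(5, 10, 0.01)), tolerance = 1e-9)
  set.seed(21)
  for (i in 1:10) {
    n_theo <- sample(3:15, 1)
    n_match <- sample(1:n_theo, 1)
    n_peaks <- sample(5:50, 1)
    expect_equal(score_psm(n_match, n_theo, n_peaks, 2000, 0.6),
                 -log10(brute_binom_tail(
                   n_match, n_theo, min(1, n_peaks * 1.2 / 2000))),
                 tolerance = 1e-9)
  }
  # monotone non-decreasing in n_matched at fixed context
  sc <- vapply(0:10, score_psm, 0, n_theoretical = 10, n_peaks = 20,
               mz_range = 2000, tol_da = 0.6)
  expect_true(all(diff(sc) >= 0))
  # intensity never enters the score: same counts, same score
  expect_equal(score_psm(4, 10, 20, 2000, 0.6), score_psm(4, 10, 20, 2000, 0.6))
})

test_that("search matches embedded peptides and is deterministic", {
  pep <- data.frame(name = "pepA", sequence = "FDSLGGGSFLG",
                    amidated = TRUE, pyroglu = FALSE)
  lib <- build_peptide_library(pep)
  mh <- lib$mh[1]
  ions <- fragment_ions("FDSLGGGSFLG", cterm_mods = "amidation")
  sp <- spectrum("ms2", tissue = "MNG", level = 2, precursor_mz = mh,
                 mz = ions$mz, intensity = rep(1, nrow(ions)))
  psms <- search_spectra(list(sp, sp), lib)
  expect_equal(nrow(psms), 2L)
  expect_equal(psms[1, ], psms[2, ], ignore_attr = TRUE)  # duplicate spectra
  expect_equal(psms$sequence[1], "FDSLGGGSFLG")
  expect_equal(psms$ppm_error_precursor[1], 0, tolerance = 1e-9)
  expect_equal(psms$n_matched[1], psms$n_theoretical[1])
  # empty library warns and returns no PSMs
  expect_warning(out <- search_spectra(list(sp), data.frame()), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("level-1 spectra are matched by precursor mass only", {
  pep <- data.frame(name = c("pepA", "pepB"),
                    sequence = c("FDSLGGGSFLG", "GAESGEAHVFDSLGGGHVPYY"),
                    amidated = c(TRUE, FALSE), pyroglu = c(FALSE, FALSE))
  lib <- build_peptide_library(pep)
  sp <- spectrum("ms1", tissue = "OL", level = 1, mz = lib$mh,
                 intensity = c(1, 1))
  psms <- search_spectra(list(sp), lib)
  expect_equal(nrow(psms), 1L)  # best PSM per spectrum
  expect_equal(psms$level, 1L)
  expect_equal(psms$n_theoretical, 1L)
})

test_that("detection table reflects PSMs and honors orderings", {
  psms <- data.frame(peptide_name = c("FLGa 1", "FLGa 3"),
                     tissue = c("MNG", "OL"))
  tab <- detection_table(psms, peptides = paste("FLGa", 1:6),
                         tissues = c("MNG", "OvG", "OL"))
  expect_equal(dim(tab), c(6L, 3L))
  expect_true(tab["FLGa 1", "MNG"])
  expect_true(tab["FLGa 3", "OL"])
  expect_equal(sum(tab), 2)
  none <- detection_table(psms[0, ], peptides = "p", tissues = "t")
  expect_false(any(none))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_detection_table(tab, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(back$peptide, paste("FLGa", 1:6))
})

test_that("config files override defaults and reject bad keys", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("tol_ppm = 100", "series = b,y", "# comment",
               "score_threshold = 2.5"), f)
  cfg <- read_config(f)
  expect_equal(cfg$tol_ppm, 100)
  expect_equal(cfg$series, c("b", "y"))
  expect_equal(cfg$score_threshold, 2.5)
  expect_equal(cfg$tol_da, 0.6)   # untouched default
  writeLines("nonsense = 1", f)
  expect_error(read_config(f), "unknown config key")
  writeLines("tol_ppm = -5", f)
  expect_error(read_config(f), "positive")
})
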