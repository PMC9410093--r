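test_that("precursor construction validates and strips stop marks", {
  p <- precursor("p", "MAAAGDE*", signal_end = 2)
  expect_equal(p$sequence, "MAAAGDE")
  expect_error(precursor("p", "MABX"), "non-standard")
  expect_error(precursor("p", ""), "non-empty")
  expect_error(precursor("p", "MAAA", signal_end = 4), "signal_end")
})

test_that("FASTA round trip preserves header tags", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">pp signal_end=3 is_partial=yes", "MLLAGDEKRAGDE"), f)
  pre <- read_precursors(f)
  expect_length(pre, 1)
  expect_equal(pre[[1]]$id, "pp")
  expect_equal(pre[[1]]$signal_end, 3L)
  expect_true(pre[[1]]$is_partial)
})

test_that("signal-peptide heuristic finds a hydrophobic core cut", {
  # 20 leucines then alanine: cut after the first small residue past the core
  p <- precursor("lp", paste0(strrep("L", 20), "A", "DDDDDEEEEE"))
  cut <- find_signal_peptide(p)
  expect_equal(cut, 21L)
  # all-acidic precursor has no hydrophobic core
  expect_true(is.na(find_signal_peptide(precursor("de", strrep("DE", 20)))))
  # partial N-terminus is an error
  expect_error(
    find_signal_peptide(precursor("pt", strrep("L", 20), is_partial = TRUE)),
    "partial")
  # fixture: predicted cut lies upstream of the first predicted peptide
  pre <- read_precursors(flga_fixture())
  cut <- find_signal_peptide(pre[[1]])
  first_pep <- min(excise_peptides(pre[[1]])$start)
  expect_false(is.na(cut))
  expect_lt(cut, first_pep)
})

test_that("cleavage sites are maximal K/R runs with the >3 anchoring rule", {
  s <- find_cleavage_sites("AAKRAA")
  expect_equal(s$start, 3L)
  expect_equal(s$end, 4L)
  expect_equal(s$kind, "dibasic")
  expect_equal(s$residues, "KR")
  expect_equal(nrow(find_cleavage_sites("AAKAA")), 0L)
  m <- find_cleavage_sites("AAKAA", allow_monobasic = TRUE)
  expect_equal(m$kind, "monobasic")
  # run of 5 reported as one tribasic anchored at the C-terminal end
  long <- find_cleavage_sites("AAKRKRKAA")
  expect_equal(nrow(long), 1L)
  expect_equal(long$kind, "tribasic")
  expect_equal(c(long$start, long$end), c(5L, 7L))
  # sites sorted by start
  multi <- find_cleavage_sites("AKRAAARRRA")
  expect_equal(multi$start, sort(multi$start))
  expect_equal(multi$kind, c("dibasic", "tribasic"))
})

test_that("PTM rules: amidation glycine and possible pyroglutamate", {
  amid <- apply_ptm_rules("FDSLGGGSFLGG", followed_by_site = TRUE)
  expect_equal(amid$sequence, "FDSLGGGSFLG")
  expect_true(amid$amidated)
  pg <- apply_ptm_rules("QAAA", followed_by_site = FALSE)
  expect_true(pg$pyroglu)
  expect_false(pg$amidated)
  # a C-terminal segment keeps its glycine and stays unamidated
  cterm <- apply_ptm_rules("GAESGEAHVFDSLGGGHVPYY", followed_by_site = FALSE)
  expect_equal(cterm$sequence, "GAESGEAHVFDSLGGGHVPYY")
  expect_false(cterm$amidated)
})

test_that("excision recovers inter-site segments with PTMs and copy indices", {
  # KK | 21-mer | KR context
  p <- precursor("x", "KKGAESGEAHVFDSLGGGHVPYYKR")
  pep <- excise_peptides(p)
  expect_equal(pep$sequence, "GAESGEAHVFDSLGGGHVPYY")
  expect_false(pep$amidated)
  # amidation segment before a dibasic site
  p2 <- precursor("y", "KKFDSLGGGSFLGGKR")
  pep2 <- excise_peptides(p2)
  expect_equal(pep2$sequence, "FDSLGGGSFLG")
  expect_true(pep2$amidated)
  # no sites on a signal-free precursor: the whole sequence is one peptide
  p3 <- precursor("z", "GAESGEAHV")
  pep3 <- excise_peptides(p3)
  expect_equal(pep3$sequence, "GAESGEAHV")
  expect_equal(pep3$copy_index, 1L)
  # copy indices count identical sequences N to C
  p4 <- precursor("w", "KKFDSLGGGSFLGGKKFDSLGGGSFLGGKK")
  expect_equal(excise_peptides(p4)$copy_index, c(1L, 2L))
  # short spacers fall below min_len
  p5 <- precursor("v", "KKEDAKKGAESGEAHVKK")
  expect_equal(excise_peptides(p5)$sequence, "GAESGEAHV")
})

test_that("count_copies is an exact multiset count", {
  pre <- read_precursors(flga_fixture())
  cc_a <- count_copies(excise_peptides(pre[[1]]))
  expect_equal(unname(cc_a[["FDSLGGGSFLG"]]), 7L)
  expect_equal(sort(unname(cc_a)), c(1L, 1L, 1L, 1L, 1L, 7L))
  cc_b <- count_copies(excise_peptides(pre[[2]]))
  expect_equal(cc_b[["FDSLGGGSFLG"]] - cc_a[["FDSLGGGSFLG"]], 1L)
  expect_equal(length(count_copies(excise_peptides(pre[[1]])[0, ])), 0L)
})

test_that("reassembly and internal-site invariants hold on synthetic precursors", {
  for (seed in 1:5) {
    gp <- gen_precursors(generator_config(seed = seed))
    for (prec in gp$precursors) {
      pep <- excise_peptides(prec, min_len = 1)
      n <- nchar(prec$sequence)
      # no internal di-/tribasic run inside any peptide span
      for (i in seq_len(nrow(pep))) {
        raw <- substring(prec$sequence, pep$start[i], pep$end[i])
        expect_false(grepl("[KR]{2}", raw))
        # amidation implies the pre-PTM segment ended in G
        if (pep$amidated[i]) expect_true(endsWith(raw, "G"))
      }
      # signal + segments + basic runs tile the precursor exactly
      covered <- rep(FALSE, n)
      covered[seq_len(prec$signal_end)] <- TRUE
      for (i in seq_len(nrow(pep))) covered[pep$start[i]:pep$end[i]] <- TRUE
      runs <- gregexpr("[KR]+", prec$sequence)[[1]]
      for (k in seq_along(runs)) {
        covered[runs[k]:(runs[k] + attr(runs, "match.length")[k] - 1)] <- TRUE
      }
      expect_true(all(covered))
    }
  }
})

test_that("excision recovers generator payloads exactly", {
  gp <- gen_precursors(generator_config(seed = 42))
  for (prec in gp$precursors) {
    truth <- gp$manifest[gp$manifest$precursor_id == prec$id, ]
    pep <- excise_peptides(prec)
    # sequences, N-to-C order, and copy counts all match the manifest
    expected_order <- rep(truth$sequence, truth$copies)
    expect_equal(pep$sequence, expected_order)
    cc <- count_copies(pep)
    expect_equal(unname(cc[truth$sequence]), truth$copies)
    expect_equal(pep$amidated,
                 rep(truth$amidated, truth$copies))
  }
})

test_that("peptide table writer round-trips through read.delim", {
  pep <- flga_peptides()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(pep, f)
  back <- utils::read.delim(f)
  expect_equal(back$sequence, pep$sequence)
  expect_equal(back$amidated, pep$amidated)
})
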