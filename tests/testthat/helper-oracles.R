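# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: alignment by exhaustive enumeration of every global
# alignment, motif scanning by regular expressions, the binomial tail by
# direct summation.

# exhaustive global-alignment score: recursively enumerate all alignments,
# scoring diagonal moves by the substitution matrix and gap runs by
# gap_open + gap_extend * length (first gap char -11, each further -1)
brute_align_score <- function(a, b, sub, gap_open = -10, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  rec <- function(i, j, prev) {
    if (i > m && j > n) return(0)
    best <- -Inf
    if (i <= m && j <= n) {
      best <- max(best, sub[av[i], bv[j]] + rec(i + 1, j + 1, "D"))
    }
    if (i <= m) {
      cost <- if (prev == "A") gap_extend else gap_open + gap_extend
      best <- max(best, cost + rec(i + 1, j, "A"))
    }
    if (j <= n) {
      cost <- if (prev == "B") gap_extend else gap_open + gap_extend
      best <- max(best, cost + rec(i, j + 1, "B"))
    }
    best
  }
  rec(1, 1, "D")
}

# regular-language motif oracle: overlapping matches via a lookahead regex
regex_scan <- function(sequence, tokens) {
  rx <- paste(vapply(strsplit(tokens, "\\s+")[[1]], function(tok) {
    if (tok == ".") "."
    else if (grepl("^\\(", tok))
      paste0("[", gsub("[()/]", "", tok), "]")
    else tok
  }, ""), collapse = "")
  hits <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1) integer() else as.integer(hits)
}

# exact binomial tail P(X >= k) by direct summation
brute_binom_tail <- function(k, n, p) {
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# random peptide sequence over the 20-letter alphabet
random_peptide <- function(len, exclude = character()) {
  pool <- setdiff(names(neuropep:::kd_hydropathy), exclude)
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# the six distinct mature peptides the packaged precursor fixture encodes
flga_peptides <- function() {
  pre <- read_precursors(flga_fixture())
  excise_peptides(pre[[1]])
}
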