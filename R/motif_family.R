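#' Construct a degenerate motif pattern
#'
#' A pattern is an ordered list of column elements: a fixed residue (`"D"`),
#' a residue class (`"(L/I)"`, any number of alternatives), or the wildcard
#' `"."`. Patterns can be written as whitespace-separated tokens
#' (`"D S (L/I) G G G"`) or, when every element is a single residue or
#' wildcard, as a compact string (`"DSLGGG"`).
#'
#' @param x Pattern string.
#' @param name Optional pattern name.
#' @return Object of class `motif_pattern`: list of character vectors of
#'   allowed residues (`NULL` marks a wildcard column).
#' @examples
#' motif_pattern("D S (L/I) G G G", name = "orcokinin-B hexapeptide")
#' @export
motif_pattern <- function(x, name = NA_character_) {
  tokens <- if (grepl("\\s", trimws(x))) strsplit(trimws(x), "\\s+")[[1]]
            else strsplit(trimws(x), "")[[1]]
  if (length(tokens) == 0) stop("empty pattern", call. = FALSE)
  elements <- lapply(tokens, function(tok) {
    if (tok == ".") return(NULL)
    if (grepl("^\\(.*\\)$", tok)) {
      cls <- strsplit(gsub("[()]", "", tok), "/")[[1]]
      if (length(cls) == 0) stop("empty residue class", call. = FALSE)
      return(cls)
    }
    tok
  })
  for (el in elements) {
    if (!is.null(el) && !all(el %in% AA_ALPHABET)) {
      stop("pattern element outside amino-acid alphabet", call. = FALSE)
    }
  }
  structure(elements, class = "motif_pattern", name = name)
}

#' @export
print.motif_pattern <- function(x, ...) {
  tok <- vapply(unclass(x), function(el) {
    if (is.null(el)) "." else if (length(el) == 1) el
    else paste0("(", paste(el, collapse = "/"), ")")
  }, "")
  cat(sprintf("<motif_pattern>%s %s\n",
              if (!is.na(attr(x, "name"))) paste0(" ", attr(x, "name")) else "",
              paste(tok, collapse = " ")))
  invisible(x)
}

#' Read a pattern library from its text format
#'
#' Format: a `>name` line followed by one line of whitespace-separated
#' column tokens (residue, `(X/Y)` class, or `.` wildcard). Lines starting
#' with `#` are comments. Plain-sequence entries (for alignment-based
#' classification) use only fixed residues.
#'
#' @param path Pattern file.
#' @return Named list of [motif_pattern] objects.
#' @export
read_patterns <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0) stop("no pattern entries in ", path, call. = FALSE)
  pats <- lapply(seq_along(hdr), function(i) {
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    body <- paste(lines[(hdr[i] + 1):to], collapse = " ")
    motif_pattern(body, name = sub("^>\\s*", "", lines[hdr[i]]))
  })
  stats::setNames(pats, vapply(pats, attr, "", "name"))
}

#' Scan a sequence for a degenerate motif
#'
#' Exact window scan: a match at position `p` means every pattern column
#' `j` is satisfied by residue `p + j - 1`. Overlapping matches are all
#' reported.
#'
#' @param sequence Amino-acid sequence.
#' @param pattern A [motif_pattern] (or pattern string, coerced).
#' @return Integer vector of 1-based match start positions (possibly
#'   empty).
#' @examples
#' scan_motif("GAESGEAHVFDSLGGGHVPYY", motif_pattern("D S (L/I) G G G"))
#' @export
scan_motif <- function(sequence, pattern) {
  check_sequence(sequence)
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  aa <- strsplit(sequence, "")[[1]]
  k <- length(pattern)
  n <- length(aa)
  if (k > n) return(integer())
  hits <- integer()
  for (p in seq_len(n - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      el <- pattern[[j]]
      if (!is.null(el) && !(aa[p + j - 1] %in% el)) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

# BLOSUM62 from Biostrings, cached
blosum62 <- function() {
  if (is.null(.neuropep_cache[["BLOSUM62"]])) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .neuropep_cache[["BLOSUM62"]] <- e$BLOSUM62
  }
  .neuropep_cache[["BLOSUM62"]]
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment (via Biostrings' dynamic-programming
#' aligner) under BLOSUM62 with affine gap costs: a gap run of length L
#' costs `-(gap_open) - L * (gap_extend)` with the defaults -10 / -1, the
#' usual choice for short peptides.
#'
#' @param a,b Amino-acid sequences.
#' @param matrix Substitution matrix name (`"BLOSUM62"`) or a numeric
#'   matrix.
#' @param gap_open,gap_extend Gap penalties (negative).
#' @return List of class `alignment_result`: `aligned_a`, `aligned_b`
#'   (gapped strings), `score`, `identity_fraction` (identical columns /
#'   alignment length).
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = -10,
                         gap_extend = -1) {
  check_sequence(a, "a"); check_sequence(b, "b")
  sub <- if (is.matrix(matrix)) matrix else
    switch(matrix, BLOSUM62 = blosum62(),
           stop("unknown substitution matrix: ", matrix, call. = FALSE))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = sub, gapOpening = abs(gap_open),
    gapExtension = abs(gap_extend))
  pa <- as.character(Biostrings::alignedPattern(al))
  pb <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  structure(
    list(aligned_a = pa, aligned_b = pb, score = Biostrings::score(al),
         identity_fraction = mean(ca == cb & ca != "-")),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$aligned_a, x$aligned_b, sep = "\n")
  cat(sprintf("score %.1f, identity %.2f\n", x$score, x$identity_fraction))
  invisible(x)
}

#' Build a consensus pattern from an aligned block
#'
#' Per column of a gapped, equal-length block: a fixed residue when its
#' frequency reaches `majority`; a two-residue class `(X/Y)` when the top
#' two residues jointly reach `majority` *and* are conservative substitutes
#' (positive BLOSUM62 score, so L/I forms a class but unrelated pairs such
#' as A/C collapse to a wildcard); otherwise a wildcard. All-gap columns are
#' dropped; gaps never enter classes.
#'
#' @param block Character vector of >= 2 equal-length gapped sequences.
#' @param majority Frequency threshold in (0, 1] (default 0.8).
#' @return A [motif_pattern].
#' @examples
#' build_consensus(c("DSLGGG", "DSIGGG"))  # D S (L/I) G G G
#' @export
build_consensus <- function(block, majority = 0.8) {
  stopifnot(length(block) >= 2, majority > 0, majority <= 1)
  if (length(unique(nchar(block))) != 1) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(block, ""))
  tokens <- character()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (all(col == "-")) next
    freq <- sort(table(col[col != "-"]) / length(col), decreasing = TRUE)
    if (length(freq) >= 1 && freq[1] >= majority) {
      tokens <- c(tokens, names(freq)[1])
    } else if (length(freq) >= 2 && freq[1] + freq[2] >= majority &&
               blosum62()[names(freq)[1], names(freq)[2]] > 0) {
      pair <- sort(names(freq)[1:2])
      tokens <- c(tokens, paste0("(", pair[1], "/", pair[2], ")"))
    } else {
      tokens <- c(tokens, ".")
    }
  }
  motif_pattern(paste(tokens, collapse = " "), name = "consensus")
}

#' Default neuropeptide family pattern library
#'
#' Loads the packaged pattern file: the strict orcokinin-B hexapeptide
#' DS(L/I)GGG, the orcokinin-B class pattern D(S/T)(L/I)GGG covering the
#' Thr variant seen in PYY-type family members, an orcokinin-C core
#' pattern, and an insect FCAN consensus sequence used by alignment. The
#' orcokinin-C and FCAN entries are synthetic stand-ins transcribed at
#' fixture-preparation time, not figure-exact.
#'
#' @return Named list of [motif_pattern] objects.
#' @export
default_patterns <- function() {
  read_patterns(.np_extdata("family_patterns_synthetic.txt"))
}

#' Classify a peptide into a neuropeptide family
#'
#' Rule cascade over the pattern library: `orcokinin_B` when the
#' DS(L/I)GGG-class motif (`orcokinin_B_class`) hits; otherwise
#' `orcokinin_C` when the orcokinin-C core pattern hits (GGG core with its
#' flanking classes) without the B-class motif; otherwise `FCAN` when the
#' FCAN consensus aligns at or above `fcan_identity` identity; otherwise
#' `unclassified`. Evidence (motif hit positions, alignment identity) is
#' returned alongside the call.
#'
#' @param sequence Peptide or precursor amino-acid sequence.
#' @param patterns Pattern library from [read_patterns] /
#'   [default_patterns]; must contain `orcokinin_B_class`, `orcokinin_C_core`
#'   and `FCAN_consensus` entries.
#' @param fcan_identity Identity threshold for the FCAN alignment route
#'   (default 0.5).
#' @return List of class `family_call`: `family`, `evidence`.
#' @export
classify_family <- function(sequence, patterns = default_patterns(),
                            fcan_identity = 0.5) {
  need <- c("orcokinin_B_class", "orcokinin_C_core", "FCAN_consensus")
  if (!all(need %in% names(patterns))) {
    stop("pattern library must contain: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  b_hits <- scan_motif(sequence, patterns[["orcokinin_B_class"]])
  c_hits <- scan_motif(sequence, patterns[["orcokinin_C_core"]])
  fcan_seq <- paste(vapply(unclass(patterns[["FCAN_consensus"]]),
                           function(el) if (is.null(el)) "A" else el[1], ""),
                    collapse = "")
  aln <- global_align(sequence, fcan_seq)
  family <-
    if (length(b_hits)) "orcokinin_B"
    else if (length(c_hits)) "orcokinin_C"
    else if (aln$identity_fraction >= fcan_identity) "FCAN"
    else "unclassified"
  structure(
    list(family = family,
         evidence = list(orcokinin_B_hits = b_hits,
                         orcokinin_C_hits = c_hits,
                         fcan_identity = aln$identity_fraction)),
    class = "family_call")
}

#' @export
print.family_call <- function(x, ...) {
  cat(sprintf("<family_call> %s (B hits: %s; C hits: %s; FCAN id %.2f)\n",
              x$family,
              paste(x$evidence$orcokinin_B_hits, collapse = ","),
              paste(x$evidence$orcokinin_C_hits, collapse = ","),
              x$evidence$fcan_identity))
  invisible(x)
}
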