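#' Construct a prohormone precursor
#'
#' A precursor is the translated prohormone: an amino-acid sequence with an
#' optional annotated signal-peptide end and a flag for N-/C-terminally
#' incomplete (partial) sequences. A single trailing `*` (stop-codon
#' translation) is stripped at construction.
#'
#' @param id Precursor identifier.
#' @param sequence Amino-acid sequence, 1-letter codes, optionally ending in
#'   `*`.
#' @param signal_end Optional 1-based index of the last signal-peptide
#'   residue.
#' @param is_partial Logical; `TRUE` if the sequence is incomplete at either
#'   terminus.
#' @return Object of class `precursor`.
#' @examples
#' precursor("p1", "MLLLLLLLLLLASAKRGAESGEAHVFDSLGGGHVPYYKR", signal_end = 14)
#' @export
precursor <- function(id, sequence, signal_end = NA_integer_,
                      is_partial = FALSE) {
  sequence <- sub("\\*$", "", sequence)
  check_sequence(sequence, "precursor sequence")
  signal_end <- as.integer(signal_end)
  if (!is.na(signal_end) &&
      (signal_end < 1 || signal_end >= nchar(sequence))) {
    stop("signal_end must lie strictly inside the sequence", call. = FALSE)
  }
  structure(
    list(id = as.character(id), sequence = sequence,
         signal_end = signal_end, is_partial = isTRUE(is_partial)),
    class = "precursor")
}

#' @export
print.precursor <- function(x, ...) {
  cat(sprintf("<precursor> %s (%d aa%s%s)\n", x$id, nchar(x$sequence),
              if (!is.na(x$signal_end))
                sprintf(", signal 1-%d", x$signal_end) else "",
              if (x$is_partial) ", partial" else ""))
  invisible(x)
}

#' Read precursors from a FASTA file
#'
#' Description lines may carry `signal_end=<int>` and `is_partial=yes|no`
#' key-value tags, which populate the corresponding precursor fields.
#' Trailing `*` stop marks are stripped.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return List of [precursor] objects.
#' @export
read_precursors <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw, ">"))) {
    if (any(nzchar(trimws(raw)))) {
      stop("malformed FASTA (no '>' header): ", path, call. = FALSE)
    }
    return(list())
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) return(list())
  lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    id <- strsplit(header, "\\s+")[[1]][1]
    se <- regmatches(header, regexpr("signal_end=\\d+", header))
    se <- if (length(se)) as.integer(sub("signal_end=", "", se)) else NA_integer_
    pp <- regmatches(header, regexpr("is_partial=(yes|no)", header))
    pp <- length(pp) > 0 && grepl("yes", pp)
    precursor(id, as.character(seqs[[i]]), signal_end = se, is_partial = pp)
  })
}

#' Predict the signal-peptidase cleavage position
#'
#' Hydrophobicity heuristic: the candidate signal peptide must contain a
#' hydrophobic core of `core_min`-`core_max` residues, entirely within the
#' first `window` residues, whose mean Kyte-Doolittle hydropathy reaches
#' `threshold`. The cut is placed after the first small residue (A, G, S or
#' C) following that core, mimicking the small-residue preference of signal
#' peptidase at positions -1/-3.
#'
#' @param prec A [precursor]; must be complete at the N-terminus.
#' @param window Number of N-terminal residues searched (default 40).
#' @param core_min,core_max Allowed hydrophobic core lengths (default 8-15).
#' @param threshold Minimum mean hydropathy of the core (default 1.6).
#' @return 1-based index of the last signal residue, or `NA_integer_` if no
#'   core reaches the threshold or no small residue follows it.
#' @export
find_signal_peptide <- function(prec, window = 40, core_min = 8,
                                core_max = 15, threshold = 1.6) {
  stopifnot(inherits(prec, "precursor"))
  if (prec$is_partial) {
    stop("cannot predict a signal peptide on a partial precursor",
         call. = FALSE)
  }
  n <- min(window, nchar(prec$sequence))
  aa <- strsplit(substr(prec$sequence, 1, n), "")[[1]]
  hyd <- kd_hydropathy[aa]
  best <- list(mean = -Inf, end = NA_integer_)
  for (len in core_min:core_max) {
    if (len > n) break
    for (start in seq_len(n - len + 1)) {
      m <- mean(hyd[start:(start + len - 1)])
      if (m > best$mean + 1e-12) best <- list(mean = m, end = start + len - 1)
    }
  }
  if (best$mean < threshold) return(NA_integer_)
  after <- aa[seq_len(n) > best$end]
  hit <- which(after %in% c("A", "G", "S", "C"))
  if (length(hit) == 0) return(NA_integer_)
  as.integer(best$end + hit[1])
}

# maximal K/R runs as a data.frame(start, end, length); internal
kr_runs <- function(sequence) {
  r <- gregexpr("[KR]+", sequence)[[1]]
  if (r[1] == -1) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  }
  len <- attr(r, "match.length")
  data.frame(start = as.integer(r), end = as.integer(r) + len - 1L,
             length = len)
}

#' Locate basic (convertase) cleavage sites on a precursor
#'
#' Prohormone convertases cleave at runs of basic residues. Maximal K/R runs
#' of length 2 (dibasic) or 3 (tribasic) are always reported; single K/R
#' residues only when `allow_monobasic = TRUE`. Runs longer than 3 are
#' reported as a single tribasic site anchored at the C-terminal end of the
#' run, so that no zero-length peptide is generated.
#'
#' @param prec A [precursor] or a plain amino-acid string.
#' @param allow_monobasic Report single K/R residues as sites (default
#'   `FALSE`).
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   `kind` (`monobasic`/`dibasic`/`tribasic`), `residues`; sorted by
#'   `start`.
#' @examples
#' find_cleavage_sites("AAKRAA")
#' @export
find_cleavage_sites <- function(prec, allow_monobasic = FALSE) {
  sequence <- if (inherits(prec, "precursor")) prec$sequence else
    check_sequence(prec)
  runs <- kr_runs(sequence)
  keep <- runs$length >= 2 | (allow_monobasic & runs$length == 1)
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      kind = character(), residues = character(),
                      stringsAsFactors = FALSE))
  }
  start <- ifelse(runs$length > 3, runs$end - 2L, runs$start)
  len <- pmin(runs$length, 3L)
  data.frame(
    start = as.integer(start),
    end = runs$end,
    kind = c("monobasic", "dibasic", "tribasic")[len],
    residues = substring(sequence, start, runs$end),
    stringsAsFactors = FALSE)
}

#' Apply amidation and pyroglutamate rules to a raw excised segment
#'
#' C-terminal amidation: a Gly immediately preceding a cleavage site is the
#' amide donor; it is removed and the peptide flagged `amidated`. A segment
#' at the precursor terminus keeps its Gly and stays unamidated. N-terminal
#' Gln flags a *possible* pyroglutamate; both forms are retained downstream
#' as search variants. Oxidation states are enumerated downstream, not here.
#'
#' @param raw_segment Excised segment, flanking basic residues already
#'   removed.
#' @param followed_by_site `TRUE` if a cleavage site follows the segment on
#'   the precursor (i.e. the segment is not C-terminal).
#' @return List with `sequence` (post-PTM), `amidated`, `pyroglu`.
#' @export
apply_ptm_rules <- function(raw_segment, followed_by_site) {
  check_sequence(raw_segment, "segment")
  amidated <- followed_by_site && endsWith(raw_segment, "G") &&
    nchar(raw_segment) > 1
  sequence <- if (amidated)
    substr(raw_segment, 1, nchar(raw_segment) - 1) else raw_segment
  list(sequence = sequence,
       amidated = amidated,
       pyroglu = startsWith(sequence, "Q"))
}

#' Excise mature peptides from a precursor
#'
#' Mature peptides are the maximal segments strictly between basic cleavage
#' sites (and after the signal peptide, when annotated), with flanking basic
#' residues removed and PTM rules ([apply_ptm_rules]) applied. Each reported
#' site is extended to its containing maximal K/R run so that leftover basic
#' residues from runs longer than 3 never enter a peptide. `copy_index`
#' numbers identical post-PTM sequences in N-to-C order.
#'
#' @param prec A [precursor].
#' @param sites Cleavage sites as returned by [find_cleavage_sites];
#'   computed from `prec` when `NULL`.
#' @param min_len Minimum post-PTM peptide length retained (default 4);
#'   shorter inter-site spacers are discarded.
#' @param allow_monobasic Passed to [find_cleavage_sites] when `sites` is
#'   `NULL`.
#' @return data.frame with columns `precursor_id`, `start`, `end` (pre-PTM
#'   span on the precursor, 1-based inclusive), `sequence` (post-PTM),
#'   `amidated`, `pyroglu`, `copy_index`.
#' @export
excise_peptides <- function(prec, sites = NULL, min_len = 4,
                            allow_monobasic = FALSE) {
  stopifnot(inherits(prec, "precursor"))
  if (is.null(sites)) {
    sites <- find_cleavage_sites(prec, allow_monobasic = allow_monobasic)
  }
  n <- nchar(prec$sequence)
  empty <- data.frame(precursor_id = character(), start = integer(),
                      end = integer(), sequence = character(),
                      amidated = logical(), pyroglu = logical(),
                      copy_index = integer(), stringsAsFactors = FALSE)
  # extend each site to its maximal K/R run
  runs <- kr_runs(prec$sequence)
  blocked <- rep(FALSE, n)
  if (nrow(sites) > 0) {
    if (is.unsorted(sites$start)) {
      stop("sites must be sorted by start", call. = FALSE)
    }
    for (i in seq_len(nrow(sites))) {
      hit <- runs$start <= sites$start[i] & runs$end >= sites$end[i]
      if (!any(hit)) {
        stop("site ", i, " does not lie on a K/R run of the precursor",
             call. = FALSE)
      }
      blocked[runs$start[which(hit)[1]]:runs$end[which(hit)[1]]] <- TRUE
    }
  }
  from <- if (!is.na(prec$signal_end)) prec$signal_end + 1L else 1L
  if (from > n) return(empty)
  usable <- !blocked & seq_len(n) >= from
  r <- rle(usable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(seg) == 0) return(empty)

  out <- lapply(seq_len(nrow(seg)), function(i) {
    raw <- substring(prec$sequence, seg$start[i], seg$end[i])
    ptm <- apply_ptm_rules(raw, followed_by_site = seg$end[i] < n)
    if (nchar(ptm$sequence) < min_len) return(NULL)
    data.frame(precursor_id = prec$id, start = seg$start[i],
               end = seg$end[i], sequence = ptm$sequence,
               amidated = ptm$amidated, pyroglu = ptm$pyroglu,
               copy_index = NA_integer_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out$copy_index <- as.integer(stats::ave(seq_len(nrow(out)), out$sequence,
                                          FUN = seq_along))
  rownames(out) <- NULL
  out
}

#' Count copies of each mature peptide
#'
#' Exact multiset count of post-PTM sequences, e.g. to recover the 7-fold
#' repeat of a multicopy neuropeptide on one precursor.
#'
#' @param peptides data.frame from [excise_peptides] (one precursor).
#' @return Named integer vector, sequence to copy count.
#' @export
count_copies <- function(peptides) {
  if (is.null(peptides) || nrow(peptides) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(peptides$sequence)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write a mature-peptide table to TSV
#'
#' @param peptides data.frame from [excise_peptides] (possibly several
#'   precursors row-bound).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
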