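#' Predict mature peptides, masses and variants from a precursor FASTA
#'
#' Runs the prohormone stage (cleavage prediction, excision, PTM rules) and
#' the mass stage (variant enumeration, monoisotopic masses) over every
#' precursor in a FASTA file and writes the mature-peptide table.
#'
#' @param fasta_path Precursor FASTA (headers may carry `signal_end=` /
#'   `is_partial=` tags).
#' @param out_tsv Output TSV of mature peptides with `neutral_mono` and
#'   `mh` columns (one row per modification variant).
#' @param min_len,allow_monobasic Passed to [excise_peptides].
#' @param alkylated Passed to [build_peptide_library].
#' @return The written data.frame, invisibly.
#' @export
run_predict <- function(fasta_path, out_tsv = NULL, min_len = 4,
                        allow_monobasic = FALSE, alkylated = FALSE) {
  precursors <- read_precursors(fasta_path)
  peptides <- do.call(rbind, lapply(precursors, excise_peptides,
                                    min_len = min_len,
                                    allow_monobasic = allow_monobasic))
  if (is.null(peptides) || nrow(peptides) == 0) {
    warning("no mature peptides predicted")
    peptides <- data.frame(precursor_id = character(), start = integer(),
                           end = integer(), sequence = character(),
                           amidated = logical(), pyroglu = logical(),
                           copy_index = integer())
    if (!is.null(out_tsv)) write_peptide_table(peptides, out_tsv)
    return(invisible(peptides))
  }
  lib <- suppressWarnings(build_peptide_library(peptides,
                                                alkylated = alkylated))
  base <- lib[!duplicated(lib$sequence), c("sequence", "neutral_mono", "mh")]
  out <- merge(peptides, base, by = "sequence", sort = FALSE)
  out <- out[order(out$precursor_id, out$start),
             c("precursor_id", "start", "end", "sequence", "amidated",
               "pyroglu", "copy_index", "neutral_mono", "mh")]
  rownames(out) <- NULL
  if (!is.null(out_tsv)) write_peptide_table(out, out_tsv)
  invisible(out)
}

read_peptide_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence", "amidated", "pyroglu")
  if (!all(need %in% names(tab))) {
    stop("peptide table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Search a spectra file against a predicted peptide table
#'
#' @param peptides_tsv Mature-peptide TSV from [run_predict] (an optional
#'   `name` column labels peptides in outputs).
#' @param mgf_path MGF file of centroided spectra.
#' @param psms_tsv,detection_tsv Optional output paths.
#' @param config Search parameters as [default_config()].
#' @return List with `psms` and `detection` (invisible).
#' @export
run_search <- function(peptides_tsv, mgf_path, psms_tsv = NULL,
                       detection_tsv = NULL, config = default_config()) {
  peptides <- read_peptide_table(peptides_tsv)
  spectra <- read_mgf(mgf_path)
  lib <- build_peptide_library(peptides, alkylated = isTRUE(config$alkylated))
  psms <- search_spectra(spectra, lib, config)
  det <- detection_table(psms)
  if (!is.null(psms_tsv)) {
    utils::write.table(psms, psms_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(detection_tsv)) write_detection_table(det, detection_tsv)
  invisible(list(psms = psms, detection = det))
}

#' Classify predicted peptides into neuropeptide families
#'
#' @param peptides_tsv Mature-peptide TSV from [run_predict].
#' @param patterns_path Pattern library file ([read_patterns] format);
#'   `NULL` uses the packaged library.
#' @param out_tsv Optional output TSV (`sequence`, `family`,
#'   `b_motif_positions`, `fcan_identity`).
#' @return The classification data.frame, invisibly.
#' @export
run_classify <- function(peptides_tsv, patterns_path = NULL,
                         out_tsv = NULL) {
  peptides <- read_peptide_table(peptides_tsv)
  patterns <- if (is.null(patterns_path)) default_patterns() else
    read_patterns(patterns_path)
  rows <- lapply(unique(peptides$sequence), function(s) {
    call <- classify_family(s, patterns)
    data.frame(sequence = s, family = call$family,
               b_motif_positions = paste(call$evidence$orcokinin_B_hits,
                                         collapse = ","),
               fcan_identity = call$evidence$fcan_identity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sequence = character(), family = character(),
                      b_motif_positions = character(),
                      fcan_identity = numeric())
  }
  if (!is.null(out_tsv)) {
    utils::write.table(out, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(out)
}

#' Summarize tissue expression of every transcript in an FPKM table
#'
#' @param fpkm_tsv Tissue x transcript FPKM TSV.
#' @param out_tsv Optional output TSV (`transcript_id`, `restriction`,
#'   `total_fpkm`).
#' @param cns_tissues CNS tissue labels.
#' @param reference_id Optional reference transcript; when given, a
#'   `max_ratio` column reports each transcript's largest per-tissue ratio
#'   to the reference.
#' @param dominance Passed to [classify_restriction].
#' @return The report data.frame, invisibly.
#' @export
run_expression <- function(fpkm_tsv, out_tsv = NULL,
                           cns_tissues = c("OL", "SupEM", "SubEM"),
                           reference_id = NULL, dominance = 0.9) {
  fpkm <- read_fpkm(fpkm_tsv)
  rows <- lapply(fpkm$transcript_id, function(id) {
    p <- fpkm_profile(fpkm, id)
    r <- data.frame(transcript_id = id,
                    restriction = classify_restriction(p, cns_tissues,
                                                       dominance),
                    total_fpkm = sum(p), stringsAsFactors = FALSE)
    if (!is.null(reference_id)) {
      r$max_ratio <- if (id == reference_id) NA_real_ else {
        ratios <- suppressWarnings(normalize_expression(fpkm, id,
                                                        reference_id))
        if (length(ratios)) max(ratios) else NA_real_
      }
    }
    r
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_tsv)) {
    utils::write.table(out, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(out)
}

#' Generate a full synthetic bundle on disk
#'
#' Writes precursors (FASTA), spectra (MGF), FPKM table (TSV) and their
#' ground-truth manifests into a directory, all derived from the config
#' seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [generator_config].
#' @return Named list of the written paths, invisibly.
#' @export
run_simulate <- function(out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gp <- gen_precursors(config)
  gs <- gen_spectra(config, gp$manifest)
  gf <- gen_fpkm(config)
  paths <- list(
    fasta = file.path(out_dir, "precursors.fasta"),
    precursor_manifest = file.path(out_dir, "precursors_manifest.tsv"),
    mgf = file.path(out_dir, "spectra.mgf"),
    spectra_manifest = file.path(out_dir, "spectra_manifest.tsv"),
    fpkm = file.path(out_dir, "fpkm.tsv"),
    fpkm_manifest = file.path(out_dir, "fpkm_manifest.tsv"))
  write_precursors(gp, paths$fasta, paths$precursor_manifest)
  write_mgf(gs$spectra, paths$mgf)
  utils::write.table(gs$manifest, paths$spectra_manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fpkm(gf$fpkm, paths$fpkm)
  utils::write.table(gf$manifest, paths$fpkm_manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Path to the packaged synthetic FLGa precursor fixture
#'
#' A two-precursor FASTA reconstructing the FLGamide A/B prohormones from
#' the facts printed about them (the published figure sequences are
#' graphical): FLGa 1 = GAESGEAHVFDSLGGGHVPYY, FLGa 2 and FLGa 3 cores from
#' the antisera antigens, 7 tandem copies of FLGa 3 on precursor A and 8 on
#' B, amidation glycines on FLGa 3/4/5, none on FLGa 1/2/6. FLGa 4/5/6 are
#' synthetic sequences consistent with the family motif.
#'
#' @return File path.
#' @export
flga_fixture <- function() .np_extdata("flga_precursors_synthetic.fasta")
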