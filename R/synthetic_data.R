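#' Configuration for the synthetic-data generator
#'
#' The defaults emulate the study conditions this pipeline targets: a
#' multicopy prohormone (one payload repeated 7 times, mirroring the 7-fold
#' neuropeptide repeat), di-/tribasic cleavage sites, amidation-signal
#' glycines on half the payloads, MALDI acquisition with Gaussian relative
#' mass error (30 ppm SD, comfortably inside the instrument's stated 50 ppm
#' precision), uniform-noise fragment spectra, and an 8-tissue panel with
#' CNS-restricted targets.
#'
#' @param seed Integer seed; mandatory, every generator draw derives from
#'   it.
#' @param n_precursors Number of precursors to generate.
#' @param n_payloads Distinct payload peptides per precursor.
#' @param payload_len_range Payload length range (residues), pre-amidation.
#' @param repeat_payload Index of the payload repeated `n_copies` times.
#' @param n_copies Copy count of the repeated payload (default 7).
#' @param amidated_fraction Fraction of payloads given an amidation Gly.
#' @param tribasic_prob Probability a cleavage site is tribasic (else
#'   dibasic).
#' @param signal_len_range Signal-peptide length range.
#' @param spacer_len_range Inter-region spacer length range; kept below the
#'   default excision `min_len` so spacers never masquerade as peptides.
#' @param ppm_error_sd SD of the Gaussian relative precursor mass error,
#'   ppm.
#' @param fragment_mz_sd SD of the absolute fragment m/z error, Da.
#' @param noise_peaks_per_spectrum Uniform noise peaks added to each level-2
#'   spectrum.
#' @param fragment_retention_prob Probability each theoretical a/b/y ion is
#'   observed.
#' @param tissue_panel,cns_tissues Tissue labels and the CNS subset.
#' @param detect_tissues Tissues in which generated peptides are embedded
#'   (the ground-truth detection pattern).
#' @param n_noise_spectra Level-2 noise-only spectra (the score null).
#' @param cns_fpkm,other_fpkm,ref_fpkm Mean FPKM of CNS cells of
#'   CNS-restricted targets, of broad targets everywhere, and of the
#'   reference transcript.
#' @param nb_size Negative-binomial size (dispersion) for nonzero FPKM
#'   cells.
#' @return Named list of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_precursors = 2,
                             n_payloads = 6,
                             payload_len_range = c(8, 21),
                             repeat_payload = 3,
                             n_copies = 7,
                             amidated_fraction = 0.5,
                             tribasic_prob = 0.2,
                             signal_len_range = c(15, 25),
                             spacer_len_range = c(0, 3),
                             ppm_error_sd = 30,
                             fragment_mz_sd = 0.1,
                             noise_peaks_per_spectrum = 20,
                             fragment_retention_prob = 0.7,
                             tissue_panel = c("ANG", "MNG", "OvG", "PSG",
                                              "OL", "SupEM", "SubEM", "OG"),
                             cns_tissues = c("OL", "SupEM", "SubEM"),
                             detect_tissues = c("MNG", "OvG", "OL", "SupEM",
                                                "SubEM"),
                             n_noise_spectra = 50,
                             cns_fpkm = 120,
                             other_fpkm = 40,
                             ref_fpkm = 100,
                             nb_size = 10) {
  if (missing(seed) || is.na(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(amidated_fraction >= 0, amidated_fraction <= 1,
            tribasic_prob >= 0, tribasic_prob <= 1,
            fragment_retention_prob >= 0, fragment_retention_prob <= 1,
            all(cns_tissues %in% tissue_panel),
            all(detect_tissues %in% tissue_panel))
  structure(as.list(environment()), class = "generator_config")
}

# run code under a deterministic RNG stream derived from (seed, offset),
# restoring the caller's RNG state afterwards
with_gen_seed <- function(config, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((config$seed + offset) %% .Machine$integer.max)
  force(code)
}

# sample a K/R-free sequence; used for payloads and spacers so that payload
# boundaries stay unambiguous (ground truth must be unique)
sample_nonbasic <- function(n, exclude = character()) {
  pool <- setdiff(AA_ALPHABET, c("K", "R", exclude))
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

sample_site <- function(tribasic_prob) {
  len <- if (stats::runif(1) < tribasic_prob) 3 else 2
  paste(sample(c("K", "R"), len, replace = TRUE), collapse = "")
}

#' Generate ground-truthed synthetic prohormone precursors
#'
#' Each precursor is a signal peptide (Met + hydrophobic core + small
#' residue), a short spacer, then payload peptides flanked by di-/tribasic
#' sites, with payload `repeat_payload` repeated `n_copies` times in
#' tandem. Amidation-signal glycines are appended to the configured payload
#' fraction (the repeated payload is always amidated, as the multicopy
#' peptide it emulates is). Payloads and spacers are K/R-free, payloads
#' never end in Gly unless amidation is intended, and payloads never start
#' with Gln, so excision ground truth is exact.
#'
#' @param config A [generator_config].
#' @return List with `precursors` (list of [precursor]) and `manifest`
#'   (data.frame: `precursor_id`, `name`, `sequence` (mature, post-PTM),
#'   `amidated`, `copies`).
#' @export
gen_precursors <- function(config) {
  with_gen_seed(config, 0, {
    payload_names <- paste0("pep", seq_len(config$n_payloads))
    # one shared payload set across precursors (splice-variant style)
    lens <- sample(config$payload_len_range[1]:config$payload_len_range[2],
                   config$n_payloads, replace = TRUE)
    payloads <- vapply(lens, function(l) {
      repeat {
        s <- sample_nonbasic(l, exclude = "Q")
        if (!endsWith(s, "G")) return(s)
      }
    }, "")
    amidated <- stats::runif(config$n_payloads) < config$amidated_fraction
    amidated[config$repeat_payload] <- TRUE

    precursors <- list()
    manifest <- list()
    for (k in seq_len(config$n_precursors)) {
      id <- sprintf("synth_prec_%02d", k)
      sig_len <- sample(config$signal_len_range[1]:config$signal_len_range[2], 1)
      core <- paste(sample(c("L", "V", "I", "A", "F"), sig_len - 2,
                           replace = TRUE), collapse = "")
      signal <- paste0("M", core, "A")
      spacer_len <- sample(config$spacer_len_range[1]:config$spacer_len_range[2], 1)
      spacer <- if (spacer_len > 0)
        sample_nonbasic(spacer_len, exclude = c("Q", "G")) else ""
      copies <- rep(1L, config$n_payloads)
      copies[config$repeat_payload] <- as.integer(config$n_copies)
      parts <- character()
      for (p in seq_len(config$n_payloads)) {
        seg <- paste0(payloads[p], if (amidated[p]) "G" else "")
        for (cc in seq_len(copies[p])) {
          parts <- c(parts, sample_site(config$tribasic_prob), seg)
        }
      }
      seqn <- paste0(signal, spacer, paste(parts, collapse = ""),
                     sample_site(config$tribasic_prob))
      precursors[[k]] <- precursor(id, seqn, signal_end = nchar(signal))
      manifest[[k]] <- data.frame(
        precursor_id = id, name = payload_names, sequence = payloads,
        amidated = amidated, copies = copies, stringsAsFactors = FALSE)
    }
    list(precursors = precursors, manifest = do.call(rbind, manifest))
  })
}

#' Generate ground-truthed synthetic spectra
#'
#' For every (tissue, peptide) pair in the ground-truth detection pattern:
#' one level-1 peak at the true `[M+H]+` times `(1 + eps)`,
#' `eps ~ N(0, ppm_error_sd * 1e-6)` (level-1 spectra pool all peptides of
#' a tissue), and one level-2 spectrum whose a/b/y ions are each retained
#' with `fragment_retention_prob`, jittered by `N(0, fragment_mz_sd)` Da,
#' plus `noise_peaks_per_spectrum` uniform noise peaks. Additionally
#' `n_noise_spectra` noise-only level-2 spectra (random precursor, noise
#' peaks only) provide a score null. Peptides whose `[M+H]+` falls outside
#' the 700-4000 Da acquisition window are skipped.
#'
#' @param config A [generator_config].
#' @param peptides data.frame with columns `name`, `sequence`, `amidated`
#'   (e.g. the `manifest` of [gen_precursors], one row per distinct
#'   peptide).
#' @return List with `spectra` (list of [spectrum]) and `manifest`
#'   (data.frame `spectrum_id`, `tissue`, `peptide_name`, `sequence`,
#'   `true_mh`; noise spectra have `peptide_name = NA`).
#' @export
gen_spectra <- function(config, peptides) {
  peptides <- peptides[!duplicated(peptides$sequence), , drop = FALSE]
  with_gen_seed(config, 1, {
    mh <- vapply(seq_len(nrow(peptides)), function(i) {
      peptide_mh(peptides$sequence[i],
                 if (peptides$amidated[i]) "amidation" else character())
    }, 0)
    # margin inside the 700-4000 window so the ppm jitter cannot leave it
    in_range <- mh >= 710 & mh <= 3990
    peptides <- peptides[in_range, , drop = FALSE]
    mh <- mh[in_range]
    spectra <- list()
    manifest <- list()
    add <- function(sp, tissue, name, sequence, true_mh) {
      spectra[[length(spectra) + 1]] <<- sp
      manifest[[length(manifest) + 1]] <<- data.frame(
        spectrum_id = sp$id, tissue = tissue, peptide_name = name,
        sequence = sequence, true_mh = true_mh, stringsAsFactors = FALSE)
    }
    for (tissue in config$detect_tissues) {
      eps <- stats::rnorm(length(mh), 0, config$ppm_error_sd * 1e-6)
      ms1_mz <- mh * (1 + eps)
      sp1 <- spectrum(sprintf("MS1_%s", tissue), tissue = tissue, level = 1,
                      mz = ms1_mz, intensity = stats::runif(length(mh), 10, 100))
      add(sp1, tissue, NA_character_, NA_character_, NA_real_)
      for (i in seq_len(nrow(peptides))) {
        ions <- fragment_ions(
          peptides$sequence[i],
          cterm_mods = if (peptides$amidated[i]) "amidation" else character())
        keep <- stats::runif(nrow(ions)) < config$fragment_retention_prob
        frag_mz <- ions$mz[keep] + stats::rnorm(sum(keep), 0,
                                                config$fragment_mz_sd)
        noise <- stats::runif(config$noise_peaks_per_spectrum, 50, 4000)
        mz <- c(frag_mz, noise)
        mz <- mz[mz >= 50 & mz <= 4000]
        sp2 <- spectrum(sprintf("MS2_%s_%s", tissue, peptides$name[i]),
                        tissue = tissue, level = 2,
                        precursor_mz = mh[i] *
                          (1 + stats::rnorm(1, 0, config$ppm_error_sd * 1e-6)),
                        mz = mz,
                        intensity = stats::runif(length(mz), 1, 100))
        add(sp2, tissue, peptides$name[i], peptides$sequence[i], mh[i])
      }
    }
    for (j in seq_len(config$n_noise_spectra)) {
      mz <- stats::runif(config$noise_peaks_per_spectrum, 50, 4000)
      sp <- spectrum(sprintf("NOISE_%03d", j), tissue = "noise", level = 2,
                     precursor_mz = stats::runif(1, 700, 4000), mz = mz,
                     intensity = stats::runif(length(mz), 1, 100))
      add(sp, "noise", NA_character_, NA_character_, NA_real_)
    }
    list(spectra = spectra, manifest = do.call(rbind, manifest))
  })
}

#' Generate a ground-truthed synthetic FPKM table
#'
#' One reference transcript positive in every tissue, plus target
#' transcripts with `CNS_restricted`, `broad`, and `silent` truth patterns.
#' Nonzero cells get negative-binomial counts around the configured means
#' (dispersion `nb_size`), emulating pooled-animal FPKM without replicate
#' structure.
#'
#' @param config A [generator_config].
#' @param n_cns_restricted,n_broad,n_silent Target transcript counts per
#'   truth class.
#' @return List with `fpkm` (data.frame as [read_fpkm]) and `manifest`
#'   (data.frame `transcript_id`, `pattern`).
#' @export
gen_fpkm <- function(config, n_cns_restricted = 2, n_broad = 2,
                     n_silent = 1) {
  with_gen_seed(config, 2, {
    tissues <- config$tissue_panel
    cns <- tissues %in% config$cns_tissues
    nb <- function(mu, n) stats::rnbinom(n, size = config$nb_size,
                                         mu = mu) + 1
    rows <- list(data.frame(transcript_id = "reference",
                            t(stats::setNames(nb(config$ref_fpkm,
                                                 length(tissues)), tissues)),
                            check.names = FALSE))
    pattern <- c("reference" = "reference")
    mk <- function(id, values, pat) {
      rows[[length(rows) + 1]] <<- data.frame(
        transcript_id = id, t(stats::setNames(values, tissues)),
        check.names = FALSE)
      pattern[id] <<- pat
    }
    for (i in seq_len(n_cns_restricted)) {
      v <- numeric(length(tissues))
      v[cns] <- nb(config$cns_fpkm, sum(cns))
      mk(sprintf("cns_%d", i), v, "CNS_restricted")
    }
    for (i in seq_len(n_broad)) {
      mk(sprintf("broad_%d", i), nb(config$other_fpkm, length(tissues)),
         "broad")
    }
    for (i in seq_len(n_silent)) {
      mk(sprintf("silent_%d", i), numeric(length(tissues)), "silent")
    }
    fpkm <- do.call(rbind, rows)
    list(fpkm = fpkm,
         manifest = data.frame(transcript_id = fpkm$transcript_id,
                               pattern = unname(pattern[fpkm$transcript_id]),
                               stringsAsFactors = FALSE))
  })
}

#' Ground-truth detection table of a synthetic spectra manifest
#'
#' @param manifest `manifest` from [gen_spectra].
#' @param peptides,tissues Optional orderings, as [detection_table].
#' @return Logical matrix of the embedded (peptide, tissue) pairs.
#' @export
manifest_detection_table <- function(manifest, peptides = NULL,
                                     tissues = NULL) {
  truth <- manifest[!is.na(manifest$peptide_name), , drop = FALSE]
  if (is.null(peptides)) peptides <- sort(unique(truth$peptide_name))
  if (is.null(tissues)) tissues <- sort(unique(truth$tissue))
  m <- matrix(FALSE, length(peptides), length(tissues),
              dimnames = list(peptides, tissues))
  m[cbind(truth$peptide_name, truth$tissue)] <- TRUE
  m
}

#' Write precursors and their manifest as FASTA + TSV
#'
#' @param gen Output of [gen_precursors].
#' @param fasta_path,manifest_path Output file paths.
#' @return `fasta_path`, invisibly.
#' @export
write_precursors <- function(gen, fasta_path, manifest_path = NULL) {
  lines <- unlist(lapply(gen$precursors, function(p) {
    c(sprintf(">%s signal_end=%d is_partial=no", p$id, p$signal_end),
      p$sequence)
  }))
  writeLines(lines, fasta_path)
  if (!is.null(manifest_path)) {
    utils::write.table(gen$manifest, manifest_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}
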