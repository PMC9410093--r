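#' Physical constants for peptide m/z arithmetic
#'
#' Monoisotopic masses in Da: water (added once per peptide), a proton
#' (MALDI \eqn{[M+H]^+} convention), and carbon monoxide (the b minus a
#' series offset).
#'
#' @format Named numeric vector with elements `water_mono`, `water_avg`,
#'   `proton`, `co`.
#' @export
np_constants <- c(
  water_mono = 18.010565,
  water_avg  = 18.0153,
  proton     = 1.007276,
  co         = 27.994915
)

#' Amino-acid residue mass table
#'
#' Standard residue (i.e. water-free) masses for the 20 proteinogenic amino
#' acids, shipped as a plain-text resource and cached on first use.
#'
#' @param kind `"mono"` for monoisotopic or `"avg"` for average masses.
#' @return Named numeric vector keyed by 1-letter amino-acid code.
#' @examples
#' residue_masses()[["G"]]
#' @export
residue_masses <- function(kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  key <- paste0("residues_", kind)
  if (is.null(.neuropep_cache[[key]])) {
    tab <- utils::read.delim(.np_extdata("residue_masses.tsv"),
                             stringsAsFactors = FALSE)
    .neuropep_cache[["residues_mono"]] <- stats::setNames(tab$mono, tab$aa)
    .neuropep_cache[["residues_avg"]]  <- stats::setNames(tab$avg, tab$aa)
  }
  .neuropep_cache[[key]]
}

#' Post-translational modification catalogue
#'
#' Fixed catalogue of mass deltas used throughout the package: C-terminal
#' amidation (-0.98402 Da, OH replaced by NH2), N-terminal pyroglutamate
#' from Gln (-17.02655 Da), Met oxidation (+15.99491 Da) and dioxidation
#' (+31.98983 Da), and Cys carbamidomethylation (+57.02146 Da, iodoacetamide
#' alkylation).
#'
#' @return data.frame with columns `name`, `target`, `mono_delta`,
#'   `avg_delta`.
#' @export
modification_catalogue <- function() {
  if (is.null(.neuropep_cache[["mods"]])) {
    .neuropep_cache[["mods"]] <- utils::read.delim(
      .np_extdata("modifications.tsv"), stringsAsFactors = FALSE)
  }
  .neuropep_cache[["mods"]]
}

mod_delta <- function(names, kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  if (length(names) == 0) return(0)
  cat <- modification_catalogue()
  idx <- match(names, cat$name)
  if (anyNA(idx)) {
    stop("unknown modification(s): ",
         paste(names[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  col <- if (kind == "mono") "mono_delta" else "avg_delta"
  sum(cat[[col]][idx])
}

# Kyte-Doolittle hydropathy index, used by the signal-peptide heuristic
kd_hydropathy <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

AA_ALPHABET <- names(kd_hydropathy)

check_sequence <- function(sequence, what = "sequence") {
  if (length(sequence) != 1 || !is.character(sequence) || !nzchar(sequence)) {
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  }
  bad <- setdiff(strsplit(sequence, "")[[1]], AA_ALPHABET)
  if (length(bad)) {
    stop(what, " contains non-standard residue(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(sequence)
}
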