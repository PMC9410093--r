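#' Peptide mass
#'
#' Sum of residue masses plus one water, plus the deltas of any
#' modifications. Positions of the modifications do not affect the intact
#' mass, so they are given by catalogue name only.
#'
#' @param sequence Amino-acid sequence.
#' @param mods Character vector of modification names from
#'   [modification_catalogue()] (repeats allowed, e.g. two oxidations).
#' @param kind `"mono"` or `"avg"`.
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("G")            # 75.03203
#' peptide_mass("GG")           # 132.05349
#' @export
peptide_mass <- function(sequence, mods = character(), kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  check_sequence(sequence)
  res <- residue_masses(kind)
  water <- if (kind == "mono") np_constants[["water_mono"]] else
    np_constants[["water_avg"]]
  sum(res[strsplit(sequence, "")[[1]]]) + water + mod_delta(mods, kind)
}

#' Singly protonated mass [M+H]+
#'
#' @inheritParams peptide_mass
#' @return `[M+H]+` in Da (monoisotopic), i.e. neutral mass + 1.007276.
#' @export
peptide_mh <- function(sequence, mods = character()) {
  peptide_mass(sequence, mods, kind = "mono") + np_constants[["proton"]]
}

#' Theoretical a/b/y fragment ions
#'
#' Standard series arithmetic on monoisotopic residue masses:
#' \eqn{b_i} = N-terminal i-residue sum + proton; \eqn{a_i = b_i - CO};
#' \eqn{y_i} = C-terminal i-residue sum + water + proton. N-terminal
#' modifications (pyroglutamate) shift the a/b series; C-terminal
#' modifications (amidation) shift the y series; residue-site modifications
#' (`site_mods`) shift whichever series spans the modified residue. The full
#'-length b ion (equal to the precursor) is not generated. Multiply charged
#' ions use (m + z*proton)/z up to `max_charge`.
#'
#' @param sequence Amino-acid sequence, length >= 2.
#' @param nterm_mods,cterm_mods Modification names applying to the N/C
#'   terminus.
#' @param site_mods data.frame with columns `name`, `pos` (1-based residue
#'   index), e.g. Met oxidation sites; `NULL` for none.
#' @param series Subset of `c("a", "b", "y")`.
#' @param max_charge Maximum charge state (default 1; MALDI is mostly 1+).
#' @return data.frame with columns `series`, `index`, `charge`, `mz`.
#' @examples
#' fragment_ions("GA")  # b1 58.02874, y1 90.05495, ...
#' @export
fragment_ions <- function(sequence, nterm_mods = character(),
                          cterm_mods = character(), site_mods = NULL,
                          series = c("a", "b", "y"), max_charge = 1) {
  check_sequence(sequence)
  n <- nchar(sequence)
  if (n < 2) stop("need at least 2 residues to fragment", call. = FALSE)
  series <- match.arg(series, c("a", "b", "y"), several.ok = TRUE)
  res <- residue_masses("mono")[strsplit(sequence, "")[[1]]]
  if (!is.null(site_mods) && nrow(site_mods) > 0) {
    cat <- modification_catalogue()
    res[site_mods$pos] <- res[site_mods$pos] +
      cat$mono_delta[match(site_mods$name, cat$name)]
  }
  proton <- np_constants[["proton"]]
  prefix <- cumsum(res)[-n] + mod_delta(nterm_mods)          # b_i neutral part
  suffix <- cumsum(rev(res))[-n] + np_constants[["water_mono"]] +
    mod_delta(cterm_mods)                                    # y_i neutral part
  out <- list()
  idx <- seq_len(n - 1)
  if ("b" %in% series) {
    out$b <- data.frame(series = "b", index = idx, mz = prefix + proton)
  }
  if ("a" %in% series) {
    out$a <- data.frame(series = "a", index = idx,
                        mz = prefix + proton - np_constants[["co"]])
  }
  if ("y" %in% series) {
    out$y <- data.frame(series = "y", index = idx, mz = suffix + proton)
  }
  out <- do.call(rbind, out)
  full <- do.call(rbind, lapply(seq_len(max_charge), function(z) {
    data.frame(series = out$series, index = out$index, charge = z,
               mz = (out$mz + (z - 1) * proton) / z)
  }))
  rownames(full) <- NULL
  full[order(full$series, full$charge, full$index), ]
}

#' Enumerate search variants of a mature peptide
#'
#' Cartesian expansion of the variable modifications used in the library
#' search: optional N-terminal pyroglutamate (only when the peptide starts
#' with Gln) and, per methionine, none / oxidation / dioxidation. Amidation
#' is fixed by the peptide's `amidated` flag (set during excision), not
#' variable; Cys carbamidomethylation is fixed when `alkylated = TRUE`
#' (iodoacetamide sample prep), otherwise absent.
#'
#' @param sequence Post-PTM peptide sequence.
#' @param amidated Logical; C-terminally amidated.
#' @param pyroglu_possible Logical; N-terminal Gln may cyclize.
#' @param alkylated Logical; sample was alkylated (fixed
#'   carbamidomethyl-Cys).
#' @return data.frame with one row per variant: `sequence`, `amidated`,
#'   `nterm_mods`, `cterm_mods`, `mods` (all names, `;`-separated),
#'   `site_mods` (list column of data.frames), `neutral_mono`, `mh`.
#' @export
enumerate_variants <- function(sequence, amidated = FALSE,
                               pyroglu_possible = startsWith(sequence, "Q"),
                               alkylated = FALSE) {
  check_sequence(sequence)
  aa <- strsplit(sequence, "")[[1]]
  met_pos <- which(aa == "M")
  fixed <- character()
  if (amidated) fixed <- c(fixed, "amidation")
  if (alkylated) fixed <- c(fixed, rep("carbamidomethyl", sum(aa == "C")))
  pg_opts <- if (isTRUE(pyroglu_possible) && startsWith(sequence, "Q"))
    c(FALSE, TRUE) else FALSE
  met_states <- if (length(met_pos))
    do.call(expand.grid, rep(list(c("none", "oxidation", "dioxidation")),
                             length(met_pos)))
  else data.frame(row.names = 1)

  rows <- list()
  for (pg in pg_opts) {
    for (r in seq_len(nrow(met_states))) {
      states <- if (ncol(met_states)) unlist(met_states[r, , drop = TRUE],
                                             use.names = FALSE) else character()
      states <- as.character(states)
      keep <- states != "none"
      site <- if (any(keep))
        data.frame(name = states[keep], pos = met_pos[keep],
                   stringsAsFactors = FALSE)
      else NULL
      nterm <- if (pg) "pyroglu" else character()
      all_mods <- c(fixed, nterm, if (!is.null(site)) site$name)
      mono <- peptide_mass(sequence, all_mods, "mono")
      rows[[length(rows) + 1]] <- data.frame(
        sequence = sequence, amidated = amidated,
        nterm_mods = paste(nterm, collapse = ";"),
        cterm_mods = if (amidated) "amidation" else "",
        mods = paste(all_mods, collapse = ";"),
        neutral_mono = mono, mh = mono + np_constants[["proton"]],
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$site_mods <- list(site)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a theoretical peptide library for spectrum searching
#'
#' Expands each mature peptide into its modification variants ("no enzyme"
#' search: all predicted peptides enter as-is) and records names for
#' reporting.
#'
#' @param peptides data.frame from [excise_peptides]; an optional `name`
#'   column labels peptides in outputs.
#' @param alkylated Passed to [enumerate_variants].
#' @return data.frame, one row per (peptide, variant), with library columns
#'   plus `peptide_name`.
#' @export
build_peptide_library <- function(peptides, alkylated = FALSE) {
  if (is.null(peptides) || nrow(peptides) == 0) {
    warning("empty peptide set: library is empty")
    return(data.frame())
  }
  nm <- if ("name" %in% names(peptides)) peptides$name else peptides$sequence
  uniq <- !duplicated(peptides$sequence)
  out <- lapply(which(uniq), function(i) {
    v <- enumerate_variants(peptides$sequence[i],
                            amidated = peptides$amidated[i],
                            pyroglu_possible = peptides$pyroglu[i],
                            alkylated = alkylated)
    v$peptide_name <- nm[i]
    v
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a theoretical peptide table to TSV
#'
#' @param library data.frame from [build_peptide_library].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_library <- function(library, path) {
  cols <- setdiff(names(library), "site_mods")
  utils::write.table(library[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
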