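#' Read a tissue x transcript FPKM table
#'
#' Expects a TSV with a `transcript_id` first column (any name) and one
#' column per tissue. Missing cells are read as 0 with a warning;
#' duplicated transcript ids are an error.
#'
#' @param path TSV file.
#' @return data.frame with column `transcript_id` and one numeric column
#'   per tissue.
#' @export
read_fpkm <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("FPKM table needs transcript ids and at least one tissue",
                          call. = FALSE)
  names(tab)[1] <- "transcript_id"
  if (anyDuplicated(tab$transcript_id)) {
    stop("duplicated transcript row(s): ",
         paste(unique(tab$transcript_id[duplicated(tab$transcript_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (j in 2:ncol(tab)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    if (anyNA(v)) {
      warning("missing FPKM cells read as 0 in tissue ", names(tab)[j])
      v[is.na(v)] <- 0
    }
    if (any(v < 0)) stop("negative FPKM in tissue ", names(tab)[j],
                         call. = FALSE)
    tab[[j]] <- v
  }
  tab
}

#' Write an FPKM table to TSV
#'
#' @param fpkm data.frame as returned by [read_fpkm].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fpkm <- function(fpkm, path) {
  utils::write.table(fpkm, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

fpkm_profile <- function(fpkm, transcript_id) {
  i <- match(transcript_id, fpkm$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id, call. = FALSE)
  unlist(fpkm[i, -1, drop = FALSE])
}

#' Normalize a transcript's FPKM to a reference gene
#'
#' Per-tissue ratio target / reference (the usual way a Fig-1C-style bar
#' profile is scaled to a housekeeping gene such as elongation protein 3).
#' Tissues where the reference is 0 are omitted with a warning.
#'
#' @param fpkm data.frame from [read_fpkm].
#' @param transcript_id Target transcript.
#' @param reference_id Reference (housekeeping) transcript.
#' @return Named numeric vector of tissue ratios.
#' @export
normalize_expression <- function(fpkm, transcript_id, reference_id) {
  target <- fpkm_profile(fpkm, transcript_id)
  ref <- fpkm_profile(fpkm, reference_id)
  drop <- ref == 0
  if (any(drop)) {
    warning("reference FPKM is 0 in: ",
            paste(names(ref)[drop], collapse = ", "), "; tissue(s) omitted")
  }
  target[!drop] / ref[!drop]
}

#' Classify the tissue restriction of an expression profile
#'
#' Descriptive classification of a pooled-animal FPKM profile:
#' * `silent` - all FPKM are 0;
#' * `CNS_restricted` - every non-CNS tissue is 0 (and some CNS tissue is
#'   not);
#' * `CNS_dominant` - the CNS share of total FPKM is at least `dominance`;
#' * `broad` - anything else.
#' The call is invariant to rescaling all FPKM by a positive constant.
#'
#' @param profile Named numeric vector of tissue FPKM (or ratios).
#' @param cns_tissues Character vector of CNS tissue labels (e.g. OL,
#'   SupEM, SubEM).
#' @param dominance CNS share threshold for `CNS_dominant` (default 0.9).
#' @return One of `"silent"`, `"CNS_restricted"`, `"CNS_dominant"`,
#'   `"broad"`.
#' @export
classify_restriction <- function(profile, cns_tissues,
                                 dominance = 0.9) {
  stopifnot(!is.null(names(profile)), all(profile >= 0))
  cns <- names(profile) %in% cns_tissues
  if (all(profile == 0)) return("silent")
  if (all(profile[!cns] == 0)) return("CNS_restricted")
  if (sum(profile[cns]) / sum(profile) >= dominance) return("CNS_dominant")
  "broad"
}

#' Bar-chart rendering of an expression profile
#'
#' Draws a per-tissue FPKM bar chart for a target transcript next to the
#' reference gene, Fig-1C style. Requires ggplot2.
#'
#' @param fpkm data.frame from [read_fpkm].
#' @param transcript_id Target transcript.
#' @param reference_id Optional reference transcript drawn alongside.
#' @return A ggplot object.
#' @export
plot_expression_profile <- function(fpkm, transcript_id,
                                    reference_id = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_expression_profile needs ggplot2", call. = FALSE)
  }
  ids <- c(transcript_id, reference_id)
  rows <- lapply(ids, function(id) {
    p <- fpkm_profile(fpkm, id)
    data.frame(transcript = id, tissue = names(p), fpkm = as.numeric(p))
  })
  df <- do.call(rbind, rows)
  df$tissue <- factor(df$tissue, levels = names(fpkm)[-1])
  ggplot2::ggplot(df, ggplot2::aes(x = tissue, y = fpkm,
                                   fill = transcript)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "FPKM") +
    ggplot2::theme_minimal()
}
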