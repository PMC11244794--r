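# Structural-variant filtering: derive the heterozygous "parental SV" set
# per hybrid from three call sets against the same reference —
#   wild_inbred : wild parent inbred vs reference,
#   f1_pollen   : F1 pollen pool vs reference,
#   self        : re-sequenced reference accession vs its own assembly
#                 (an artifact mask).
# An SV heterozygous in the F1 must be seen in both the inbred and the
# pollen data; anything overlapping a self call is a problematic region.

#' Structural-variant filter parameters
#'
#' @param min_detect_len minimum detected SV length in bp (default 50).
#' @param min_analysis_len analysis-set threshold: SVs strictly larger than
#'   this (default 1000 bp) enter enrichment analyses.
#' @param min_inv_report_len inversions strictly larger than this (default
#'   30 kb) form the large-inversion report class.
#' @param match_reciprocal_overlap reciprocal overlap required to call an
#'   inbred and a pollen SV the same event (default 0.5, the community
#'   concordance convention; the matching rule is a package decision, not a
#'   property of the data).
#' @return object of class `sv_filter_params`.
#' @export
sv_filter_params <- function(min_detect_len = 50,
                             min_analysis_len = 1000,
                             min_inv_report_len = 30e3,
                             match_reciprocal_overlap = 0.5) {
  stopifnot(min_detect_len > 0, min_analysis_len > 0,
            min_inv_report_len > 0,
            match_reciprocal_overlap > 0, match_reciprocal_overlap <= 1)
  structure(list(min_detect_len = min_detect_len,
                 min_analysis_len = min_analysis_len,
                 min_inv_report_len = min_inv_report_len,
                 match_reciprocal_overlap = match_reciprocal_overlap),
            class = "sv_filter_params")
}

#' Match inbred SV calls against F1 pollen calls
#'
#' An inbred SV is retained as a parental SV iff some pollen SV of the same
#' type overlaps it with at least the configured reciprocal overlap; the
#' inbred coordinates are kept. Same-locus calls of conflicting type are
#' not matched but reported in a discordance table.
#'
#' @param inbred,pollen `GRanges` with a `type` metadata column.
#' @param params [sv_filter_params()].
#' @return `GRanges` of parental SVs (subset of `inbred`); attribute
#'   `discordant` holds a `data.frame` of type-conflicting locus pairs.
#' @export
match_sv_calls <- function(inbred, pollen, params = sv_filter_params()) {
  stopifnot(!is.null(mcols(inbred)$type), !is.null(mcols(pollen)$type))
  inbred <- as_unstranded(inbred)
  pollen <- as_unstranded(pollen)
  hits <- findOverlaps(inbred, pollen, ignore.strand = TRUE)
  ro <- reciprocal_overlap(inbred[queryHits(hits)], pollen[subjectHits(hits)])
  same <- mcols(inbred)$type[queryHits(hits)] ==
    mcols(pollen)$type[subjectHits(hits)]
  matched <- unique(queryHits(hits)[ro >= params$match_reciprocal_overlap & same])
  disc_idx <- ro >= params$match_reciprocal_overlap & !same
  discordant <- data.frame(
    chrom = as.character(seqnames(inbred))[queryHits(hits)[disc_idx]],
    inbred_start = start(inbred)[queryHits(hits)[disc_idx]],
    inbred_type = mcols(inbred)$type[queryHits(hits)[disc_idx]],
    pollen_type = mcols(pollen)$type[subjectHits(hits)[disc_idx]],
    stringsAsFactors = FALSE)
  out <- inbred[sort(matched)]
  mcols(out)$source <- rep("parental", length(out))
  attr(out, "discordant") <- discordant
  out
}

#' Remove parental SVs overlapping self SVs, keep DEL/INV
#'
#' Retains parental SVs of the deletion and inversion type with zero bp of
#' overlap against any self SV ("does not overlap" is strict: a single
#' shared base discards the call). Other SV types pass through readers for
#' reporting but are excluded here.
#'
#' @param parental `GRanges` with `type` metadata (from [match_sv_calls()]).
#' @param self_svs `GRanges` of self SVs (any type).
#' @return filtered `GRanges`.
#' @export
subtract_self_svs <- function(parental, self_svs) {
  parental <- as_unstranded(parental)
  keep_type <- mcols(parental)$type %in% c("DEL", "INV")
  out <- parental[keep_type]
  if (length(self_svs)) {
    out <- out[!overlapsAny(out, as_unstranded(self_svs), ignore.strand = TRUE)]
  }
  out
}

#' Label SVs with size classes
#'
#' Adds logical columns for each size class an SV satisfies:
#' `detect` (length >= 50 bp), `analysis` (length strictly > 1 kb; the set
#' used for enrichment), `inv_report` (inversions strictly > 30 kb).
#'
#' @param svs `GRanges` with `type` metadata.
#' @param params [sv_filter_params()].
#' @return `svs` with added metadata columns.
#' @export
apply_size_classes <- function(svs, params = sv_filter_params()) {
  len <- width(svs)
  mcols(svs)$detect <- len >= params$min_detect_len
  mcols(svs)$analysis <- len > params$min_analysis_len
  mcols(svs)$inv_report <- mcols(svs)$type == "INV" & len > params$min_inv_report_len
  svs
}

#' Full parental-SV filter for one hybrid
#'
#' Chains [match_sv_calls()], [subtract_self_svs()] and
#' [apply_size_classes()]; filtering is monotone (output is a subset of the
#' inbred input).
#'
#' @param inbred,pollen,self_svs `GRanges` call sets with `type` metadata.
#' @param params [sv_filter_params()].
#' @return filtered, size-labelled `GRanges`; attribute `log` records the
#'   count entering and leaving each step.
#' @export
filter_parental_svs <- function(inbred, pollen, self_svs,
                                params = sv_filter_params()) {
  parental <- match_sv_calls(inbred, pollen, params)
  filtered <- subtract_self_svs(parental, self_svs)
  out <- apply_size_classes(filtered, params)
  attr(out, "log") <- data.frame(
    step = c("inbred", "parental", "del_inv_no_self"),
    n = c(length(inbred), length(parental), length(filtered)))
  attr(out, "discordant") <- attr(parental, "discordant")
  out
}
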