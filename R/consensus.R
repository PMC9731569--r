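#' Classify a variant from its curated evidence profile
#'
#' Mechanical implementation of the pathogenicity annotation criteria used
#' for the globin SNV dataset. A variant is pathogenic/likely pathogenic
#' when heterozygotes show abnormal haematology or Hb properties (or the
#' variant is dominant), or when it causes disease in trans with an
#' established pathogenic variant or in the homozygous state. It is
#' benign/likely benign when seen in at least three independent
#' heterozygotes with normal haematology and Hb properties, or when it does
#' not cause disease in trans with an established pathogenic variant —
#' provided no pathogenic evidence exists. Anything else, any profile with
#' conflicting evidence, and any record stemming from an unpublished direct
#' submission, is a VUS.
#'
#' All arguments are vectorised; the function is total (it never throws on
#' conflicting evidence — the conflict is reported through the
#' `"conflict"` attribute).
#'
#' @param het_abnormal_or_dominant Logical: abnormal haematology/Hb
#'   properties or disease in heterozygotes.
#' @param disease_in_trans_or_homozygous Logical: causes disease in trans
#'   with a pathogenic variant or when homozygous.
#' @param benign_het_occurrences Non-negative integer: independent
#'   heterozygous observations with normal haematology and Hb properties.
#' @param benign_in_trans Logical: does not cause disease in trans with an
#'   established pathogenic variant.
#' @param conflicting_evidence Logical: evidence conflicts; forces VUS.
#' @param unpublished_direct_submission Logical: record submitted without a
#'   peer-reviewed publication; forces VUS.
#' @return Character vector in `{"PLP","BLB","VUS"}` with a logical
#'   `"conflict"` attribute marking profiles holding both pathogenic and
#'   benign evidence.
#' @examples
#' classify_evidence(benign_het_occurrences = 3)            # "BLB"
#' classify_evidence(disease_in_trans_or_homozygous = TRUE) # "PLP"
#' classify_evidence(benign_het_occurrences = 2)            # "VUS"
#' @export
classify_evidence <- function(het_abnormal_or_dominant = FALSE,
                              disease_in_trans_or_homozygous = FALSE,
                              benign_het_occurrences = 0L,
                              benign_in_trans = FALSE,
                              conflicting_evidence = FALSE,
                              unpublished_direct_submission = FALSE) {
  n <- max(length(het_abnormal_or_dominant),
           length(disease_in_trans_or_homozygous),
           length(benign_het_occurrences), length(benign_in_trans),
           length(conflicting_evidence), length(unpublished_direct_submission))
  het_abnormal_or_dominant <- rep_len(het_abnormal_or_dominant, n)
  disease_in_trans_or_homozygous <- rep_len(disease_in_trans_or_homozygous, n)
  benign_het_occurrences <- rep_len(benign_het_occurrences, n)
  benign_in_trans <- rep_len(benign_in_trans, n)
  conflicting_evidence <- rep_len(conflicting_evidence, n)
  unpublished_direct_submission <- rep_len(unpublished_direct_submission, n)
  if (any(benign_het_occurrences < 0))
    stop("benign_het_occurrences must be non-negative")

  pathogenic <- het_abnormal_or_dominant | disease_in_trans_or_homozygous
  benign <- benign_het_occurrences >= 3 | benign_in_trans
  conflict <- (pathogenic & benign) | conflicting_evidence
  blocked <- conflict | unpublished_direct_submission

  out <- rep("VUS", n)
  out[pathogenic & !blocked] <- "PLP"
  out[benign & !pathogenic & !blocked] <- "BLB"
  attr(out, "conflict") <- pathogenic & benign
  out
}

#' Merge two independent expert calls (Delphi step)
#'
#' Two groups of haemoglobinopathy experts annotate each variant
#' independently; agreeing calls become the consensus, disagreements are
#' marked for discussion and provisionally resolved to VUS (the manual
#' discussion outcome can be supplied downstream as an override).
#'
#' @param call_a,call_b Character vectors of calls in `{"PLP","BLB","VUS"}`.
#' @return Data frame with columns `consensus` and `needs_discussion`.
#' @examples
#' merge_delphi("PLP", "PLP")  # consensus PLP, no discussion
#' merge_delphi("PLP", "BLB")  # VUS, needs discussion
#' @export
merge_delphi <- function(call_a, call_b) {
  stopifnot(length(call_a) == length(call_b))
  bad <- setdiff(unique(c(call_a, call_b)), pathogenicity_classes)
  if (length(bad))
    stop("unknown pathogenicity call(s): ", paste(bad, collapse = ", "))
  agree <- call_a == call_b
  data.frame(consensus = ifelse(agree, call_a, "VUS"),
             needs_discussion = !agree)
}
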