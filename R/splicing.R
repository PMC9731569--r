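#' Assemble the splicing evaluation label set
#'
#' Positives are P/LP variants whose effect category is a splicing subtype
#' (splice acceptor/donor/region or cryptic splice site). Negatives are
#' every other definitively annotated (non-VUS) variant. Variants curated
#' as both missense and splicing are excluded from both sides because their
#' mechanism of pathogenicity is ambiguous; VUS take no part.
#'
#' @param cohort Cohort data.frame (VUS rows, if present, are set aside).
#' @return A list with character-vector elements `positives`, `negatives`,
#'   `excluded` (dual missense+splicing) and `vus`; the four sets partition
#'   the cohort.
#' @export
assemble_splicing_dataset <- function(cohort) {
  validate_cohort(cohort)
  is_vus <- cohort$expert_class == "VUS"
  dual <- cohort$dual_missense_splicing & !is_vus
  splice <- cohort$effect_category %in% splicing_categories
  pos <- !is_vus & !dual & splice & cohort$expert_class == "PLP"
  neg <- !is_vus & !dual & !pos
  out <- list(positives = cohort$variant_id[pos],
              negatives = cohort$variant_id[neg],
              excluded = cohort$variant_id[dual],
              vus = cohort$variant_id[is_vus])
  if (!length(out$positives))
    warning("no splice-affecting P/LP variants in the cohort")
  out
}

#' Maximum SpliceAI delta score
#'
#' SpliceAI reports four delta scores per variant (acceptor gain/loss,
#' donor gain/loss); the variant's splicing score is their maximum. Any
#' missing component makes the result missing.
#'
#' @param ds_ag,ds_al,ds_dg,ds_dl Numeric vectors in `[0, 1]`.
#' @return Numeric vector of per-variant maxima (`NA` where any input is).
#' @examples
#' spliceai_delta_max(0.1, 0.8, 0.0, 0.2)  # 0.8
#' @export
spliceai_delta_max <- function(ds_ag, ds_al, ds_dg, ds_dl) {
  m <- cbind(ds_ag, ds_al, ds_dg, ds_dl)
  out <- apply(m, 1L, max)
  out[rowSums(is.na(m)) > 0L] <- NA_real_
  unname(out)
}

#' MaxEntScan dual-threshold splicing call
#'
#' MaxEntScan scores the reference and alternative allele at a splice
#' site. `Diff = |ref - alt|` is the absolute score change and
#' `Per = 100 * Diff / |ref|` the percentage change relative to the
#' reference score. A variant is called splice-disrupting when both
#' exceed their thresholds (the published rule is Diff > 2 and Per > 5).
#' When the reference score is exactly zero, `Per` is undefined and the
#' call is decided on `Diff` alone; such calls are flagged through the
#' `"per_undefined"` attribute.
#'
#' @param ref_score,alt_score Numeric vectors of site scores.
#' @param diff_threshold Threshold on the absolute difference (default 2).
#' @param per_threshold Threshold on the percentage change (default 5).
#' @return Logical vector of calls with attribute `"per_undefined"`.
#' @examples
#' maxentscan_call(8.0, 5.0)   # TRUE  (Diff 3, Per 37.5)
#' maxentscan_call(8.0, 7.5)   # FALSE (Diff 0.5)
#' @export
maxentscan_call <- function(ref_score, alt_score, diff_threshold = 2,
                            per_threshold = 5) {
  stopifnot(length(ref_score) == length(alt_score))
  diff <- abs(ref_score - alt_score)
  per <- 100 * diff / abs(ref_score)
  undef <- is.finite(diff) & ref_score == 0
  call <- diff > diff_threshold & per > per_threshold
  call[undef] <- diff[undef] > diff_threshold
  attr(call, "per_undefined") <- undef
  call
}

#' Sweep MaxEntScan Diff/Per threshold combinations
#'
#' The dual-threshold rule is a binary classifier indexed by the pair
#' `(diff_threshold, per_threshold)`; this sweeps a small 2-D grid and
#' selects the MCC-optimal combination (ties: higher LR+, then the
#' stricter — larger — thresholds).
#'
#' @param ref_score,alt_score Aligned site scores (missing pairs dropped).
#' @param labels `"PLP"`/`"BLB"`-style labels; here positives are
#'   splice-affecting variants.
#' @param diff_grid,per_grid Candidate thresholds.
#' @param ci_level Confidence level for LR intervals.
#' @return List: `best` (one-row data.frame with `diff_threshold`,
#'   `per_threshold` and [metric_set()] columns) and `sweep` (all rows).
#' @export
maxentscan_sweep <- function(ref_score, alt_score, labels,
                             diff_grid = seq(0, 10, by = 0.5),
                             per_grid = seq(0, 100, by = 5),
                             ci_level = 0.95) {
  keep <- !is.na(ref_score) & !is.na(alt_score)
  ref_score <- ref_score[keep]; alt_score <- alt_score[keep]
  labels <- labels[keep]
  if (!length(labels)) stop("no scored variant pairs for MaxEntScan")
  combos <- expand.grid(diff_threshold = diff_grid, per_threshold = per_grid)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    call <- maxentscan_call(ref_score, alt_score,
                            combos$diff_threshold[k], combos$per_threshold[k])
    is_p <- labels == "PLP"
    cm <- confusion(tp = sum(call & is_p), fn = sum(!call & is_p),
                    fp = sum(call & !is_p), tn = sum(!call & !is_p))
    cbind(combos[k, , drop = FALSE], metric_set(cm, ci_level = ci_level))
  })
  sweep <- do.call(rbind, rows)
  rownames(sweep) <- NULL
  best <- sweep[order(-sweep$mcc, -sweep$lr_pos, -sweep$diff_threshold,
                      -sweep$per_threshold), ][1, , drop = FALSE]
  rownames(best) <- NULL
  list(best = best, sweep = sweep)
}

#' Evaluate splicing predictors against the splicing label set
#'
#' Each splicing tool is swept over its threshold grid on the variants it
#' scores (only SpliceAI scores variants away from canonical splice sites,
#' so per-tool evaluation subsets differ) and the MCC-optimal threshold is
#' selected. Results with fewer than two scored negatives, or with five or
#' fewer of each of TN/FP/FN, are flagged unreliable: likelihood ratios
#' computed from so few benign examples should not be interpreted.
#'
#' @param labelset Result of [assemble_splicing_dataset()].
#' @param scores Score matrix (rows: variant ids; columns include the
#'   splicing tools to evaluate).
#' @param tools List of [tool_config()] objects; only those with
#'   `category == "splicing"` and a score column are evaluated.
#' @param ci_level Confidence level for LR intervals.
#' @return Data frame: one row per tool with `threshold`, the
#'   [metric_set()] columns, `n_negatives` and `reliable`.
#' @export
evaluate_splicing_tools <- function(labelset, scores, tools,
                                    ci_level = 0.95) {
  tools <- as_tool_config_list(tools)
  splice_tools <- Filter(function(t) t$category == "splicing" &&
                           t$name %in% colnames(scores), tools)
  out <- list()
  for (tool in splice_tools) {
    ids <- c(labelset$positives, labelset$negatives)
    lab <- c(rep("PLP", length(labelset$positives)),
             rep("BLB", length(labelset$negatives)))
    s <- scores[match(ids, rownames(scores)), tool$name]
    ok <- !is.na(s)
    s <- s[ok]; lab_ok <- lab[ok]
    if (length(unique(s)) < 2L || length(unique(lab_ok)) < 2L) {
      warning("tool ", tool$name,
              " lacks informative scores on the splicing label set; skipped")
      next
    }
    best <- calibrate_binary(tool, s, lab_ok, ci_level = ci_level)
    n_neg <- sum(lab_ok == "BLB")
    reliable <- n_neg >= 2L &&
      !all(c(best$tn, best$fp, best$fn) <= 5L)
    row <- cbind(best, data.frame(n_negatives = n_neg, reliable = reliable))
    attr(row, "sweep") <- NULL
    out[[tool$name]] <- row
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
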