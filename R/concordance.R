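#' Build a categorical call matrix across tools
#'
#' Converts a score matrix into calls per the supplied thresholds. A single
#' threshold per tool yields binary calls (`"pathogenic"`/`"benign"`); a
#' named pair `c(benign = , pathogenic = )` yields trichotomous calls with
#' `"no_call"` for scores strictly inside the gap. Missing scores give
#' `"missing"`.
#'
#' @param scores Score matrix (variants x tools).
#' @param tools List of [tool_config()] objects.
#' @param thresholds Named list: per tool either one numeric threshold or a
#'   named numeric pair. Every scored tool must be covered.
#' @return Character matrix with the same dimnames as `scores[, names(thresholds)]`.
#' @export
build_call_matrix <- function(scores, tools, thresholds) {
  tools <- as_tool_config_list(tools)
  missing_thr <- setdiff(names(thresholds), colnames(scores))
  if (length(missing_thr))
    stop("thresholds supplied for tools absent from the score matrix: ",
         paste(missing_thr, collapse = ", "))
  out <- matrix("missing", nrow = nrow(scores), ncol = length(thresholds),
                dimnames = list(rownames(scores), names(thresholds)))
  for (nm in names(thresholds)) {
    tool <- tools[[nm]]
    if (is.null(tool)) stop("no tool configuration for ", nm)
    thr <- thresholds[[nm]]
    s <- scores[, nm]
    if (all(is.na(s)))
      warning("all scores missing for tool ", nm)
    if (length(thr) == 1L) {
      p <- pathogenic_call(s, unname(thr), tool)
      out[, nm] <- ifelse(is.na(s), "missing",
                          ifelse(p, "pathogenic", "benign"))
    } else if (length(thr) == 2L && all(c("benign", "pathogenic") %in% names(thr))) {
      p <- pathogenic_call(s, thr[["pathogenic"]], tool)
      b <- !pathogenic_call(s, thr[["benign"]], tool)
      out[, nm] <- ifelse(is.na(s), "missing",
                          ifelse(p, "pathogenic",
                                 ifelse(b, "benign", "no_call")))
    } else {
      stop("threshold for ", nm,
           " must be a single value or c(benign=, pathogenic=)")
    }
  }
  out
}

#' Pairwise concordance between tools
#'
#' Entry (i, j) is the fraction of variants on which tools i and j make the
#' same definite call (pathogenic or benign), among variants where both
#' make definite calls. Pairs with no co-called variant get `NA`; the
#' diagonal is 1.
#'
#' @param call_matrix Result of [build_call_matrix()].
#' @return Symmetric numeric matrix (tools x tools).
#' @export
pairwise_concordance <- function(call_matrix) {
  tools <- colnames(call_matrix)
  if (length(tools) < 2L) stop("need at least two tools for concordance")
  k <- length(tools)
  out <- matrix(NA_real_, k, k, dimnames = list(tools, tools))
  definite <- call_matrix == "pathogenic" | call_matrix == "benign"
  for (i in seq_len(k)) {
    out[i, i] <- 1
    for (j in seq_len(k)[-seq_len(i)]) {
      both <- definite[, i] & definite[, j]
      if (!any(both)) next
      agree <- call_matrix[both, i] == call_matrix[both, j]
      out[i, j] <- out[j, i] <- mean(agree)
    }
  }
  out
}

#' Hierarchical ordering of tools by concordance
#'
#' Orders tools by complete-linkage agglomerative clustering on the
#' distance `1 - concordance` (undefined entries treated as full
#' discordance for ordering purposes only). Tools are pre-sorted by name
#' so the leaf order is deterministic and invariant to the input column
#' order.
#'
#' @param concordance Matrix from [pairwise_concordance()].
#' @return Character vector: the tools in clustered display order.
#' @export
cluster_order <- function(concordance) {
  tools <- sort(rownames(concordance))
  if (length(tools) == 1L) return(tools)
  m <- concordance[tools, tools]
  m[is.na(m)] <- 0
  d <- stats::as.dist(1 - m)
  hc <- stats::hclust(d, method = "complete")
  tools[hc$order]
}

#' Concordance of a tool combination with the expert annotation
#'
#' The concordance rate of a combination is the fraction of variants of
#' the target class for which every tool in the combination makes the
#' definite call matching the expert class. Abstentions (`no_call`) and
#' missing scores break concordance: an assertion is required to match.
#'
#' @param call_matrix Result of [build_call_matrix()].
#' @param expert_labels Character vector (`PLP`/`BLB`/`VUS`) aligned with
#'   the rows of `call_matrix`.
#' @param combination Character vector of at least one tool name.
#' @param target_class `"PLP"` or `"BLB"`.
#' @return Concordance rate in `[0, 1]` (`NA` when no variant has the
#'   target class).
#' @export
combination_concordance <- function(call_matrix, expert_labels, combination,
                                    target_class = c("PLP", "BLB")) {
  target_class <- match.arg(target_class)
  if (!length(combination)) stop("combination must name at least one tool")
  missing_tools <- setdiff(combination, colnames(call_matrix))
  if (length(missing_tools))
    stop("combination names unknown tool(s): ",
         paste(missing_tools, collapse = ", "))
  stopifnot(length(expert_labels) == nrow(call_matrix))
  rows <- expert_labels == target_class
  if (!any(rows)) return(NA_real_)
  want <- if (target_class == "PLP") "pathogenic" else "benign"
  sub <- call_matrix[rows, combination, drop = FALSE]
  mean(rowSums(sub == want) == length(combination))
}

#' Rank tool combinations by concordance rate
#'
#' Enumerates all combinations of `min_size` or more tools and ranks them
#' by [combination_concordance()] for the target class. Ties are broken by
#' smaller combination size, then lexicographically, so the ranking is
#' deterministic.
#'
#' @inheritParams combination_concordance
#' @param tools Tools to combine; defaults to all columns of `call_matrix`.
#' @param min_size Smallest combination size (default 2).
#' @param top_k Number of top combinations to return (default 10).
#' @return Data frame with `combination`, `size`, `class`, `n`,
#'   `concordance_rate`, ordered best first.
#' @export
rank_tool_combinations <- function(call_matrix, expert_labels,
                                   target_class = c("PLP", "BLB"),
                                   tools = colnames(call_matrix),
                                   min_size = 2L, top_k = 10L) {
  target_class <- match.arg(target_class)
  stopifnot(length(tools) >= min_size)
  n_class <- sum(expert_labels == target_class)
  combos <- list()
  for (size in seq(min_size, length(tools))) {
    cc <- utils::combn(sort(tools), size, simplify = FALSE)
    combos <- c(combos, cc)
  }
  rate <- vapply(combos, function(cmb)
    combination_concordance(call_matrix, expert_labels, cmb, target_class),
    numeric(1))
  df <- data.frame(
    combination = vapply(combos, paste, character(1), collapse = "+"),
    size = lengths(combos),
    class = target_class,
    n = n_class,
    concordance_rate = rate)
  df <- df[order(-df$concordance_rate, df$size, df$combination), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}
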