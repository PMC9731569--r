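#' Build a threshold grid for a tool
#'
#' Tools whose scores live on the unit interval get the canonical grid
#' `0.00, 0.05, ..., 1.00` (21 values). For unbounded tools the grid spans
#' the observed score range in 100 equal steps (101 values), giving a
#' resolution comparable to the 0.05 unit-interval step at bounded cost.
#'
#' @param tool A [tool_config()] object.
#' @param observed_scores Numeric vector of the tool's scores (`NA` allowed
#'   and ignored); required for unbounded tools.
#' @return A `threshold_grid` object: list with `tool`, `values`, `step`,
#'   `source`.
#' @export
build_grid <- function(tool, observed_scores = NULL) {
  stopifnot(inherits(tool, "tool_config"))
  if (tool$bounded_unit_interval) {
    values <- seq(0, 1, by = 0.05)
    step <- 0.05
    source <- "unit_interval"
  } else {
    obs <- observed_scores[!is.na(observed_scores)]
    if (length(unique(obs)) < 2L)
      stop("need at least two distinct observed scores to build a grid for ",
           tool$name)
    r <- range(obs)
    values <- seq(r[1], r[2], length.out = 101L)
    step <- (r[2] - r[1]) / 100
    source <- "observed_range"
  }
  structure(list(tool = tool$name, values = values, step = step,
                 source = source),
            class = "threshold_grid")
}

refine_grid <- function(grid, center, refine_factor) {
  # local grid of fine steps spanning one coarse step either side of center
  fine <- grid$step / refine_factor
  values <- seq(center - grid$step, center + grid$step, by = fine)
  structure(list(tool = grid$tool, values = values, step = fine,
                 source = "refined"),
            class = "threshold_grid")
}

#' Sweep a threshold grid and compute all metrics at each step
#'
#' Varies the decision threshold over the grid and computes the full
#' [metric_set()] at every value. Missing scores are removed first (no
#' imputation), so `n_pv` is constant across rows.
#'
#' @param tool A [tool_config()] object.
#' @param scores Numeric vector (may contain `NA`, which are dropped).
#' @param labels Character vector in `{"PLP","BLB"}` aligned with `scores`.
#' @param grid A [build_grid()] result; defaults to the tool's natural grid.
#' @param ci_level Confidence level for LR intervals.
#' @return Data frame with one row per grid value: `tool`, `threshold` and
#'   the [metric_set()] columns.
#' @export
sweep_thresholds <- function(tool, scores, labels, grid = NULL,
                             ci_level = 0.95) {
  stopifnot(inherits(tool, "tool_config"), length(scores) == length(labels))
  keep <- !is.na(scores)
  scores <- scores[keep]
  labels <- labels[keep]
  if (length(scores) == 0L)
    stop("no non-missing scores for tool ", tool$name)
  if (is.null(grid)) grid <- build_grid(tool, scores)
  rows <- lapply(grid$values, function(t) {
    cm <- confusion_at_threshold(scores, labels, t, tool)
    cbind(data.frame(tool = tool$name, threshold = t),
          metric_set(cm, ci_level = ci_level))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the MCC-optimal binary threshold from a sweep
#'
#' Returns the sweep row with maximal MCC. Ties are broken by the higher
#' LR+ point estimate, then by the stricter (more pathogenic-conservative)
#' threshold: the higher threshold for a higher-pathogenic tool, the lower
#' for a lower-pathogenic one.
#'
#' @param sweep Result of [sweep_thresholds()].
#' @param tool The [tool_config()] the sweep was computed with (needed for
#'   direction-aware tie-breaking).
#' @return The selected one-row data.frame.
#' @export
select_mcc_optimal <- function(sweep, tool) {
  stopifnot(is.data.frame(sweep), nrow(sweep) > 0L,
            inherits(tool, "tool_config"))
  m <- sweep$mcc
  if (all(is.na(m))) stop("all MCC values are undefined in the sweep")
  best <- which(!is.na(m) & m == max(m, na.rm = TRUE))
  if (length(best) > 1L) {
    lrp <- sweep$lr_pos[best]
    if (!all(is.na(lrp))) {
      top <- which(!is.na(lrp) & lrp == max(lrp, na.rm = TRUE))
      best <- best[top]
    }
  }
  if (length(best) > 1L) {
    thr <- sweep$threshold[best]
    best <- if (tool$direction == "higher_pathogenic") {
      best[which.max(thr)]
    } else {
      best[which.min(thr)]
    }
  }
  row <- sweep[best[1], , drop = FALSE]
  rownames(row) <- NULL
  row
}

#' Binary calibration of one tool
#'
#' Convenience wrapper: grid, sweep, MCC-optimal selection. Returns the
#' selected row with the full sweep as attribute `"sweep"`.
#'
#' @inheritParams sweep_thresholds
#' @return One-row data.frame (see [select_mcc_optimal()]).
#' @export
calibrate_binary <- function(tool, scores, labels, grid = NULL,
                             ci_level = 0.95) {
  sweep <- sweep_thresholds(tool, scores, labels, grid, ci_level)
  best <- select_mcc_optimal(sweep, tool)
  attr(best, "sweep") <- sweep
  best
}
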