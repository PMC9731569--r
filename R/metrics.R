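#' Confusion matrix for a binary pathogenicity classifier
#'
#' The atom of every downstream statistic: `tp` = P/LP variants called
#' pathogenic, `fn` = P/LP called benign, `fp` = B/LB called pathogenic,
#' `tn` = B/LB called benign.
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return A `confusion` object.
#' @export
confusion <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("confusion cells must be non-negative integers")
  structure(as.list(cells), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  FN %d  FP %d  TN %d  (n = %d)\n",
              x$tp, x$fn, x$fp, x$tn, x$tp + x$fn + x$fp + x$tn))
  invisible(x)
}

#' Is a score called pathogenic at a threshold?
#'
#' Applies the tool's direction of pathogenicity and comparator
#' inclusivity. `NA` scores yield `NA` calls.
#'
#' @param scores Numeric vector.
#' @param threshold Decision threshold.
#' @param tool A [tool_config()] object.
#' @return Logical vector.
#' @export
pathogenic_call <- function(scores, threshold, tool) {
  stopifnot(inherits(tool, "tool_config"), length(threshold) == 1L,
            is.finite(threshold))
  if (tool$direction == "higher_pathogenic") {
    if (tool$pathogenic_inclusive) scores >= threshold else scores > threshold
  } else {
    if (tool$pathogenic_inclusive) scores <= threshold else scores < threshold
  }
}

#' Confusion matrix of a tool at one decision threshold
#'
#' Missing scores must be excluded before the call; labels are the expert
#' classes of the scored variants.
#'
#' @param scores Numeric vector, no `NA`.
#' @param labels Character vector in `{"PLP","BLB"}`, same length.
#' @param threshold Decision threshold.
#' @param tool A [tool_config()] object.
#' @return A [confusion()] object.
#' @export
confusion_at_threshold <- function(scores, labels, threshold, tool) {
  if (length(scores) == 0L)
    stop("no scored variants: cannot form a confusion matrix")
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores))
    stop("scores contain missing values; exclude them before calling")
  bad <- setdiff(unique(labels), c("PLP", "BLB"))
  if (length(bad))
    stop("labels must be PLP or BLB; found: ", paste(bad, collapse = ", "))
  called <- pathogenic_call(scores, threshold, tool)
  is_p <- labels == "PLP"
  confusion(tp = sum(called & is_p), fn = sum(!called & is_p),
            fp = sum(called & !is_p), tn = sum(!called & !is_p))
}

#' Sensitivity, specificity and accuracy
#'
#' Se = TP/(TP+FN), Sp = TN/(FP+TN), Ac = (TP+TN)/n. A zero margin makes
#' the corresponding metric `NA` (undefined), never 0.
#'
#' @param cm A [confusion()] object.
#' @return Named list with `sensitivity`, `specificity`, `accuracy`.
#' @export
basic_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  n_pos <- cm$tp + cm$fn
  n_neg <- cm$fp + cm$tn
  list(
    sensitivity = if (n_pos > 0) cm$tp / n_pos else NA_real_,
    specificity = if (n_neg > 0) cm$tn / n_neg else NA_real_,
    accuracy = if (n_pos + n_neg > 0) (cm$tp + cm$tn) / (n_pos + n_neg) else NA_real_
  )
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' conventional value 0 when any factor of the radicand vanishes (a
#' degenerate classifier or single-class sample carries no correlation).
#'
#' @param cm A [confusion()] object.
#' @return A real in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  tp <- as.numeric(cm$tp); fn <- as.numeric(cm$fn)
  fp <- as.numeric(cm$fp); tn <- as.numeric(cm$tn)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Likelihood ratios with log-method confidence intervals
#'
#' LR+ = Se/(1-Sp) quantifies how much a pathogenic call raises the odds of
#' pathogenicity; LR- = (1-Se)/Sp how much a benign call lowers them. The
#' confidence intervals use the standard log method:
#' `var(ln LR+) = 1/TP - 1/(TP+FN) + 1/FP - 1/(FP+TN)` and symmetrically
#' `var(ln LR-) = 1/FN - 1/(TP+FN) + 1/TN - 1/(FP+TN)`, with the exact
#' two-sided normal quantile for `ci_level`.
#'
#' A ratio whose defining cells contain a zero (TP or FP for LR+, FN or TN
#' for LR-) is computed from all four cells plus a 0.5 continuity
#' correction and flagged via `corrected_pos`/`corrected_neg`; this keeps
#' estimates finite without touching well-populated tables. Both margins
#' empty is an error.
#'
#' @param cm A [confusion()] object.
#' @param ci_level Two-sided confidence level, default 0.95.
#' @return List with `lr_pos`, `lr_pos_ci` (length-2), `lr_neg`,
#'   `lr_neg_ci`, `corrected_pos`, `corrected_neg`.
#' @export
likelihood_ratios <- function(cm, ci_level = 0.95) {
  stopifnot(inherits(cm, "confusion"), ci_level > 0, ci_level < 1)
  if (cm$tp + cm$fn == 0 || cm$fp + cm$tn == 0)
    stop("both pathogenic and benign variants are required for likelihood ratios")
  z <- stats::qnorm(1 - (1 - ci_level) / 2)

  one_lr <- function(tp, fn, fp, tn, kind) {
    # kind "pos": LR+ from Se/(1-Sp); kind "neg": LR- from (1-Se)/Sp
    corrected <- (kind == "pos" && (tp == 0 || fp == 0)) ||
      (kind == "neg" && (fn == 0 || tn == 0))
    if (corrected) {
      tp <- tp + 0.5; fn <- fn + 0.5; fp <- fp + 0.5; tn <- tn + 0.5
    }
    se <- tp / (tp + fn)
    sp <- tn / (fp + tn)
    if (kind == "pos") {
      lr <- se / (1 - sp)
      v <- 1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn)
    } else {
      lr <- (1 - se) / sp
      v <- 1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn)
    }
    half <- z * sqrt(v)
    list(lr = lr, ci = exp(log(lr) + c(-half, half)), corrected = corrected)
  }

  pos <- one_lr(kind = "pos", tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn)
  neg <- one_lr(kind = "neg", tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn)
  list(lr_pos = pos$lr, lr_pos_ci = pos$ci,
       lr_neg = neg$lr, lr_neg_ci = neg$ci,
       corrected_pos = pos$corrected, corrected_neg = neg$corrected)
}

# Bayesian-framework odds of pathogenicity per evidence level.
oddsp_levels <- c(supporting = 2.08, moderate = 4.33,
                  strong = 18.7, very_strong = 350)

#' Ordered evidence-strength levels
#' @format Character vector from `"none"` to `"very_strong"`.
#' @export
strength_levels <- c("none", "supporting", "moderate", "strong", "very_strong")

#' ACMG/AMP evidence strength from a likelihood-ratio confidence bound
#'
#' Under the Bayesian adaptation of the ACMG/AMP framework, the odds of
#' pathogenicity required for each evidence level are 2.08 (supporting),
#' 4.33 (moderate), 18.7 (strong) and 350 (very strong). The pathogenic
#' side is graded conservatively on the lower bound of the LR+ confidence
#' interval (a lower bound of 2.08 or more earns supporting, inclusive);
#' the benign side on the upper bound of the LR- interval against the
#' reciprocal odds (an upper bound of 1/2.08 or less earns supporting).
#' The highest satisfied level is returned.
#'
#' @param lr Point estimate (must be positive; used only for validation).
#' @param ci Length-2 confidence interval `(low, high)`.
#' @param side `"pathogenic"` or `"benign"`.
#' @return One of [strength_levels], as a character scalar.
#' @examples
#' evidence_strength(3.21, c(2.19, 4.72), "pathogenic")  # "supporting"
#' evidence_strength(8.27, c(4.34, 15.75), "pathogenic") # "moderate"
#' evidence_strength(0.42, c(0.37, 0.48), "benign")      # "supporting"
#' @export
evidence_strength <- function(lr, ci, side = c("pathogenic", "benign")) {
  side <- match.arg(side)
  stopifnot(length(ci) == 2L, is.finite(lr), lr > 0)
  if (side == "pathogenic") {
    bound <- ci[1]
    met <- bound >= oddsp_levels
  } else {
    bound <- ci[2]
    met <- bound <= 1 / oddsp_levels
  }
  if (!any(met)) return("none")
  names(oddsp_levels)[max(which(met))]
}

#' Compare two evidence-strength levels
#'
#' @param a,b Levels from [strength_levels].
#' @return `TRUE` when `a` is at least as strong as `b`.
#' @export
strength_at_least <- function(a, b) {
  match(a, strength_levels) >= match(b, strength_levels)
}

#' Full metric set at one threshold
#'
#' Convenience wrapper combining [basic_metrics()], [mcc()] and
#' [likelihood_ratios()] into one flat row. Degenerate tables (a zero
#' margin) yield `NA` likelihood ratios rather than an error when
#' `strict = FALSE`.
#'
#' @param cm A [confusion()] object.
#' @param ci_level Confidence level for the LR intervals.
#' @param strict Error on single-class tables (default `FALSE`: sentinels).
#' @return One-row data.frame with columns `n_pv, tp, fn, fp, tn, ac, se,
#'   sp, mcc, lr_pos, lr_pos_lo, lr_pos_hi, lr_neg, lr_neg_lo, lr_neg_hi`.
#' @export
metric_set <- function(cm, ci_level = 0.95, strict = FALSE) {
  bm <- basic_metrics(cm)
  lr <- if (cm$tp + cm$fn > 0 && cm$fp + cm$tn > 0) {
    likelihood_ratios(cm, ci_level)
  } else if (strict) {
    stop("single-class confusion matrix")
  } else {
    list(lr_pos = NA_real_, lr_pos_ci = c(NA_real_, NA_real_),
         lr_neg = NA_real_, lr_neg_ci = c(NA_real_, NA_real_))
  }
  data.frame(n_pv = cm$tp + cm$fn + cm$fp + cm$tn,
             tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
             ac = bm$accuracy, se = bm$sensitivity, sp = bm$specificity,
             mcc = mcc(cm),
             lr_pos = lr$lr_pos, lr_pos_lo = lr$lr_pos_ci[1],
             lr_pos_hi = lr$lr_pos_ci[2],
             lr_neg = lr$lr_neg, lr_neg_lo = lr$lr_neg_ci[1],
             lr_neg_hi = lr$lr_neg_ci[2])
}
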