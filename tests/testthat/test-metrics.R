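test_that("confusion_at_threshold honours direction and inclusivity", {
  scores <- c(0.1, 0.2, 0.8, 0.9)
  labels <- c("BLB", "BLB", "PLP", "PLP")
  cm <- confusion_at_threshold(scores, labels, 0.5, higher_tool())
  expect_equal(unclass(cm)[c("tp", "fn", "fp", "tn")],
               list(tp = 2L, fn = 0L, fp = 0L, tn = 2L))
  cm_flip <- confusion_at_threshold(scores, labels, 0.5, lower_tool())
  expect_equal(unclass(cm_flip)[c("tp", "fn", "fp", "tn")],
               list(tp = 0L, fn = 2L, fp = 2L, tn = 0L))
  # inclusivity: score exactly at the threshold
  incl <- confusion_at_threshold(c(0.5, 0.9), c("PLP", "PLP"), 0.5,
                                 higher_tool(inclusive = TRUE))
  excl <- confusion_at_threshold(c(0.5, 0.9), c("PLP", "PLP"), 0.5,
                                 higher_tool(inclusive = FALSE))
  expect_identical(incl$tp, 2L)
  expect_identical(excl$tp, 1L)
  expect_error(confusion_at_threshold(numeric(), character(), 0.5,
                                      higher_tool()), "no scored")
  expect_error(confusion_at_threshold(c(0.5, NA), c("PLP", "BLB"), 0.5,
                                      higher_tool()), "missing")
})

test_that("basic metrics use margin definitions with NA for empty margins", {
  expect_equal(basic_metrics(confusion(5, 0, 0, 5)),
               list(sensitivity = 1, specificity = 1, accuracy = 1))
  m <- basic_metrics(confusion(3, 1, 0, 0))
  expect_true(is.na(m$specificity))
  expect_equal(m$sensitivity, 0.75)
})

test_that("MCC matches hand-computed values and conventions", {
  expect_equal(mcc(confusion(10, 0, 0, 10)), 1)
  expect_equal(mcc(confusion(5, 5, 5, 5)), 0)
  expect_equal(mcc(confusion(0, 10, 10, 0)), -1)
  expect_equal(mcc(confusion(3, 0, 2, 0)), 0)  # zero margin -> 0 by convention
})

test_that("uninformative tables give unit likelihood ratios", {
  lr <- likelihood_ratios(confusion(25, 25, 25, 25))
  expect_equal(lr$lr_pos, 1)
  expect_equal(lr$lr_neg, 1)
  expect_false(lr$corrected_pos || lr$corrected_neg)
  expect_lt(lr$lr_pos_ci[1], 1)
  expect_gt(lr$lr_pos_ci[2], 1)
})

test_that("zero cells trigger flagged continuity corrections, not infinities", {
  lr <- likelihood_ratios(confusion(10, 2, 0, 12))
  expect_true(lr$corrected_pos)
  expect_false(lr$corrected_neg)
  expect_true(is.finite(lr$lr_pos) && is.finite(lr$lr_pos_ci[2]))
  lr2 <- likelihood_ratios(confusion(12, 0, 3, 9))
  expect_true(lr2$corrected_neg)
  expect_gt(lr2$lr_neg, 0)
  expect_error(likelihood_ratios(confusion(0, 0, 3, 9)), "required")
})

test_that("class relabelling maps LR+ onto the reciprocal of LR-", {
  set.seed(11)
  for (i in 1:25) {
    cells <- rpois(4, 20) + 1
    cm <- confusion(cells[1], cells[2], cells[3], cells[4])
    # swap classes and invert every call: tp<->tn, fn<->fp
    sw <- confusion(cells[4], cells[3], cells[2], cells[1])
    expect_equal(likelihood_ratios(sw)$lr_pos,
                 1 / likelihood_ratios(cm)$lr_neg)
  }
})

test_that("scaling all cells preserves point estimates and narrows CIs", {
  cm <- confusion(40, 10, 8, 30)
  base_lr <- likelihood_ratios(cm)
  base_m <- basic_metrics(cm)
  for (k in c(2L, 5L)) {
    big <- confusion(40 * k, 10 * k, 8 * k, 30 * k)
    expect_equal(basic_metrics(big), base_m)
    expect_equal(mcc(big), mcc(cm))
    lr <- likelihood_ratios(big)
    expect_equal(lr$lr_pos, base_lr$lr_pos)
    expect_equal(lr$lr_neg, base_lr$lr_neg)
    expect_lt(diff(lr$lr_pos_ci), diff(base_lr$lr_pos_ci))
    expect_lt(diff(lr$lr_neg_ci), diff(base_lr$lr_neg_ci))
  }
})

test_that("evidence strength grades CI bounds against the Bayesian odds", {
  expect_identical(evidence_strength(3.21, c(2.19, 4.72), "pathogenic"),
                   "supporting")
  expect_identical(evidence_strength(8.27, c(4.34, 15.75), "pathogenic"),
                   "moderate")
  expect_identical(evidence_strength(58.12, c(27.23, 124.03), "pathogenic"),
                   "strong")
  expect_identical(evidence_strength(400, c(351, 500), "pathogenic"),
                   "very_strong")
  expect_identical(evidence_strength(2.5, c(2.079, 3), "pathogenic"), "none")
  expect_identical(evidence_strength(0.42, c(0.37, 0.48), "benign"),
                   "supporting")
  expect_identical(evidence_strength(0.4, c(0.3, 0.49), "benign"), "none")
  # grading is monotone in the bound
  bounds <- seq(0.5, 400, length.out = 60)
  lev <- vapply(bounds, function(b)
    match(evidence_strength(b + 1, c(b, b + 2), "pathogenic"),
          strength_levels), integer(1))
  expect_false(is.unsorted(lev))
})

test_that("metric_set flattens all statistics consistently", {
  ms <- metric_set(confusion(655, 39, 101, 91))
  expect_equal(ms$n_pv, 886)
  expect_equal(ms$ac, 746 / 886)
  expect_equal(ms$lr_pos, (655 / 694) / (101 / 192))
  expect_true(ms$lr_pos_lo < ms$lr_pos && ms$lr_pos < ms$lr_pos_hi)
  degen <- metric_set(confusion(5, 2, 0, 0))
  expect_true(is.na(degen$lr_pos))
})
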