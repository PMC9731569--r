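test_that("threshold grids follow the unit-interval and observed-range rules", {
  g <- build_grid(higher_tool())
  expect_length(g$values, 21L)
  expect_equal(g$values[1], 0)
  expect_equal(g$values[21], 1)
  expect_equal(g$step, 0.05)

  g2 <- build_grid(higher_tool(bounded = FALSE), c(-5, 0, 5))
  expect_length(g2$values, 101L)
  expect_equal(g2$step, 0.1)
  expect_equal(range(g2$values), c(-5, 5))

  expect_error(build_grid(higher_tool(bounded = FALSE), c(2, 2, 2)),
               "distinct")
})

test_that("sweeps are monotone in sensitivity/specificity per direction", {
  set.seed(4)
  scores <- c(rbeta(60, 5, 2), rbeta(40, 2, 5))
  labels <- c(rep("PLP", 60), rep("BLB", 40))
  sw <- sweep_thresholds(higher_tool(), scores, labels)
  expect_identical(nrow(sw), 21L)
  expect_true(all(diff(sw$se) <= 0))
  expect_true(all(diff(sw$sp) >= 0))
  expect_equal(unique(sw$n_pv), 100)

  swl <- sweep_thresholds(lower_tool(), 1 - scores, labels)
  expect_true(all(diff(swl$se) >= 0))
  expect_true(all(diff(swl$sp) <= 0))
})

test_that("missing scores are excluded without imputation", {
  scores <- c(0.1, NA, 0.9, NA)
  labels <- c("BLB", "BLB", "PLP", "PLP")
  sw <- sweep_thresholds(higher_tool(), scores, labels)
  expect_equal(unique(sw$n_pv), 2)
})

test_that("MCC-optimal selection matches a midpoint brute-force oracle", {
  # oracle: evaluate MCC at every midpoint between consecutive distinct
  # scores, independently of the grid machinery
  brute_force_best <- function(scores, labels) {
    s <- sort(unique(scores))
    mids <- (s[-1] + s[-length(s)]) / 2
    mccs <- vapply(mids, function(t) {
      tp <- sum(scores > t & labels == "PLP")
      fn <- sum(scores <= t & labels == "PLP")
      fp <- sum(scores > t & labels == "BLB")
      tn <- sum(scores <= t & labels == "BLB")
      d <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
      if (d == 0) 0 else (tp * tn - fp * fn) / sqrt(d)
    }, numeric(1))
    list(threshold = mids[which.max(mccs)], mcc = max(mccs))
  }
  set.seed(21)
  scores <- c(rbeta(250, 6, 2), rbeta(250, 2, 6))
  labels <- c(rep("PLP", 250), rep("BLB", 250))
  tool <- higher_tool()
  best <- select_mcc_optimal(sweep_thresholds(tool, scores, labels), tool)
  oracle <- brute_force_best(scores, labels)
  expect_lte(abs(best$threshold - oracle$threshold), 0.05)
  expect_lte(oracle$mcc - best$mcc, 0.05)
  expect_gte(best$mcc, 0.5)
})

test_that("selection returns the grid maximum and breaks ties as specified", {
  set.seed(9)
  scores <- c(rbeta(100, 6, 2), rbeta(100, 2, 6))
  labels <- rep(c("PLP", "BLB"), each = 100)
  tool <- higher_tool()
  sw <- sweep_thresholds(tool, scores, labels)
  best <- select_mcc_optimal(sw, tool)
  expect_true(all(best$mcc >= sw$mcc))

  # hand-built tied sweep: equal MCC, second row higher LR+
  tie <- sw[1:2, ]
  tie$mcc <- 0.5
  tie$lr_pos <- c(2, 3)
  expect_equal(select_mcc_optimal(tie, tool)$lr_pos, 3)
  # equal MCC and LR+: stricter (higher for higher_pathogenic) threshold wins
  tie$lr_pos <- 2
  tie$threshold <- c(0.2, 0.4)
  expect_equal(select_mcc_optimal(tie, tool)$threshold, 0.4)
  expect_equal(select_mcc_optimal(tie, lower_tool())$threshold, 0.2)
})

test_that("refining the grid never loses attained MCC", {
  set.seed(33)
  scores <- c(rbeta(150, 6, 2), rbeta(150, 2, 6))
  labels <- rep(c("PLP", "BLB"), each = 150)
  tool <- higher_tool(bounded = FALSE)
  coarse <- build_grid(tool, scores)
  fine <- coarse
  fine$values <- seq(min(scores), max(scores),
                     length.out = 2L * length(coarse$values) - 1L)
  best_c <- select_mcc_optimal(sweep_thresholds(tool, scores, labels, coarse),
                               tool)
  best_f <- select_mcc_optimal(sweep_thresholds(tool, scores, labels, fine),
                               tool)
  expect_gte(best_f$mcc, best_c$mcc - 1e-12)
})

test_that("a planted optimum at 0.5 is recovered within one grid step", {
  co <- balanced_cohort(600, seed = 5)
  sc <- simulate_scores(co, binary_recovery_spec(), seed = 6)
  tool <- higher_tool("sim")
  best <- calibrate_binary(tool, sc[, "sim"], co$expert_class)
  expect_lte(abs(best$threshold - 0.5), 0.05 + 1e-9)
})
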