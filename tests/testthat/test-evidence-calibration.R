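test_that("pair evaluation arithmetic is exact and collapses to binary", {
  set.seed(2)
  scores <- c(rbeta(80, 6, 2), rbeta(80, 2, 6))
  labels <- rep(c("PLP", "BLB"), each = 80)
  tool <- higher_tool()
  pair <- evaluate_pair(tool, scores, labels, 0.3, 0.7)
  expect_equal(pair$pct_correctly_pv,
               100 * pair$correctly_pv / pair$n_pv)
  expect_lte(pair$correctly_pv, pair$n_pv)

  # t_b = t_p: correctly predicted equals binary accuracy
  dich <- evaluate_pair(tool, scores, labels, 0.5, 0.5)
  cm <- confusion_at_threshold(scores, labels, 0.5, tool)
  expect_equal(dich$correctly_pv, cm$tp + cm$tn)
  expect_equal(dich$pct_correctly_pv / 100, basic_metrics(cm)$accuracy)

  expect_error(evaluate_pair(tool, scores, labels, 0.7, 0.3), "stricter")
})

test_that("no-call zone widening is monotone in tp and tn", {
  set.seed(3)
  scores <- c(rbeta(100, 5, 2), rbeta(100, 2, 5))
  labels <- rep(c("PLP", "BLB"), each = 100)
  tool <- higher_tool()
  sw <- sweep_thresholds(tool, scores, labels)
  expect_true(all(diff(sw$tp) <= 0))  # tp non-increasing as t_p rises
  expect_true(all(diff(sw$tn) >= 0))  # tn non-increasing as t_b falls
})

test_that("the pair search recovers a planted (0.3, 0.7) pair", {
  co <- balanced_cohort(800, seed = 101)
  sc <- simulate_scores(co, pair_recovery_spec(), seed = 102)
  tool <- higher_tool("sim")
  # median recovered pair over seeded replicates; a single replicate's
  # feasibility boundary can jitter by one grid step at this sample size
  recovered <- t(vapply(1:15, function(r) {
    co_r <- balanced_cohort(800, seed = 100 + 2 * r)
    sc_r <- simulate_scores(co_r, pair_recovery_spec(), seed = 101 + 2 * r)
    pairs <- search_threshold_pairs(tool, sc_r[, "sim"], co_r$expert_class,
                                    min_strength = "supporting")
    if (nrow(pairs) == 0L) return(c(NA_real_, NA_real_))
    expect_true(all(strength_at_least(pairs$pathogenic_strength, "supporting")))
    expect_true(all(strength_at_least(pairs$benign_strength, "supporting")))
    c(pairs$benign_threshold[1], pairs$pathogenic_threshold[1])
  }, numeric(2)))
  expect_gte(mean(!is.na(recovered[, 1])), 0.7)
  expect_lte(abs(stats::median(recovered[, 1], na.rm = TRUE) - 0.3),
             0.05 + 1e-9)
  expect_lte(abs(stats::median(recovered[, 2], na.rm = TRUE) - 0.7),
             0.05 + 1e-9)
})

test_that("fully overlapping classes admit no supporting pair", {
  set.seed(7)
  scores <- rbeta(200, 2, 2)
  labels <- rep(c("PLP", "BLB"), 100)
  pairs <- search_threshold_pairs(higher_tool(), scores, labels,
                                  min_strength = "supporting")
  expect_identical(nrow(pairs), 0L)
})

test_that("dichotomy is a special case under min_strength = none", {
  set.seed(13)
  scores <- c(rbeta(120, 8, 2), rbeta(120, 2, 8))
  labels <- rep(c("PLP", "BLB"), each = 120)
  tool <- higher_tool()
  best_bin <- select_mcc_optimal(sweep_thresholds(tool, scores, labels), tool)
  pairs <- search_threshold_pairs(tool, scores, labels, min_strength = "none")
  dich <- pairs[pairs$benign_threshold == pairs$pathogenic_threshold, ]
  expect_true(any(abs(dich$pathogenic_threshold - best_bin$threshold) < 1e-9))
})

test_that("fine-tuning is conservative: identity at factor 1, never degrades", {
  co <- balanced_cohort(500, seed = 55)
  sc <- simulate_scores(co, pair_recovery_spec(), seed = 56)
  tool <- higher_tool("sim")
  s <- sc[, "sim"]; lab <- co$expert_class
  grid <- build_grid(tool, s)
  pairs <- search_threshold_pairs(tool, s, lab, grid, "supporting")
  if (nrow(pairs) == 0L)
    pairs <- search_threshold_pairs(tool, s, lab, grid, "none")
  pair <- pairs[1, ]
  expect_identical(finetune_pair(tool, s, lab, pair, grid,
                                 refine_factor = 1L), pair)
  tuned <- finetune_pair(tool, s, lab, pair, grid,
                         min_strength = pair$pathogenic_strength,
                         refine_factor = 10L)
  expect_gte(tuned$correctly_pv, pair$correctly_pv)
  expect_lte(abs(tuned$pathogenic_threshold - pair$pathogenic_threshold),
             grid$step + 1e-9)
  expect_lte(abs(tuned$benign_threshold - pair$benign_threshold),
             grid$step + 1e-9)
})

test_that("subset calibration reports pairs only where the tool is informative", {
  set.seed(77)
  n <- 400
  eff <- rep(c("missense", "synonymous"), each = n / 2)
  cls <- rep(rep(c("PLP", "BLB"), each = n / 4), 2)
  co <- data.frame(
    variant_id = sprintf("v%03d", seq_len(n)),
    gene = "HBB",
    effect_category = eff,
    dual_missense_splicing = FALSE,
    expert_class = cls)
  # informative on missense rows only; pure noise elsewhere
  s <- numeric(n)
  mis <- eff == "missense"
  s[mis & cls == "PLP"] <- rbeta(sum(mis & cls == "PLP"), 8, 2)
  s[mis & cls == "BLB"] <- rbeta(sum(mis & cls == "BLB"), 2, 8)
  s[!mis] <- rbeta(sum(!mis), 2, 2)
  sc <- matrix(s, ncol = 1, dimnames = list(co$variant_id, "sim"))
  subs <- study_subsets()[c("missense", "non_missense")]
  res <- calibrate_subsets(co, sc, list(higher_tool("sim")), subs,
                           refine_factor = 1L)
  expect_true(any(res$subset == "missense" & res$status == "ok"))
  expect_identical(unique(res$status[res$subset == "non_missense"]),
                   "no_pair")

  # single-class subset is skipped with a diagnostic status
  co2 <- co
  co2$expert_class[co2$effect_category == "synonymous"] <- "PLP"
  res2 <- suppressWarnings(
    calibrate_subsets(co2, sc, list(higher_tool("sim")),
                      study_subsets()["non_missense"], refine_factor = 1L))
  expect_identical(res2$status, "single_class")
})

test_that("pair ranking is deterministic for fixed inputs", {
  set.seed(19)
  scores <- c(rbeta(150, 2.05, 1.4), rbeta(150, 1.4, 2.05))
  labels <- rep(c("PLP", "BLB"), each = 150)
  a <- search_threshold_pairs(higher_tool(), scores, labels,
                              min_strength = "none")
  b <- search_threshold_pairs(higher_tool(), scores, labels,
                              min_strength = "none")
  expect_identical(a, b)
})
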