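make_call_fixture <- function() {
  scores <- matrix(c(0.9, 0.8, 0.1, 0.2,
                     0.9, 0.7, 0.2, 0.1,
                     0.1, 0.2, 0.8, 0.9),
                   nrow = 4,
                   dimnames = list(paste0("v", 1:4), c("A", "B", "C")))
  tools <- list(higher_tool("A"), higher_tool("B"), higher_tool("C"))
  list(scores = scores, tools = tools)
}

test_that("call matrices encode binary and trichotomous calls", {
  fx <- make_call_fixture()
  m <- build_call_matrix(fx$scores, fx$tools,
                         list(A = 0.5, B = 0.5, C = 0.5))
  expect_identical(m["v1", "A"], "pathogenic")
  expect_identical(m["v3", "A"], "benign")
  # a threshold pair with a gap produces no_call inside it
  m2 <- build_call_matrix(fx$scores, fx$tools,
                          list(A = c(benign = 0.3, pathogenic = 0.85),
                               B = 0.5, C = 0.5))
  expect_identical(m2["v2", "A"], "no_call")   # 0.8 sits in the gap
  expect_identical(m2["v1", "A"], "pathogenic")
  expect_identical(m2["v3", "A"], "benign")
  # missing scores and missing thresholds
  sc <- fx$scores; sc[, "C"] <- NA
  expect_warning(m3 <- build_call_matrix(sc, fx$tools,
                                         list(A = 0.5, B = 0.5, C = 0.5)),
                 "missing")
  expect_true(all(m3[, "C"] == "missing"))
  expect_error(build_call_matrix(fx$scores, fx$tools, list(Z = 0.5)),
               "absent")
})

test_that("pairwise concordance is symmetric with a unit diagonal", {
  fx <- make_call_fixture()
  m <- build_call_matrix(fx$scores, fx$tools,
                         list(A = 0.5, B = 0.5, C = 0.5))
  pc <- pairwise_concordance(m)
  expect_equal(pc["A", "B"], 1)      # identical call columns
  expect_equal(pc["A", "C"], 0)      # complementary
  expect_equal(diag(pc), c(A = 1, B = 1, C = 1))
  expect_equal(pc, t(pc))
  # concordance over the co-called subset only
  m[1, "B"] <- "missing"
  pc2 <- pairwise_concordance(m)
  expect_equal(pc2["A", "B"], 1)
})

test_that("cluster order is deterministic, complete and groups similar tools", {
  fx <- make_call_fixture()
  m <- build_call_matrix(fx$scores, fx$tools,
                         list(A = 0.5, B = 0.5, C = 0.5))
  pc <- pairwise_concordance(m)
  ord <- cluster_order(pc)
  expect_setequal(ord, c("A", "B", "C"))
  expect_equal(abs(diff(match(c("A", "B"), ord))), 1)  # identical pair adjacent
  expect_identical(cluster_order(pc[c(2, 3, 1), c(2, 3, 1)]), ord)
  expect_identical(cluster_order(pc["A", "A", drop = FALSE]), "A")
})

test_that("block-structured concordance yields contiguous blocks", {
  # two perfectly concordant blocks {A,B} and {C,D}, discordant across
  conc <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  conc[1:2, 1:2] <- 1
  conc[3:4, 3:4] <- 1
  ord <- cluster_order(conc)
  pos <- match(LETTERS[1:4], ord)
  expect_equal(abs(pos[1] - pos[2]), 1)
  expect_equal(abs(pos[3] - pos[4]), 1)
})

test_that("combination concordance requires every tool to assert the class", {
  fx <- make_call_fixture()
  labels <- c("PLP", "PLP", "BLB", "BLB")
  m <- build_call_matrix(fx$scores, fx$tools,
                         list(A = 0.5, B = 0.5, C = 0.5))
  expect_equal(combination_concordance(m, labels, c("A", "B"), "PLP"), 1)
  expect_equal(combination_concordance(m, labels, c("A", "C"), "PLP"), 0)
  # an abstaining tool breaks concordance for every combination it joins
  m2 <- m; m2[, "B"] <- "no_call"
  expect_equal(combination_concordance(m2, labels, c("A", "B"), "PLP"), 0)
  expect_error(combination_concordance(m, labels, character(), "PLP"),
               "at least one")

  # anti-monotone in combination size
  set.seed(18)
  for (r in 1:10) {
    sc <- matrix(runif(60), 20, 3,
                 dimnames = list(paste0("x", 1:20), c("A", "B", "C")))
    lab <- sample(c("PLP", "BLB"), 20, replace = TRUE)
    mm <- build_call_matrix(sc, fx$tools, list(A = 0.5, B = 0.5, C = 0.5))
    two <- combination_concordance(mm, lab, c("A", "B"), "PLP")
    three <- combination_concordance(mm, lab, c("A", "B", "C"), "PLP")
    if (!is.na(two) && !is.na(three)) expect_lte(three, two)
  }
})

test_that("combination ranking is deterministic and sized correctly", {
  fx <- make_call_fixture()
  labels <- c("PLP", "PLP", "BLB", "BLB")
  m <- build_call_matrix(fx$scores, fx$tools,
                         list(A = 0.5, B = 0.5, C = 0.5))
  rk <- rank_tool_combinations(m, labels, "PLP", top_k = 4)
  expect_identical(rk$combination[1], "A+B")
  expect_true(all(rk$size >= 2))
  expect_identical(rk, rank_tool_combinations(m, labels, "PLP", top_k = 4))
})
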