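# shared fixtures: tiny cohorts, tool configs and simulation specs built in code

higher_tool <- function(name = "toolH", inclusive = FALSE, bounded = TRUE,
                        category = "general") {
  tool_config(name, "higher_pathogenic", pathogenic_inclusive = inclusive,
              bounded_unit_interval = bounded, category = category)
}

lower_tool <- function(name = "toolL", inclusive = FALSE, bounded = TRUE) {
  tool_config(name, "lower_pathogenic", pathogenic_inclusive = inclusive,
              bounded_unit_interval = bounded)
}

tiny_cohort <- function() {
  data.frame(
    variant_id = c("c.1A>G", "c.2T>C", "c.3G>A", "c.4C>T", "c.5G>T"),
    gene = c("HBB", "HBB", "HBA2", "HBA1", "HBB"),
    effect_category = c("missense", "synonymous", "splice_donor",
                        "missense", "missense"),
    dual_missense_splicing = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    expert_class = c("PLP", "BLB", "PLP", "VUS", "PLP"))
}

# balanced-class cohort for calibration tests (no VUS)
balanced_cohort <- function(n, seed = 1L) {
  generate_cohort(cohort_spec(
    n_variants = n,
    class_proportions = c(PLP = 0.5, BLB = 0.5, VUS = 0),
    dual_rate = 0,
    seed = seed))
}

# simulation specs matching the planted-truth study conditions
binary_recovery_spec <- function(missing_rate = 0) {
  tool_sim_spec("sim", family = "beta",
                pathogenic_params = c(6, 2), benign_params = c(2, 6),
                missing_rate = missing_rate)
}

pair_recovery_spec <- function() {
  tool_sim_spec("sim", family = "beta",
                pathogenic_params = c(2.05, 1.4), benign_params = c(1.4, 2.05),
                planted_pair = c(0.3, 0.7))
}

expect_one_row <- function(df) expect_identical(nrow(df), 1L)
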