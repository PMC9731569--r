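#' Pipeline run configuration
#'
#' Bundles paths/objects and analysis settings for [run_full_pipeline()].
#' `variants` and `scores` may be file paths (read with [read_variants()] /
#' [read_scores()]) or in-memory objects.
#'
#' @param variants Cohort data.frame or path to variants.tsv.
#' @param scores Score matrix or path to scores.tsv.
#' @param tools List of [tool_config()] objects, or a path to a tools YAML;
#'   default [default_tool_config()].
#' @param out_dir Output directory (created if absent).
#' @param subsets Subset specs to calibrate over; default [study_subsets()].
#' @param min_strength Evidence strength both sides of a pair must reach.
#' @param refine_factor Fine-tuning ratio (1 disables).
#' @param ci_level Confidence level in (0, 1).
#' @param seed Integer seed recorded in the manifest (the analysis itself
#'   is deterministic; the seed matters when the inputs are simulated).
#' @param max_combo_tools Cap on the number of tools entering the
#'   combination-concordance enumeration.
#' @return A `run_config` object.
#' @export
run_config <- function(variants, scores, tools = default_tool_config(),
                       out_dir = NULL, subsets = study_subsets(),
                       min_strength = "supporting", refine_factor = 10L,
                       ci_level = 0.95, seed = 1L, max_combo_tools = 8L) {
  stopifnot(ci_level > 0, ci_level < 1, min_strength %in% strength_levels)
  if (is.character(tools) && length(tools) == 1L)
    tools <- read_tool_config(tools)
  structure(list(variants = variants, scores = scores,
                 tools = as_tool_config_list(tools), out_dir = out_dir,
                 subsets = subsets, min_strength = min_strength,
                 refine_factor = as.integer(refine_factor),
                 ci_level = ci_level, seed = as.integer(seed),
                 max_combo_tools = as.integer(max_combo_tools)),
            class = "run_config")
}

#' Run the full calibration pipeline
#'
#' Stages, in order: descriptive summary of the full cohort; VUS removal;
#' per-tool binary calibration (MCC-optimal thresholds with all metrics);
#' non-overlapping threshold-pair calibration per subset; splicing
#' assessment (when splicing tools are scored); inter-tool concordance at
#' the MCC-optimal thresholds plus combination concordance among the tools
#' whose pairs met the strength requirement on the full set. Every stage's
#' table is returned and, when `config$out_dir` is set, written via
#' [write_reports()] together with a run manifest. The pipeline is a pure
#' function of its inputs and settings: identical configuration yields
#' byte-identical reports.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a named list of result tables
#'   (`summary`, `binary`, `calibration`, `splicing`, `concordance`,
#'   `cluster_order`, `combos`, `manifest`).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (is.character(config$variants))
    read_variants(config$variants) else config$variants
  validate_cohort(cohort)
  scores <- if (is.character(config$scores))
    read_scores(config$scores, config$tools) else config$scores
  orphan <- setdiff(rownames(scores), cohort$variant_id)
  if (length(orphan))
    stop("score matrix contains variant ids absent from the cohort: ",
         paste(utils::head(orphan, 5L), collapse = ", "))

  summary_tbl <- descriptive_summary(cohort)
  message(sprintf("cohort: %d variants (%d P/LP, %d B/LB, %d VUS)",
                  nrow(cohort), sum(cohort$expert_class == "PLP"),
                  sum(cohort$expert_class == "BLB"),
                  sum(cohort$expert_class == "VUS")))

  nonvus <- suppressWarnings(drop_vus(cohort))
  labels <- stats::setNames(nonvus$expert_class, nonvus$variant_id)

  # binary calibration per scored tool
  binary_rows <- list()
  thresholds <- list()
  for (nm in intersect(colnames(scores), names(config$tools))) {
    tool <- config$tools[[nm]]
    s <- scores[match(nonvus$variant_id, rownames(scores)), nm]
    ok <- !is.na(s)
    if (sum(ok) == 0L || length(unique(labels[ok])) < 2L ||
        length(unique(s[ok])) < 2L) next
    best <- calibrate_binary(tool, s[ok], labels[ok],
                             ci_level = config$ci_level)
    attr(best, "sweep") <- NULL
    binary_rows[[nm]] <- best
    thresholds[[nm]] <- best$threshold
  }
  binary_tbl <- if (length(binary_rows)) {
    out <- do.call(rbind, binary_rows); rownames(out) <- NULL; out
  } else data.frame()
  message(sprintf("binary calibration: %d tool(s)", nrow(binary_tbl)))

  calibration_tbl <- calibrate_subsets(cohort, scores, config$tools,
                                       config$subsets, config$min_strength,
                                       config$refine_factor,
                                       config$ci_level)
  message(sprintf("threshold pairs: %d surviving row(s)",
                  sum(calibration_tbl$status == "ok")))

  labelset <- if (any(nonvus$effect_category %in% splicing_categories &
                        nonvus$expert_class == "PLP" &
                        !nonvus$dual_missense_splicing)) {
    suppressWarnings(assemble_splicing_dataset(nonvus))
  } else NULL
  splicing_tbl <- if (!is.null(labelset)) {
    suppressWarnings(
      evaluate_splicing_tools(labelset, scores, config$tools,
                              config$ci_level))
  } else data.frame()
  message(sprintf("splicing assessment: %d tool(s)", nrow(splicing_tbl)))

  concordance <- NULL; order_out <- character(); combos <- data.frame()
  if (length(thresholds) >= 2L) {
    calls <- build_call_matrix(
      scores[match(nonvus$variant_id, rownames(scores)), , drop = FALSE],
      config$tools, thresholds)
    concordance <- pairwise_concordance(calls)
    order_out <- cluster_order(concordance)
    passing <- unique(calibration_tbl$tool[
      calibration_tbl$status == "ok" & calibration_tbl$subset == "all"])
    passing <- intersect(passing, colnames(calls))
    if (length(passing) > config$max_combo_tools)
      passing <- sort(passing)[seq_len(config$max_combo_tools)]
    if (length(passing) >= 2L) {
      combos <- rbind(
        rank_tool_combinations(calls, nonvus$expert_class, "PLP",
                               tools = passing),
        rank_tool_combinations(calls, nonvus$expert_class, "BLB",
                               tools = passing))
    }
  }
  message(sprintf("concordance: %d tool(s) clustered, %d combination row(s)",
                  length(order_out), nrow(combos)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("hbcalib")),
    seed = config$seed,
    ci_level = config$ci_level,
    min_strength = config$min_strength,
    refine_factor = config$refine_factor,
    n_variants = nrow(cohort),
    n_plp = sum(cohort$expert_class == "PLP"),
    n_blb = sum(cohort$expert_class == "BLB"),
    n_vus = sum(cohort$expert_class == "VUS"),
    n_tools_scored = ncol(scores),
    n_tools_binary = nrow(binary_tbl),
    reports = c("summary.tsv", "binary_calibration.tsv", "calibration.tsv",
                "splicing.tsv", "concordance.tsv", "cluster_order.txt",
                "combos.tsv"))

  results <- list(summary = summary_tbl, binary = binary_tbl,
                  calibration = calibration_tbl, splicing = splicing_tbl,
                  concordance = concordance, cluster_order = order_out,
                  combos = combos, manifest = manifest)
  if (!is.null(config$out_dir)) write_reports(results, config$out_dir)
  invisible(results)
}

descriptive_summary <- function(cohort) {
  by_class <- as.data.frame(table(class = cohort$expert_class),
                            stringsAsFactors = FALSE)
  by_class$dimension <- "expert_class"
  names(by_class)[1] <- "level"
  by_gene <- as.data.frame(table(level = cohort$gene),
                           stringsAsFactors = FALSE)
  by_gene$dimension <- "gene"
  by_eff <- as.data.frame(table(level = cohort$effect_category),
                          stringsAsFactors = FALSE)
  by_eff$dimension <- "effect_category"
  out <- rbind(by_class, by_gene, by_eff)
  out$pct <- round(100 * out$Freq / nrow(cohort), 2)
  names(out)[names(out) == "Freq"] <- "n"
  out[, c("dimension", "level", "n", "pct")]
}

#' Write pipeline reports to disk
#'
#' Writes the machine-readable TSVs (full precision) plus the JSON run
#' manifest. Human-readable rounding is left to the caller; every number
#' in the reports is recomputable from the TSVs. Outputs contain no
#' timestamps, so identical results produce byte-identical files.
#'
#' @param results List returned by [run_full_pipeline()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_reports <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  w(results$summary, "summary.tsv")
  w(results$binary, "binary_calibration.tsv")
  w(results$calibration, "calibration.tsv")
  w(results$splicing, "splicing.tsv")
  if (!is.null(results$concordance)) {
    conc <- data.frame(tool = rownames(results$concordance),
                       results$concordance, check.names = FALSE)
    w(conc, "concordance.tsv")
  } else {
    w(data.frame(tool = character()), "concordance.tsv")
  }
  writeLines(results$cluster_order, file.path(out_dir, "cluster_order.txt"))
  w(results$combos, "combos.tsv")
  jsonlite::write_json(results$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Emit a complete simulated input bundle
#'
#' Writes `variants.tsv`, `scores.tsv`, `evidence.tsv` and `truth.json`
#' (the planted simulation parameters) to a directory, for exercising the
#' pipeline end to end without curated data.
#'
#' @param out_dir Output directory.
#' @param spec A [cohort_spec()].
#' @param tool_specs List of [tool_sim_spec()] objects.
#' @return Invisibly, a list with the generated `cohort`, `scores`,
#'   `evidence` and the file paths.
#' @export
simulate_study_inputs <- function(out_dir, spec = cohort_spec(),
                                  tool_specs) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(spec)
  scores <- simulate_scores(cohort, tool_specs, seed = spec$seed + 1L)
  evidence <- generate_evidence_profiles(cohort, seed = spec$seed + 2L)
  write_variants(cohort, file.path(out_dir, "variants.tsv"))
  write_scores(scores, file.path(out_dir, "scores.tsv"))
  utils::write.table(evidence, file.path(out_dir, "evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    seed = spec$seed,
    n_variants = spec$n_variants,
    class_proportions = as.list(spec$class_proportions),
    tools = lapply(tool_specs, function(ts) {
      list(tool = ts$tool, family = ts$family, direction = ts$direction,
           pathogenic_params = ts$pathogenic_params,
           benign_params = ts$benign_params,
           missing_rate = ts$missing_rate,
           planted_pair = ts$planted_pair)
    }))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, scores = scores, evidence = evidence,
                 paths = file.path(out_dir, c("variants.tsv", "scores.tsv",
                                              "evidence.tsv", "truth.json"))))
}
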