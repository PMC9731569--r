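#' Sequence-ontology derived effect categories
#'
#' The closed vocabulary of variant effect categories used throughout the
#' package. Unknown strings in input files are rejected rather than mapped
#' to a catch-all, so curation errors surface at load time.
#'
#' @format Character vector of category names.
#' @export
effect_categories <- c(
  "missense", "synonymous", "frameshift", "initiation_codon", "inframe_indel",
  "splice_acceptor", "splice_donor", "splice_region", "cryptic_splice",
  "stop_lost", "stop_gained",
  "promoter", "five_prime_utr", "three_prime_utr", "polyadenylation"
)

#' Effect categories counted as splicing
#' @keywords internal
splicing_categories <- c("splice_acceptor", "splice_donor",
                         "splice_region", "cryptic_splice")

# Null variant classes: complete loss-of-function categories for which the
# curated globin dataset contains no benign representatives.
null_categories <- c("frameshift", "stop_gained", "splice_acceptor",
                     "splice_donor", "initiation_codon")

pathogenicity_classes <- c("PLP", "BLB", "VUS")
globin_genes <- c("HBA1", "HBA2", "HBB")

phenotype_columns <- c("hb_group", "thal_allele_phenotype", "o2_affinity",
                       "stability", "mechanism")

validate_cohort <- function(cohort) {
  required <- c("variant_id", "gene", "effect_category",
                "dual_missense_splicing", "expert_class")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  dup <- cohort$variant_id[duplicated(cohort$variant_id)]
  if (length(dup))
    stop("duplicate variant_id in cohort: ",
         paste(unique(dup), collapse = ", "))
  bad_gene <- setdiff(unique(cohort$gene), globin_genes)
  if (length(bad_gene))
    stop("unknown gene(s): ", paste(bad_gene, collapse = ", "))
  bad_eff <- setdiff(unique(cohort$effect_category), effect_categories)
  if (length(bad_eff))
    stop("unknown effect_category value(s): ", paste(bad_eff, collapse = ", "))
  bad_cls <- setdiff(unique(cohort$expert_class), pathogenicity_classes)
  if (length(bad_cls))
    stop("unknown expert_class value(s): ", paste(bad_cls, collapse = ", "))
  bad_dual <- cohort$dual_missense_splicing &
    !(cohort$effect_category %in% c("missense", splicing_categories))
  if (any(bad_dual))
    stop("dual_missense_splicing set on non-missense/non-splicing variant(s): ",
         paste(cohort$variant_id[bad_dual], collapse = ", "))
  invisible(cohort)
}

#' Read an annotated variant cohort
#'
#' Reads a tab-separated cohort file with one row per SNV. Required columns:
#' `variant_id` (HGVS-style string, unique), `gene` (HBA1/HBA2/HBB),
#' `effect_category` (one of [effect_categories]), `expert_class`
#' (PLP/BLB/VUS). `dual_missense_splicing` (logical, default FALSE) and the
#' phenotype columns (`hb_group`, `thal_allele_phenotype`, `o2_affinity`,
#' `stability`, `mechanism`) are optional. `""` and `"NA"` parse as missing.
#' VUS rows are retained; remove them at the analysis boundary with
#' [drop_vus()].
#'
#' @param path Path to a TSV file with a header row.
#' @return A data.frame, one row per variant, validated against the cohort
#'   invariants.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("variant file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          na.strings = c("", "NA"), check.names = FALSE,
                          quote = "", comment.char = "")
  required <- c("variant_id", "gene", "effect_category", "expert_class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("variant file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if ("dual_missense_splicing" %in% names(df)) {
    dual <- df$dual_missense_splicing
    df$dual_missense_splicing <- !is.na(dual) &
      tolower(dual) %in% c("true", "t", "1", "yes")
  } else {
    df$dual_missense_splicing <- FALSE
  }
  keep <- c("variant_id", "gene", "effect_category", "dual_missense_splicing",
            "expert_class", intersect(phenotype_columns, names(df)))
  df <- df[, keep, drop = FALSE]
  validate_cohort(df)
  df
}

#' Write a cohort to TSV
#'
#' Inverse of [read_variants()]: missing phenotype values are written as
#' empty cells so a round trip reproduces the cohort exactly.
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort
  out$dual_missense_splicing <- ifelse(out$dual_missense_splicing, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a predictor score matrix
#'
#' Reads a dbNSFP-style tab-separated matrix: a `variant_id` column plus one
#' numeric column per tool. Empty cells and `NA` become missing values; no
#' imputation is ever performed. Every column must correspond to a
#' configured tool and every non-empty cell must parse as a number.
#'
#' @param path Path to a TSV file.
#' @param tools List of [tool_config()] objects (or the result of
#'   [default_tool_config()]); score columns are checked against their names.
#' @return Numeric matrix with variant ids as row names and tools as
#'   column names; missing scores are `NA`.
#' @export
read_scores <- function(path, tools = default_tool_config()) {
  if (!file.exists(path)) stop("score file not found: ", path)
  tools <- as_tool_config_list(tools)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          na.strings = c("", "NA"), check.names = FALSE,
                          quote = "", comment.char = "")
  if (!"variant_id" %in% names(df))
    stop("score file lacks a variant_id column")
  tool_cols <- setdiff(names(df), "variant_id")
  unknown <- setdiff(tool_cols, names(tools))
  if (length(unknown))
    stop("score columns not present in the tool configuration: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(df$variant_id))
    stop("duplicate variant_id in score file: ",
         paste(unique(df$variant_id[duplicated(df$variant_id)]), collapse = ", "))
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = length(tool_cols),
                dimnames = list(df$variant_id, tool_cols))
  for (col in tool_cols) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric score for variant '%s', tool '%s': '%s'",
                   df$variant_id[bad[1]], col, raw[bad[1]]))
    mat[, col] <- num
  }
  mat
}

#' Write a score matrix to TSV
#'
#' Missing cells are written empty, so [read_scores()] of the output
#' reproduces the matrix including its missingness pattern.
#'
#' @param scores Numeric matrix with variant row names and tool column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(variant_id = rownames(scores), check.names = FALSE)
  for (col in colnames(scores)) {
    v <- scores[, col]
    df[[col]] <- ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE,
                                             scientific = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Subset specifications
#'
#' A subset specification names a predicate over variant records. The five
#' study subsets (missense-only, non-missense, and the three genes) are
#' available from [study_subsets()].
#'
#' @param name Subset name.
#' @param predicate Function taking a cohort data.frame and returning a
#'   logical vector.
#' @return A `subset_spec` object.
#' @export
subset_spec <- function(name, predicate) {
  stopifnot(is.character(name), length(name) == 1L, is.function(predicate))
  structure(list(name = name, predicate = predicate), class = "subset_spec")
}

#' The five study subsets
#'
#' `all` (identity), `missense` (missense effect category), `non_missense`
#' (its complement), and one subset per globin gene.
#'
#' @return Named list of [subset_spec()] objects.
#' @export
study_subsets <- function() {
  specs <- list(
    subset_spec("all", function(df) rep(TRUE, nrow(df))),
    subset_spec("missense", function(df) df$effect_category == "missense"),
    subset_spec("non_missense", function(df) df$effect_category != "missense"),
    subset_spec("HBB", function(df) df$gene == "HBB"),
    subset_spec("HBA2", function(df) df$gene == "HBA2"),
    subset_spec("HBA1", function(df) df$gene == "HBA1")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Filter a cohort by a subset specification
#'
#' @param cohort Cohort data.frame.
#' @param subset A [subset_spec()] object.
#' @return The matching rows, order preserved; an empty result is legal.
#' @export
filter_subset <- function(cohort, subset) {
  stopifnot(inherits(subset, "subset_spec"))
  keep <- subset$predicate(cohort)
  stopifnot(is.logical(keep), length(keep) == nrow(cohort))
  cohort[which(keep), , drop = FALSE]
}

#' Remove variants of uncertain significance
#'
#' Restricts a cohort to its definitively annotated variants (P/LP and
#' B/LB), the analysis set for every calibration step. Warns when the
#' result contains a single class, since downstream confusion-matrix
#' statistics then degenerate.
#'
#' @param cohort Cohort data.frame.
#' @return The non-VUS rows, with attributes `n_plp` and `n_blb`.
#' @export
drop_vus <- function(cohort) {
  out <- cohort[cohort$expert_class != "VUS", , drop = FALSE]
  n_plp <- sum(out$expert_class == "PLP")
  n_blb <- sum(out$expert_class == "BLB")
  if (nrow(out) > 0L && (n_plp == 0L || n_blb == 0L))
    warning("cohort contains a single pathogenicity class after removing VUS; ",
            "downstream metrics will be degenerate")
  if (nrow(out) == 0L)
    warning("cohort is empty after removing VUS")
  attr(out, "n_plp") <- n_plp
  attr(out, "n_blb") <- n_blb
  out
}
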