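# run code under a fixed seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Specification of a synthetic globin SNV cohort
#'
#' The defaults reproduce the composition of the curated globin SNV
#' dataset: pathogenicity classes 51.1% P/LP, 11.9% B/LB, 36.9% VUS
#' (832/194/601 of 1627), genes 63.5% HBB, 21.5% HBA2, 15% HBA1, and 59%
#' missense variants with the remaining mass spread uniformly over the
#' other effect categories.
#'
#' @param n_variants Number of variants to generate.
#' @param class_proportions Named numeric simplex over `PLP`, `BLB`, `VUS`.
#' @param gene_proportions Named numeric simplex over `HBB`, `HBA2`, `HBA1`.
#' @param effect_mix Named numeric simplex over [effect_categories].
#' @param dual_rate Probability that an eligible (missense or splicing)
#'   variant carries the dual missense+splicing curation flag.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_variants = 1627L,
                        class_proportions = c(PLP = 832, BLB = 194,
                                              VUS = 601) / 1627,
                        gene_proportions = c(HBB = 1033, HBA2 = 350,
                                             HBA1 = 244) / 1627,
                        effect_mix = default_effect_mix(),
                        dual_rate = 0.02,
                        seed = 1L) {
  stopifnot(n_variants >= 1L,
            setequal(names(class_proportions), pathogenicity_classes),
            setequal(names(gene_proportions), globin_genes),
            all(names(effect_mix) %in% effect_categories),
            dual_rate >= 0, dual_rate < 1)
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (abs(sum(gene_proportions) - 1) > 1e-9)
    stop("gene proportions must sum to 1")
  if (abs(sum(effect_mix) - 1) > 1e-9)
    stop("effect mix must sum to 1")
  structure(list(n_variants = as.integer(n_variants),
                 class_proportions = class_proportions,
                 gene_proportions = gene_proportions,
                 effect_mix = effect_mix,
                 dual_rate = dual_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default effect-category mix (59% missense, remainder uniform)
#' @return Named numeric simplex over [effect_categories].
#' @export
default_effect_mix <- function() {
  mix <- stats::setNames(rep((1 - 0.59) / (length(effect_categories) - 1L),
                             length(effect_categories)),
                         effect_categories)
  mix["missense"] <- 0.59
  mix
}

#' Generate a synthetic annotated cohort
#'
#' Draws pathogenicity class, gene and effect category as independent
#' multinomials, then enforces the structural property of the
#' curated dataset that no benign/likely benign variant is a null variant
#' (frameshift, stop gained, canonical splice acceptor/donor, initiation
#' codon): B/LB rows landing on a null category are re-drawn from the
#' non-null categories with renormalised weights. Dual missense+splicing
#' flags are assigned at `dual_rate` among eligible rows.
#'
#' @param spec A [cohort_spec()].
#' @return A validated cohort data.frame ([read_variants()] schema).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_variants
    cls <- sample(names(spec$class_proportions), n, replace = TRUE,
                  prob = spec$class_proportions)
    gene <- sample(names(spec$gene_proportions), n, replace = TRUE,
                   prob = spec$gene_proportions)
    eff <- sample(names(spec$effect_mix), n, replace = TRUE,
                  prob = spec$effect_mix)
    redraw <- cls == "BLB" & eff %in% null_categories
    if (any(redraw)) {
      ok_cats <- setdiff(names(spec$effect_mix), null_categories)
      w <- spec$effect_mix[ok_cats]
      eff[redraw] <- sample(ok_cats, sum(redraw), replace = TRUE,
                            prob = w / sum(w))
    }
    eligible <- eff %in% c("missense", splicing_categories)
    dual <- eligible & stats::runif(n) < spec$dual_rate
    cohort <- data.frame(
      variant_id = sprintf("snv_%05d", seq_len(n)),
      gene = gene,
      effect_category = eff,
      dual_missense_splicing = dual,
      expert_class = cls)
    validate_cohort(cohort)
    cohort
  })
}

#' Specification of one simulated predictor
#'
#' Class-conditional score distributions: beta for unit-interval tools,
#' gaussian otherwise. VUS variants draw from a mixture of the two class
#' distributions. An optional `planted_pair` records the (benign,
#' pathogenic) thresholds the parameters were chosen around, for
#' recovery tests.
#'
#' @param tool Tool name.
#' @param direction Pathogenic direction (see [tool_config()]).
#' @param family `"beta"` or `"gaussian"`.
#' @param pathogenic_params,benign_params Length-2 numeric: `shape1, shape2`
#'   for beta, `mean, sd` for gaussian.
#' @param vus_mixture_weight Probability a VUS score is drawn from the
#'   pathogenic component (default 0.5).
#' @param missing_rate Per-variant probability of a missing score.
#' @param planted_pair Optional numeric `c(benign, pathogenic)` thresholds.
#' @return A `tool_sim_spec` object; its `config` element is the matching
#'   [tool_config()].
#' @export
tool_sim_spec <- function(tool, direction = "higher_pathogenic",
                          family = c("beta", "gaussian"),
                          pathogenic_params, benign_params,
                          vus_mixture_weight = 0.5, missing_rate = 0,
                          planted_pair = NULL) {
  family <- match.arg(family)
  stopifnot(length(pathogenic_params) == 2L, length(benign_params) == 2L,
            vus_mixture_weight >= 0, vus_mixture_weight <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(planted_pair)) stopifnot(length(planted_pair) == 2L)
  structure(list(tool = tool, direction = direction, family = family,
                 pathogenic_params = pathogenic_params,
                 benign_params = benign_params,
                 vus_mixture_weight = vus_mixture_weight,
                 missing_rate = missing_rate,
                 planted_pair = planted_pair,
                 config = tool_config(tool, direction,
                                      pathogenic_inclusive = FALSE,
                                      bounded_unit_interval = family == "beta",
                                      category = "general")),
            class = "tool_sim_spec")
}

draw_scores <- function(spec, n, component) {
  p <- if (component == "pathogenic") spec$pathogenic_params else spec$benign_params
  switch(spec$family,
         beta = stats::rbeta(n, p[1], p[2]),
         gaussian = stats::rnorm(n, p[1], p[2]))
}

#' Simulate a predictor score matrix for a cohort
#'
#' Per tool, each variant's score is drawn from the class-conditional
#' distribution of its expert class; VUS draw from the stated mixture.
#' Missingness is independent Bernoulli per tool. Fully deterministic
#' given the seed.
#'
#' @param cohort Cohort data.frame.
#' @param specs List of [tool_sim_spec()] objects.
#' @param seed Integer seed.
#' @return Numeric matrix (variants x tools) with `NA` for missing.
#' @export
simulate_scores <- function(cohort, specs, seed = 1L) {
  if (inherits(specs, "tool_sim_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "tool_sim_spec")))
  names(specs) <- vapply(specs, `[[`, character(1), "tool")
  with_seed(seed, {
    n <- nrow(cohort)
    mat <- matrix(NA_real_, n, length(specs),
                  dimnames = list(cohort$variant_id, names(specs)))
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      cls <- cohort$expert_class
      s <- numeric(n)
      is_p <- cls == "PLP"; is_b <- cls == "BLB"; is_v <- cls == "VUS"
      s[is_p] <- draw_scores(sp, sum(is_p), "pathogenic")
      s[is_b] <- draw_scores(sp, sum(is_b), "benign")
      if (any(is_v)) {
        from_p <- stats::runif(sum(is_v)) < sp$vus_mixture_weight
        v <- numeric(sum(is_v))
        v[from_p] <- draw_scores(sp, sum(from_p), "pathogenic")
        v[!from_p] <- draw_scores(sp, sum(!from_p), "benign")
        s[is_v] <- v
      }
      if (sp$missing_rate > 0)
        s[stats::runif(n) < sp$missing_rate] <- NA_real_
      mat[, nm] <- s
    }
    mat
  })
}

#' Generate evidence profiles consistent with each record's class
#'
#' Produces curation-style evidence rows such that [classify_evidence()]
#' reproduces the generating class exactly for non-VUS records: P/LP rows
#' receive a pathogenic observation (heterozygote abnormality or disease
#' in trans/homozygous), B/LB rows at least three benign heterozygous
#' occurrences or a benign-in-trans observation, and VUS rows
#' non-definitive profiles (0-2 benign occurrences, no flags).
#'
#' @param cohort Cohort data.frame.
#' @param seed Integer seed.
#' @return Data frame: `variant_id` plus the [classify_evidence()] fields.
#' @export
generate_evidence_profiles <- function(cohort, seed = 1L) {
  with_seed(seed, {
    n <- nrow(cohort)
    prof <- data.frame(
      variant_id = cohort$variant_id,
      het_abnormal_or_dominant = FALSE,
      disease_in_trans_or_homozygous = FALSE,
      benign_het_occurrences = 0L,
      benign_in_trans = FALSE,
      conflicting_evidence = FALSE,
      unpublished_direct_submission = FALSE)
    is_p <- cohort$expert_class == "PLP"
    is_b <- cohort$expert_class == "BLB"
    is_v <- cohort$expert_class == "VUS"
    het <- stats::runif(n) < 0.5
    prof$het_abnormal_or_dominant[is_p & het] <- TRUE
    prof$disease_in_trans_or_homozygous[is_p & !het] <- TRUE
    via_count <- stats::runif(n) < 0.7
    prof$benign_het_occurrences[is_b & via_count] <-
      sample(3:8, sum(is_b & via_count), replace = TRUE)
    prof$benign_in_trans[is_b & !via_count] <- TRUE
    prof$benign_het_occurrences[is_v] <-
      sample(0:2, sum(is_v), replace = TRUE)
    prof
  })
}
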