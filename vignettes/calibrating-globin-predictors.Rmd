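---
title: "Calibrating in silico predictors for globin gene variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating in silico predictors for globin gene variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbcalib)
```

## The problem

Haemoglobinopathies — the thalassaemias and the structural haemoglobin
disorders — are caused by variants in the globin genes *HBA1*, *HBA2* and
*HBB*. Under the ACMG/AMP variant-interpretation framework, in silico
pathogenicity predictors contribute computational evidence through the PP3
(pathogenic) and BP4 (benign) criteria. Predictors ship with genome-wide
default thresholds, but their behaviour is locus-specific: a threshold that
performs well across the exome can be badly miscalibrated on a short,
intensely studied gene cluster. hbcalib calibrates predictor thresholds
against an expert-annotated cohort of globin single nucleotide variants and
expresses the result in the currency the Bayesian adaptation of the
ACMG/AMP framework understands: likelihood ratios and evidence strengths.

## The evaluation model

Every calibration starts from a confusion matrix at a decision threshold
$t$. With `TP` the correctly predicted pathogenic/likely pathogenic (P/LP)
variants, `TN` the correctly predicted benign/likely benign (B/LB), and
`FP`/`FN` their complements:

* sensitivity $Se = TP/(TP+FN)$, specificity $Sp = TN/(FP+TN)$, accuracy
  $(TP+TN)/n$;
* Matthews correlation coefficient
  $MCC = (TP\cdot TN - FP\cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$,
  with the conventional value 0 when the radicand vanishes;
* likelihood ratios $LR^+ = Se/(1-Sp)$ and $LR^- = (1-Se)/Sp$, with
  log-method confidence intervals:
  $\mathrm{var}(\ln LR^+) = 1/TP - 1/(TP+FN) + 1/FP - 1/(FP+TN)$ and
  symmetrically for $LR^-$, using the exact normal quantile
  (`qnorm(0.975)` = 1.959964 at the default 95% level, not 1.96). The
  exact quantile matters: the published benchmark intervals only
  reproduce to the printed two decimals with it.

Evidence strengths follow the Bayesian framework's odds of pathogenicity:
supporting 2.08, moderate 4.33, strong 18.7, very strong 350. Grading is
deliberately conservative: the pathogenic side is graded on the *lower*
bound of the $LR^+$ interval (inclusive), the benign side on the *upper*
bound of the $LR^-$ interval against the reciprocal odds ($1/2.08 \approx
0.48$ for supporting). A point estimate that clears the bar while its
interval does not earns nothing.

### Zero cells

$LR^+$ is infinite when $FP = 0$ and zero when $TP = 0$ (symmetrically for
$LR^-$ with $TN$/$FN$). For exactly those tables, `likelihood_ratios()`
adds a 0.5 continuity correction to all four cells for the affected ratio
and flags the result (`corrected_pos`/`corrected_neg`). Well-populated
tables are never touched, so the benchmark statistics are reproduced
exactly.

## Binary calibration

`sweep_thresholds()` varies the decision threshold over a grid and
computes the full metric set at each step; `select_mcc_optimal()` picks
the MCC-maximising row. Two grid policies exist:

* tools scoring on the unit interval use the canonical grid
  $0, 0.05, \ldots, 1$ (21 values);
* unbounded tools use 100 equal steps spanning the observed score range
  (101 values). The comparable published analysis used "custom ranges" for
  such tools without stating them; a data-driven equal-step grid keeps the
  resolution comparable to the unit-interval grid at bounded cost, and
  exact replication of unbounded-tool thresholds is accordingly not
  promised.

MCC ties are broken by the higher $LR^+$ point estimate, then by the
stricter (more pathogenic-conservative) threshold — the study's primary
axis is confidence in pathogenic prediction. Degenerate grid endpoints
(all-positive or all-negative calling) are kept with sentinel metrics
rather than dropped; a near-degenerate selection is informative in itself,
as the fitCons-style pattern ($Se = 1$, $Sp \approx 0.01$) shows.

Each tool's comparison semantics come from its `tool_config()`: direction
of pathogenicity (FATHMM, SIFT, LRT and PROVEAN call *low* scores
pathogenic), comparator inclusivity (BayesDel's published comparator is
`>=`, CADD's is `>`), and score boundedness. The shipped
`default_tool_config()` transcribes the published comparators for all 31
tools and is overridable via YAML.

## Trichotomous (evidence) calibration

A single threshold rarely reaches even supporting strength on both sides.
The trichotomous approach uses a non-overlapping pair $(t_b, t_p)$: scores
beyond $t_p$ in the pathogenic direction receive pathogenic evidence,
scores at or below $t_b$ benign evidence, and the zone between is a
no-call. `search_threshold_pairs()` enumerates all ordered grid pairs,
computes the pathogenic side's $LR^+$ interval from the 2×2 at $t_p$ and
the benign side's $LR^-$ interval at $t_b$, filters pairs where both sides
reach the requested strength on their CI bounds, and ranks survivors by
the number of correctly predicted variants ($TP(t_p) + TN(t_b)$). The
percentage denominator is *all* variants the tool scores, so no-calls
count against a pair — a pair that abstains on half the cohort must earn
it. Ranking ties break by combined evidence ($LR^+/LR^-$), then by the
narrower no-call zone. An empty result is a legal, reportable outcome;
whole subsets can admit no pair.

`finetune_pair()` re-searches a local grid at one tenth (by default) of
the coarse step around each selected threshold, never degrading the
correctly-predicted count or dropping below the strength filter.
`calibrate_subsets()` runs the whole procedure per tool across the study
subsets (all, missense, non-missense, per-gene) and reports both the best
pair at the requested strength and, where attainable, the best pair at the
highest pathogenic tier. Benign tiers above supporting are computed but
flagged (`benign_extrapolated`): the published evidence framework was only
ever exercised at benign supporting.

## Splicing assessment

The splicing label set treats as positives the P/LP variants with a
splicing effect category (acceptor, donor, splice region, cryptic site)
and as negatives every other non-VUS variant; variants curated as both
missense and splicing are excluded from both sides because their
mechanism is ambiguous. SpliceAI's per-variant score is the maximum of its
four delta scores. MaxEntScan uses a dual rule on the reference and
alternative site scores: `Diff` $= |ref - alt|$ and `Per` $= 100\,|ref -
alt|/|ref|$, calling a variant splice-disrupting when both exceed their
thresholds. The percentage denominator is the *reference* score magnitude
— "percentage of change between reference and alternative" is read as
change relative to the reference; this is an assumption and is documented
as such. When the reference score is exactly zero the call falls back to
`Diff` alone and is flagged. Because so few benign variants sit in
splicing regions, results with fewer than two scored negatives, or with
five or fewer of each of TN/FP/FN, carry `reliable = FALSE`.

## Concordance

`build_call_matrix()` converts scores into categorical calls (binary or
trichotomous), `pairwise_concordance()` measures agreement over variants
where both tools make definite calls, and `cluster_order()` orders tools
by complete-linkage clustering on $1 - $ concordance with name-sorted,
deterministic leaves (no linkage was published; complete linkage is the
conservative choice for block recovery). `combination_concordance()`
scores tool combinations against the expert annotation: every tool in the
combination must assert the matching class, so abstentions and missing
scores break concordance. Concordance is anti-monotone in combination
size by construction.

## The synthetic cohort generator

`generate_cohort()` emulates the curated dataset's composition: classes
51.1% P/LP, 11.9% B/LB, 36.9% VUS (832/194/601 of 1627), genes 63.5%
*HBB*, 21.5% *HBA2*, 15% *HBA1* (using the per-class gene counts, which
sum to 244 for *HBA1*), and 59% missense with the remainder uniform over
the other effect categories. One structural property of the curated data
is enforced, not just sampled: no B/LB null variant (frameshift, stop
gained, canonical splice, initiation codon) is ever generated, mirroring
the loss-of-function disease mechanism. `simulate_scores()` draws
class-conditional scores — beta distributions for unit-interval tools,
gaussians otherwise — with per-tool Bernoulli missingness; VUS scores come
from a 50/50 mixture of the class components by default (no VUS score
model exists to copy; the mixture is only used for display-path testing).
All generation is seed-deterministic and leaves the caller's RNG state
untouched.

What the generator does *not* emulate: sequence context, mutational
spectra, and realistic inter-tool correlation (meta-predictors share
features with their inputs). Concordance tests on synthetic data
therefore probe the mechanics of the computation, not empirical
concordance levels in real cohorts.

### Planted-truth test conditions

Two fixed simulation designs back the recovery tests, both chosen by
population-level calculation before any test was run:

* *Binary*: balanced classes, pathogenic $\sim$ Beta(6,2), benign $\sim$
  Beta(2,6) (population AUC 0.985). By symmetry the population MCC
  optimum is 0.5; the test requires recovery within two grid steps in at
  least 95 of 100 seeded replicates at $n$ between 500 and 1000.
* *Trichotomous*: balanced classes at $n = 800$, pathogenic $\sim$
  Beta(2.05, 1.4), benign $\sim$ Beta(1.4, 2.05). The population-optimal
  supporting-strength pair on the 0.05 grid is exactly (0.30, 0.70).
  At this sample size the feasibility boundary — where the $LR$
  confidence bound crosses the supporting odds — jitters by one grid step
  between replicates for any smooth class-conditional design, so a single
  replicate's recovered pair is one grid step wide of the target roughly
  half the time. The recovery tests therefore assert the *median*
  recovered pair over seeded replicates (within one grid step of the
  planted values) together with a majority find-rate, which is the
  property the method actually possesses.

## Numerical and degenerate-input choices

* Undefined metrics are `NA` sentinels, never zeros: a zero margin makes
  the corresponding rate undefined, and a pair of tools with no co-called
  variants has undefined concordance (imputed as full discordance only
  inside the clustering step, which needs a complete matrix).
* MCC's zero-denominator convention is 0, consistent with "random
  prediction".
* Reports round to two decimals for human consumption; machine outputs
  (TSV/JSON) carry full precision, and every reported number is
  recomputable from the machine outputs.
* The pipeline writes no timestamps, so identical inputs and settings
  produce byte-identical report bundles.

## Problem sizes in the shipped tests

The test suite exercises cohorts of 200–10 000 variants: composition
checks at $n = 10^4$ (three binomial standard errors), recovery tests at
$n$ = 500–1000 with 100 (binary) and 60 (trichotomous) replicates, and
pipeline runs at $n$ = 250–400 with two simulated tools. These sizes hold
the full suite to well under a minute of simulation work while keeping
every statistical bound comfortably powered.

## Known limitations

* Unbounded-tool grids are data-driven; published thresholds obtained
  with unstated custom grids will be matched only to grid resolution.
* The benign-in-trans criterion is a boolean; how many such observations
  should be required is not specified in the source criteria and is not
  guessed here.
* The Delphi merge implements only the mechanical rules: agreement wins,
  disagreement becomes VUS with a review flag. The human discussion path
  is represented by an override column the pipeline accepts but never
  generates.
* No ROC/AUC machinery, posterior-probability calibration, or
  multi-tool evidence combination is provided; the framework here is
  interval likelihood ratios, matching the calibration study design.
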