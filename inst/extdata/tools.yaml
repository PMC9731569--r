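# Per-tool comparison semantics for the globin-gene predictor evaluation.
# direction: which end of the score scale is pathogenic.
# pathogenic_inclusive: whether the threshold value itself is a pathogenic call
#   (a >= / <= comparator); follows each tool's published decision comparator.
# bounded_unit_interval: scores confined to [0,1] (fixes the 0.05 threshold grid).
BayesDel_addAF:
  direction: higher_pathogenic
  pathogenic_inclusive: true
  bounded_unit_interval: false
  category: general
CADD:
  direction: higher_pathogenic
  bounded_unit_interval: false
  category: general
ClinPred:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: general
Condel:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: general
DANN:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: general
Eigen-PC:
  direction: higher_pathogenic
  bounded_unit_interval: false
  category: general
FATHMM:
  direction: lower_pathogenic
  pathogenic_inclusive: true
  bounded_unit_interval: false
  category: general
fathmm-MKL:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: general
GERP++:
  direction: higher_pathogenic
  bounded_unit_interval: false
  category: conservation
integrated_fitCons:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: general
LIST-S2:
  direction: higher_pathogenic
  pathogenic_inclusive: true
  bounded_unit_interval: true
  category: general
LRT:
  direction: lower_pathogenic
  bounded_unit_interval: true
  category: general
MetaLR_score:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: general
MetaSVM_score:
  direction: higher_pathogenic
  bounded_unit_interval: false
  category: general
MutationAssessor:
  direction: higher_pathogenic
  bounded_unit_interval: false
  category: general
MutationTaster:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: general
MutPred:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: general
phastCons17way:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: conservation
phastCons30way:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: conservation
phyloP100way:
  direction: higher_pathogenic
  bounded_unit_interval: false
  category: conservation
phyloP30way:
  direction: higher_pathogenic
  bounded_unit_interval: false
  category: conservation
PolyPhen-2:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: general
PROVEAN:
  direction: lower_pathogenic
  pathogenic_inclusive: true
  bounded_unit_interval: false
  category: general
REVEL:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: general
SIFT:
  direction: lower_pathogenic
  bounded_unit_interval: true
  category: general
SiPhy_29way:
  direction: higher_pathogenic
  bounded_unit_interval: false
  category: conservation
VEST4:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: general
ada:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: splicing
rf:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: splicing
SpliceAI:
  direction: higher_pathogenic
  bounded_unit_interval: true
  category: splicing
MaxEntScan:
  direction: higher_pathogenic
  bounded_unit_interval: false
  category: splicing
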