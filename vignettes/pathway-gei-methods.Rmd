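---
title: "Methods: logic-regression GEI analysis on a candidate gene pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: logic-regression GEI analysis on a candidate gene pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`pathgei` tests gene-environment interactions (GEIs) on a candidate
pathway in three steps, trading single-SNP resolution for gene- and
pathway-level Boolean summaries that are then crossed with exposures.

**Genotype coding.**  Each SNP contributes two binary indicators: dominant
(at least one minor allele) and recessive (two minor alleles).  The minor
allele is declared in the pathway configuration, never re-estimated from
the sample, so leaf labels are stable across datasets.  Indicator coding —
rather than an additive 0/1/2 count — lets a Boolean tree express dominant,
recessive and compound genotype profiles directly, which is also what makes
the fitted trees readable as genotype rules.

**Step 1: gene-specific trees.**  For gene $g$ with indicator columns
$x_{g}$, logic regression fits

$$\mathrm{logit}\,P(\text{case}) = \beta_0 + \beta_1 T(x_g)$$

for the case-control endpoint, or an exponential survival model
$\lambda_i = \exp(\beta_0 + \beta_1 T(x_{g,i}))$ on cases only for the
survival endpoint, where $T$ ranges over AND/OR trees with possibly
negated leaves.  The likelihood is maximised exactly for any candidate
tree (see *Numerical choices*), and tree space is searched by simulated
annealing.  Model size — number of trees and total leaf budget — is chosen
by stratified K-fold cross-validation; the selected model's best tree is
the gene-specific tree (GST).  Every GST carries its De Morgan complement
(swap AND/OR, negate leaves), which evaluates to its pointwise negation:
both genotype profiles of a gene are available downstream.

**Step 2: pathway trees.**  The identical machinery runs with the 0/1 GST
columns as leaves.  The fitted pathway trees are *adjustment covariates*
in Step 3: they absorb the pathway's aggregate genetic main effect so that
interaction terms are tested on top of it, not instead of it.

**Step 3: GEI models.**  The pathway is partitioned into sub-pathways
(nine in the shipped configuration).  For each sub-pathway, every GST and
every complement is crossed with every non-reference level of the three
exposures (smoking: <20 / ≥20 pack-years vs never; alcohol: heavy vs
none-to-moderate; protein: high vs low animal/vegetable ratio).  The risk
model is logistic:

$$\mathrm{logit}\,P(\text{case}) = \beta_0 + \sum_g \beta_g T_g
  + \sum_e \beta_e \mathbf 1[E = e]
  + \sum \beta_{\mathrm{INT}} \, T_g \,\mathbf 1[E = e]
  + \gamma' z,$$

with $z$ = age, sex, race, study center and the pathway-tree columns; the
survival model is a Cox partial likelihood with the same columns, Efron
tie handling, cases only, and the baseline hazard stratified by SEER
stage (eventless strata contribute nothing).  Backward selection removes
one interaction term at a time — the largest Wald p — until all remaining
terms have $p \le 0.05$; main effects and adjustment covariates are never
removed, so model hierarchy holds throughout.  Survivors from all
sub-pathways are then jointly refitted in one full-pathway model, and the
terms significant there form the reported GEI set.  $OR_{\mathrm{INT}} =
e^{\beta_{\mathrm{INT}}}$ is the ratio of the gene's stratum-specific odds
ratios across exposure levels, an identity (`gene_or_level = gene_or_ref
* or_int`) the fits verify internally.

**Permutation correction.**  The final-model significant-GEI count is
compared with its distribution over re-runs of Step 3 in which every GST
column and every exposure column is independently permuted across
subjects.  Permutation preserves each column's prevalence exactly while
severing its link to outcome and covariates; the empirical p is the
fraction of runs reaching the observed count (a `>=` convention, so an
observed count of zero gives p = 1).  Permuting only at Step 3 is
justified by the independence of the GEI tests from the tree-building
steps: the GST columns are fixed functions of genotype once built.

# Exposure derivation

* **Smoking** — under 100 lifetime cigarettes is *never*; otherwise
  pack-years = cigarettes/day × years smoked / 20, categorised `lt20py` /
  `ge20py` with 20 pack-years in the upper category.
* **Alcohol** — consumption reported for 10 and 20 years before the
  referent period is averaged; *heavy* means the average strictly exceeds
  20 g/week (men) or 10 g/week (women).  Averaging is this package's
  aggregation rule: the two recall points describe one long-term exposure
  and the mean is its natural summary; an either-exceeds rule is a
  one-line change in `derive_alcohol()` if a user prefers it.
* **Protein** — the animal/vegetable protein intake ratio is *high* when
  strictly above 1.5.  The strict inequality is a boundary convention;
  ratios landing exactly on a cut-off are rare for continuous intake data.
  A zero vegetable intake makes the ratio unbounded and is assigned *high*
  with a warning rather than an error, since the subject's ratio genuinely
  exceeds any cut-off.

# Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| annealing iterations | 25,000/restart | geometric cooling 0.999/iteration |
| start temperature | auto | calibrated so ~90% of initially worsening moves are accepted; 0 gives greedy hill-climbing |
| restarts | 10 | best-scoring model kept |
| CV grid | 1–2 trees × 1–8 total leaves | plain minimum; ties to fewer leaves, then fewer trees |
| CV folds | 10 | stratified by outcome class / event status |
| significance threshold | 0.05 | backward selection and the final count |
| permutations B | 1000 | per-index seeding; order-independent |

The annealing defaults are the package's own: the framework calls for
simulated annealing and cross-validation but prescribes no schedule, so
the defaults are sized for a few hundred indicator columns per gene and
are fully configurable through `anneal_schedule()` and `cv_grid()`.  The move
set is the canonical logic-regression one (alternate-leaf,
alternate-operator, grow-branch, prune-branch, split-leaf, delete-leaf),
drawn uniformly over the moves legal for the current tree.  One GST is kept
per gene — the framework treats a GST as *the* summary profile of a gene —
so when cross-validation selects a two-tree model, the tree with the larger
absolute coefficient becomes the GST and the event is noted on the object.

# The synthetic-data generator

`simulation_design()` defaults describe the study the framework targets:
747 cases / 956 controls; 34 genes carrying 257 SNPs; exposure prevalences
48.7 / 23.4 / 27.9% (smoking never / <20 / ≥20 pack-years), 22.8% heavy
alcohol, 64.4% high protein ratio; SEER-stage distribution
(2.7 / 52.9 / 34.1 / 8.4 / 1.9% for in-situ / local / regional / distant /
unknown); and per-subject administrative censoring drawn from 72–126
months so every subject has over five years of potential follow-up.
Genotypes arise from two latent Gaussian allele draws per SNP thresholded
at the MAF quantile; within a gene the draws share a common factor with
correlation `ld_rho` (default 0.2, an unvalidated stand-in — the study's
SNP panel has no published LD estimates), so Hardy-Weinberg equilibrium
holds marginally while within-gene LD is present.  Panel MAFs are a fixed
low-discrepancy sequence on [0.05, 0.5]: the panel is configuration, not a
random draw.

Outcomes are simulated prospectively from a logistic model containing the
planted tree-by-exposure products, then quota-sampled to the case/control
totals; by standard case-control theory the interaction coefficients keep
their odds-ratio interpretation, and the intercept (default −0.62) only
controls sampling efficiency.  Survival is exponential per stage with
planted log-hazard terms, cases only.

What the generator does *not* emulate: recall and measurement error in
interview data, genotyping error and missingness patterns, realistic
haplotype structure (LD is exchangeable within gene), covariate-exposure
confounding, and secular trends in follow-up.  Passing the validation
suite therefore shows the *machinery* is correct and calibrated under the
stated data-generating process — not that real-data findings at these
magnitudes are guaranteed to replicate.

# Numerical choices

* Logistic and exponential tree scores are exact MLEs computed by
  Newton-Raphson with step-halving on the outcome aggregated by tree-value
  pattern (at most $2^k$ groups for $k$ trees): convergence
  $|\Delta \ell| < 10^{-10}$, at most 100 iterations.  Aggregation makes
  each annealing step O(subjects) for evaluation and O(1) for fitting.
* Separation is flagged at $|\hat\beta| > 15$ on the log scale; separated
  GEI terms are reported with an infinite-CI sentinel, and their inflated
  standard errors make them drop early in backward selection rather than
  masquerade as findings.
* Constant (monomorphic) tree columns are held at coefficient zero and
  flagged; a fully monomorphic gene yields a degenerate GST excluded
  downstream.
* A GST and its complement crossed with the *same* exposure level are
  exactly collinear given the exposure main effect — they carry the same
  Wald test with opposite sign — so the design builder drops the aliased
  product column (lowest prevalence first) instead of failing; rank
  deficiency among pathway-tree columns (e.g. a single-leaf pathway tree
  duplicating a GST main effect) is resolved by dropping the pathway-tree
  column; aliasing among adjustment covariates is an error naming the
  columns.
* Backward-selection ties at the maximal p are broken by smaller
  $|\hat\beta|$, then term name, so selection is deterministic.
* All searches, simulations and permutations are governed by explicit
  integer seeds; the pipeline derives per-stage streams from one master
  seed, so enabling permutations never changes the GSTs.
* Canonical tree form (children of commutative operators sorted by their
  serialisation) makes logs and reports stable across runs.

# Validation problem sizes

The acceptance checks (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) use: exhaustive enumeration limited to ≤6 columns
× ≤3 leaves as the annealing oracle (20 seeded runs on a planted two-leaf
instance at n = 500); Wald-CI coverage of a planted
$OR_{\mathrm{INT}} = 2$ over 200 replicates at the study size (747/956)
with a three-gene panel, a single-leaf planted profile and a single-leaf
Step-1 size grid — sized so that tree recovery is not the binding factor
of a coverage check; and null calibration from 50 four-gene null datasets
(per-term rejection rate) plus 5 null datasets × B = 200 permutations
(empirical-p behaviour).  These sizes are the package's choice of a
convincing-but-compact validation design.

# Limitations

* Logic-regression search is stochastic; different seeds can return
  Boolean-equivalent trees with different shapes (canonicalisation), or,
  on weak signals, genuinely different trees.  A tree and its complement
  are interchangeable as predictors — fits are identical with the
  coefficient sign flipped — so reported directions follow the fitted
  coefficient, not a carrier/non-carrier convention.
* Backward selection inflates the apparent significance of retained
  terms; the permutation correction quantifies exactly this, and final
  inference should rest on the permutation empirical p, not on the
  retained-term p-values alone.
* The exponential survival score in Steps 1–2 assumes constant hazards
  within stage; Step 3's stratified Cox model relaxes the baseline but
  keeps proportional hazards for covariates.
* Sub-pathway membership is a modelling input; the shipped nine-group
  configuration is a biologically motivated default and should be
  overridden when a better-supported grouping exists.
* Missing genotypes evaluate as "predicate false" in tree leaves; under
  substantial or informative missingness this biases tree prevalences and
  a dedicated missing-data treatment would be needed.
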