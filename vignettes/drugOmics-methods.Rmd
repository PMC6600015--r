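---
title: "Methods: multi-omic drug-sensitivity benchmarking in drugOmics"
author: "drugOmics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic drug-sensitivity benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugOmics)
```

# The problem

Cell-line drug screens ask which molecular data layer — somatic mutations,
transcript expression, or (phospho)protein abundance — best predicts how
sensitive a cancer cell line is to a drug. The statistical difficulty is the
p >> n regime: a typical melanoma-scale panel has ~49 cell lines against 88
antibodies or tens of thousands of transcripts, and naive regression overfits
badly. drugOmics implements the full comparison pipeline: dose-response
summarisation, leakage-free repeated nested cross-validation around several
learners (PLS first among them), permutation-based significance, multi-omic
integration, and cross-tissue transfer — together with a synthetic panel
generator that provides ground truth for validating every stage.

# Drug-sensitivity summary

Viability screens measure the fraction of surviving cells at a ladder of
doses (nine doses in a 1:3 serial dilution by default, evenly spaced in log
concentration). `meanViabilityAUC()` summarises each (cell line, drug) curve
as the arithmetic mean viability over the dose grid — equivalently the
normalized area under the dose-response curve, since the grid is even in log
space. Lower AUC means more sensitive. AUC avoids the saturation and
instability problems of IC50-type potency estimates; IC50 and maximum
inhibition are available as optional side outputs but feed nothing
downstream. Drugs that barely vary across the panel carry no learnable
signal, so `selectVariableDrugs()` filters by the coefficient of variation
sigma/mu (sample SD), either keeping the top k drugs or all drugs above a
threshold (0.2 is the conventional cut).

# The modeling protocol

All learners run inside one leakage-free protocol (`repeatedNestedCV()`),
per drug:

0. Cell lines without a measured AUC are discarded — never imputed.
1. Lines are split into 10 random folds (unstratified; fold assignments are
   derived from named seed substreams so every drug and repeat is
   independently reproducible).
2. Within each training fold, expression values are transformed —
   log2(1 + x) for transcripts, log2(x) for proteins — and filtered:
   transcripts need mean >= 2.0 and sample SD >= 0.5 on the transformed
   scale, proteins SD >= 0.1, and binary mutation columns must be carried by
   between 3 and n - 3 training lines. Filter membership uses training lines
   only.
3. Surviving features are standardized to mean 0, SD 1 with training-fold
   parameters; zero-variance columns are dropped rather than erroring, since
   fold subsets can create them.
4. Hyperparameters are selected by a nested 10-fold CV inside the training
   fold (see per-learner notes below).
5. The held-out fold is transformed with the *training* parameters and
   predicted.
6. Steps 2-5 iterate over folds so every line is predicted exactly once per
   repeat; per-repeat Spearman rho, fraction of variance explained
   R^2 = 1 - <(ahat - a)^2> / <(a - abar)^2>, and RMS are recorded.
7. The partition is redrawn and everything repeated (100 repeats by
   default); summary metrics are means over repeats, and per-line
   predictions are across-repeat means. The summary rho is the mean of
   per-repeat rho values, not the rho of averaged predictions.

Negative cross-validated correlations are reported as-is: they indicate a
non-predictive model, and hiding them would bias the benchmark.

## PLS

Partial least squares builds components — linear combinations of the input
features — that maximize covariance with the response, then regresses on
those few components. It is the reference learner here precisely because it
is designed for p >> n with correlated predictors. `plsFit()` implements
NIPALS with deflation; for a single response the inner iteration converges
in one step (the weight vector is proportional to X'y), so the fit is
direct and deterministic. For multi-response PLS2 the classical iterative
loop runs to a 1e-12 tolerance with at most 500 iterations. The component
count is chosen per training fold as the *smallest* count at which adding
one more component increases the nested-CV RMS (search range 1-10); this
"first increase" rule is deliberately conservative, favouring smaller
models over the global RMS minimum. The response is centered but not
scaled: rank- and variance-ratio-based metrics are invariant to scaling a
single response. Per-feature importance is read from the regression
coefficients of the standardized-input model (interpretable directly as
AUC change per SD of the marker); Variable Importance in Projection
(`vipScores()`, squared values averaging to 1) is provided as the standard
alternative. For multi-response PLS2 the shared component count is chosen by
`pls2SelectNcomp()` as the plain argmin of the nested-CV RMS curves *summed
over drugs* — the count is a compromise across all responses, which is
PLS2's inherent trade-off. The nested-CV inner loop is implemented in C++
(RcppArmadillo) with semantics identical to the R path — an equality test
pins the two against each other — because permutation backgrounds rerun it
tens of thousands of times.

## Comparison learners

*Regression tree* (`treeFit()`, backed by rpart): greedy variance-reduction
splits with a minimum bucket of 5 lines per leaf; cost-complexity pruning
over the tree's own cp sequence, pruned at the plain minimum of a nested
10-fold CV error (no 1-SE rule, which would need a justification the
benchmark design does not supply). Trees are the natural genomic learner:
binary mutation inputs and the nonlinear AND/OR structure of genetic
interactions.

*Elastic net / lasso* (`elasticNetFit()`, backed by glmnet): minimizes
(1/2n) RSS + lambda ((1 - alpha) ||b||^2 + alpha ||b||_1) with an
unpenalized intercept. glmnet's internal response standardization rescales
its quadratic penalty by the population SD of y, so the package applies an
exact reparameterization (verified against the ridge closed form and a
numerical optimizer in the tests) to keep the stated objective. `alpha` is
searched over 0, 0.1, ..., 1.0 and lambda over a data-driven path, winner
by minimum nested-CV RMS; ties go to the smallest alpha, then the largest
lambda (the sparser/smoother model). `lassoSparsitySweep()` reports CV
performance as a function of support size along the lasso path — how few
markers still give near-optimal predictions.

*Maximum correlation* (`maxCorrFit()`): simple regression on the single
feature with the largest absolute Pearson correlation with the response —
the "best single biomarker" baseline every multivariate model must beat.
Pearson (not rank) correlation is used because the model it feeds is
linear.

## Permutation significance

Observed performance is compared with an empirical null obtained by
shuffling the response across cell lines and rerunning the *entire*
pipeline — including fold-wise filtering and nested hyperparameter
selection — per shuffle (`permutationBackground()`). Each shuffle uses a
single CV run; with null distributions at N up to 8192 shuffles per drug,
repeated CV per shuffle would be prohibitive, and the repeat-averaging of
the observed statistic narrows its distribution only mildly (the
calibration test below verifies uniform p-values under this exact design).
The one-sided empirical p-value uses the add-one formula
p = (1 + #\{null >= observed\}) / (1 + N), which is bounded below by
1/(1 + N) and never zero. Across drugs, p-values are Benjamini-Hochberg
adjusted within each (data type, learner) family (`bhAdjust()`).

## Integration and transfer

Early integration concatenates independently prepared blocks before a
single fit (`earlyIntegrationFit()`); late integration combines per-block
predictions weighted by inverse RMS (`lateIntegrationPredict()`), a convex
combination. The RMS used for the weights is each block's nested-CV RMS on
training data, so no test information enters the weights.

`tissueMeanPredictor()` is the tumor-type baseline: leave one line out,
predict it by the mean AUC of the remaining lines of its tissue. A
molecular model is only interesting where it beats this.
`crossTissueTransfer()` holds out an entire tissue, trains once on the
rest (hyperparameters still by nested CV inside the training set), and
evaluates on the held-out tissue — a single tissue-defined split with no
outer repeats, matching the design it emulates. Because the cross-tissue
training set is much larger than any within-tissue set,
`crossFairBenchmark()` repeats the transfer with training sets subsampled
(without replacement, avoiding duplicated lines) to the target tissue's
size; the spread over resamples quantifies what transfer is worth at equal
n. Drugs nearly flat in either partition are removed first
(`filterTransferDrugs()`, CV threshold 0.2 on both sides).

# The synthetic panel generator

`generatePanel()` produces panels with the statistical structure the
analyses assume, plus a `GroundTruth` object recording exactly what was
planted. Defaults emulate a melanoma-scale screen: 49 cell lines, 88
proteins, 2000 transcripts, 300 binary mutations, 12 drugs, nine-dose 1:3
dilution curves. The generative model:

- Three latent "pathway activity" factors per cell line, plus a bimodal
  switch factor (a two-state mixture).
- Transcripts: per-gene Gaussian log2(1 + x) marginals (means ~ N(4, 2),
  within-gene SD ~ U(0.2, 1.5)), with roughly half the genes partially
  loading on one latent factor. The spread of means and SDs is chosen so
  the default mean/variance filters retain a nontrivial subset rather than
  all or none.
- Proteins: each protein is a noisy linear readout of one matched
  transcript plus one latent factor, emitted on a positive linear
  intensity scale so the standard log2 transform applies downstream. The
  first two proteins are overridden to form the anti-correlated switch
  pair (one high where the other is low), emulating mutually exclusive
  marker expression; their correlation is about -0.9 at defaults.
- Mutations: Bernoulli columns with prevalences spread over the range the
  frequency filter keeps, plus one driver column planted in exactly
  round(0.7 n) lines.
- Drugs: each drug has a baseline AUC ~ U(0.45, 0.85). The first drug
  class is driver-dependent: its AUC drops by ~0.25 in driver-mutated
  lines (the mutated target is the biomarker). Other informative drugs
  carry a 5-protein linear signature: the five strongest readouts of one
  latent factor, with coefficient magnitudes U(0.8, 1.2) and signs aligned
  with the factor — a coherent correlated marker group, the way pathway
  markers behave in real proteomic data, rather than five isolated
  features whose individual effects could be arbitrarily small. Drugs in a
  shared class reuse one signature with per-drug scale jitter, giving the
  correlated drug-class structure visible in real panels. Null drugs get
  baseline only: every bit of their observed variation is measurement
  noise.
- Effect size: the planted signal SD is `effectSize` times the AUC
  measurement noise SD (`viabilityNoiseSd / sqrt(nDoses)`), so the
  noiseless panel R^2 of an informative drug is
  effectSize^2 / (1 + effectSize^2) in closed form — e.g. effectSize
  sqrt(0.7/0.3) plants a true R^2 of 0.7.
- Dose-response: for each (line, drug), a logistic curve in log dose
  (upper asymptote 1, lower 0) whose inflection is solved numerically so
  the noiseless dose-grid mean equals the planted AUC exactly; additive
  Gaussian viability noise (SD 0.05 by default — screens rarely report
  this magnitude, so it is an exposed free choice) is then truncated at
  zero. Targets at or above 1 (growth stimulation) give flat curves. A
  single-parameter curve family is used because only the AUC summary is
  ever consumed; the curve shape itself is unidentified by the analyses.
- Duplicates: `nDuplicatePatients` lines are near-copies of a randomly
  chosen original — continuous features get N(0, 0.05 SD) perturbations,
  the binary mutation row is copied exactly (a Gaussian perturbation would
  break binarity), and the patient id is shared — enabling
  `excludeDuplicatePatients()` robustness checks.
- Random-number discipline: one master seed with independent named
  substreams per block, so changing the drug layout never perturbs the
  transcript draw, and identical configs give byte-identical panels.

What the generator does *not* emulate: realistic mutational signatures or
mutation co-occurrence, copy-number/methylation layers, dose-dependent
measurement error, batch effects, or nonlinear genotype-phenotype maps
beyond the single driver. Tests passing on these panels therefore
demonstrate that the *pipeline* is correct and calibrated — they do not by
themselves establish how predictive any data layer is in real tumors.

# Numerical and design choices

- NIPALS tolerance 1e-12, max 500 iterations (PLS2 only; PLS1 is direct).
  Which classical PLS variant is used matters only at the 1e-8 level,
  below every tolerance in the test suite.
- Tree tie-breaks are delegated to rpart's deterministic column-order
  scanning; pruning uses the plain CV minimum.
- The standardizer drops zero-variance training columns with a warning
  instead of erroring; fold-wise subsets of binary matrices routinely
  produce them.
- Mutation encoding is gene-level binarization; `buildMutationMatrix()`
  applies read depth >= 30, supporting-read fraction >= 0.2, impact at
  least MODERATE (unknown impact fails, conservatively; ordering LOW <
  MODERATE < HIGH), and excludes HLA-/MUC- prefixed genes as recurrent
  false positives. Population-variant filtering against external databases
  is out of scope; variant tables are assumed pre-filtered.
- Sample SD is used everywhere a "SD" threshold appears.
- Fold assignment is uniform and unstratified; seeds derive per
  (drug, repeat, shuffle) from the master seed.
- Two-cluster analyses cut the dendrogram below its final merge; drug-AUC
  clustering uses per-drug normalized AUCs with complete-case rows, and
  pairwise-complete correlations for the drug-drug view.

# Validation suite and problem sizes

The package's acceptance checks (in `tests/testthat/test-acceptance.R`,
recomputed fresh by `scripts/acceptance.R`) exercise: exact PLS/OLS
equivalence at full rank and agreement with an eigen-decomposition
reference; permutation-p uniformity over 50 null drugs at 200 shuffles
with 5-repeat observed CV; recovery of a planted 5-protein signature at
true R^2 0.7 (mean CV rho and top-10 coefficient membership, n = 49 x 88);
a driver-mutation positive control where only the two driver drugs beat
their 200-shuffle tree background and the driver sits at the tree root
(150 mutations; the mutation-block size is kept at a few hundred columns,
which preserves the p >> n regime while keeping the 2,000-odd tree
refits of the background cheap); data-type ranking on an
expression-driven panel; the metric unit identities; within- vs equal-n
cross-tissue transfer at 64 resamples; and hand-counted filter fixtures.
These sizes are the package's chosen validation conditions: large enough
that every mechanism (fold-wise filtering, nested selection, permutation
machinery) is genuinely exercised, small enough to run routinely.

# Known limitations

- PLS2's missing-response handling restricts to cell lines complete for
  all modeled drugs — the simplest consistent reading of the discard rule;
  with many sparsely measured drugs this can shrink the panel badly.
- Permutation nulls use one CV run per shuffle (see above); p-values
  inherit a mild conservatism in the extreme tails.
- The cross-tissue design uses a single tissue-defined split; its variance
  over panels is quantified only through the cross-fair resampling, not
  through outer repeats.
- Tree models serialize to JSON for inspection only; they cannot be
  reconstructed from the file, unlike the linear models.
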