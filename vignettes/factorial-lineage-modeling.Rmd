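---
title: "Factorial response-surface modeling of hiPSC lineage commitment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial response-surface modeling of hiPSC lineage commitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemfactor)
```

## The problem

Human induced pluripotent stem cells (hiPSCs) in the primed state are held
in place by a balance of signaling inputs — chiefly FGF, TGFβ/Nodal and
Wnt. To dissect individual and synergistic contributions of these pathways
to pluripotency maintenance versus germ-layer commitment, cells are exposed
to all combinations of three concentration levels of three soluble
activators (a 3³ full factorial: FGF2 at 0/35/100 ng/mL, TGFβ1 at 0/0.7/2
ng/mL, and the GSK3β inhibitor CHIR99021 — a canonical Wnt agonist — at
0/2/6 µM) on a minimal E6 basal medium, read out by real-time PCR of eleven
lineage marker genes, and summarized as five weighted lineage scores that
are then modeled as quadratic response surfaces over the factor space.

`stemfactor` implements that entire analysis as composable, tested stages,
plus a synthetic qPCR generator with known ground truth so every stage can
be validated end-to-end even though no raw dataset ships with the package.

## The design and its coding

`canonical_design()` builds the 27-condition run table (FGF2
slowest-varying, CHIR fastest), splits it into three blocks of nine, and
replicates Sample 1 — the unsupplemented E6 condition — three times, giving
29 observations and 28 total degrees of freedom.

Concentrations are coded for regression in two steps: each factor's three
levels are read as nominal activation fractions $f \in \{0, 1/3, 1\}$ *by
level index*, then centered and scaled as $X = 2(f - \tfrac12)$, giving
coded levels $\{-1, -\tfrac13, +1\}$. Two points deserve emphasis:

* The nominal fractions deliberately ignore the true concentration ratios
  (35/100 = 0.35, 0.7/2 = 0.35): the design treats "low activation" as one
  third of "high activation" for every factor. `coded_matrix(design,
  coding = "concentration")` provides the literal-ratio alternative.
* The quadratic columns are plain squares of the centered linear values,
  not orthogonal polynomial contrasts. With simple centering the linear
  column means over the 27 runs are $-1/9$, not 0, so single-term tests of
  linear and quadratic effects are correlated; this is the simplest reading
  of "centered and scaled polynomials" as practiced by DOE software, and
  partial F-tests (below) account for the correlation by construction.

A note on the TGFβ mid-level: published descriptions of this class of
design are internally inconsistent between 0.7 and 0.85 ng/mL; the run
table here uses 0.7 ng/mL throughout. Under nominal coding the choice is
immaterial to every downstream number.

## From Ct values to scores

`relative_expression()` applies the standard 2^−ΔΔCt quantification:
technical replicates are averaged on the Ct scale (the Livak convention;
averaging the linearized quantities instead would bias upward under noise),
ΔCt normalizes each target to the endogenous control (GAPDH) within a
sample, and ΔΔCt normalizes to the calibrator sample (the mTeSR1 control),
which therefore maps to exactly 1 for every gene.

`minmax_normalize()` rescales each gene to [0, 1] using its observed
extremes. The normalization cohort matters: by default the extremes are
taken over *all* samples including the mTeSR1/E8/E6 controls, since the
controls anchor the pluripotent end of each marker's range; restricting to
the 27 factorial conditions is available via `cohort`. Replicated samples
enter as separate observations and are never pre-averaged — this preserves
the 28-df bookkeeping at the modeling stage.

Panels are unweighted means of their member genes (pluripotency: OCT4,
NANOG; ectoderm: FGF5, PAX6, P75; mesendoderm: MIXL1, T; mesoderm: NKX2.5,
MESP1; endoderm: SOX17, PDX1), and the five scores are fixed weighted
combinations of the five panels:

$$\mathrm{Pluripotency} = 1.5 P_{pluri} - 0.25 P_{ecto} - 0.25 P_{mesend}
  - 0.5 P_{meso} - 0.5 P_{endo}$$

and analogously for the ectoderm (leading weight 1.75), mesendoderm,
endoderm and mesoderm (leading weight 2) scores. Every weight row sums to
zero, so a sample expressing all panels equally scores zero on every axis —
the scores measure *contrast* between lineages, not overall expression.
The weights ship as data (`inst/extdata/weights.yaml`) so alternative
weightings are testable without code changes; gene matching is
case-insensitive and alias-aware (T = Brachyury = TBXT, P75 = NGFR).

## The response-surface model

Each score is fitted by ordinary least squares to the full quadratic model

$$Y = \beta_0 + \sum_i \beta_i X_i + \sum_i \beta_{ii} X_i^2 +
  \sum_{i<j} \beta_{ij} X_i X_j + \varepsilon$$

(10 parameters; with 29 observations, 19 residual df). The solve goes
through QR factorization, never the normal equations, so noiseless
responses are recovered to ≤ 1e−8 absolute error — a property the test
suite checks directly against generating coefficients.

Term significance uses partial (Type III) single-df F-tests: the full
model is compared against the model with that one column deleted, and
$F = \Delta SS / \hat\sigma^2$ is referred to $F(1, 19)$. For 1-df terms
this is identical to the squared coefficient t-test (also verified in the
tests). Because of the E6 triplicate the design is near- but not exactly
orthogonal, so Type I and Type III sums of squares differ slightly; Type
III matches how commercial DOE packages report per-term p-values. Terms
with p < 0.05 are flagged; the model is never refined by dropping terms,
and no multiplicity correction is applied across the 9 terms or 5 models —
both choices mirror standard response-surface practice, and both are
deliberate: the models are descriptive summaries, not hypothesis screens.
R² and adjusted R² ($1-(1-R^2)(n-1)/(n-10)$) are reported for every model.

Degenerate inputs are handled explicitly: a perfect fit (zero residual
variance) reports p = 0 for terms with non-negligible sum of squares with
a warning; rank deficiency names the collinear columns rather than
silently pivoting them away.

## Clustering and PCA

Samples are clustered on their 5-score vectors using Pearson correlation
distance $d = 1 - r$ (not $1 - |r|$: anti-correlated lineage profiles are
maximally distant) and UPGMA average linkage via `stats::hclust`. The test
suite verifies the merge heights against a brute-force oracle that
recomputes every cluster-pair distance as the mean of all cross-pair
distances from the original matrix.

`pca_svd()` centers columns (unit-variance scaling off by default — the
five scores are already on a common scale) and, when entries are missing,
fills them by iterative low-rank SVD reconstruction (rank 2, tolerance
1e−6 on the RMS change of imputed cells, at most 100 iterations) before a
final SVD. On complete data the imputation loop is a no-op and the
explained-variance fractions equal those of a covariance
eigen-decomposition to 1e−10.

## The synthetic generator

`wnt_dominant_scenario()` encodes, as generating quadratic surfaces on the
calibrator-relative log2 expression scale, the qualitative biology the
pipeline should recover:

* mesendoderm and endoderm markers rise steeply with CHIR (linear
  coefficient +2 log2 units on the coded scale);
* pluripotency and ectoderm markers fall with CHIR (−2.5 and −2);
* mesoderm markers peak at the *intermediate* CHIR level (negative
  quadratic CHIR coefficient −3 placing the parabola vertex at coded
  −1/3);
* FGF2 and TGFβ contribute negatively to ectoderm markers (−0.7 each);
* an FGF×CHIR synergy is negative on pluripotency (−0.75) and positive on
  ectoderm/mesoderm markers (+0.6).

CHIR responses are saturating — most of the effect is realized at 2 µM —
encoded by concave quadratic CHIR terms on the monotone genes. This is
what makes the low- and high-CHIR conditions cluster together against the
CHIR-free conditions, as a Wnt-dominant experiment shows; with purely
linear surfaces the exponential expression scale would leave mid-CHIR
samples resembling unstimulated ones.

Noise is Gaussian on the Ct (cycle) scale, SD 0.25 cycles by default —
a typical qPCR technical error — with 3 technical replicates per
(sample, gene), a parameter the experiment descriptions leave open. Ground
truth is defined relative to the mTeSR1 calibrator (whose true log2
expression is 0 for every gene by construction); target-gene intercepts
place mTeSR1 high in the pluripotency markers' range and low in the
lineage markers' ranges, and the E8 control carries an explicit per-gene
override vector with the same character. Because of this construction the
noiseless pipeline inverts the generator exactly: 2^−ΔΔCt = 2^L to
≤ 1e−10, which the tests assert.

Effect sizes (|β| 2–2.5 for dominant CHIR terms, 0.5–0.75 for synergies)
were chosen so that, at n = 29 and σ = 0.25, dominant terms are detected
at p < 0.05 with high power while synergies remain borderline —
verified by the simulation-based tests, not assumed.

What the generator does *not* emulate: amplification-efficiency variation
between assays (the Pfaffl correction is out of scope), correlated
biological replicate structure, plate/batch effects, or expression
censoring at high Ct. Passing tests therefore demonstrate correctness of
the analysis arithmetic and calibration of the statistics under an
idealized error model, not robustness to every artifact of real qPCR data.

## Problem sizes used in validation

The simulation suites use 2,000 null datasets for the per-term false
positive calibration (pooled rejection rate over the 9 term tests,
asserted inside a 99% binomial band around 0.05), 500 generator-fit
replicates for parameter recovery (bias within 3 Monte-Carlo SEs;
empirical coefficient SD within 15% of the closed-form OLS standard error
$\sqrt{2\sigma^2/r \cdot (X'X)^{-1}_{jj}}$ — the factor 2/r reflecting
that each ΔCt is a difference of two r-replicate means), 200 random
6-sample instances for the UPGMA oracle and 100 seeds for the
cluster-separation check. These sizes give Monte-Carlo standard errors
comfortably below the asserted tolerances.

## Known limitations

* Published R² values (0.93–0.97) and PC1 variance shares (~91%) from real
  experiments of this design are not reproducible here: they depend on raw
  data that were never deposited. The package reproduces the *structure*
  of the analysis and validates it on synthetic ground truth.
* Only one condition is replicated, so lack-of-fit testing against pure
  error is not meaningful and is not offered.
* The UPGMA implementation delegates to `stats::hclust`; tie-breaking
  among exactly equal merge candidates follows its internals. On
  continuous data ties have measure zero and merge heights are
  tie-order-invariant (the oracle comparison covers this).
* Control samples carry no factor concentrations and therefore can never
  enter the response-surface fits; they participate in normalization,
  clustering and PCA only.
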