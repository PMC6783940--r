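# stemfactor

Factorial response-surface modeling of human induced pluripotent stem cell
(hiPSC) lineage commitment from qPCR marker panels.

## What it is for

Primed hiPSCs are held in pluripotency by a balance of FGF, TGFβ/Nodal and
Wnt signaling. A 3³ full factorial experiment — FGF2 at 0/35/100 ng/mL,
TGFβ1 at 0/0.7/2 ng/mL, the Wnt agonist CHIR99021 at 0/2/6 µM, 27 culture
conditions on E6 basal medium — lets individual and synergistic pathway
contributions be separated with a modest number of samples. `stemfactor`
implements the complete analysis of such an experiment:

1. **Design** — build and code the factorial run table. Levels are treated
   as nominal activation fractions {0, 1/3, 1} and centered/scaled to coded
   values X ∈ {−1, −1/3, +1}.
2. **Quantification** — 2^−ΔΔCt relative expression from raw Ct tables
   (GAPDH endogenous control, mTeSR1 calibrator).
3. **Scoring** — per-gene min–max normalization, lineage marker panels
   (pluripotency: OCT4, NANOG; ectoderm: FGF5, PAX6, P75; mesendoderm:
   MIXL1, T; mesoderm: NKX2.5, MESP1; endoderm: SOX17, PDX1), and five
   fixed zero-sum weighted scores, e.g.

   Pluripotency Score = 1.5·Pluripotent − 0.25·Ectoderm − 0.25·Mesendoderm
   − 0.5·Mesoderm − 0.5·Endoderm.

4. **Modeling** — per score, the full quadratic response surface

   Y = β₀ + β₁X₁ + β₁₁X₁² + β₂X₂ + β₂₂X₂² + β₃X₃ + β₃₃X₃² + β₁₂X₁X₂ +
   β₁₃X₁X₃ + β₂₃X₂X₃

   fitted by QR-based OLS (with the E6 triplicate: n = 29, 28 total df, 19
   residual df), with per-term partial (Type III) F-tests at α = 0.05, R²
   and adjusted R².
5. **Multivariate summary** — UPGMA clustering on Pearson correlation
   distance of the score vectors, and PCA via SVD with iterative low-rank
   imputation of missing entries.
6. **Synthetic ground truth** — a seeded generator
   (`wnt_dominant_scenario()`) producing complete Ct tables from known
   per-gene quadratic surfaces, so coefficient recovery, test calibration
   and cluster structure are verifiable end-to-end.

## Worked example

```r
library(stemfactor)
cfg <- pipeline_config(scenario = wnt_dominant_scenario(seed = 42))
rep <- run_pipeline(cfg)
print(rep)
#> Pipeline run report
#>  expression: 35 samples x 11 genes
#>  models: Pluripotency, Ectoderm, Mesendoderm, Endoderm, Mesoderm
#>   Pluripotency  R2 = 0.942, R2-adj = 0.914
#>   Ectoderm      R2 = 0.945, R2-adj = 0.919
#>   Mesendoderm   R2 = 0.985, R2-adj = 0.978
#>   Endoderm      R2 = 0.988, R2-adj = 0.983
#>   Mesoderm      R2 = 0.978, R2-adj = 0.968
#>  clusters (k = 2): sizes 17, 18
#>  PCA: PC1 75.3%, PC2 19.6%
```

The 35 samples are the 27 factorial conditions (Sample 1/E6 in
triplicate) plus triplicate mTeSR1 and E8 controls. The two clusters
separate CHIR-free from CHIR-exposed conditions — the Wnt-dominance
readout — and PC1 carries most of the score variance along the same axis.
Each fitted model exposes its coefficients and per-term ANOVA:

```r
summary(rep$fits$Mesendoderm)
#> Full quadratic response-surface model: Mesendoderm
#> n = 29, df(total) = 28, df(residual) = 19
#> R2 = 0.9849, R2-adj = 0.9777
#>      b0      b1      b2      b3     b11     b22     b33     b12     b13     b23
#>  1.0261 -0.0254  0.0128  0.7855 -0.1112 -0.0060 -0.7359 -0.0405  0.0880 -0.0064
#>
#> Per-term partial F-tests (Mesendoderm), F(1, 19):
#>  term        ss df         f         p significant
#>    b3 1.111e+01  1 1.017e+03 5.806e-18        TRUE
#>   b33 2.566e+00  1 2.347e+02 3.790e-12        TRUE
#>   b13 1.056e-01  1 9.663e+00 5.784e-03        TRUE
#>   ...
```

The dominant positive CHIR linear term (b3) with its concave quadratic
(b33) says mesendoderm commitment rises steeply, and saturates, with Wnt
activation; the small significant FGF×CHIR interaction (b13) is the
built-in synergy of the generating scenario. `predict(fit, ...)` evaluates
the surface on coded grids (with slicing) and `plot(fit)` draws contour
slices.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/stemfactor` (subcommands `design`, `simulate`, `express`,
`score`, `fit`, `cluster`, `pca`, `run`, `validate`).

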