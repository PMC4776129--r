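---
title: "An integrated-radius model for screening-level metal water quality criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated-radius model for screening-level metal water quality criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metcrit)
```

## The problem

Acute water quality criteria — criteria maximum concentrations (CMCs, µg/L)
— exist for only a handful of transition metals, because deriving one the
conventional way requires toxicity tests across many aquatic species. For
the several dozen transition metals without such data (including the
lanthanides and actinides), `metcrit` implements a QICAR-style shortcut:
regress the ln-transformed CMCs of the metals that *do* have recommended
values on their physicochemical descriptors, and use that relationship to
predict screening-level CMCs for the rest from descriptor values alone.

The training set is unavoidably tiny: eight records (Cd, Cr(III), Cr(VI),
Cu, Hg, Ni, Ag, Zn — the two chromium valences are separate records sharing
structural descriptors). Everything in the package is designed around being
honest at n = 8: exact small-sample t and F statistics, leave-one-out
cross-validation, and a leverage-based applicability domain so that
predictions outside the training region are flagged rather than trusted.

## The model

Three steps, each a function:

1. **Screen** (`pearson_screen()`): each of 26 descriptors is correlated
   with ln CMC; `significance_filter()` keeps those with r² > 0.5 and
   p < 0.05 (seven survive: the softness index σp, covalent radius CR,
   electron density AR/AW, atomic number AN, atomic weight AW, AN/ΔIP and
   the Pauling ionic radius r).
2. **Integrate** (`fit_pca()`): the surviving radius-family descriptors are
   collinear, so the first principal component of the Pearson correlation
   matrix of {CR, r, AR/AW} replaces them. Its loading vector defines the
   *integrated radius* score
   $$X_1 = 0.567\,CR + 0.568\,r - 0.597\,AR/AW,$$
   and its leading eigenvalue explains 88.8% of the subset variance.
3. **Regress** (`fit_ppcr()`): ordinary least squares of ln CMC on $X_1$,
   giving $\ln \mathrm{CMC} = -8.75\,X_1 + 13.34$ (R² = 0.63, RSE = 1.58 ln
   units, F = 10.23, P = 0.019). `predict()` back-transforms to µg/L and
   attaches a 95% band and an in-domain flag.

### The score convention

A point that the printed coefficients pin down but no text states: the
score is the **raw projection** of *unstandardized, untransformed*
descriptor values onto the unit-norm first eigenvector of the correlation
matrix. Neither standardized PC scores (which have standard deviation
`sd1` ≈ 1.63 and are numerically incompatible with a slope of −8.75) nor
ln-transformed inputs (whose correlation matrix gives a first-PC share of
≈89.5%, not 88.8%) reproduce the published regression; the raw projection
reproduces the slope and intercept essentially exactly. We verified this
with an independent least-squares oracle before adopting it, and the test
suite re-verifies it on every run.

Two loading modes exist because two legitimate vectors do:
`loadings = "computed"` uses the eigenvector of the current data (the
default, correct for any subset), while `loadings = "printed"` uses the
published three-decimal vector, which the reproduction report and the
acceptance checks use so that coefficients match to the printed digits.
The two agree within 0.001 per component; all scale-free statistics (R²,
F, P) are provably identical under any rescaling of the score, a property
the tests assert directly.

Sign orientation is fixed by making the loading on the first subset
descriptor positive. A globally flipped vector changes the slope's sign
and nothing else.

### Transform policy in the screen

Descriptors, like most concentration-scale quantities, are treated as
log-normal, so the default policy ln-transforms every strictly positive
descriptor (melting point, negative for Hg, stays raw). The published
correlation table, however, is internally inconsistent: σp, CR and r
reproduce under ln–ln, while AN, AW, AN/ΔIP and AR/AW reproduce with the
raw descriptor against ln CMC. The policy is therefore per-descriptor
configurable, and `table2_policy()` pins, for each descriptor, the
transform that matches the published coefficient. For σp no transform
reproduces the printed t statistic exactly (4.47 printed vs 4.60 under
ln–ln); the correlation itself still rounds to the printed 0.88.

## Data hygiene

Published descriptor tables round derived ratios brutally (electron
density for Hg prints as 0.01 where the true ratio is 0.00877 — a 14%
error). `recompute_derived()` therefore overwrites every derived column
(AR/AW, Xm²r, Z/r, Z/r², Z²/r, Z/AR, Z/AR², Z/(r·x)) from its parents at
full floating precision, and `ppcr_training_table()` does this by default;
the published regression is only recovered at full precision. One caveat
the fixture audit documents: the bundled table's printed ionic-radius
ratios (Z/r and relatives) are not consistent with its printed Pauling r
column — they were evidently computed from a different radius convention —
so only the AR- and AW-based ratios can be audited against their parents.
None of the inconsistent columns enters the selected model.

Missing values propagate as `NA` and any operation touching a missing
field fails with the record named; nothing is imputed. The ionic-radius
convention for *new* metals is deliberately left to the user: radii differ
across compilations (Pauling, Shannon, Goldschmidt, coordination numbers),
the training column is Pauling, and supplying a mixed convention is the
easiest way to get a silently wrong score.

## Validation

**Cross-validation.** `cross_validate()` defaults to leave-one-out — the
deterministic, conventional choice at n = 8 (k and a fold-shuffling seed
are available for k-fold). Per fold, the *entire* pipeline is refit: PCA
loadings on the training fold, raw-projection scores, OLS. Holding the
loadings fixed (`loading_override`) instead reproduces the closed-form
PRESS shortcut $e_i/(1-h_i)$ exactly, which the tests use as an oracle; the
two modes differ only slightly here (Q² 0.359 refit vs 0.361 fixed). The
published Q²cv of 0.55 (with RMSEcv 0.32) is not reproducible under
leave-one-out with any loading mode, and an RMSE of 0.32 is hard to
reconcile with a residual standard error of 1.58 on the same scale; the
original k and fold assignment are unknown, so the package reports its own
honest statistics and pins nothing to those two numbers. A y-scrambling
check (refitting after permuting the CMCs) drives the median Q² below
zero, confirming the positive Q² is signal, not machinery.

**Applicability domain.** For the one-predictor score regression the
leverage is $h_i = 1/n + (x_i - \bar{x})^2 / \sum (x_j - \bar{x})^2$, and
the warning threshold is the standard QSAR $h^\ast = 3(p+1)/n$ with p = 1
predictor, so $h^\ast = 0.75$ at n = 8 (the constant 3 is an argument).
All eight training metals are inside (maximum leverage: Ag at 0.389), and
the hat values sum to 2, the trace of the hat matrix for slope plus
intercept. `williams_export()` and `autoplot()` give the Williams plot of
standardized residuals against leverage, with |standardized residual| > 3
flagged as a response outlier.

**Rank concordance.** `rank_concordance()` compares the ordering of
predicted CMCs with amphipod (*Hyalella azteca*) LC50 values within
periodic-table groups, reporting concordant/discordant/tie per group (ties
are reported, never broken by index order) plus an overall Spearman ρ on
the ln scale. Gold is excluded by default — its toxicity record is too
thin to rank — with an `include_au` escape hatch. The bundled comparison
table keeps the two group-VIII pairs (Co/Rh and Ni/Pt) as separate blocks,
matching how they are compared.

## The synthetic-data generator

`simulate_training_table()` exists so that properties of the pipeline can
be tested against a known truth: `k` i.i.d. log-normal descriptors
(meanlog 0, sdlog 0.5 — positive, order-one values with a few-fold spread,
like the radius and ratio descriptors), and
$\ln \mathrm{CMC} = \beta \cdot X_1 + \varepsilon$ with the score built by
the same raw-projection convention the fitting code uses and
$\varepsilon \sim N(0, \sigma)$. With $\sigma = 0$ the downstream fit must
interpolate (R² = 1, slope = β exactly); with noise, the recovered slope
must sit within three standard errors of β. What the generator does *not*
emulate — deliberately — is the structure of real descriptor tables:
correlated descriptor families, shared values across oxidation states, and
measurement conventions that differ by compiler. Passing the recovery
tests therefore shows the estimator is correct, not that an eight-record
real table pins the slope tightly; the width of the real model's
confidence band (slope −8.75 ± 2.74 SE) is the honest statement of that.

## Numerical choices

* Eigendecomposition via the symmetric `eigen()`; invariants checked to
  1e−9 (unit-norm loading, eigenvalues non-negative, descending, summing
  to k). Constant columns are an explicit error naming the column, not an
  `NaN` correlation.
* OLS through `stats::lm`; the fit object freezes slope, intercept, R²,
  RSE, F, P, the score mean and centred sum of squares — everything
  intervals and leverages need — so a serialized model (`write_model()`,
  plain JSON at full precision) predicts identically after reload.
* Intervals are computed on the ln scale with $t_{0.975,\,n-2}$ and
  back-transformed multiplicatively; the default band is the mean-response
  confidence band (what the model's standard plot shows), with the wider
  prediction interval behind an argument.
* Test problem sizes are deliberately desk-scale: the real table is 8 × 26,
  property tests use tables of 8–50 rows with 1–5 columns, parameter
  recovery uses n = 200, and y-scrambling uses 100 permutations — the
  whole suite runs in seconds.

## Known limitations

* The model sees only intrinsic ion properties. Speciation, hardness, pH
  and dissolved-organic-carbon effects (the territory of biotic-ligand
  models) are out of scope; predictions are screening-level values, not
  site-adjusted criteria.
* Published fitted values for Cu (39 µg/L) cannot be reproduced by this
  pipeline (which gives ≈57 µg/L) even though Ni, Zn, Cd and Ag all agree
  within a few percent; a different copper radius was likely used
  upstream. The reproduction report excludes Cu from its pinned
  comparisons and documents it.
* Published regressions for the alternative descriptor subsets ({AW, CR,
  r} and relatives) are not reproducible under any score convention we
  tested; `fit_ppcr()` fits those subsets and reports its own statistics.
* An r² > 0.5 screen on 26 descriptors at n = 8 with no multiplicity
  correction (none is applied, by design, matching the source analysis) is
  a generous filter; the principal-component step, not the screen, is what
  controls redundancy.
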