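---
title: "Methods: comparing evolutionary rates of thermal tolerance and climatic niche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing evolutionary rates of thermal tolerance and climatic niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermorates)
```

## The question

Do plant physiological limits to temperature — cold tolerance (`T_min`) and
heat tolerance (`T_max`), both in °C — evolve faster or slower than the
climatic conditions species actually occupy, summarized as the minimum
temperature of the coldest month (MTCM, Bio6) and the maximum temperature of
the warmest month (MTWM, Bio5) across each species' range? `thermorates`
implements the comparative machinery for that question on a time-calibrated
phylogeny: all four quantities are continuous traits in °C, so their
Brownian-motion rates (σ², °C²/My) are directly comparable within a stated
pair on the same species set and the same tree.

## The rate model and the likelihood-ratio test

Under Brownian motion, trait values across the tips of a phylogeny are
multivariate normal with covariance σ²C, where `C[i, j]` is the depth of the
most recent common ancestor of tips *i* and *j* (the shared evolutionary
time) and `C[i, i]` is the tip's age. Both σ² and the root state have closed
ML solutions by generalized least squares:

- root: μ̂ = (1ᵀC⁻¹1)⁻¹ 1ᵀC⁻¹x
- rate: σ̂² = (x − μ̂1)ᵀC⁻¹(x − μ̂1) / n  (ML divisor n; REML is available
  via `reml = TRUE` but is not the default, because the rate convention
  throughout is plain maximum likelihood)

The central statistic is a likelihood-ratio test of rate equality for two
traits measured on the same species. The unconstrained model gives each trait
its own (μ, σ²); the constrained model shares one σ² while keeping separate
means, so

σ̂²_c = (Q_A + Q_B)/(2n),  LRT = 2(lnL_separate − lnL_common),

compared to χ² with 1 df — exactly one parameter (the second rate) is
removed. Between-trait evolutionary correlation is fixed at zero in *both*
models. This is a deliberate design choice: the hypothesis concerns rates
only, a shared correlation parameter cancels to first order in the LRT, and
omitting it keeps the constrained model nested with the same means. The test
is invariant to adding constants to either trait and to rescaling both traits
by a common factor (rescaling one trait alone scales its σ² by the square of
the factor — which is why comparisons are only meaningful for traits in the
same units, here °C).

A practical caveat inherited from the study design: sparse taxon sampling
inflates branch lengths and therefore biases absolute σ² values. The package
follows the same discipline — only paired, same-tree comparisons are
interpreted — and every comparison result carries the pruned-tree height so
per-stratum scaling is auditable.

## Four models, AIC, and ancestral states

For the absolute-rate analysis, each trait is first fitted with four models,
expressed as transforms of the unit-rate covariance:

| model | parameters | transform |
|---|---|---|
| BM | σ², μ | identity |
| λ (Pagel) | σ², μ, λ ∈ [0, 1] | off-diagonals × λ |
| OU (one optimum) | σ², μ, α > 0 | `exp(−2α(T − s))(1 − exp(−2αs))/(2α)` at shared depth s |
| WN (white noise) | σ², μ | T·I |

The OU form is the fixed-root, non-stationary convention. The stationary
alternative changes σ̂² but not which member of a pair is faster; the
fixed-root form is used because it nests BM exactly as α → 0 and matches the
common comparative-methods default. WN is scaled as T·I rather than I so that
σ² keeps one per-My interpretation across all four models (under WN, σ̂² is
the iid residual variance divided by tree height). OU requires an ultrametric
tree (gate: relative tip-depth spread ≤ 1e−6); for BM/λ/WN a non-ultrametric
tree is legal.

Fitting profiles the single shape parameter (α on a log grid over
[1e−8/T, 50/T] with local refinement; λ by bounded optimization on [0, 1]
with explicit endpoint checks), with σ² and μ concentrated out analytically
at every candidate. The bounds make the OU family span effectively-BM to
effectively-white-noise; the optimizer tolerance is 1e−8 on the shape
parameter. Model choice is by AIC (2k − 2lnL, k = 2 or 3); exact ties go to
the model with fewer parameters, then to the fixed order BM < WN < λ < OU.
AIC rather than AICc is the default because the selection rule is stated in
terms of AIC; AICc would only matter at n within a few multiples of k.

Ancestral states under the selected model are conditional expectations: the
tip covariance is transformed as above, node-to-tip covariances apply *the
same* elementwise rule at the node–tip shared-path depth (software
conventions differ here, so this is stated explicitly), and each internal
node gets â = μ̂ + cᵀC′⁻¹(x − μ̂1). The root estimate is μ̂ itself, and under
WN every ancestor collapses to the grand mean.

## Absolute tip rates and the paired test

The absolute evolutionary rate of a species is
|tip value − reconstructed parent state| / divergence time (°C/My).
"Divergence time" is read as the terminal branch length, since the estimated
ancestor is the parent node; the alternative reading (root-to-tip age) is
implemented behind `divergence = "age"` so the comparison direction can be
checked under both. Under a WN winner the parent is the grand mean and the
divergence time is the tip's depth, which keeps the formula well defined.
Tips on zero-length terminal branches are excluded and counted — an epsilon
fill-in would dominate the subsequent log scale, so exclusion with reporting
is the safer rule. The species-level comparison is then a paired t-test on
ln rates over species with both rates positive; all-zero differences give
t = 0, p = 1, and a constant nonzero difference (zero variance) is flagged
degenerate with p = 0 rather than returning NaN.

## Niche summarization and the analysis table

Occurrence records (species, longitude, latitude, Bio5, Bio6) are summarized
per species as: arithmetic means of both variables; the 90th percentile of
Bio5 ("upper MTWM") and 10th percentile of Bio6 ("lower MTCM") under the
linear-interpolation percentile definition (R type 7), chosen and documented
so results reproduce bit for bit. The phrase "top 90% values" admits a
literal reading — the mean of the tail beyond the percentile — which is
available as `tail_mode = "tail_mean"`; the percentile reading is the default
because the downstream rate analysis needs one scalar per species. The third
variant takes Bio5/Bio6 at the experimental site's coordinate via
nearest-cell extraction from a gridded surface (ESRI ASCII format; points on
cell edges belong to the east/north neighbor; out-of-extent points are
flagged missing, not errors). Repeated physiological measurements are
averaged per species; conflicting hardening labels collapse to "unknown"
with a warning, since no resolution rule is defensible without the original
sources. All three niche variants feed the same assembly step, and the
pipeline can be rerun under each to check that comparison directions are
stable.

## PGLS

The tolerance-versus-niche association is a single-predictor GLS regression
with residual covariance C(λ). λ defaults to 1 (BM residuals), with an ML
mode that profiles λ on [0, 1]; both are runnable because published analyses
are often ambiguous about which was used. R² is defined against the GLS
intercept-only baseline under the *same* V — the raw-space variance would be
incoherent once V ≠ I. The slope test uses residual variance RSS/(n − 2) and
a t distribution with n − 2 df. The standard six panels are
{T_min ~ MTCM, T_max ~ MTWM} × {all, hardened, non-hardened}, each on its
stratum's pruned tree; strata under 3 species are skipped with a log entry.

## The synthetic world

The generator exists so every stage is testable offline; its defaults were
fixed once, before any test was run against them, to mirror the structure the
real analysis reports:

- 300 species on a Yule tree conditioned on n, rescaled to height 60 My
  (rescaling keeps °C²/My rates on a realistic scale for °C traits; the
  raw pure-birth height would put tip standard deviations at tens of
  degrees).
- Hardening strata 50% hardened / 20% non-hardened / 30% unknown, roughly
  the proportions of the real cold-tolerance panel.
- `T_min` rates per stratum 1.0 / 0.05 / 0.3 °C²/My: hardened cold tolerance
  evolves fast, non-hardened slowly. `MTCM = a·T_min + BM noise` with
  a = 0.25 / 0.5 / 0.3 and noise rates 0.04 / 0.08 / 0.06, which makes the
  cold niche slower than hardened `T_min`, *faster* than non-hardened
  `T_min`, tightly coupled in the hardened stratum and weakly coupled
  otherwise — the qualitative pattern of the real tables.
- `T_max` at 0.05 °C²/My in all strata with MTWM coupling 0.2 and noise
  0.048, so heat tolerance and warm niche evolve at near-equal rates with a
  weak association.
- Occurrences are Gaussian clouds (SD 2°) centered where two linear climate
  surfaces return the species' niche values, 25 points per species, on a
  0.5°-resolution grid; Bio5 − Bio6 is positive everywhere by construction.

Traits are drawn by scaling one latent unit-rate BM per trait family by the
tip's stratum. Within a stratum this is exactly BM at the stated rate — which
is what the per-stratum analyses fit — but the pooled "all" stratum is a
scale mixture, not a single BM, so pooled σ̂² can exceed every stratum rate
in some draws. That is a feature shared with the real data (published group
rates span five orders of magnitude) and is why only within-stratum
directions, not pooled magnitudes, are asserted by the tests. A second,
branchwise BM simulator (recursive normal increments along edges) provides a
code path independent of the covariance factorization; agreement between the
two guards against a transform bug canceling itself in recovery tests.

What a green synthetic run does *not* establish: anything about measurement
heterogeneity across physiological assays, spatial sampling bias in real
occurrences, name-matching losses against a megatree, or the absolute
magnitudes of published rates — reproducing those requires the deposited
dataset and megatree, which are deliberately out of scope offline.

## Numerical choices

- Covariances are factored by Cholesky; on failure the diagonal is jittered
  once by 1e−10 × tree height (polytomy-rich megatrees create near-singular
  blocks), and failure after jitter is an error carrying a condition-number
  estimate.
- Constant traits return a degenerate fit (σ̂² = 0, `valid = FALSE`, NA
  likelihood) instead of raising, so batch strata can be skipped and logged.
- The LRT is clipped at zero (it can be −1e−12 through rounding); a value
  below −1e−8 warns, because that indicates a real optimizer failure rather
  than noise.
- Ultrametricity is a relative tolerance (1e−6 of height): a warning gate
  for BM/λ/WN, a hard requirement for OU.
- Newick output carries 10 significant digits so trees round-trip below
  1e−9.
- Display tables round to 2 decimals with "–" for empty strata, and a
  full-precision companion file is always written alongside.

## Known limitations

- No multivariate rate matrices, no rate shifts along branches, no
  measurement-error term in the likelihoods.
- The paired LRT's χ²₁ reference is asymptotic; for very small strata a
  parametric bootstrap would be preferable (strata under 3 species are
  refused outright).
- ML-λ PGLS profiles λ only; no confidence interval on λ is reported.
- The occurrence reader validates coordinates but performs no cleaning:
  native-range filtering and outlier removal are upstream concerns.
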