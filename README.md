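# thermorates

Phylogenetic comparative analysis of how fast plant **physiological thermal
tolerance** evolves relative to the **climatic niche**. The package is aimed
at comparative ecophysiologists who have (a) a time-calibrated phylogeny,
(b) species-level cold/heat tolerance measurements (`T_min`, `T_max`, °C),
and (c) occurrence-level climate records (Bio5 = maximum temperature of the
warmest month, MTWM; Bio6 = minimum temperature of the coldest month, MTCM),
and who want to ask: *which evolves faster — the physiology or the niche?*

## What it computes

All four quantities are continuous traits in °C on the same tree, so their
Brownian-motion rates are directly comparable within a pair:

- **Overall rates and the rate LRT.** Under BM, tip values are MVN with
  covariance σ²C (C = shared ancestry times). ML estimates are closed-form
  GLS: μ̂ = (1ᵀC⁻¹1)⁻¹1ᵀC⁻¹x, σ̂² = (x−μ̂1)ᵀC⁻¹(x−μ̂1)/n. Rate equality of
  two traits on the same species set is tested with
  LRT = 2(lnL_separate − lnL_common) ~ χ²₁, where the common-rate model
  pools σ̂²_c = (Q_A + Q_B)/(2n) with separate means.
- **Four-model fitting + AIC** (BM, single-optimum OU, Pagel's λ, white
  noise) for each trait, ancestral state reconstruction on the best model's
  transformed covariance, **absolute tip rates**
  |tip − ancestor| / branch time (°C/My), and paired t-tests on ln rates.
- **PGLS** of tolerance on niche (λ fixed at 1 or ML-profiled), with R²
  against the GLS intercept-only baseline.
- **Niche assembly** from occurrences (mean / tail-percentile / local-site
  variants) and **a seeded synthetic-data generator** (Yule trees,
  correlated traits with hardening strata, occurrence clouds on gridded
  climate surfaces) so the whole pipeline runs offline.

## Worked example

```r
library(thermorates)

# a fully synthetic study: 300 species, hardening strata, occurrence clouds
sc  <- make_study_scenario(seed = 1)
tab <- assemble_analysis_table(sc$traits, summarize_niche(sc$occurrences))

T_min <- setNames(tab$T_min, tab$species)
MTCM  <- setNames(tab$MTCM,  tab$species)
lrt_rate_comparison(sc$tree, T_min, MTCM, "T_min", "MTCM")
#> Rate comparison: T_min vs MTCM (n = 300)
#>   sigma2: 2.677 vs 0.1981   (faster: T_min)
#>   LRT = 408.0991 (df = 1), p = 9.504e-91

figure4_panels(tab, sc$tree)[, c("panel", "stratum", "n", "R2", "p_value")]
#>        panel      stratum   n          R2      p_value
#> 1 T_min~MTCM          all 300 0.418956336 5.230037e-37
#> 2 T_min~MTCM     hardened 151 0.506317074 1.322909e-24
#> 3 T_min~MTCM non_hardened  75 0.065553128 2.661144e-02
#> 4 T_max~MTWM          all 300 0.032299967 1.775839e-03
#> 5 T_max~MTWM     hardened 151 0.094907502 1.189890e-04
#> 6 T_max~MTWM non_hardened  75 0.005671147 5.207844e-01
```

Cold tolerance evolves an order of magnitude faster than the cold niche
(σ² = 2.68 vs 0.20 °C²/My, decisively rejected rate equality), and the
tolerance–niche association is strong for hardened species (R² = 0.51) but
weak for non-hardened ones (R² = 0.07) — the qualitative pattern this kind
of analysis probes. Model selection for `T_min` here picks λ
(AIC: BM 1818.9, WN 1838.3, **LA 1645.0**, OU 1723.1), which the
absolute-rate stage then uses for reconstruction.

The full stratified analysis (groups × hardening × comparisons i–iv) runs
from files:

```r
write_scenario(sc, "scenario")
cfg <- analysis_config(tree = "scenario/tree.nwk",
                       traits = "scenario/traits.tsv",
                       occurrences = "scenario/occurrences.tsv",
                       out_dir = "results_tables")
res <- run_all(cfg)   # overall_rates, absolute_rates, pgls + TSVs
```

or from the command line:

```sh
Rscript -e 'thermorates::thermo_cli()' simulate --n 300 --seed 1 --out scenario
Rscript -e 'thermorates::thermo_cli()' run-all --config run.cfg --out results_tables
```

where `run.cfg` is a flat `key=value` file (`tree=`, `traits=`,
`occurrences=`, `niche_variant=mean|tail|local`, `lambda_mode=fixed|ml`,
...).

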