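# phyloplast

Comparative phylogenetic analysis of anuran larval development under pond
desiccation risk.

## The problem

Amphibian larvae in ephemeral ponds race pond drying: do species that breed
in **High-risk** (temporary) ponds evolve faster development, different
growth, and smaller mass at metamorphosis than **Low-risk** (permanent-pond)
breeders — and do they respond more plastically when the water level drops?
Answering this with literature-compiled data (one or more experimental
*cases* per species, each with constant- and drying-treatment summaries)
requires comparative methods: species share evolutionary history, so
ordinary regression understates uncertainty whenever traits carry
phylogenetic signal.

`phyloplast` implements the full toolchain for this design, for anyone
analysing paired-treatment comparative datasets on a phylogeny:

* **Derived traits** — developmental rate `1/T` (days⁻¹), mean growth rate
  `M/T` (g·day⁻¹), log₁₀ transforms; body volumes convert to mass at
  density 1 g/mL.
* **Plasticity statistics** — percent change
  `100 (x_d − x_c) / x_c` (drying minus constant, so reductions are
  negative) and Hedges' *d* with its sampling variance as a
  variability-aware cross-check.
* **PGLS model selection** — the same linear model is fitted by generalized
  least squares under two residual covariance structures: a *star*
  phylogeny (independence; conventional statistics) and Brownian motion on
  **Grafen** branch lengths (node height = (descendant tips − 1)/(total
  tips − 1), unit tree height). Model support is compared by AIC and Akaike
  weights `w_i = exp(−Δ_i/2) / Σ exp(−Δ_j/2)`; a decisive phylogenetic win
  is evidence of phylogenetic signal.
* **Soft-polytomy df correction** — replicate cases enter as near-zero
  branch-length polytomies at the tips; hypothesis tests conservatively
  subtract one residual degree of freedom per unresolved node
  (`corrected_df(62, 2, 25)` → t₃₅ instead of t₆₀).
* **Analysis stages** — venue screening, High-vs-Low trait comparisons,
  ANCOVA controlling for developmental time, plasticity comparisons, the
  time-plasticity × risk interaction, and plasticity-vs-mean regressions,
  orchestrated by `run_full_analysis()` into a JSON + TSV report.
* **Synthetic data** — pure-birth trees, Brownian traits with group shifts,
  and paired-treatment case tables with controllable group-dependent
  plasticity (`simulate_dataset()`), used to validate every statistical
  claim above.

## Worked example

```r
library(phyloplast)

sim <- simulate_dataset(sim_params(seed = 1))   # 62 cases, 30 species
mc  <- compare_groups(sim$cases, sim$tree, "log10_dev_rate")
mc
#> Model comparison (star vs grafen covariance)
#>   model    logLik       AIC         AICw
#>    star  44.79601 -83.59202 1.000000e+00
#>  grafen -55.84913 117.69826 1.951513e-44
#> best: star   soft polytomies: 16
#>
#>   model coefficient   estimate          se            t df_raw df_corrected
#>    star (Intercept) -1.7518262  0.02144951 -81.67208838     60           44
#>    star    riskHigh  0.3342748  0.03033419  11.01973841     60           44
#>  grafen (Intercept) -1.7122992 16.44137174  -0.10414577     60           44
#>  grafen    riskHigh  0.2998023  5.03700464   0.05951997     60           44
#>  df_used            p
#>       60 3.283849e-63
#>       60 4.761881e-16
#>       44 9.175270e-01
#>       44 9.528075e-01
```

Reading this: the simulated world injected a +0.3 shift in log₁₀
developmental rate for High-risk species plus independent per-case noise.
Both fits recover the shift (`riskHigh` ≈ 0.33 and 0.30). The star model
wins the AIC comparison decisively (weight ≈ 1) because per-case noise
dominates the phylogenetic signal here; the phylogenetic fit's much larger
standard errors show how strongly near-duplicate replicate tips devalue
within-species information under Brownian covariance. The phylogenetic
row's t is referred to 44 df (60 raw − 16 replicate-tip polytomies).

The same analysis over every stage:

```r
report <- run_full_analysis(analysis_config(seed = 1), sim$cases, sim$tree)
write_report(report, "out/")   # report.json + derived/plasticity/model TSVs
```

Command line (installed under `system.file("cli", "phyloplast")`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli","phyloplast",package="phyloplast"))') \
  simulate --seed 7 --n-species 30 --out demo/
Rscript ... analyze --tree demo/tree.nwk --data demo/cases.tsv --out demo/out/
```

## Documentation

The methods vignette (`vignettes/phyloplast-methods.Rmd`) describes the
model, the degrees-of-freedom correction, the synthetic world and its
deliberate misspecification, numerical choices, and known limitations.
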