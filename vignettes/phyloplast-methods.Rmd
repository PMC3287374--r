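---
title: "Methods: PGLS model selection for larval plasticity under desiccation risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PGLS model selection for larval plasticity under desiccation risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloplast)
```

## The question and the data design

Anuran larvae developing in drying ponds face time-limited metamorphosis.
The comparative design this package serves asks four questions of a
literature-compiled dataset (cases = species × study, each with
constant-water and, usually, drying-water treatment summaries of larval
period and mass at metamorphosis):

1. Do High-risk (ephemeral-pond) breeders differ from Low-risk
   (permanent-pond) breeders in developmental rate, mean growth rate, and
   mass at metamorphosis?
2. Do the growth/mass differences persist after controlling for
   developmental time (ANCOVA)?
3. Is drying-induced plasticity of those traits larger in High-risk
   species?
4. Does mass/growth plasticity track time plasticity differently in the
   two groups (interaction), and does plasticity depend on the species'
   mean trait values?

Risk category and venue are **inputs** — this package never infers habitat
from databases, and it does not reconstruct the underlying phylogeny;
users supply a rooted Newick tree (or simulate one).

## Model

For a response vector $y$ (a log10 mean trait or a percent plasticity) and
design matrix $X$, we fit

$$y = X\beta + \varepsilon,\qquad \varepsilon \sim
\mathcal N(0,\ \sigma^2 V),$$

with $V$ **fixed** at one of two structures:

* **star**: $V = I$ — residual independence, i.e. conventional statistics;
* **grafen**: Brownian-motion covariance on Grafen branch lengths. Each
  node's height is $(d-1)/(n-1)$ ($d$ = descendant tips, $n$ = total
  tips; the height exponent $\rho$ is fixed at 1, Grafen's default), so
  the tree is ultrametric with unit height and $V_{ij}$ is the root-to-MRCA
  distance of tips $i,j$.

$\hat\beta = (X^\top V^{-1}X)^{-1}X^\top V^{-1}y$ is computed by Cholesky
whitening; $\sigma^2$ is profiled at its ML value $r^\top V^{-1} r/n$, so

$$\log L = -\tfrac n2 \log(2\pi\hat\sigma^2_{ML}) - \tfrac12\log|V|
- \tfrac n2 .$$

ML (not REML) is used deliberately: the two candidate models share their
fixed effects and differ only in $V$, so ML likelihoods (and hence AIC) are
directly comparable. Standard errors use the unbiased scale
$r^\top V^{-1}r/(n-p)$, and both scales are reported on the fit object.

**AIC and Akaike weights.** $AIC = -2\log L + 2(p+1)$: the residual
variance counts as a parameter; the covariance *structure* adds none
(ρ is fixed), so the star/grafen AIC difference reduces to the
$-2\log L$ difference. Weights are $w_i = e^{-\Delta_i/2}/\sum_j
e^{-\Delta_j/2}$ and sum to one per comparison. Exact ties
($|\Delta| < 10^{-9}$) resolve to the star model, the simpler covariance
assumption. One published comparison reports AIC 537.17 vs 543.58 with
weights 0.94/0.06 where this formula gives ≈0.96/0.04; we implement the
standard formula and note, rather than tune to, the discrepancy.

**Replicate cases and the polytomy correction.** Multiple cases per
species enter as tip polytomies: the species tip is replaced by a cluster
of case-labelled tips on branches of length $\varepsilon$
(default $10^{-6}\times$ tree height — strictly positive so $V$ stays
invertible; the zero-length limit is numerically singular), with the
parent branch shortened so total height is conserved. Every internal node
with more than two children — whatever its child count — then costs **one**
residual degree of freedom in coefficient $t$-tests:
$df = n - p - (\#\text{polytomies})$. This is the conservative guard
against pseudo-replication from unresolved structure; with 62 cases, 2
mean parameters and 25 polytomies it yields $t_{35}$ rather than
$t_{60}$. We count *all* internal nodes with more than two children,
including the root. Tests are two-sided with no multiplicity correction.

## Derived traits and plasticity scales

Developmental rate is $1/T$ (days$^{-1}$; a 106-day larval period is a
rate of 0.0094), mean growth rate is $M/T$ — a deliberate straight-line
summary of a nonlinear trajectory, valid only as an endpoint descriptor.
Mean-trait analyses use log10 transforms (normality); plasticity is
computed on the **raw** trait scale as $100(x_d - x_c)/x_c$. Time
plasticity defaults to the *period* scale (the rate scale is available via
`time_scale = "rate"`, since the published phrasing is ambiguous; the two
are monotone transforms of each other). Hedges' $d$ (drying − constant,
matching the percent sign convention) is provided per trait with the
standard small-sample correction and large-sample variance; for derived
traits (rate, growth) the treatment SDs come from a delta-method
approximation of the period/mass summaries, since only those summaries
exist. On generator output percent plasticity and $d$ correlate above 0.8,
which is the justification for reporting the more interpretable percent
scale in the analysis stages.

## The synthetic world

`simulate_dataset()` emulates the structure of the compiled dataset with
known truth. Defaults — chosen once to mirror the stated study design, and
not revisited:

| parameter | default | rationale |
|---|---|---|
| species / cases | 30 / 62 (16 species × 3 cases) | compiled dataset's size |
| BM rate `sigma2_bm` | 0.04 (log10²·height⁻¹) | ≈ 0.2 log10 units of interspecific SD |
| group shifts | +0.3 (log10 rate), −0.3 (log10 mass) | High-risk faster, smaller |
| risk assignment | clustered on the tree (BM threshold) | risk is phylogenetically structured; `"random"` breaks it |
| time plasticity | −20 % (High) vs −5 % (Low), SD 8 | strong vs weak drying response |
| mass plasticity | −15 % vs −5 %, slope on time plasticity 1 vs 0, noise 5 % | tracking vs compensation |
| case jitter | 0.05 log10 units | among-study variation |
| reported summaries | CV 10 % (period), 15 % (mass), n = 20 | typical experiment scale |
| root states | 60-day period, 0.32 g | mid-range anuran values |

Percent draws at or below −100 (impossible: the trait would be
non-positive) are resampled and counted in the truth record. The root
state enters every tip identically, so it is irrelevant to group
contrasts.

**What the generator does *not* emulate** — and hence what a green test
does not establish: growth-trajectory shape within ontogeny, publication
bias, venue effects (venues are assigned at random with no effect),
heteroscedastic or correlated measurement error, and risk groups that
disagree within a species.

**Deliberate misspecification.** The *default* world — replicate cases
with independent per-case noise on near-zero branches — satisfies
*neither* covariance structure exactly, like real data. Consequences we
rely on and test:

* calibration (uniform null $p$-values) is claimed only in the two
  correctly specified sub-worlds (no replicates with `sigma2_bm = 0` for
  the star model; no case noise for the grafen model);
* in the default world the phylogenetic model's $\sigma^2$ is inflated by
  within-species noise, making its tests conservative — which is the
  direction the polytomy df-correction is meant to guarantee, and what the
  conservativeness acceptance test measures;
* AIC model-selection sanity (Brownian world → grafen wins; iid world →
  star wins) is tested in the matching pure worlds.

## Numerical and design choices

* Cholesky failure on $V$ triggers one jitter of
  $10^{-10}\,\mathrm{tr}(V)/n$ (warned); failure after that is an error
  suggesting a larger replicate $\varepsilon$.
* Saturated or zero-residual fits are flagged degenerate; AIC on them is
  an error, and stages propagate it as a failed stage rather than a
  number.
* Rank-deficient designs name the collinear columns.
* Stages that *cannot* run (single venue, too few paired cases, one risk
  group) are **skipped** with a reason, not failed; the pipeline
  (`run_full_analysis()`) records every stage's status and continues.
* Each stage prunes the tree to the species it actually uses and
  re-derives Grafen lengths on the pruned tree, keeping unit height; the
  star model never reads branch lengths, so conventional results are
  identical whatever tree is supplied.
* When a species appears in both risk groups, risk is a per-case
  predictor; the tree contributes correlation only.
* Reports contain no timestamps, so identical config + seed reproduces
  byte-identical JSON.

## Known limitations

* $\rho$ (Grafen) and Pagel's $\lambda$ are not estimated; the comparison
  is strictly star vs fixed-Grafen, so "phylogenetic signal" is a
  two-point model choice, not a continuous estimate.
* Hedges' $d$ for derived traits rests on a delta-method SD; with very
  small treatment $n$ it is reported as `NA` rather than extrapolated.
* Sampling-variance weighting (meta-analytic GLS) is out of scope; cases
  are equally weighted.
* The 2-MC-SE acceptance checks on 500-replicate simulations are
  themselves statistical tests with a few-percent false-alarm rate by
  construction.
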