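---
title: "Decadal 15N pulse-labelling analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decadal 15N pulse-labelling analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsetrace)
```

## The problem

A single pulse of highly enriched ammonium nitrate (¹⁵NH₄¹⁵NO₃, 98 at.%)
applied to the surface of a moss-covered heathland marks one cohort of
incoming atmospheric nitrogen. Following the label through plant fractions,
the moss layer, the O/A/B horizons of the podzol and the leachate over nine
annual sampling occasions answers three questions that bulk N budgets
cannot: where incoming N is retained, how it moves between compartments,
and how much leaves the system unobserved. `pulsetrace` implements that
analysis chain — isotope arithmetic, pool accounting, recovery tables,
mass-balance flow inference, and a gamma mixed model for enrichment trends
— together with a simulator that generates ground-truth-bearing synthetic
experiments for every stage.

## Isotope arithmetic

All measurements arrive on the delta scale, the per-mil deviation of the
¹⁵N/¹⁴N ratio from atmospheric N₂:
$\delta^{15}N = (R_{sample}/R_{standard} - 1)\times 1000$. The scale
anchor `R15N_AIR = 0.0036765` is the conventional absolute ratio of air
N₂; the source study does not state the value it used, so it is exposed as
an argument everywhere it enters. Enrichment of a labelled sample over its
paired reference,
$EN = 1000\,(\delta_{s}-\delta_{r})/(\delta_{r}+1000)$, equals the
relative ratio change and is therefore independent of that anchor.
Recovery converts atom-percent excess into tracer mass:
$m_{pool}\,(at\%_{pool}-at\%_{ref})/(at\%_{tracer}-at\%_{ref})$, with the
nitrogen pool mass $m_{pool}$ in g N m⁻². Everything is carried at full
double precision; the report writers round to two decimals.

The applied dose is converted to excess ¹⁵N per m² from the molar
composition of the double-labelled salt (two N per formula unit, molar
mass built from the stated label atom-percent). By default the recovery
denominator is the *excess* ¹⁵N above natural abundance, consistent with
the excess in the numerator; the gross ¹⁵N content of the dose is
available via `basis = "gross"`. The dose is interpreted per square
metre, which is the basis on which recovery percentages are meaningful.

## Pairing and aggregation

The design is paired: each plot has a labelled and a reference subplot.
Enrichment and recovery are computed per plot against the same-plot
reference, falling back to the compartment-year mean reference when a pair
is missing. Two aggregation modes exist because published tables of this
kind mix them: `per_plot_mean` (the default; mean ± SE over plots of
per-plot values, matching a design with n = 7 plots) and `mean_of_deltas`
(the formula applied to group-mean deltas, which is the only way printed
group means can be processed, and the mode used when reproducing printed
enrichment cells). The two agree exactly when all plots share one
reference delta; on real data they differ slightly because enrichment is
nonlinear in the reference. A handful of printed cells are consistent only
with one mode or the other, which is why both are first-class.

Compartments not sampled every year (older woody biomass, roots) are
omitted from annual totals unless explicitly included, so totals change
composition across years exactly as sampled — never imputed.

Paired Student's t-tests (two-sided, per compartment × year) flag cells
with fewer than two pairs or zero-variance differences as "not evaluable"
rather than producing infinities; no multiple-testing correction is
applied, matching the original analysis style.

## Flow inference

Changes in recovery between two sampling years are attributed to flows
along a fixed directed topology: moss → O → A → B → leachate, plant uptake
from the O-horizon with litter returned to it, and a residual edge
moss → loss. Each node of the resolution order (B, A, plants, O, moss) has
exactly one unknown incident edge, so the ledger solves in one bottom-up
pass from the node balances *inflow − outflow = Δ*; the residual absorbs
whatever the measured compartments cannot account for and is interpreted
as gaseous loss from the moss layer. Two consequences of this design are
worth stating plainly:

* upward transport in the soil profile (bioturbation) appears as a
  *negative* O → A flow rather than as an extra cycle — adding a return
  edge would make the one-pass system unidentifiable;
* a negative residual signals apparent creation of tracer (measurement
  noise) and is reported with a warning, never clamped.

How uptake and litter return were partitioned when the original flow
schematic was drawn is not documented; the resolution order used here is
one consistent choice and is validated against the simulator, where the
true flows are known. Published bold flow numbers in such schematics are
figure content and are not used as ground truth anywhere in the package.

## The enrichment trend model

Per-plot enrichments, stratified into five main compartments
(above-ground biomass, moss, O, A, B), follow a gamma generalized additive
mixed model with log link:

$$EN_{ij} \sim \Gamma\!\big(\text{mean} = \exp(\alpha + f(t_{ij}) +
\beta\,C_{ij} + b_i)\big),$$

with a plot random intercept $b_i \sim N(0, \sigma_b^2)$ and AR-1
correlated residuals within a series. Design choices:

* **Fixed-df spline.** The time effect is a cubic regression spline with
  four degrees of freedom, implemented as an *unpenalized* basis (knots at
  quantiles, centering constraint absorbed). A fixed df is stated by the
  study design; removing penalization turns the GAMM into a parametric
  gamma GLMM and removes smoothing-parameter selection that the original
  analysis does not describe. A penalized variant is out of scope.
* **AR-1 per plot × compartment series.** With five compartments measured
  per plot and year, a single per-plot chain is ill-defined (duplicate
  time points). The chain is therefore nested in plot × compartment and
  ordered by year, the standard reading of "AR-1 nested within plot" for
  such layouts. It enters as a latent Gaussian AR-1 process on the linear
  predictor with marginal SD `sd_resid` and correlation `rho`.
* **Estimation.** Laplace-approximated likelihood via `glmmTMB`:
  maximum likelihood for model comparison, REML for reported estimates —
  the same division of labour as the original workflow. "REML" for a
  gamma GAMM is software-specific; here it means glmmTMB's restricted
  likelihood (fixed effects integrated out), which is a likelihood-level
  definition, not a claim of equivalence to any other package. Boundary
  fits (AR-1 SD collapsing to zero) are kept with their convergence
  diagnostics recorded; only non-finite estimates raise an error. A
  failed `nlminb` step is retried once with BFGS.
* **Offset.** 0.001 is added to the enrichment response so that exact
  zeros are admissible under the gamma likelihood.
* **Outlier rule.** "Visual screening of dotplots" is not reproducible,
  so the package uses fences at Q3 + 3 IQR (Q1 − 3 IQR) within
  compartment, removing at most 2 % of the data, most extreme first, with
  a written report of every removal.
* **Adjusted R².** Computed on the link scale against the intercept-only
  predictor and explicitly approximate — the original table's R² is not
  defined in its methods, and no attempt is made to match it.
* **Model selection.** The four candidates (time, compartment,
  time + compartment, time × compartment) are compared by AIC with Akaike
  weights $w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$. Candidates that
  fail to converge are excluded with a warning and weights renormalised.

## What the simulator emulates — and what it does not

`simulate_tracer_fate()` is an annual discrete-time, first-order transfer
model: the pulse enters the moss at time zero, each compartment exports
fixed rate fractions per year along the flow topology, and losses
accumulate in absorbing nodes. Sampling was annual in the field, so an
annual map is the natural resolution — a continuous-time ODE with more
structure would not be identifiable from annual data and was rejected.
Per-plot heterogeneity is a lognormal jitter (SD 0.15 on the log scale) of
the transfer rates; measurement error is Gaussian on the delta scale
(SD 0.5 ‰ by default), because isotope-ratio mass spectrometry error
lives on that scale, not on the mass scale.

The default rates (moss → O 0.15, moss → loss 0.17, O → A 0.02,
O → plants 0.03, A → B 0.05, plants → litter 0.40, litter → O 0.70,
B → leachate 0.002 yr⁻¹) were chosen once so the simulated trajectories
echo the decadal field pattern — roughly two-thirds of the dose in the
moss at first sampling falling to about a seventh within four years, the
O-horizon climbing towards ~40 % of the dose by year eight, and more than
30 points of unattributed loss in the first five years. They are a
qualitative template, not a fit to any published table. The pool-mass
table shipped for tests (`synthetic_pool_table()`) is likewise synthetic:
plausible magnitudes for a sandy podzol heathland (moss ≈ 8.5, O ≈ 70,
mineral horizons > 150 g N m⁻²), since the field study's pool masses come
from prior work and are not printed. Natural-abundance baselines are set
per compartment (moss ≈ −6 ‰, B-horizon ≈ +7 ‰), matching the realistic
ordering of deltas down the profile.

What the simulator deliberately does *not* contain: microbial
immobilisation dynamics, weather-driven year effects, isotope
fractionation during denitrification, within-year dynamics, or root
uptake below 15 cm. Passing round-trip tests on simulated data therefore
demonstrates the *internal consistency* of the pipeline (measurement
inversion, mass balance, flow identifiability) — not that the first-order
model is an adequate description of any real heathland.

`simulate_enrichment_glmm()` draws from the trend model itself: plot
intercepts, an AR-1 chain per series, and a gamma response around
`exp(eta)`. The gamma shape defaults to 50 (log-scale CV ≈ 0.14), so the
stated residual chain SD of 0.439 dominates the within-series variation
and the variance components remain identifiable at the field design size
of 7 plots × 9 years × 5 compartments; `shape = Inf` gives the
deterministic mean, which the reduced-model tests use. Per-compartment
time effects are centered across the design years so that the intercept
retains its meaning regardless of the trend shapes.

## Numerical contracts

The test suite pins down the numerical behaviour the package promises:
delta ↔ ratio ↔ atom-percent round-trips to 1e-12 relative; simulator
mass conservation to 1e-9; noise-free simulate → measure → recover
inversion to 1e-9; ledger closure at every node to 1e-9; Akaike weights
summing to one to 1e-12. Replicate studies run at the field design size:
200 replicates for intercept recovery (the REML mean must sit within two
Monte-Carlo standard errors of the generating value 3.941) and 100
replicates for model selection (the interaction model must reach Akaike
weight > 0.99 in at least 90 % of replicates). Those sizes keep each
study in the minutes range on a single core while leaving the Monte-Carlo
error well below the effects being checked.

## Known limitations

* Flow inference yields point flows only; no uncertainty is propagated
  (the source analysis presents point flows as well).
* The one-pass topology cannot represent true cycles; persistent upward
  soil transport would need a different estimator.
* REML/ML here are Laplace approximations; at 7 plots the plot-intercept
  SD is estimated with substantial sampling error, and boundary fits do
  occur — they are reported, not hidden.
* Printed group means can only be processed in `mean_of_deltas` mode;
  plot-level standard errors cannot be reconstructed from them.
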