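---
title: "Competing explanations for marine diazotrophs in a global box model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing explanations for marine diazotrophs in a global box model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Diazotrophs fix dinitrogen and therefore do not depend on ambient nitrate,
but they grow more slowly than ordinary phytoplankton. Under these two
assumptions alone, their niche is the water that is low in bioavailable
nitrogen relative to phosphorus — essentially the surface expression of
denitrification zones — and their own fixation shrinks that niche by
topping the nitrogen deficit back up. Observed diazotroph distributions
(e.g. abundant *Trichodesmium* in the oligotrophic subtropical North
Atlantic) do not look like that, which suggests an additional competitive
advantage. Two candidates from the literature are:

* **selective grazing** — zooplankton partly avoid diazotrophs
  (preference $\theta_d < \theta_o$), and
* **high-affinity phosphate uptake** — a lower half-saturation constant
  for phosphate ($k_P^d < k_P$).

`diazocomp` implements a deliberately small global model in which these
two paradigms can be given equal contemporary skill and then pushed into a
warming scenario, where they diverge. The package also contains the misfit
and bloom diagnostics used to compare such model versions with
observation-like fields, and a synthetic observation generator so that
every diagnostic can be exercised against known ground truth.

## Model structure

The ocean is 16 columns (8 latitude bands × 2 basins, Atlantic-like and
Indo-Pacific-like) of two layers each (100 m surface, 3600 m deep),
totalling a realistic $3.6\times10^{14}\,\mathrm{m^2}$ and
$1.3\times10^{18}\,\mathrm{m^3}$. Each column carries six tracers per
layer: NO$_3$, PO$_4$, ordinary phytoplankton $P_O$, diazotrophs $P_D$,
zooplankton $Z$ and detritus $D$ (biomass in nitrogen currency,
mmol N m$^{-3}$). Columns exchange water vertically (piston velocities
standing for upwelling/ventilation: vigorous at the poles and tropics,
0.8–2.4 m yr$^{-1}$ in the subtropical gyres) and laterally with their
neighbours; the basins connect through the circumpolar band.

Growth follows Liebig's law of the minimum over light and nutrients with
Monod (saturating) terms,

$$J_O = \min\!\left(J_{IO},\; J_O^{max}\frac{NO_3}{k_N+NO_3},\;
        J_O^{max}\frac{PO_4}{k_P+PO_4}\right),$$

and diazotroph growth is the same construction without the nitrate term,

$$J_D = \min\!\left(J_{IO},\; J_D^{max}\frac{PO_4}{k_P^d+PO_4}\right),
  \qquad J_D^{max} = C_d\,J_O^{max},$$

shut off entirely below 15 °C. Grazing is linear in prey,
$G = \mu_{max}\,Z\,\theta\,P$ with $\mu_{max}=0.4\,\mathrm{d^{-1}}$; this
is the printed form of the multiple-prey functional response, and an
optional saturating denominator
$1+(\theta_o P_O+\theta_d P_D+\theta_{det} D)/k_{graze}$ is available
behind the `holling_saturating` flag (default off). Losses are linear;
detritus remineralizes in both layers and sinks from surface to deep; in
the three deep boxes flagged as oxygen-minimum-zone sources (tropical
Indo-Pacific in both hemispheres and tropical Atlantic) a fraction
`f_denit` of remineralized nitrogen is removed — the nitrogen sink.
Iron limitation is a static mask that scales the maximum growth rates in
the polar bands. Phosphorus is exactly conserved; nitrogen changes only
through fixation and denitrification, and the tests hold the model to
both budgets (1e-10 relative and better).

**Nitrogen sourcing by diazotrophs.** Diazotrophs draw ambient nitrate
first and fix only the remainder of their nitrogen demand; the fixed
fraction is $(k_N/(k_N+NO_3))^{h}$ with sharpness $h$ (`fix_pow`,
default 2). The quadratic exponent makes fixation shut down decisively
once nitrate fills in. This matters: with a gentler switch ($h=1$),
diazotrophs in nitrate-rich water keep fixing a few percent of their
demand, the ocean accumulates nitrogen for tens of millennia and the
high-affinity configuration never reaches quasi-equilibrium; with $h=2$
every configuration equilibrates within ~5000–7500 model years while the
closure argument (fixation fills the deficit, the niche shrinks) is
unchanged.

## Experiments

`build_config()` encodes the paradigms as parameter relations and rejects
overrides that violate them:

| experiment | relations | denitrification |
|---|---|---|
| CONTR | $\theta_d=\theta_o$, $k_P^d=k_P$ | on |
| GRAZ  | $\theta_d=0.1<\theta_o=0.3$, $k_P^d=k_P$ | on |
| OLIGO | $k_P^d=0.012<k_P=0.044$, $\theta_d=\theta_o$ | on |
| DECAY | as CONTR | **off** |

`spinup_to_equilibrium()` integrates in 200-year blocks until the drift
of global fixation, diazotroph biomass and the nitrogen inventory falls
below 0.1 % per century (cap 9000 years, reported honestly if missed).
The warming scenario (`run_scenario()`) raises surface temperature by
4 °C and scales the vertical exchange by up to −50 % along a normalized
quadratic ramp from 1800 to 2150 — a minimal proxy for the
stratification increase of a high-emission trajectory. The temperate
bands sit at 13–13.5 °C, so the warming also opens new diazotroph habitat
in mid-century, as warming does at the poleward edge of the real habitat.

## Parameters

Printed, field-standard values: $\mu_{max}=0.4\,\mathrm{d^{-1}}$,
$\theta_o=0.3$, $\theta_d=0.1$ (selective grazing), the 15 °C cutoff, the
Redfield ratio 16, the chlorophyll conversion 1.59 mg Chl a per mmol N
and the oligotrophy threshold 0.07 mg Chl a m$^{-3}$. $k_P=k_N/16$ with
$k_N=0.7$ mmol N m$^{-3}$ ties the phosphate half-saturation to its
nitrogen equivalent; note that the implied $k_P^d$ range of width 0.044
is the one whose 20 % step is 0.0088, the reference step of the
sensitivity scans (`sensitivity_scan()` also uses 0.02 as 20 % of the
$\theta_d$ range 0.1).

Everything else is a package calibration constant, chosen once so that
the model is a defensible miniature ocean, and documented here rather
than attributed to any external source: mortality 0.03 d$^{-1}$,
zooplankton assimilation 0.7, excretion 0.004 d$^{-1}$ and mortality
0.006 d$^{-1}$ (low specific losses so that zooplankton exert real
top-down control at realistic prey densities), detritus remineralization
0.03 (surface) and 0.005 (deep) d$^{-1}$, sinking transfer 0.10 d$^{-1}$,
denitrified fraction 0.15, growth handicap $C_d=0.5$. The handicap is the
load-bearing choice: at $C_d=0.5$ a selectively grazed diazotroph
($\theta_d=0.1$) still cannot out-compete ordinary phytoplankton for
phosphate in the pre-industrial tropics, so the GRAZ configuration keeps
a small standing stock confined to the denitrification-fed columns —
while under warming, as productivity and grazers decline, the same
configuration crosses its invasion threshold and blooms before declining
again. A milder handicap lets GRAZ diazotrophs invade everywhere
immediately and erases the contrast between the paradigms that the
contemporary ocean actually shows.

The circulation constants double as calibration of the niche-drainage
timescale: with the default ventilation the pre-industrial equilibrium
holds an excess-phosphorus inventory whose ratio to the fixation rate is
close to 1100 years, so that the DECAY experiment, rescaled to the
canonical 5.5 Pmol N inventory, starts near the low-end global fixation
estimate of 70 Tg N yr$^{-1}$.

## The DECAY experiment and its timescale

`run_decay_experiment()` is the full pipeline: spin CONTR to
quasi-equilibrium; rescale the dissolved phosphate deficit field by a
single factor so the global excess-P inventory in nitrogen equivalents is
exactly 5.5 Pmol N (`rescale_excess_p()` — scaling the deficit rather
than adding phosphate uniformly preserves the spun-up geography of the
niche and avoids a spurious surface bloom); switch denitrification off;
integrate 1500 years; fit a log-linear decline to the global diazotroph
biomass over years 101–1500. The analytic expectation is
`niche_closure_timescale()`: inventory over rate, 1100 years at
70 Tg N yr$^{-1}$ and 385 (≈400) years at 200 Tg N yr$^{-1}$. The
simulated decline is exponential to $R^2>0.99$ with an e-folding time
about 15 % above 1100 years — the rescaled inventory partly sits in
slowly ventilated gyre and polar reservoirs that drain through the deep
circulation — and the acceptance test holds it within 25 %.

## Numerical choices

Fixed-step classical RK4 with `dt = 0.5` days (which divides the 365-day
model year exactly); the right-hand side is implemented twice, once in
readable R (`tendencies()`, `step_state()`) and once in C++ for the
multi-millennial integrations, and the two are held equal to 1e-12 in the
tests. Halving the step changes a one-year trajectory by less than
1e-6 relative. Limitation terms clamp concentrations at zero inside
Runge–Kutta stages; after each step, negative excursions smaller than
`clip_eps` (1e-5 mmol m$^{-3}$) are clipped to zero with the clipped mass
logged, and anything larger is a hard error advising a smaller step — at
the default step no clipping occurs in any shipped experiment. Annual
diagnostics accumulate fluxes with the RK4 quadrature weights, which is
why the nitrogen budget closes to solver precision in the tests. Spin-up
drift is measured on 20-year means at the ends of each 200-year block.
Problem sizes throughout (16 columns, 1500-year DECAY, 350-year
scenarios, ~5000–7500-year spin-ups) were chosen as the smallest runs on
which the analysis is stable; the whole test suite and the acceptance
script each run in a couple of minutes on one core.

## Synthetic observations

`generate_obs_field()` emulates the statistical character of the global
fixation and biomass data products this kind of model is compared
against: a sum of Gaussian hotspots with lognormal amplitudes inside a
warm band (|lat| ≤ 40°, the synthetic counterpart of the 15 °C habitat
constraint), hard zeros outside, thinning of the smallest in-band values
to a prescribed overall zero fraction, and mean-one lognormal
multiplicative noise — patchy, positively skewed, mostly empty, with the
noise-free truth returned alongside. `sample_sparse_points()` and
`regrid_to_model()` mimic anecdotal shipboard sampling and its gridding
(nearest cell, cell-mean, unobserved cells masked). What the generator
does **not** emulate: spatial correlation of the noise, seasonal
aliasing, depth structure (biomass is generated directly as an upper-100 m
inventory in mg C m$^{-2}$), or the abundance biases of nifH-based
counts. Tests passing against these fields therefore show that the
diagnostics are computed correctly on data of the right statistical
shape, not that the model matches any real data product.

Diagnostics conventions, where the literature leaves a choice open:
"upper 10 percentiles" is read as the 90th percentile of positive cell
values with linear interpolation (the mean of the top decile is available
behind a flag); the RMSE misfit is unweighted by area (an area-weighted
variant exists); units are mandatory on every field and mismatched units
are an error, never a silent conversion; the biomass-to-fixation ratio is
flagged undefined in years without fixation. Carbon conversion uses
Redfield 106:16 and 12 g mol$^{-1}$.

## What the warming projections show, and their limits

At pre-industrial equilibrium all three versions fix 42–45 Tg N yr$^{-1}$
(balanced against denitrification), but their standing stocks differ by
an order of magnitude: OLIGO holds ~134 Tg C spread into the oligotrophic
gyres, GRAZ ~21 Tg C and CONTR ~14 Tg C confined near the
denitrification-fed columns, so the biomass:fixation ratio separates the
paradigms (≈3.0 vs ≈0.5 Tg C per Tg N yr$^{-1}$) even where fixation
alone cannot. Under the warming ramp the oligotrophic area fraction
doubles between 2000 and 2100 (0.105 → 0.21), OLIGO biomass rises while
OLIGO fixation eventually falls, and GRAZ rises then declines in both
variables — the qualitative divergence that makes the ambiguity of the
underlying controls a projection problem.

Two behaviours of spatially explicit, seasonally resolved models do not
transfer to a closed 16-column model and are reported as such rather than forced:
equilibrium **fixation** is pinned by the global nitrogen budget, so
parameter sensitivity expresses itself almost entirely in biomass (both
paradigms respond strongly and nonlinearly there, with regime boundaries
near $\theta_d \approx 0.06$ and $k_P^d \approx 0.02$); and diazotrophs
outside the flagged columns never vanish completely — the nitrogen
deficit itself spreads through the deep circulation — so the
"all diazotrophs retreat to the upwelling regions" collapse appears as a
smooth decline rather than a detectable 1 % tipping point. Other known
limitations: no seasonality by default (the light field accepts a
seasonal sinusoid, but the shipped experiments run annual-mean), no
prognostic iron or oxygen, prescribed denitrification locations, and a
single generic zooplankton whose linear functional response admits
limit-cycle behaviour in the polar boxes (annual means remain steady).
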