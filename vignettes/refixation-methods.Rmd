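---
title: "Methods: estimating CO2 refixation from A/Ci curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating CO2 refixation from A/Ci curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mitochondria in illuminated mesophyll cells release CO2 continuously through
respiration and photorespiration. A molecule released in the cytosol either
diffuses back into a chloroplast and is carboxylated again ("refixed"), or it
escapes through the cell wall, the intercellular airspace and the stomata.
The fraction refixed, `P_r`, is set by the relative diffusion resistances of
the two pathways, so leaves with high mesophyll resistance (`r_m`) and high
stomatal resistance (`r_s`) — typically evergreen, late-successional
species — are expected to recycle more of their own respired CO2. This
package estimates `P_r` per leaf from a standard A/Ci gas-exchange curve and
provides the comparative statistics to test those expectations across
species, functional types and seasons.

## Forward model

Net assimilation follows the biochemical model of C3 photosynthesis: the
gross rate is the minimum of a Rubisco-limited, an RuBP-regeneration-limited
and a triose-phosphate-use-limited rate, evaluated at the chloroplast CO2
partial pressure `Cc`,

* Rubisco:  `A = Vcmax (Cc - G*) / (Cc + Kc (1 + O/Ko)) - Rd`
* RuBP:     `A = (Jmax/4) (Cc - G*) / (Cc + 2 G*) - Rd`
* TPU:      `A = 3 TPU - Rd`

with `Cc = Ci - rm * A`. Substituting the drawdown into the two
substrate-saturating forms yields a quadratic in `A`; the lesser root is the
physical branch (it collapses to the explicit formula as `rm -> 0`, which is
also how it is tested, together with a bisection oracle on the implicit
equation).

All computations are at the 25 degree C block temperature of the measurement
protocol; no temperature response is modelled, and the leaf-temperature field
of the data format is carried but unused. The kinetic constants default to
the widely used tobacco-derived values at 25 degrees C (`Kc` = 27.2 Pa,
`Ko` = 16.6 kPa, `G*` = 3.74 Pa, `O` = 21 kPa) and are configurable; the
source study does not print the constants its fitting service used.

Units: pressures in Pa (mole fractions converted per record as
`ppm * 1e-6 * P`), rates in umol m-2 s-1, resistances in m2 s Pa umol-1
(pressure-based, because intraleaf diffusion follows partial-pressure
gradients); the molar-to-pressure conversion is `r[Pa] = P * 1e-6 * r[molar]`.

## Refixation model

The released CO2 at cytosolic partial pressure `x_py` feeds two competing
fluxes: escape, proportional to `x_py / (r_wp + r_sc)` (cell wall + plasma
membrane, then stomata), and refixation, proportional to
`x_py / (r_ch + k^-1)` (chloroplast envelope, then the carboxylation
reaction itself, `k^-1 = Cc / Vc`). The refixed fraction is the refixation
flux over the total,

`P_r = (1 + (r_ch + k^-1) / (r_wp + r_sc))^-1`,

in which `x_py` cancels. This is the "one minus escape fraction" definition;
it increases with the outward resistances and decreases with the
chloroplast-side resistances, which is the directional behaviour the
comparative analysis tests. (A one-line algebraic "simplification" of this
formula circulating in the literature swaps the two resistance sums and
thereby computes the escape fraction instead; we implement the definitional
flux-ratio form, which is also the only form consistent with the observed
positive `P_r`-`r_m` relationship.)

Two quantities in the chain are not observable from gas exchange alone:

* the split of `r_m` into wall (`r_wp`) and chloroplast (`r_ch`) components.
  It is exposed as `phi_wall` (`r_wp = phi_wall * rm`), default 0.5, and kept
  in the fit table so `P_r` can be recomputed for any split without
  refitting (`refix_table()`);
* the operating point. Following the measurement convention that stomatal
  resistance is reported at the first 400-p.p.m. record, the whole chain
  (`Cc`, `Vc`, `k^-1`, `r_sc`) is evaluated at that record.

## Inverse problem

Each curve is fit independently (no hierarchical pooling). Because the three
limitation states partition the Ci axis in a fixed order
(rubisco -> rubp -> tpu), the fitter enumerates every contiguous
segmentation of the Ci-sorted points — boundaries
`min_rubisco <= b1 <= b2 <= n`, empty upper segments allowed, 45
segmentations for the default `n = 10, min_rubisco = 2` — and solves a
bounded nonlinear least-squares problem per segmentation, each point
evaluated under its assigned state. The selected fit is the minimum-SSE
*admissible* one, where admissible means every point's assigned state
attains the minimum of the three candidate rates within `tol_admiss`
(1e-6 umol m-2 s-1, relative above 1 umol m-2 s-1); ties break toward fewer
active states, then the smaller Rubisco boundary. If no admissible fit
exists the overall minimum-SSE fit is returned flagged inadmissible.

Numerical choices:

* optimizer: `nlminb` (bounded quasi-Newton) over
  `(Vcmax, Jmax, TPU, Rd, rm)` with bounds (1, 500), (2, 1000), (0.1, 200),
  (0.01, 20), (0, 10); the SSE kernel is compiled (the R forward model stays
  the reference path and the tests assert kernel/R equivalence);
* deterministic multi-start: if the first start fails, fixed jitter
  multipliers (0.5, 2, 1.25) are applied to the heuristic start — no RNG in
  the fitting path;
* initialization: `Rd` from the negated intercept through the two lowest-Ci
  points, `Vcmax` from a zero-`rm` one-point inversion, `Jmax` from the
  high-Ci plateau, `TPU = (plateau + Rd)/3`, `rm = 0.05`, all clamped to
  bounds, fixed defaults for degenerate curves;
* a state with no assigned points leaves its parameter (`Jmax` or `TPU`)
  unidentifiable; it is frozen at its upper bound and reported in `frozen`
  rather than left to wander;
* records whose `A` sits more than 5 robust-sd (MAD with a floor of
  0.05 umol m-2 s-1, the typical analyser repeatability) from a running
  median are flagged, never dropped;
* infeasible parameter probes (no positive-`Cc` root) receive a large finite
  penalty so bounded optimization continues smoothly.

## Synthetic study generator

No raw data accompany the source study, so the package ships a generator
that emulates its design: 6 woody species (two deciduous broadleaves, one
deciduous conifer, two evergreen conifers, one evergreen broadleaf shrub;
four primary- and two climax-successional), 3 seasons, 9 replicate branches
per cell (the protocol used 8-10), and the 10-step reference-CO2 sequence
400, 300, 200, 100, 50, 400, 600, 800, 1000, 1200 p.p.m. at irradiance
1000 umol m-2 s-1 and 101325 Pa. For each sample, parameters are drawn from
species profiles, the curve is generated by balancing stomatal supply
against biochemical demand (`Ci = Ca - A/gsc`, stomatal conductance held
constant across steps), and Gaussian noise of sd 0.2 umol m-2 s-1 (typical
infrared gas-analyser repeatability; the study states no error model) is
added to `A`.

Profile choices, made once and frozen:

* `Vcmax` means 40-65 umol m-2 s-1 across species with
  `Jmax ~= 1.6 Vcmax` and `TPU ~= Jmax/14`; these conserved ratios keep all
  three limitation states expressed on the measured grid, which the study
  design implies (all of `Vcmax`, `Jmax` and TPU were estimated from every
  curve) and which makes all five parameters identifiable. Capacities
  co-scale within a sample through a shared latent factor (correlation 0.8).
* `rm` and `gsw` per species were calibrated so the *emergent* mean `P_r`
  at the 400-p.p.m. operating point approximates the magnitudes reported
  for these species (about 42/36/42/41/55/60% for birch, oak, larch, pine,
  spruce, lingonberry) — calibration targets for pipeline testing, not
  ground-truth claims.
* cell-wall thickness and airspace-fraction means and sds use the printed
  per-species values where available; LMA and water content use
  field-realistic values for the functional types.
* `rm`, LMA and cell-wall thickness share a latent leaf-construction factor
  (pairwise correlation 0.5): the generator *states* the trait structure the
  downstream regressions are designed to detect.
* season multipliers lower photosynthetic capacity and LMA early in the
  season, raise water content early, and lower stomatal conductance late;
  `rm` is season-constant, mirroring the absence of a season signal on it.

A single master seed controls everything; each sample uses a derived
substream (`(seed * 1009 + 7919 * index) mod 2^31 - 1`), so outputs are
byte-identical regardless of evaluation order.

What the generator does **not** emulate: stomatal kinetics across CO2 steps,
temperature/VPD covariation, instrument drift, leaks or match offsets,
curve-to-curve operator differences, or any anatomical mechanism linking
`r_m` to wall thickness (the correlation is imposed, not derived). A green
round-trip test therefore establishes that the estimator inverts the model
class it assumes, and that the statistics recover structure of the stated
kind and size — not that the estimator is robust to instrument pathologies
absent from the generator.

## Statistics

* Two-factor ANOVA (species + season, no interaction, matching the reported
  two-column layout) with Type II sums of squares — each factor adjusted for
  the other, appropriate for the unbalanced real design and identical to the
  sequential decomposition under balance (both are available and tested
  against a hand-worked decomposition). Residual normality is screened with
  Shapiro-Wilk at 0.05; on rejection, strictly positive responses are
  log-transformed, others rank-transformed (the study says only that data
  were transformed where necessary). Zero-residual-variance layouts take
  explicit guards (`F = 0, p = 1` when the effect is also zero; `F = Inf,
  p = 0` otherwise).
* Tukey HSD on one-way layouts with a compact letter display: letters are
  the maximal cliques of the non-significance graph, so sharing a letter is
  exactly equivalent to a non-significant pairwise difference; "a" goes to
  the lowest-mean clique and the order is deterministic.
* Nested OLS models `Pr ~ rm`, `Pr ~ rm + rs`, `Pr ~ rm + rs + LMA`
  (estimate, t, p, intercept, residual df, adjusted R2, model F), plus
  pooled and per-species simple regressions of `Pr` on each trait.
  Coefficients are tested against the normal-equations closed form;
  rank-deficient terms are dropped with a warning.
* Trait columns measured on subsamples (airspace fraction, wall thickness)
  are analysed pairwise-complete, never imputed.

## Known limitations

* C3, steady-state, 25 degrees C only; no fluorescence co-fitting, no
  confidence intervals (point estimates per curve, as in the source
  analysis).
* `P_r` inherits the arbitrariness of `phi_wall`; report it alongside, or
  sweep it with `refix_table()`.
* `rm` is weakly identified from 10-point curves; under realistic noise its
  per-curve error is materially larger than for `Vcmax`/`Jmax` (the
  acceptance suite bounds the median errors at 30% vs 10%).
* The segmentation enumeration assumes contiguous limitation states along
  Ci, which holds for the standard parameterization but is asserted, not
  proven, for every fitted parameter combination.
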