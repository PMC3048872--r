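---
title: "Two-state analysis of protein thermal denaturation with dscfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state analysis of protein thermal denaturation with dscfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscfit)
```

## The problem

Differential scanning calorimetry (DSC) measures the heat capacity of a
protein solution as temperature is ramped; unfolding appears as an
endothermic peak. Two independent enthalpy estimates come out of one
scan: the *calorimetric* enthalpy $\Delta H$ (the area under the excess
heat-capacity peak) and the *van't Hoff* enthalpy $\Delta H^{VH}$ (from
the sharpness of the transition). Their ratio diagnoses the unfolding
mechanism: $\Delta H/\Delta H^{VH} \approx 1$ (conventionally 0.8–1.2)
indicates a two-state transition of the monomer.

A second, structure-based route predicts what the enthalpy *should* be
if the protein unfolded completely: empirical correlations map the
change in apolar and polar solvent-accessible surface area
($\Delta ASA$) between the folded structure and an extended unfolded
reference onto $\Delta C_p$ and $\Delta H$. When the measured
$\Delta H$ falls far below this prediction, a substantial amount of
ordered structure persists in the thermally denatured state. `dscfit`
implements both routes, plus CD melt fitting and ligand-linked
thermal-shift analysis, behind one consistent set of fitting functions.

## The two-state model

With $K(T) = \exp\!\left[\frac{\Delta H^{VH}}{R}\left(\frac{1}{T_m} -
\frac{1}{T}\right)\right]$ the equilibrium constant of unfolding
($T$ in kelvin, $R = 1.9872$ cal mol$^{-1}$ K$^{-1}$), the unfolded
fraction is $\theta = K/(1+K)$ and the excess molar heat capacity is

$$C_p^{ex}(T) \;=\; \frac{\Delta H \,\Delta H^{VH}\, K}
{R\,T^2\,(1+K)^2}.$$

Because $C_p^{ex} = \Delta H \, d\theta/dT$, the curve integrates to
$\Delta H$ exactly and peaks (at $K = 1$, i.e. essentially at $T_m$) at
$\Delta H \Delta H^{VH} / (4 R T_m^2)$ — both identities are enforced
as tests. Equal calorimetric and van't Hoff enthalpies are *not*
assumed; the two are independent parameters, and their ratio is the
cooperativity diagnostic.

The model contains no $\Delta C_p$ step between the folded and unfolded
trends: that step is part of the *chemical baseline*, which is removed
before fitting (below). Public interfaces use °C and kcal/mol; kelvin
and cal/mol appear only inside the exponentials.

```{r model}
apo <- two_state_params(tm = 62.5, dh_cal = 111.6, dh_vh = 96.3)
two_state_excess_cp(62.5, apo)   # peak height, kcal/mol/K
vant_hoff_ratio(apo)
```

## From raw scan to excess heat capacity

`subtract_reference()` removes the buffer-buffer scan (linear
interpolation onto the sample grid, no extrapolation), `to_molar()`
divides by the moles of protein in the cell (concentration × cell
volume; the default simulated metadata uses a 0.527 mL cell and low
micromolar protein), and `remove_chemical_baseline()` removes the
smooth trend beneath the peak.

The baseline algorithm is a *progress baseline*: linear trends are
fitted in a pre-transition and a post-transition window (defaults: the
lowest and highest 15% of the grid, configurable), and the baseline in
between is the blend $(1-\alpha)\,b_{pre}(T) + \alpha\,b_{post}(T)$,
where $\alpha(T)$ is the extent of conversion estimated from the
running integral of the positive excess signal. Since $\alpha$ depends
on the excess and the excess on the baseline, the construction is
iterated (≤ 20 rounds, relative tolerance $10^{-6}$; non-convergence
returns the last iterate with a warning). The first iterate connects
the window edges with a cubic Hermite segment matching value and slope
of both trends. This is standard DSC practice for the "chemical
baseline" step; it is validated by injection/recovery: a simulated
curve with a known baseline must give it back within 1% of the peak
height, and the excess must still integrate to the injected
$\Delta H$ within 2%.

## Fitting

All three fits (`fit_two_state()`, `fit_cd_melt()`,
`fit_titration()`) use bounded Levenberg–Marquardt least squares
(`minpack.lm`), tolerance $10^{-10}$, at most 500 iterations, started
from data-driven guesses; they return a classed object with `coef`,
`summary`, `predict`, `residuals`, `plot` and `simulate` methods.
Standard errors are Gauss–Newton estimates from a central-difference
Jacobian at the optimum; a numerically singular Jacobian (an
unidentifiable parameter, e.g. $K_d$ from a flat titration) reports
infinite uncertainty rather than a misleading number. Scan-rate
metadata never enters any fit — the analysis is an equilibrium one, so
two scans differing only in recorded rate give bit-identical results.

The DSC initial guess takes $T_m$ from the peak position (plateau ties
broken toward the lowest temperature), $\Delta H$ from the trapezoidal
area, and $\Delta H^{VH}$ by inverting the peak-height identity.

```{r fit}
tg <- simulate_thermogram(apo, noise_sd = 0.1, seed = 42)
fit <- fit_two_state(tg)
summary(fit)
```

## CD melts and thermal shifts

A CD melt is modelled as the population-weighted average of linearly
sloping native and denatured baselines, with its *own* apparent
midpoint and apparent van't Hoff enthalpy — deliberately not tied to
the DSC parameters, because optical and calorimetric probes can report
different apparent midpoints for the same protein (here they differ by
several degrees), and the package reports both without reconciling
them.

Ligand-induced stabilization is modelled by single-site linkage to the
native state with a temperature-independent dissociation constant
referenced to $T_{m,0}$:
$$\frac{1}{T_{m,0}} - \frac{1}{T_m(L)} =
\frac{R}{\Delta H_0}\,\ln\!\left(1 + \frac{L}{K_d}\right),$$
solved in closed form. This is the simplest model consistent with a
monotone semi-log titration; the unfolding $\Delta C_p$ is omitted
from the relation, and $\Delta H_0$ is fixed to the calorimetric value
supplied by the caller because it is not identifiable from the shift
curve alone. On a semi-log plot the curve is flat below $K_d$ and
turns upward (convex in $\ln L$) above it; it does not saturate. The
default validation scenario uses $T_{m,0} = 62.5$ °C,
$\Delta H_0 = 111.6$ kcal/mol and $K_d = 8\,\mu$M, which places a
~10 °C stabilization at a saturating (mM-scale) ligand concentration.

## Structure-based energetics

`shrake_rupley_asa()` computes solvent-accessible surface areas with
the Shrake–Rupley point-counting method on a deterministic
golden-spiral lattice (default 960 points/atom, probe 1.4 Å), so
results are bit-reproducible; it is cross-checked against a
Monte-Carlo rejection-sampling oracle in the tests. Heavy atoms only;
radii C 1.70, N 1.55, O 1.52, S 1.80 Å from a plain-text constants
table. Carbon and sulfur surface counts as apolar, nitrogen and oxygen
as polar. `parse_structure()` reads PDB ATOM records (first model
only) via `bio3d`, excluding waters always and other HETATM groups
(bound nucleotides) by default, resolving alternate locations by
highest occupancy with ties to altloc A.

The unfolded reference sums per-residue extended Gly-X-Gly tripeptide
accessibilities from a shipped table (totals follow the classic
extended-tripeptide scale; the apolar/polar split follows the
heavy-atom element convention). The energetics correlations are then

$$\Delta C_p = (0.45\,\Delta ASA_{ap} - 0.26\,\Delta ASA_{pol})/1000
\quad \text{kcal K}^{-1}\text{mol}^{-1},$$
$$\Delta H(60\,°C) = (31.4\,\Delta ASA_{pol} -
8.44\,\Delta ASA_{ap})/1000 \quad \text{kcal/mol},$$

with Kirchhoff extrapolation $\Delta H(T) = \Delta H(60) +
\Delta C_p\,(T-60)$. The coefficients were verified, before being
pinned in the source, to reproduce the published per-structure
$\Delta C_p$ and $\Delta H$ values from their $\Delta ASA$ inputs
within printed rounding. Recomputing $\Delta ASA$ from the original
PDB entries is a documented optional workflow, not a promise: the ASA
program, radii and unfolded reference behind published $\Delta ASA$
tables are typically unspecified, so the pipeline takes $\Delta ASA$
values as input. The residual-structure index
$\Delta H_{exp}/\Delta H_{calc}$ quantifies how much of the predicted
full-unfolding enthalpy is actually observed.

```{r energetics}
predict_energetics(dasa_ap = 18746, dasa_pol = 10598, tm = 71,
                   dh_exp = 120.4)
```

## What the synthetic data emulate — and what they do not

`simulate_thermogram()`, `simulate_cd_melt()` and
`simulate_titration()` generate data with exactly the statistical
structure the fits assume: the closed-form model evaluated on an exact
temperature grid plus iid Gaussian noise on the dependent variable
only, with the chemical baseline injected as the $\theta$-weighted
blend of linear folded/unfolded trends. Defaults mirror the target
acquisition conditions: a 15–95 °C scan at 0.1 °C spacing, 1.5 K/min
recorded scan rate, and noise $\sigma = 0.1$ kcal mol$^{-1}$ K$^{-1}$
— small against the ~12 kcal mol$^{-1}$ K$^{-1}$ peak, as in clean
instrument data. Every generator is a pure function of its arguments
and seed (default 0), leaves the caller's RNG stream untouched, and
carries its ground truth as an attribute.

What passing recovery tests therefore demonstrate is correctness of
the estimator under the model's own assumptions. Real thermograms
violate them in ways the generator deliberately omits: thermal
denaturation followed by aggregation is *irreversible*, so the
equilibrium parameters are apparent ones valid at the recorded scan
rate (symmetric transitions and a near-unity enthalpy ratio indicate
the kinetic distortion is small, and the fit itself is justified only
under those diagnostics); instrument drift is not white noise; and
exothermic aggregation can distort the post-transition region.
Kinetic (Lumry–Eyring) models, multi-state fits and aggregation
kinetics are out of scope.

`toy_structure()` supplies deterministic coordinate sets — an isolated
atom (analytic sphere area), a 100 Å-separated pair (no occlusion), a
caged atom (full occlusion), an idealized 20-residue poly-alanine
helix and a two-chain copy of it (additivity) — used to validate the
ASA engine where exact answers exist. The helix is geometrically
idealized (five heavy atoms per residue on coaxial cylinders), which
is sufficient for surface-area properties but is not a
stereochemically exact peptide.

## Numerical choices and problem sizes

* Optimizer: `nls.lm`, `ftol = ptol = 1e-10`, 500 iterations max;
  positivity enforced by bounds ($K_d$ via log-parameterization).
* Peak/argmax ties break toward the lowest temperature index.
* Enthalpy conservation is checked by trapezoidal quadrature on a
  0.02 °C grid spanning $T_m \pm 60$ °C (relative error < $10^{-3}$).
* The test suite uses 20-seed Monte-Carlo recovery studies for each
  published parameter set (and one 100-seed bias check on a coarser
  0.2 °C grid); ASA oracle comparisons use $10^6$ rejection samples
  for the deep 5-atom check and $2\times10^4$ for the property sweep.
  These sizes make the default suite run in well under a minute while
  holding the Monte-Carlo error far below the tolerances tested.
* Degenerate inputs are first-class: flat thermograms and edge peaks
  raise a no-transition condition; disjoint grids, missing metadata
  and malformed windows raise classed errors named for the failure.

## Known limitations

Irreversibility is diagnosed, not modelled; the linkage model assumes
one binding site with temperature-independent $K_d$, so multi-site
binding (two cyclic-nucleotide sites, for instance) is summarized by a
single apparent constant; the unfolded-reference table is an
approximation, which is why $\Delta ASA$ values, not structures, are
the canonical input to the energetics route; and mmCIF, multi-scan
averaging and native instrument formats are not read.
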