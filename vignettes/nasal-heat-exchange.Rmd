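---
title: "Modelling nasal heat and water exchange in coiled airways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nasal heat and water exchange in coiled airways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestibulum)
```

## The problem

Amniote nasal passages condition respired air: inspiration warms and
humidifies it on the way to the lungs, expiration recovers part of that heat
and water before the breath escapes.  Mammals and birds do this with
turbinates — scrolls that split the airstream into many narrow parallel
channels.  Ankylosaurian dinosaurs lacked respiratory turbinates but carried
extraordinarily elongated, coiled nasal vestibules.  `vestibulum` provides
the machinery to ask whether a single long, winding duct achieves the same
end: airway geometry containers and transforms, flow-regime diagnostics,
psychrometrics, breath-level caloric budgets, and a reduced-order exchanger
that predicts axial temperature and humidity profiles.

Everything operates on a 1D centerline abstraction: ordered stations with
arc position $s$, cross-sectional area $A$, wetted perimeter $P$, a 3D point
and a region label.  This is a deliberate reduction — the downstream physics
(Reynolds and Womersley numbers, hydraulic diameter $D_h = 4A/P$, duct heat
transfer) consumes nothing a surface mesh would add, and it makes every
analysis reproducible from plain CSV/JSON tables.

## Synthetic geometries and what they emulate

CT-derived airway casts of the original specimens are not redistributable,
so the package generates parametric stand-ins (`airway_spec()`,
`generate_airway()`).  The vestibule is laid out as a helix: $n$ turns of
coil diameter equal to the requested in-plane extent, with the axial rise
derived so the requested arc length is met exactly (an unreachable
combination raises an infeasibility error).  Cross sections are flattened
ducts parameterised by caliber $d$ (the hydraulic diameter — physically, the
mucosal gap) and a perimeter elongation factor $f \ge 1$: $P = f\pi d$,
$A = f\pi d^2/4$.  Real vestibular cross sections are slot-like, not
circular; $f$ captures that without modelling the section shape.

The shipped presets pin four published constraints per taxon:

- vestibule arc lengths 440 mm (*Panoplosaurus*) and 808.74 mm
  (*Euoplocephalus*), with mean bony-bounded calibers 15.8 / 22.9 mm and
  soft-tissue calibers 10 mm.  (The source reports the *Panoplosaurus*
  vestibule as 400 mm in one table and 440 mm in the text; only 440 mm is
  consistent with the published 55 % shortening, so the presets use it.)
- coil extents solved so the straight nostril-to-CNP distance equals the
  published shortened vestibules (200 mm and 162.14 mm) — this is what makes
  the 55 % / 80 % "basic"-variant reductions emerge from geometry rather
  than being assumed;
- soft-tissue perimeter factors solved so the vestibule perimeter yields the
  published reversed-Reynolds low flows (37 and 48 L/min at Re 2000), and
  bony-bounded factors solved from the published cast volumes;
- loop counts 2 and 3, reflecting the more convoluted ankylosaurid
  vestibule.

Specimen presets are noise-free.  A lognormal caliber-noise option
(CV default 0.05, a fabricated but plausible roughness) exists for
robustness fixtures; it is deliberately not used for the named presets
because the reversed-Reynolds flow is a minimum statistic that multiplicative
noise biases low.  What the generator does *not* emulate: septum, paranasal
sinuses, section-shape detail, or the true 3D course of the loops.  Tests
passing on these geometries therefore validate the pipeline's physics and
bookkeeping, not anatomical fidelity.

## Model variants

Three transforms generate the comparative airway set: `soft_tissue_correct()`
rescales sections shape-preservingly (area $k^2$, perimeter $k$) until the
mean vestibule caliber reaches a target (default 10 mm, the upper mucosal
gap observed across extant amniotes); `make_basic()` replaces the vestibule
with the straight nostril-to-CNP segment at the vestibule's mean section;
`make_straightened()` re-lays the vestibule along a straight line at exactly
conserved length, area and perimeter, isolating the effect of curvature.
"Average caliber" is arc-length weighted (the source does not specify a
weighting; arc weighting is the natural choice on a station grid).

## Flow regime

`reynolds()`, `womersley()` and `classify_flow()` implement the standard
duct diagnostics with $\nu = 1.412\times10^{-5}\,\mathrm{m^2/s}$ (air at
15 °C).  Classification boundaries follow the quoted thresholds: laminar
below 2000, transitional on the closed interval [2000, 4000], turbulent
above; quasi-steady below Wo 1, unsteady above 10.  The reversed-Reynolds
estimator scans the main flow path — the olfactory recess is a blind side
chamber and the tracheal extension is artificial plumbing, so both are
excluded by default (configurable) — and returns the minimum station flow at
the target Reynolds number.

## Psychrometrics and budgets

Saturation pressure uses the Magnus form
$e_s = 610.94\,\exp(17.625T/(T+243.04))$ Pa (the source does not name its
formulation; Magnus is accurate to a fraction of a percent here).  Water
content is offered in two conventions — mixing ratio
$w = 0.622\,e/(p-e)$ and specific humidity $w/(1+w)$ — because the source's
wording ("mass fraction") and its printed latent-heat numbers are mutually
inconsistent at the few-percent level; the default is the mass-fraction
(specific humidity) basis.  Latent heat interpolates a bundled saturated
steam table (0–100 °C, 5 °C steps).  Under these standard property models
the recomputed latent conditioning costs come out ~4–5 % above the published
646 / 1218 cal — inside the ±10 % band that the convention ambiguity
implies, and flagged as such in the tests.

Budget arithmetic follows the published equations: air mass
$m = V_T \times 1.146$ g/L, sensible heat $m\,C_p\,\Delta T$ with
$C_p = 0.24$ cal g⁻¹ °C⁻¹, evaporation priced at body temperature and
condensation at the expired temperature, expired air always saturated.  Two
reproduction details are worth stating.  First, the published cost table
only reproduces exactly with the air mass rounded to the gram, while the
savings tables require full precision; `analysis/03_caloric_budgets.R` and
the acceptance checks mirror that split.  Second, profiles carry the
published rounded tidal volumes (34 000 / 64 000 ml) rather than the raw
allometric predictions (33 992 / 64 060 ml), again because the savings rows
are printed from the rounded values.  The comparative extant-taxa module
takes the published per-taxon air masses, heat capacities and temperature
changes as inputs and recomputes energy as capacity × ΔT; its printed
capacity column is kept as an input because the published rounding cascade
is internally inconsistent (3 significant figures on inspiration, 2 on
expiration for the same animal).

## The surrogate exchanger

The reduced-order model is a stand-in for 3D CFD, not a re-implementation of
it.  Bulk temperature and water content obey

$$\frac{dT}{ds} = \frac{h P (T_w - T)}{\dot m c_p}, \qquad
  \frac{dw}{ds} = \frac{h P (w_{sat}(T_w) - w)}{\dot m c_p},$$

with $h$ built from the laminar constant-wall-temperature Nusselt number
$\mathrm{Nu}_0 = 3.66$, multiplied by a curvature enhancement
$1 + \alpha\sqrt{\mathrm{De}}$,
$\mathrm{De} = \mathrm{Re}\sqrt{D_h\kappa/2}$ with Menger (circumscribed
circle) curvature $\kappa$, and the 0.5 mm mucosal conduction film in
series.  $\alpha = 0.1$ by default — conservative relative to published
curved-tube correlations, and config-exposed.  The Lewis analogy
($\mathrm{Sh} = \mathrm{Nu}$) gives moisture the same relaxation rate;
moisture is additionally capped at saturation of the local bulk temperature
(the latent heat of that condensation is not fed back into the air stream —
a known simplification).  Air conductivity is evaluated at the local film
temperature by default.

Numerics: a fixed-step RK4 march at station resolution (1 mm default) with
linear property interpolation.  On a uniform duct the scheme matches the
closed-form exponential solution to better than $10^{-6}$ relative, energy
closes to 0.1 %, and halving the spacing moves exit temperatures by well
under 0.1 °C; these are all enforced by tests.

Expiration enters at the choana at body temperature, saturated, and marches
back to the nostril.  Its wall temperature profile mirrors the local
inspired-air temperature — operationalising the assumption that the warming
of inspired air came at the expense of an equal cooling of the walls.  A
uniform-offset alternative (body temperature minus the total inspiratory
warming, everywhere) is available via
`exchanger_config(expiration_wall = "uniform_offset")`.  Per-region heating
shares default to the sensible-enthalpy basis with a full-enthalpy option,
since the reporting convention behind published "percent of heating in the
vestibule" figures is not stated.

What the surrogate can and cannot claim: it reproduces the *direction* of
every published contrast — soft-tissue beats straightened beats shortened,
lower flow beats higher flow, the vestibule dominates conditioning, and the
shortened airway loses several degrees more on expiration — and on the
best-case geometry it reproduces near-complete inspiratory conditioning
(within 1 °C of body temperature, ≥ 99 % vestibular share).  It does not
resolve vortices or secondary flows, so its expired-air temperatures are
systematically warmer than the CFD values (≈ 25 °C vs 15.9 °C for the
*Euoplocephalus* soft-tissue low-flow case): a bulk 1D model cannot
reproduce boundary-layer breakup, and the mirrored-wall assumption leaves
the downstream walls warm.  Quantitative savings therefore come from the
budget module driven by published expired temperatures, while the surrogate
supplies mechanisms, orderings and sensitivities.

## Problem sizes and determinism

Preset geometries discretise at 1 mm (≈ 950–1 450 stations); a full
two-taxon variant sweep is 12 exchanger runs and completes in a few seconds.
The generator is seedable and restores the session RNG state; specimen
presets are deterministic.  The analysis scripts (`analysis/01`–`05`) write
all summary tables to `results/`, and `scripts/acceptance.R --seed N`
re-derives every headline number from a clean session.

## Known limitations

Beyond those already noted: no turbulence closure (flows above Re 4000 only
trigger a warning), dry-air ideal-gas density, constant $c_p$, no wall
thermal inertia or vascular regulation, no olfactory-recess exchange, and
heat is not conserved between the inspiration and expiration phases beyond
the mirrored-wall bookkeeping.  These are acceptable for breath-level
energetics; they would not be for intra-breath dynamics.
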