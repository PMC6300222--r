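# vestibulum

Heat and water exchange in long, convoluted nasal airways.

Ankylosaurian dinosaurs carried enormously elongated, coiled nasal vestibules
— airway lengths of 440 mm (*Panoplosaurus mirus*) and 809 mm
(*Euoplocephalus tutus*) folded into the snout.  A long-standing functional
hypothesis holds that these coils worked like the respiratory turbinates of
mammals and birds: they warm and humidify inspired air, then reclaim much of
that heat and water as the breath leaves.  `vestibulum` implements a
desk-scale pipeline for testing that hypothesis on centerline airway
geometries: parametric airway models and their variant transforms,
flow-regime diagnostics, moist-air psychrometrics, respiratory caloric
budgets, and a reduced-order quasi-1D heat/moisture exchanger that stands in
for full 3D CFD.

It is written for comparative physiologists and vertebrate paleontologists
who want the energetics of nasal air conditioning without a meshing and CFD
toolchain.

## The model in brief

An airway is an ordered set of centerline stations, each carrying arc
position *s*, cross-sectional area *A*, wetted perimeter *P*, a 3D point and
an anatomical region (vestibule, cavum nasi proprium, nasopharyngeal duct,
…).  Everything downstream consumes only these scalars:

- **Flow regime.**  Re = 4Q/(Pν) and Wo = (Dh/2)√(2πf/ν) with
  Dh = 4A/P.  The *reversed-Reynolds* estimator inverts the Reynolds
  equation at Re = 2000 across every cross section and takes the minimum,
  Q = min_i Re·P_i·ν/4 — an upper bound for fully laminar resting airflow.
- **Caloric budget.**  Sensible cost m·Cp·ΔT (Cp = 0.24 cal g⁻¹ °C⁻¹, air
  mass m = VT·1.146 g L⁻¹, tidal volume VT = 20.3·M¹·⁰⁶ ml), latent cost
  ΔM(H₂O)·ΔH_vap from Magnus saturation pressures and a saturated steam
  table.  Savings divide what expiration returns by what inspiration cost;
  water recovery follows the classic countercurrent accounting.
- **Surrogate exchanger.**  Bulk temperature and water content relax toward
  the wall state, dT/ds = hP(T_w − T)/(ṁcp), with h from the laminar
  constant-wall-temperature Nusselt number Nu₀ = 3.66 amplified by a
  Dean-number curvature factor (1 + α√De), a mucosal conduction resistance
  in series, and Sh = Nu for moisture.  Expiration runs the march backwards
  against a wall profile cooled by exactly what inspiration extracted.

## Worked example

```r
library(vestibulum)

# the Euoplocephalus soft-tissue airway: 808.74 mm coiled vestibule,
# 10 mm mean caliber
a  <- generate_airway(airway_presets()$euoplocephalus_st)
region_metrics(a, "vestibule")$length_mm
#> [1] 808.74

# maximum laminar flow through its narrowest cross section
60000 * reversed_reynolds_flow(a)
#> [1] 48   # L/min

# one 64 L breath, conditioned from 15 degC / 50% rh to 35 degC saturated
budget <- expiration_savings(breath_scenario(expired_temperature_c = 15.87,
                                             tidal_volume_l = 64))
budget
#> <energy budget: cost 1623 cal (352 sensible + 1271 latent),
#>  recovered 1377 cal, heat savings 85%, water savings 80%>

# reduced-order exchange at the low flow rate
insp <- simulate_inspiration(a, 48 / 60000)
insp
#> <inspiration at Q = 48.0 L/min: exit 34.27 degC, 33.80 g/kg>
round(insp$region_heating_share[["vestibule"]], 2)
#> [1] 0.99
```

The breath of air costs ~1.6 kcal to warm by 20 °C and saturate; cooling it
back to 15.9 °C on the way out returns ~85 % of that energy and ~80 % of the
water.  The exchanger shows why: at 48 L/min the coiled vestibule alone
delivers 99 % of the warming, bringing air within a degree of body
temperature before it reaches the main nasal chamber.

The numbered scripts under `analysis/` run the full study — geometries and
variant transforms, flow regimes, caloric budgets for every airway model,
surrogate sweeps, and the extant-taxa comparison — and write their tables to
`results/`.

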