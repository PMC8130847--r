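# scaffdeg

Strain-modulated degradation simulation for PLLA bioresorbable vascular
scaffolds (BVS).

A bioresorbable scaffold supports an artery for a few months after
deployment and is then absorbed. Where it degrades first — and when its
ring-and-link structure fragments — is governed by the mechanical strain
left in the polymer by crimping and expansion: regions stretched the most
degrade the fastest. `scaffdeg` turns that observation into a reusable
simulator for device engineers and researchers who have a per-element
strain field of a deployed scaffold (from a finite element deployment
analysis, or from this package's synthetic generator) and want the ensuing
degradation timeline without re-running an FE chain.

## Model

Degradation of a material point is tracked by a scalar degree
*D* ∈ [0, 1], defined as the fractional loss of fracture strain,
*D* = (ε₀ − ε_t)/ε₀, and evolving with the local maximum principal strain
ε and time *t* (days) as a power law

> *D*(ε, *t*) = *a* (*b* + *c* εⁿ) *t*ᵐ,

with calibrated constants *a* = 0.385, *b* = 0.152, *c* = 0.616,
*m* = 0.342, *n* = 0.236. The fracture strain decays linearly with damage,
ε_t = ε₀ (1 − *D*) with ε₀ = 1.22, and an element is removed (element
death) once ε_t falls to its own strain. Inverting the law gives the local
fracture time

> *t*\*(ε) = [ (1 − ε/ε₀) / (*a* (*b* + *c* εⁿ)) ]^{1/*m*},

about 29.5 days at ε = 0.3 and 232 days at ε = 0.02. The simulator
aggregates element deaths into mass-loss trajectories, mass-weighted
strain histograms, strut-discontinuity (connected-component) events and a
scaffold-capacity surrogate. The artery wall is modelled as an
incompressible reduced polynomial hyperelastic solid,
*U* = Σᵢ Cᵢ₀ (Ī₁ − 3)ⁱ (i = 1…6), from which uniaxial stress, the initial
modulus 6 C₁₀ and a reduced-order lumen-diameter trend are derived. The
five kinetic constants can be refitted to degradation-experiment records
by bounded Levenberg–Marquardt least squares.

## Worked example

```r
library(scaffdeg)

fracture_time(c(0.3, 0.02))
#> [1]  29.49225 231.85614         # days: under 1 month vs beyond 7 months

recoil_rate(3.5, 3.28)
#> [1] 6.3                          # percent elastic recoil at deployment

field <- generate_stent_field(stent_field_spec(n_rings = 2, seed = 42))
sim <- run_degradation(field, simulation_config(dt = 0.5, horizon = 180))
sim$trajectory
#>   time_days time_months mass_loss_ratio n_components capacity n_alive n_dead
#> 1         0           0       0.0000000            1        1      54      0
#> 2        30           1       0.1296296            8        0      47      7
#> 3        60           2       0.2222222           15        0      42     12
#> 4        90           3       0.2962963           14        0      38     16
#> 5       120           4       0.3333333           12        0      36     18
#> 6       150           5       0.3333333           12        0      36     18
#> 7       180           6       0.4814815           14        0      28     26
```

The high-strain crowns fracture within the first month, the scaffold
fragments (component count rises above 1) only after those first deaths,
mass loss grows monotonically to 48% at six months on this coarse
54-element field, and the capacity surrogate drops to 0 once every closed
ring path is broken. `sim$events` lists each element's death time and
strain; `lumen_trend(sim$trajectory$capacity)` maps capacity onto a
3.28 mm → 3.0 mm lumen-diameter trend.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/scaffold-degrade.R synth-field --rings 2 --seed 42 --out field.csv
Rscript inst/cli/scaffold-degrade.R run --field field.csv --out outdir/
Rscript inst/cli/scaffold-degrade.R artery-uniaxial --stretch 1.2
```

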