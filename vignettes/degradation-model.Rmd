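---
title: "Strain-modulated degradation of bioresorbable scaffolds: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-modulated degradation of bioresorbable scaffolds: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffdeg)
```

## The model

A poly-l-lactide (PLLA) bioresorbable vascular scaffold hydrolyses faster
where the polymer is stretched more. `scaffdeg` abstracts this into a
continuum-damage picture on a discretized scaffold: each element carries a
scalar degradation degree $D \in [0,1]$, the fractional loss of the
material's fracture strain,

$$D = \frac{\varepsilon_0 - \varepsilon_t}{\varepsilon_0},$$

which evolves with the element's maximum principal strain $\varepsilon$
and time $t$ (days) as

$$D(\varepsilon, t) = a\,(b + c\,\varepsilon^{n})\,t^{m},$$

capped at 1. The fracture strain decays linearly,
$\varepsilon_t = \varepsilon_0 (1 - D)$, and the element is deleted
(element death, mimicking material absorption) once
$\varepsilon_t \le \varepsilon$. Setting $D = 1 - \varepsilon/\varepsilon_0$
and inverting gives the closed-form local fracture time

$$t^{*}(\varepsilon) =
  \left[\frac{1 - \varepsilon/\varepsilon_0}
             {a\,(b + c\,\varepsilon^{n})}\right]^{1/m},$$

which is strictly decreasing in strain: about `r round(fracture_time(0.3), 1)`
days at $\varepsilon = 0.3$ and `r round(fracture_time(0.02), 1)` days at
$\varepsilon = 0.02$ under the default coefficients.

Key assumptions, stated up front:

* **The strain field is frozen.** Deployment (crimping, expansion, recoil)
  sets the maximum principal strain per element, and that field changes
  little while the polymer degrades. This is the simplification that
  removes the finite element dependency: no stress redistribution after
  element death is computed. Users who do have FE output per time point can
  pass a `strain_update` hook to `run_degradation()`, applied at snapshot
  times.
* **Damage is irreversible and per element.** $D$ never decreases, $D = 1$
  is absorbing, and the death criterion is evaluated per element, not per
  integration point.
* **The strain measure is whatever the field provides.** The calibration
  experiments report pre-stretch strains without stating engineering
  versus logarithmic measure; the kinetics treat the supplied field on the
  same footing. For the strains involved (mostly below 0.5) the difference
  is modest but users mixing measures should convert first.
* **One month is 30 days** wherever times are reported in months.
* **Death direction.** The physically consistent criterion — and the one
  implemented — is that fracture initiates when the *fracture strain falls
  to* the element's strain. (A verbal description of the original
  subroutine inverts that inequality; we read it as a typo, since the
  stated negative fracture-strain/degree relationship and the
  fracture-time curve both require the implemented direction.)

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `a`, `b`, `c` | rate constants of the damage law | 0.385, 0.152, 0.616 | – |
| `m` | time exponent | 0.342 | – (t in days) |
| `n` | strain exponent | 0.236 | – |
| `epsilon0` | initial fracture strain | 1.22 | – |
| `dt` | simulator step | 0.5 | days |
| `horizon` | simulated period | 180 | days |
| `snapshot_interval` | trajectory/snapshot spacing | 30 | days |
| `C10…C60` | artery reduced polynomial coefficients | 6.52e-3 … 8.69e-2 | MPa |

The defaults for `a…n` are the published least-squares calibration for
PLLA strips pre-stretched to strains 0, 0.2 and 0.4 and sampled at 3, 10,
20 and 30 days; `epsilon0` is a coefficient, not a hard-coded constant, so
other polymer batches can be represented. The artery coefficients'
units are not stated by their source; MPa is assumed, the convention for
coronary tissue, and only ratios of the capacity-to-diameter surrogate
depend on them anyway.

## Damage accumulation under time-varying strain

The closed form $D(\varepsilon, t)$ is defined for constant strain. When
strain can change, the increment rule is an *equivalent-time*
(strain-hardening) scheme: recover the pseudo-time $t_{eq}$ at which the
law at the current strain would yield the current degree,
$t_{eq} = (D/k)^{1/m}$ with $k = a(b + c\varepsilon^n)$, then re-evaluate
at $t_{eq} + \Delta t$. This choice is rate-consistent and exactly
reproduces the closed form for constant strain under any partition of the
time axis (a property the tests assert to 1e-9 relative). The naive
alternative — re-evaluating the closed form at global time with the
current strain — is available as `accumulation = "global_time"`; the two
coincide while the field is frozen and differ only under a strain hook.

## Fitting the coefficients

`fit_degradation_coefficients()` minimizes the residual sum of squares
between predicted and observed degrees with bounded Levenberg–Marquardt
(`minpack.lm`), bounds $a,b,c \in [0,10]$, $m,n \in [0.01, 3]$, started at
the package defaults. Two methodological points:

* **Identifiability.** The law can be expanded as
  $D = (ab)\,t^m + (ac)\,\varepsilon^n t^m$: the data determine the
  *products* $ab$ and $ac$ (plus $m$, $n$), not $a$, $b$, $c$
  individually. The fit is deterministic given its initialization, and
  starting from the published values returns them exactly on noise-free
  data; from a distant start it lands elsewhere on the same ridge with
  identical products and residuals. Tests assert the identifiable
  combinations, not the ridge position.
* **Design checks.** At least five records spanning two distinct strains
  and two distinct times are required; a single-strain or single-time
  design raises an identifiability error rather than returning an
  arbitrary ridge point.

## The simulator

`run_degradation()` advances all alive elements by `dt`, updates fracture
strains, and applies deaths simultaneously at the end of each step so
results are independent of element ordering. Element death times therefore
land on the step grid within `dt` of the closed-form $t^*(\varepsilon)$ —
the suite checks this for 1,000 random strains at `dt = 0.25` d. Snapshots
(trajectory rows, optional full states, VTK files when the field carries
mesh geometry) are written every `snapshot_interval` days, monthly by
default.

Degenerate inputs: empty fields and non-finite strains abort with a
diagnostic; negative (compressive) principal strains are clamped to zero
at read time with a warning count, since compression does not drive
hydrolytic damage in this law.

### Derived quantities

* **Mass loss ratio** — dead volume over total volume (unit density), with
  exact alive + dead mass conservation at every step.
* **Strain histogram** — mass fractions over strain bins; the default
  edges (0.29, 0.16, 0.098, 0.067, 0.047, 0.036) are representative
  deployment strain levels useful for predicting mass-loss slopes from the
  acute strain map. Open end bins collect outliers so fractions sum to 1.
* **Strut discontinuity** — connected components of the alive-element
  adjacency graph (`igraph`); a count above the fully-alive baseline is a
  fragmentation event.
* **Capacity surrogate** — the alive mass fraction, gated to 0 once the
  alive graph contains no cycle. The rationale: hoop (radial) support
  requires a closed circumferential load path, and in a ring-and-link
  topology every closed path is a graph cycle; once all are broken the
  scaffold cannot carry hoop load regardless of remaining mass. This is a
  documented surrogate for the stent–artery contact force, which would
  require an FE contact solution. Edge-free fields (isolated point clouds)
  carry no topology and skip the gate. `lumen_trend()` then maps capacity
  monotonically onto a lumen diameter between the deployed (3.28 mm) and
  unloaded (3.0 mm) endpoints — linear by default, smoothstep as an
  option, since no constitutive coupling between capacity and diameter is
  published.

## The artery response

The vessel wall is an incompressible isotropic reduced polynomial
hyperelastic solid, $U = \sum_{i=1}^{6} C_{i0} (\bar I_1 - 3)^i$. Under
incompressible uniaxial stretch $\lambda$,
$\bar I_1 = \lambda^2 + 2/\lambda$ and the Cauchy stress is
$\sigma = 2(\lambda^2 - 1/\lambda) \sum_i i\,C_{i0} (\bar I_1 - 3)^{i-1}$,
giving an initial modulus of $6 C_{10} = 0.0391$ MPa. Because $C_{50}$ is
negative the polynomial is not globally positive; positivity of $U$ is
asserted numerically on the working range $\bar I_1 \in [3, 4.5]$ rather
than claimed globally.

## The synthetic generator

`generate_stent_field()` builds a coarse ring-and-link graph — `n_rings`
closed rings of `peaks_per_ring` crowns (default 6) separated by strut
bodies, joined by link chains — and assigns strains by structural role:
crowns highest (median 0.3), links intermediate (0.1), strut bodies lowest
(0.03), each with multiplicative lognormal scatter
($\sigma_{\log} = 0.15$) so strains stay positive. These defaults
reproduce the qualitative structure of a deployed scaffold's strain map —
crowns of the U-bends fracture first, within a month; strut bodies outlive
six months — and the generation is deterministic per seed without
disturbing the global RNG stream.

What the generator does **not** emulate: the real device's
tens-of-thousands-element mesh and its actual strain magnitudes, residual
strain gradients through the strut thickness, and stress redistribution
after deaths. Passing tests on synthetic fields therefore demonstrate the
bookkeeping and the kinetics, not a validated prediction of any specific
device's mass-loss percentages; quantities that depend on the unpublished
deployment strain field (e.g. exact monthly mass-loss ratios or the
day-15 onset) are matched qualitatively, not numerically.
`generate_degradation_dataset()` likewise forward-simulates calibration
records (closed-form degree plus clipped Gaussian noise) for fitting
tests.

## Numerical choices and problem sizes

* Closed-form inversions are used everywhere in preference to root
  finding; the tests cross-check them against an independent bisection
  oracle to 1e-6 days.
* Death comparison uses an absolute slack of 1e-12 on the fracture-strain
  inequality to make grid-point deaths deterministic.
* The test suite runs on fields of tens to hundreds of elements and a
  1,000-element death-time consistency check at `dt = 0.25` d over 320
  days; these sizes exercise every code path while keeping the default
  suite fast. Larger fields scale linearly in elements and steps.
* A zero rate factor ($a b = 0$ and $c\,\varepsilon^n = 0$) leaves the
  degree unchanged and yields an infinite fracture time rather than an
  error.

## Known limitations

* No stress redistribution after element death, no fatigue or pulsatile
  loading, no arterial remodeling or 3D arterial stress fields — the
  capacity and lumen outputs are surrogates.
* No softening of the PLLA's elastic constants during degradation: the
  calibration data show fracture-strain loss, not stiffness loss.
* No molecular-weight or hydrolysis chemistry: mass loss here is the dead
  element mass fraction, which is *not* the same physical quantity as a
  measured molecular-weight decrease, and the two should not be compared
  numerically.
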