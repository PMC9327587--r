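---
title: "canopyflux: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{canopyflux: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyflux)
```

`canopyflux` simulates the clear-sky shortwave (0.3–3 µm) radiation regime
of a forest plot described only by per-tree crown attributes: stem
position, species class (conifer or broadleaf), tree height, clear bole
height and the two crown half-widths. This vignette documents the model,
every tunable parameter, the numerical choices, and — importantly — what
the model does and does not reproduce.

## 1. Solar geometry

Solar altitude comes from the spherical formula
$\sin\theta_a = \sin\theta_l\sin\theta_d + \cos\theta_l\cos\theta_d\cos\theta_h$
with latitude $\theta_l$, declination $\theta_d$ and hour angle
$\theta_h$. Design choices:

* **Declination and orbit eccentricity** use the Spencer truncated Fourier
  series, the standard parameterization in clear-sky engineering models.
  At the default study latitude (32.076° N) this puts the June-15 noon
  altitude at 81.21°, matching the headline value to two decimals.
* **"Local solar time" is taken literally**: $\theta_h = 15°(t-12)$, no
  equation-of-time or longitude correction. Users working from civil clock
  time must convert before calling the package.
* **Azimuth convention**: degrees clockwise from north in $[0,360)$,
  morning below 180, exactly 180 at solar noon whenever declination is
  below latitude (the `atan2` components make this exact, not approximate).
* Angles cross module boundaries in degrees; radians are internal.

A reference pair worth knowing: at 10:00 solar time on July 15 the model
returns altitude 61.41° / azimuth 103.85°. Published descriptions of the
same site quote (61.58°, 102.32°); no self-consistent declination model
reproduces both printed angles simultaneously (the altitude would need
$\theta_d \approx 22.0°$, the azimuth $\approx 22.5°$, while mid-July
declination is 21.6–21.7°), so we regard the Spencer-consistent values as
correct and the sub-degree discrepancy as irreducible.

## 2. Clear-sky irradiance

Total horizontal-surface irradiance is
$I_{total} = I_{direct} + I_{dr} + I_{da} + I_{dm}$ with

* $I_{direct} = 0.9751\, I_{sc}\, r_0\, \tau_r \tau_o \tau_g \tau_w \tau_a \sin\theta_a$
  (0.9751 restricts the budget to 0.3–3 µm; $I_{sc} = 1367$ W/m²),
* a Rayleigh diffuse term proportional to $0.5\,(1-\tau_r)$,
* an aerosol diffuse term proportional to $F_c (1-\tau_{as})$ with the
  0.79 urban (soot-containing) aerosol factor,
* the ground–sky multiple-reflection closure
  $I_{dm} = (I_{direct}+I_{dr}+I_{da})\,\rho_g\rho_a/(1-\rho_g\rho_a)$,
  $\rho_a = 0.0685 + (1-F_c)(1-\tau_{as})$.

The five band transmittances are computed from air mass (Kasten-type
formula at standard pressure), ozone column, precipitable water and
visibility with the Iqbal Model C parameterizations; aerosol optical depth
derives from visibility through the Ångström turbidity estimate. The
Rayleigh-diffuse prefactor is the standard Model C form $0.5(1-\tau_r)$
together with the orbit factor $r_0$; one widely-circulated rendering of
this equation is typographically garbled, and we use the standard form.

**Calibrated defaults.** The fixed optical constants are
$\omega_0 = 0.9$, $F_c = 0.84$, urban factor 0.79 and $\rho_g = 0.2$. The
three free atmospheric inputs were chosen once, as plausible values for a
humid subtropical urban site in summer, so that the June-15 noon total at
32.076° N is about 920 W/m²: ozone 0.35 cm, precipitable water 4.0 cm,
visibility 7 km, giving 919.74 W/m² (within 0.1% of the 920.26 W/m²
reference). `tools/calibrate_atmosphere.R` reproduces this scan. They are
a calibration, not measured values; users with sounding or AERONET data
should override them via `atmosphere()`.

## 3. Crown primitives

Conifer crowns are cones (apex at the tree top, elliptical base of
half-widths $a$, $b$ at the clear bole height), broadleaf crowns upper
semiellipsoids; both occupy $z \in [\text{bole}, \text{height}]$ with
vertical extent $c = \text{height} - \text{bole}$. Only the upper/outer
sheet is modelled — no base disc, no trunk — because the ray tracer only
ever sees the canopy from above or between crowns. Crowns of neighbouring
trees may interpenetrate; occlusion is resolved by first-hit ray casting,
not by clipping. A published form of the cone equation squares the
constant $(\text{height}-z_{center})$ where the geometry requires the
running coordinate; we implement the cone that matches the stated
parameter meanings (apex at the top, base radius $a,b$ at the bole).

## 4. Surface meshing

Each crown footprint is sampled with its centre plus `n_rings` concentric
elliptical rings of ξ points each, triangulated in 2-D, and back-projected
onto the crown surface. Choices that matter:

* **Vertex spacing drives resolution**: by default `n_rings` is the crown
  profile arc length (cone slant, or quarter-ellipse arc) divided by the
  target spacing, and ξ the footprint perimeter divided by it. The default
  1.36 m reflects a deliberate accuracy/runtime tradeoff for plot-scale
  work; a 60-tree conifer plot meshes to roughly 20,000–40,000 facets.
* **Triangulation happens in the axis-normalized footprint frame**
  (coordinates divided by the half-widths), where every ring is a circle
  with equal arc spacing. For strongly elongated crowns this prevents the
  long sliver facets that a raw-coordinate Delaunay produces, whose lifted
  normals can point sideways or inward; in the normalized frame all lifted
  normals are provably outward. Connectivity is identical either way, so
  projecting the lifted mesh back to the plane reproduces the planar
  triangulation exactly.
* **Delaunay implementation**: an incremental Bowyer–Watson algorithm in
  C++ with extended-precision (`long double`) in-circle/orientation
  predicates and a far-away super-triangle. On-circle points count as
  outside the circumcircle, which makes cocircular ring samples
  well-defined (any triangulation of a cocircular fan is Delaunay). The
  test suite verifies triangle-set identity against the independent
  `deldir` tessellation on random point sets and brute-forces the
  empty-circumcircle property.
* **Degenerate facets** (zero area after lifting, e.g. at a cone apex)
  are dropped; normals are the facet cross products re-oriented upward,
  or radially outward for the rare vertical facet.

## 5. Beam tracing

Beams start on a 100 m source plane as a cell-centred lattice (default
spacing 0.2 m = 25 beams/m²) sharing the solar beam direction. The
conceptual plane is 800 m × 800 m centred on the plot — far larger than
any scene — and the lattice is anchored to that plane's absolute origin,
so culling beams that cannot intersect the scene's bounding box changes
nothing but runtime (verified by test).

Intersection uses the plane-parameter form $t = N\cdot(p_1 - o)/(N\cdot d)$
with a same-side cross-product inside test. Numerical guards: parallel
rejection at $|N\cdot d| < 10^{-12}\,|N||d|$, hits behind the origin
rejected at $t \le 10^{-12}$, inside-test slack $10^{-9}$ relative to the
squared normal, first-hit ties (within $10^{-9}$ on $t$) broken toward the
lowest facet index. The production path walks a uniform plan-view grid
(Amanatides–Woo traversal over facet bounding boxes, 2 m cells by
default); an exhaustive-loop twin is kept solely as an oracle and the two
are asserted identical on batteries of random scenes.

Each first hit spawns exactly two children, traced one bounce (no
grandchildren):

* a **specular reflection** $r = d - 2(d\cdot N)N$, which may hit any
  facet except the one it left (intra-crown re-collision is allowed:
  crowns interpenetrate and concave canopy regions exist);
* a **Snell-refracted transmission** with ratio $e = 0.5$
  ($\sin\theta_{out} = e\sin\theta_{in}$), which skips every facet of the
  originating tree — it models energy passing through the crown onto the
  trees behind, not internal structure.

Children start $10^{-6}$ m along their direction to avoid
self-intersection. Beams missing the canopy terminate at the ground and
are counted but carry no flux; ground reflectance enters only through
$\rho_g$ inside the irradiance model.

## 6. Flux accounting

Every beam carries power $I_{total}/\ell$ (W). Facet fluxes are

$$E_{incident} = \sum (I_{total}/\ell)\cos\theta,\qquad
  E_{reflect} = \sum (I_{total}/\ell)\cos\theta\,\rho,\qquad
  E_{trans} = \sum (I_{total}/\ell)\cos\theta\,\tau,$$

where $\theta$ is the angle between the (child) ray and the normal of the
facet it strikes, folded to $[0°,90°]$ (outward normals face arriving rays
from behind, so the raw cosine is negative; folding keeps fluxes
non-negative). Class optics default to ρ = 0.25 / τ = 0.15 for conifers
and ρ = 0.17 / τ = 0.20 for broadleaves — band-averaged leaf/needle values
for 0.3–3 µm. The reflectance/transmittance attributed to a child ray is
taken from the species of the crown that reflected or was penetrated (the
energy-modifying surface); a config switch (`attribute_to = "receiver"`)
selects the receiving facet's class instead, since either reading of
"the species the facets belong to" is defensible.

### What the cosine weighting implies — read this before interpreting results

The per-beam power is *fixed* at $I_{total}/\ell$ regardless of sun
obliquity, so the facet cosine is an additional geometric weighting, not
an energy partition. Radiometrically, a beam representing one lattice cell
of horizontal area deposits *all* of its power on whatever it first hits;
multiplying by $\cos\theta$ under-counts steep facets. The consequences
are systematic and worth stating plainly (all of them are measured by the
shipped test suite, on synthetic plots drawn from the study attribute
ranges at 0.4 m beam spacing over 20 seeds):

* A steep cone under a high sun is hit at grazing incidence
  ($|\cos\theta| \approx a/\sqrt{a^2+c^2} \approx 0.3$ for typical
  conifers), so conifer plots receive *less* cosine-weighted incident flux
  at noon (mean 959 kW) than at 9:00 or 16:00, when oblique beams strike
  the sun-facing flanks nearly head-on over a larger silhouette. The
  diurnal incident-flux curve has a noon *dip* for steep-crowned plots
  (noon was the within-day maximum in only 50% of plot×date cases), and
  October noon flux exceeds June's (June ≥ October in 0% of seeds).
* Broadleaf plots, whose ellipsoid caps face the noon sun with near-unit
  cosines, out-collect conifer plots at noon (conifer > broadleaf in 30%
  of seeds) despite intercepting fewer beams.
* Within a pure broadleaf plot, reflected re-collisions outnumber
  transmitted ones (transmitted rays must reach a *different* tree), so
  $E_{trans} > E_{reflect}$ held in only 5% of seeds even though
  τ (0.20) exceeds ρ (0.17). The conifer ordering
  $E_{reflect} > E_{trans}$ holds in 100% of seeds.

Field-validated descriptions of comparable plots report the opposite
seasonal/species orderings together with plot totals close to
$0.9 \times I_{total} \times$ plot area — magnitudes consistent with
*full-power* interception counting and inconsistent with the facet-cosine
weighting those same sources print as their equation. We implement the
printed equation, keep the discrepancy visible (the corresponding
acceptance assertions fail honestly rather than being weakened), and
recommend `counts["num_incident"] * per_beam_power` — both in every
`flux_report` — to readers who want the energy-conserving interception
total. Quantities that do *not* depend on this choice: the irradiance
model, interception counts, hit geometry, shading/occlusion patterns, and
the flat-canopy limit (for a horizontal canopy the cosine is 1 and
$E_{incident}$ recovers $I_{total}\times$ area within beam-discretization
error, about 1% at 0.2 m spacing).

## 7. Synthetic plots

`generate_plot()` emulates the three study-plot configurations — pure
conifer (60 trees), pure broadleaf (60), mixed (61; 33 conifer + 28
broadleaf) on 50 m × 50 m — by drawing tree height, both full crown
widths and clear bole height uniformly and independently within the
published per-kind ranges (the ranges already force height > bole), and
placing stems by minimum-spacing rejection sampling (4 m conifer, 5 m
broadleaf/mixed; chosen so conifer canopies are dense and broadleaf ones
more open, and documented as a tuning knob). Each draw is reproducible
from its seed.

What this emulates: attribute ranges, species mixes, stand density
regimes, total crown volume (a seed-1 conifer plot's ~26,000 m³ is close
to the ~25,000 m³ reported for the real conifer stand). What it does not:
the true stem map and attribute correlations (published only as ranges and
means), spatial clustering beyond minimum spacing, within-crown foliage
structure, or segmentation error. Passing ordering/conservation tests on
these plots therefore says the *model* behaves as analysed under realistic
stand statistics — not that any specific real plot's fluxes are
reproduced; per-tree layouts would be required for that, and plot-total
fluxes are sensitive to them.

## 8. Problem sizes and determinism

Default plot-scale runs (60 trees, 1.36 m mesh spacing, 0.2 m beams) trace
~100,000 beams against ~20,000–40,000 facets in a few seconds. The test
suite runs its heaviest property — the 20-seed, two-plot-kind,
six-instant ordering sweep — at 0.4 m beam spacing, and its refinement
check at 0.4/0.2/0.1 m on fixed deterministic fixtures, chosen so
discretization error (not lattice noise) dominates the measured deltas.
Everything is deterministic given the configuration seed; the only
randomness is in synthetic scene generation.

## 9. Known limitations

* Clear-sky only; no clouds, terrain shading, or longwave budget.
* Single-bounce secondary transport; no diffuse (cosine-lobe) scattering,
  no participating-media attenuation inside crowns, no ground-reflected
  rays.
* Crowns are opaque geometric sheets for interception; within-crown gap
  structure is summarized by a single class transmittance.
* The facet-cosine flux weighting discussed in §6, kept for fidelity to
  the published formulation, inverts several intuitive seasonal/species
  orderings for steep-crowned stands.
* The low-sun interception of a plot can legitimately exceed
  $I_{total}\times$ plot area (the canopy shades ground outside the plot),
  so energy-bound checks are meaningful only near the daily maximum solar
  altitude.
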