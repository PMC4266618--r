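---
title: "Modelling glioblastoma growth, brain invasion and anti-angiogenic therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glioblastoma growth, brain invasion and anti-angiogenic therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliogrow)
```

## The model

`gliogrow` simulates glioblastoma multiforme (GBM) at the scale of a
clinical MRI slice.  Four densities live on a 2-D grid, each expressed per
carrying capacity: proliferative tumour cells $P$, invasive tumour cells
$I$, healthy brain $B$, and necrotic (dead) material $N$.  The central
biological assumption is the *go-or-grow* phenotype: $P$ cells divide but
do not move, $I$ cells move but do not divide, and the local level of
hypoxia switches cells between the two.

Oxygen is not modelled explicitly.  Instead the local *hypoxic state* is a
saturating function of the total cell density
$C = P + I + B + N$:

$$H = \min\!\left(\tfrac{C}{C_\mathrm{ref}},\, 1\right),$$

so crowded tissue — dead cells included, since they still occupy space and
displace vasculature — is hypoxic tissue.  Two spatial threshold fields
structure the response to $H$:

* below the **hypoxic threshold** $\tau_h$, tissue is normoxic: $P$
  divides at its maximal rate $M_\mathrm{max}$ and invasive cells revert
  to the proliferative phenotype at rate $\beta_{IP}$;
* between $\tau_h$ and the **lethal threshold** $\tau_l$, division slows,
  $P$ cells switch to the invasive phenotype (rate ramping up to
  $\beta_{PI}$), and back-conversion shuts down;
* above $\tau_l$, cells of all living types die at a rate that climbs
  rapidly to $\mu_\mathrm{max}$; dying cells of every type are collected
  into $N$ with weight one, so the reaction terms other than mitosis
  conserve $C$ exactly.

Invasive cells migrate by two mechanisms.  **Passive diffusion (PD)** is
Fickian spread at rate $D(x) = D_0\,(1 + w(x)(\kappa_{wm} - 1))$, faster
along white-matter tracks (fraction $w$).  **Active transport (AT)** is
bulk advection up the healthy-brain gradient with velocity
$\gamma \nabla B$: invasive cells on the hypoxic edge stream towards
regions richer in healthy brain (and its vasculature) and stop once $B$
is uniform.  Both mechanisms respect the brain mask (skin and bone are
impermeable) and neither carries cells into the necrotic core, whose
diffusivity is zero.

**Angiogenesis** raises both thresholds towards caps as a function of the
local proliferative density, $\dot\tau = \alpha P (\tau^\mathrm{cap} -
\tau)$: vascularised tumour tolerates higher density before slowing and
dying.  **Anti-angiogenic (AA) therapy** suppresses that term and resets
the thresholds to their baseline values (instant reset by default;
`relax_rate` exposes a finite relaxation).  The reset choice follows the
observed treatment dynamics, where the treated growth curve collapses
onto the AA-from-time-zero curve rather than freezing in place.

## Functional forms

The threshold responses are pinned down qualitatively — monotone ramps
with saturation — but not algebraically, so each is a simple linear form
behind a switchable option:

| quantity | default form | alternative |
|---|---|---|
| mitosis $M(H)$ | `saturating`: $M_\mathrm{max}$ for $H \le \tau_h$, linear to 0 at $H = 1$ | `banded`: vanishes already at $\tau_l$ |
| death $\mu(H)$ | `steep`: 0 at $\tau_l$, $\mu_\mathrm{max}$ at $\tau_l + 0.02$ | `gradual`: $\mu_\mathrm{max}$ at $H = 1$ |
| switch $P\!\to\!I$ | 0 at $\tau_h$, $\beta_{PI}$ at $H = 1$ | — |
| switch $I\!\to\!P$ | $\beta_{IP}$ at $\tau_h$, 0 at $\tau_l$ | — |

Two of these defaults deserve justification, because the package's own
simulations forced the choice:

* **Mitosis must persist beyond the lethal threshold.**  If $M$ vanishes
  at $\tau_l$ (the `banded` form), total density approaches $\tau_l$ from
  below and stalls exactly where death would begin; the death rate then
  never activates and *no necrotic core can ever form*, in either the
  untreated or the treated tumour.  The `saturating` default lets crowded
  tissue overshoot $\tau_l$ and die, which is what produces the classical
  necrotic core.
* **Death onset must be steep.**  With a gentle ramp (reaching
  $\mu_\mathrm{max}$ only at $H = 1$), tissue self-organises to sit just
  above $\tau_l$ where the death rate is negligible, and the brain never
  reaches the 90%-dead criterion that defines radiological necrosis.  The
  `steep` default (full death rate within 0.02 of the threshold) encodes
  "rapid necrosis" beyond the lethal threshold and produces sharply
  delimited cores.

## Default parameters

Time and length units are arbitrary (one step is $dt = 0.1$ time units on
a unit grid cell).  The defaults were chosen once so that a tumour seeded
as a single cell ($P = 10^{-2}$, $I = 10^{-3}$) on the 127×127 phantom
develops the full phenomenology on the standard 5000-step horizon —
multilayer structure by mid-run, treatment window at steps 2500–3500 —
and they are the package's study conditions:

* $M_\mathrm{max} = 0.1$, $\mu_\mathrm{max} = 2$: death is fast compared
  with growth, so the lethal band kills cleanly ("rapid necrosis").
* $\beta_{PI} = 0.05 < M_\mathrm{max}$: a seeded colony densifies faster
  than hypoxia drains it into the invasive compartment.  (If
  $\beta_{PI} \ge M_\mathrm{max}$ the balance point of growth against
  switching sits below $\tau_l$ and the tumour never ignites necrosis.)
* $\beta_{IP} = 0.15$: invasive cells that reach fresh brain revert
  briskly, closing the growth–invasion–necrosis cycle.
* $D_0 = 0.02$, $\kappa_{wm} = 5$, $\gamma = 4$: both mechanisms move an
  invasive front several tens of cells over the horizon, with AT dominant
  at the default setting.
* $\alpha = 1$ with caps $(0.9, 0.97)$: angiogenesis saturates quickly
  wherever $P$ is substantial.  This makes the Full-vs-AA contrast large
  (the AA tumour reaches roughly a tenth of the untreated proliferative
  mass at the same horizon) and makes the vascular-normalization
  comparison act through the timing of suppression rather than through
  an unsaturated rate.
* thresholds $(\tau_{h0}, \tau_{l0}) = (0.7, 0.85)$ with $B_0 = 0.5$,
  $C_\mathrm{ref} = 1$: healthy brain is normoxic with headroom 0.2
  before hypoxia and 0.35 before lethality.
* necrosis cutoff 0.90 of initial brain, invasion cutoff $10^{-4}$:
  the radiological definitions used by every percent readout.

The vascular-normalization schedule multiplies $\alpha$ by 2 for 500
steps from the start of AA.  A shorter window (250 steps) leaves too
little of the enlarged pre-suppression tumour to dominate the
post-suppression trajectory, and the invasive-mass contrast with plain AA
reverses; 500 steps is the package default, exposed in the schedule.

## Numerics

Explicit first-order operator splitting, in fixed order per step:
reaction (local kinetics), threshold dynamics, active transport, passive
diffusion.  Differences against other orderings are $O(dt)$ and far below
the test tolerances at the default $dt$.  PD uses conservative central
fluxes with arithmetic face averaging of $D$; AT uses donor-cell upwind
fluxes, which are stable and positivity-preserving under the CFL bound
(checked on every call; `stable_dt()` returns
$0.9\,\min(h^2/4D_\mathrm{max},\, h/\gamma|\nabla B|_\mathrm{max})$).
Per-cell outflows — both reactive and advective — are capped at the
available density, so all fields stay non-negative and both transport
operators conserve invasive mass to round-off on any mask geometry.
Zero-flux conditions hold across the mask boundary and across any face
into a necrotic cell, so invasive cells never re-enter the dead core.

Degenerate inputs are handled explicitly: an empty raster is an error, a
tumour seeded outside the mask is an error, a zero-step simulation
returns the seeding observables, and a failed sweep point is recorded
with an error flag rather than dropped.

## The synthetic brain and what the tests do (and do not) show

`synthetic_brain()` builds an elliptical brain (about 55% of the grid)
with an impermeable rim and 2–4 sinusoidal white-matter bands,
deterministic given a seed.  It reproduces the geometric features the
model interacts with — a bounded domain, impermeable boundary, anisotropy
bands — but none of the anatomical detail of a real slice: no ventricles,
no grey/white topology, no hemispheric asymmetry.  Passing tests on the
phantom therefore demonstrate the model's internal phenomenology
(multilayer structure, growth without angiogenesis, rebound, the
necrosis–invasion association), not fidelity to any patient's anatomy.
Real labelled slices can be imported with `load_brain_slice()`.

Similarly, `synth_cohort()` generates lesion diameters and
progression-free survival (PFS) with the population structure the
clinical statistics need — two groups with exponential PFS at means 333
and 178 days and ~20% censoring, and a latent tumour-size factor that
links the necrosis area to the (FLAIR − tumour) area, with occasional
heavy-tailed measurement outliers.  It exercises the estimators; it does
not emulate scanner physics or reader variability.

## Problem sizes used by the checks

The packaged checks run the clinical-scale protocols (Full, AA,
treatment, normalization) on the 127×127 phantom for 5000 steps, the
matched-mass AT/PD comparison on a 64×64 phantom at a 4000-step horizon
(bisection on $\gamma$ against the PD-only reference, 5% mass
tolerance), and the sensitivity sweep as a 3×3 grid over the
$M_\mathrm{max} \times \gamma$ pair — growth vigour crossed with
transport strength — at the clinical scale and the standard 3000-step
sweep horizon.  The sweep deliberately stays at 127×127: on small
domains vigorous parameter combinations consume the entire brain by the
horizon, and once everything is necrotic the instantaneous invaded area
collapses, spuriously anticorrelating the two readouts.  These sizes
keep a complete run of the suite within minutes while preserving every
qualitative regime of the full-scale model.

## Known limitations

* At matched final proliferative mass, the PD-only configuration shows
  *more* percent necrosis than AT-only in this implementation: a compact
  diffusion-driven tumour saturates its interior to $C \approx 1$ and
  kills it completely, which is the most necrosis-efficient geometry per
  unit of proliferative mass a mass-conserving model (with dead cells
  counted in $H$) admits.  AT-only dominates every invasive readout
  (invasive mass by an order of magnitude, invaded area) but not the
  necrotic area.  Exploration across mitotic/death forms, threshold-band
  widths, anisotropy and transport regimes did not produce a regime
  reversing this while preserving the rest of the phenomenology.
* The 2-D slice ignores out-of-plane growth; percent readouts are
  area-based.  Percent invasion is an instantaneous readout: on a small
  or long-saturated domain it *decreases* again as invaded tissue turns
  necrotic, so association analyses should be run pre-saturation.
* Under suppressed angiogenesis the proliferative mass pulses (a
  grow–cull limit cycle around the lethal threshold) rather than growing
  monotonically sample-by-sample; trends over a few hundred steps are
  the meaningful readout.
* Angiogenesis is a threshold effect, not a vascular model: no oxygen
  diffusion, chemotaxis or vessel network is simulated, by design.
* Explicit time stepping means very large transport coefficients require
  proportionally smaller `dt` (the solver refuses unstable steps rather
  than silently damping them).
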