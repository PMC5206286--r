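---
title: "A multi-phase-field model of nuclear architecture reorganization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-phase-field model of nuclear architecture reorganization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`chromarch` treats interphase chromatin at the domain scale rather than the
fiber scale. Each of the N chromosome territories is a phase-field
$\phi_m(\mathbf{x},t)$ taking values near 0 (absent) or 1 (present);
heterochromatin is a single field $\psi$; the nucleus is a *prescribed*
field $\phi_0$ (0 inside, 1 outside) that never responds to chromatin. The
model assumes:

* chromatin in a chromosome stays within one territory, and territories
  exclude each other but may intermingle across a diffuse interface;
* heterochromatin stays within chromosomes; its complement inside a
  territory is euchromatin (L1-rich heterochromatin and chromocenters are
  not distinguished);
* chromosome and heterochromatin volumes relax toward target values —
  constants in the conventional regime, time-dependent during the
  conventional-to-inverted reorganization;
* the nucleus fully occupied by chromosomes is energetically preferred;
* envelope tethering of heterochromatin (LBR / lamin A) enters only
  through one affinity coefficient $\gamma \ge 0$;
* dynamics is deterministic gradient flow — no thermal noise.

The energy is $E = E_0 + E_1 + E_2 + E_3$ with the diffuse-interface term
$E_0$ (gradient energy plus the double well $g(u) = u^2(1-u)^2/4$), the
restriction term $E_1$ (coefficients $\beta_0, \beta_\psi, \beta_\phi$),
the volume term $E_2$ (coefficients $\alpha_0, \alpha_V, \alpha_v$ acting
on $V_m = \int h(\phi_m)$ and $v_m = \int h(\phi_m)h(\psi)$ with
$h(u) = u^3(10 - 15u + 6u^2)$), and the affinity term
$E_3 = \gamma \int \nabla h(\phi_0)\cdot\nabla h(\psi)$. Steepest descent
gives the reaction–diffusion system implemented in `step_state()` (pure R,
the defining reference) and in the compiled stepper (identical to
round-off, used by `run_simulation()`).

Two conventions are worth recording. First, the double well is normalized
so that $-g'(u) = u(1-u)(u-\tfrac12)$, the kernel that appears in the
evolution equations; any other normalization would be inconsistent with
the reaction kernel above. Second, the territory-exclusion sum in $E_1$
counts each unordered pair of chromosomes once. Counting ordered pairs
would double that term's weight and make the reaction field $A_m$ no
longer the exact functional derivative of the evaluated energy; with the
unordered convention the discrete dynamics is an exact gradient flow of
the discrete energy, which is what the energy-descent test verifies to a
relative tolerance of $10^{-6}$ per step.

## Parameters

All parameters are non-dimensional; lengths scale with $L = 5\,\mu m$ and
times with $T = 5\,h$ (mobility $\mu = 1/T$). Defaults follow the
representative set:

| parameter | default | meaning |
|---|---|---|
| $\alpha_0$ | 25/6 | full-occupancy intensity |
| $\alpha_V$ | 10/6 | chromosome volume-target intensity |
| $\alpha_v$ | 20/3 | heterochromatin volume-target intensity |
| $\beta_0$ | 5/3 | confinement to the nucleus |
| $\beta_\phi$ | 1 | territory exclusion |
| $\beta_\psi$ | 2/3 | heterochromatin confinement |
| $\gamma$ | 0 (0.0022/3 when tethering is on) | envelope affinity |
| $\varepsilon_\phi^2$ | 2e-4 (range 1.8e-4–7.4e-4) | territory interface |
| $\varepsilon_\psi^2$ | 6e-4 (range 1.96e-4–7.84e-4) | He–Eu interface |

The gradient coefficients map to intermingling widths through
$\delta = 4\sqrt2\,\varepsilon\,\mathrm{artanh}(1-2\lambda)$ with
$\lambda = 0.15$ (`interface_width()`), i.e. 0.329–0.667 µm between
territories and 0.343–0.687 µm between heterochromatin and euchromatin at
the 5 µm length scale. The products $\mu\varepsilon^2$ are the interface
diffusion coefficients (at most ~4e-3 µm²/h, far below the ~0.16 µm²/h
ceiling implied by measured chromatin mobility).

In the inverted regime the conversion fraction rises along the sigmoid
$\rho_m(t) = \rho_m(0) + \bar\rho_m t/(t + \alpha_1 e^{-\alpha_2(t-t^*)})$
or the saturating variant $\rho_m(0) + \bar\rho_m t/(10+t)$. The scenario
captions label the sigmoid's center "T"; since T is already the time
scale, the presets store it as $t^*$. The caption for the strong/weak
conventional scenarios omits $\alpha_0$; the presets use the
representative 25/6. Both reported values of $\gamma$ (0.0022/3 in the
parameter table, 0.022 in the persistent-affinity ablation) are kept as
preset values; the discrepancy is not resolved here.

## Numerics

* Cell-centered grid on $[0,L_x]\times[0,L_y]$ (default 1.2 × 1.8);
  midpoint Riemann sums with weight $dx\,dy$ for all integrals.
* Five-point central-difference Laplacian; zero-flux (mirror) boundaries.
  The boundary choice is immaterial — $\beta_0$ keeps all evolving fields
  away from the box — but fixing it makes runs bit-reproducible.
* Forward Euler with the diffusion stability guard
  $\max(\varepsilon_\phi^2,\varepsilon_\psi^2)(dt/dx^2 + dt/dy^2)\le 1/2$;
  configurations over the bound are refused, not clamped.
* Resolution tiers: `reference` (200 × 300, dt = 6e-4, the reference
  discretization), `scaled_down` (100 × 150) and `coarse` (60 × 90), the
  latter two with dt scaled in proportion to the cell area so the
  stability factor of the reference scheme (~0.026) is preserved. The
  persistent-affinity scenario needs a smaller step than the coarse tier
  default because its reaction term scales with
  $\gamma\,\nabla^2 h(\phi_0) \sim \gamma/w_0^2$ for nucleus interface
  width $w_0$; `tier_config(dt = )` exposes the override and the packaged
  tests use dt = 2e-3 there.
* $\phi_0$, the targets and $\rho_m(t)$ are refreshed at the start of each
  step (first-order consistent). While the nucleus is static, the
  compiled stepper caches $h(\phi_0)$, its Laplacian and the nuclear
  volume.
* Fields are *not* clamped to $[0,1]$; excursions beyond $[-0.05, 1.05]$
  are logged in the result's `boundViolations` so parameter errors surface
  instead of being masked.
* The nucleus field uses the equilibrium tanh profile over a signed
  elliptical level-set surrogate ($(q-1)q/|\nabla q|$ for
  $q = \sqrt{(x/a)^2 + (y/b)^2}$); the error relative to true signed
  distance is far below the interface width. Interfaces thinner than ~4
  cells trigger a warning (the nucleus profile at the two reduced tiers —
  a known, accepted under-resolution).

## Initial conditions and the day-3 fixture

`sector_init()` tiles the nucleus interior into N angular sectors with a
seeded random offset ("slices of pizza"), each sector smoothed by the
equilibrium tanh width of the territory field so early steps are not
dominated by interface-relaxation shock. Heterochromatin starts as a
peripheral band at the outer end of each sector sized to a per-chromosome
area fraction drawn uniformly from [0.23, 0.28] (one draw per chromosome
from the scenario seed). The bands are inset from the sector boundaries by
one interface arc, with the band deepened to preserve the area fraction:
this gives each chromosome a distinct peripheral dome, matching the
discrete heterochromatin domains seen in newborn rod nuclei, instead of a
single connected peripheral ring. All randomness (offset and fraction
draws) flows from a single seed.

Inverted-regime scenarios start from the day-3 state of a conventional run
with positive affinity (`conventional_fixture()`), regenerated on demand
and cached per session — never shipped as data. Per-chromosome volume
targets are the initial nuclear volume divided by N; initial conversion
fractions are measured from the fixture. By day 3 the peripheral domes
have physically spread along the envelope into a connected band (the weak
separation endpoint is heterochromatin distributed almost homogeneously
along the envelope), so the cluster count of a reorganization run starts
at 1, fragments into per-territory clusters when the affinity is released,
and then fuses monotonically to the terminal single cluster. The packaged
regression checks monotone decrease from that post-release maximum.

## Scenario design choices

* "Size" in shrink percentages means area: a nucleus shrinking "to 60 %"
  ends with 60 % of its initial area (axes scale by $\sqrt{0.6}$, or to
  the equal-area circle when it also rounds up), consistent with the
  model's volume coupling and the reported ~40 % volume decrease.
* The shrink schedule is linear over a window; only the endpoints are
  physically specified. The presets use [0, 134.4] — birth to the P28
  analogue at the 5 h time scale — as the window.
* The chromosome contraction ratio r defaults to the final/initial
  nuclear area so the occupancy and volume-target terms stay compatible
  during shrink.
* Ablation cut-offs: the mild-shrink arms (fixed conversion; persistent
  affinity) use a final area of 80 %. The unoccupied-nucleus arm cuts the
  area *by* 40 % (to 60 %) while chromatin volume targets contract to
  49 % of their starting values with the occupancy term disabled
  ($\alpha_0 = 0$): only then does unoccupied space exist — a nucleus
  smaller than the chromatin target would be refilled and the ablation
  would not test what it claims. The realized final chromatin volume sits
  a few percent below the 49 % target: curvature of the diffuse
  interfaces shrinks domains slightly against the volume penalty.
* The reorganization run continues with $\gamma = 0$ from a fixture built
  with $\gamma > 0$; the switch-off happens at the hand-over (day 3), the
  operational reading of "lack of affinity" during reorganization.

## Analysis metrics

* `count_clusters()`: connected components of $\{\psi \ge 0.5\}$,
  4-connectivity; both threshold and connectivity are explicit arguments
  (these operational choices are this package's, not prescribed by the
  model), and the labeling is cross-checked against an independent
  implementation in the tests.
* `contact_fraction()`: mean $h(\psi)$ over the envelope-adjacent shell —
  the nucleus interface annulus $\{\lambda \le \phi_0 \le 1-\lambda\}$
  dilated inward by a band. The default band is one intrinsic interface
  width $2\sqrt2\,\varepsilon_\psi$ (~0.069 non-dimensional at the
  default $\varepsilon_\psi^2$). A band as deep as the full
  $\lambda$-width $\delta_\psi$ (~0.12) would reach the diffuse boundary
  of a large central cluster: with the reorganization scenario's
  heterochromatin share (~55 % of nuclear area) the euchromatin annulus
  is only ~0.13 wide, so the deeper shell reports contact ~0.15 for a
  fully inverted state at *any* resolution and the classification below
  could never call it inverted. The intrinsic width is the smallest band
  consistent with "contact is meaningful at the interface scale" and
  separates the endpoints cleanly (conventional ~0.8, inverted ~0.03).
* `classify_architecture()`: `inverted_single` (one cluster, contact
  < 0.1), `inverted_multi` (several clusters, contact < 0.1),
  `conventional` (contact at least half the heterochromatin area share),
  else `intermediate`.
* `phase_boundary()`: per nuclear size, the minimal $\delta_\psi$ (or
  maximal $\delta_\phi$) whose sweep run ends `inverted_single`;
  non-monotone sweeps are flagged and reported raw.

## What the tests do and do not show

The synthetic scenarios emulate the geometry, parameter sets and schedules
of the rod-cell reorganization; they do not emulate thermal fluctuations,
three-dimensional geometry, nucleoli, or distinct chromocenters, and no
real microscopy data is touched. Passing tests therefore demonstrate the
model's internal physics — analytic interface widths, gradient-flow
descent, volume targeting, and the qualitative dependence of the endpoint
architecture on affinity, conversion rate and occupancy — at reduced
resolution (the 100 × 150 and 60 × 90 tiers with horizons of 300 time
units, chosen so the terminal pattern is reached; the width-convergence
checks run at the full reference resolution in one dimension). They do not
calibrate the model against images, and agreement at reduced resolution
does not by itself certify quantitative accuracy of, e.g., reorganization
time scales at the reference resolution.

## Known limitations

* Two-dimensional only; the reference discretization in 2-D is the
  reference resolution.
* The nucleus never responds to chromatin (prescribed $\phi_0$).
* Cluster counting at a fixed threshold can be sensitive near merge
  events on coarse grids; the recorded trajectories use strides of ~2
  time units, coarse enough that transient threshold flickers were not
  observed in the packaged scenarios.
* The ratio of minimal interface width to grid size quoted alongside the
  reference discretization (~26) is not reproducible from the
  width formula and parameter ranges (which give ~11); that convention is
  not used anywhere in this package.
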