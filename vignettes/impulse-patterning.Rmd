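---
title: "Impulse-controlled acoustic patterning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impulse-controlled acoustic patterning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acoustopattern)
```

`acoustopattern` is a desk-scale 2D simulator for patterning
microparticles (ultimately, cells) with a circular ultrasonic phased
array by *impulse control*: rapidly switching the array between simple
acoustic states so that the particles respond to the impulse each state
delivers rather than to any single continuous field. This vignette
documents the physical model, the numerical choices, and the design
decisions a user or reviewer would want to audit.

## Device and field model

The simulated device is a ring of `N = 64` phase- and
amplitude-controlled elements around a circular water chamber of
diameter 10.98 mm, driven at 2.35 MHz. The operating wavelength defaults
to the device value 0.644 mm; `c0/frequency` (0.638 mm at 1500 m/s) is
available by constructing the geometry with `wavelength = NULL`. The
two values are mutually inconsistent at the per-cent level (0.644 mm
implies c of about 1513 m/s); both are exposed and the discrepancy is
deliberately left unresolved. All trap-count and node-spacing arithmetic
uses whichever wavelength the geometry carries.

Complex pressure fields are synthesized by Huygens matrix propagation:
for a drive state with per-element complex sources $a_0 = A e^{i\phi}$,
the pressure at grid point $r$ is $p = H a_0$ with

$$H_{rs} = \frac{S_w\, e^{-i k r_{rs}}}{2\pi\sqrt{r_{rs}}}\,
  \mathrm{sinc}\!\left[\frac{a \pi^2 \sin\theta_{rs}}{\lambda}\right],$$

where $r_{rs}$ is the element-to-point distance, $\theta_{rs}$ the angle
off the element normal, $a$ the element width (0.45 mm by default: the
inter-element arc pitch minus a small kerf; this only enters the smooth
sinc directivity), and $\mathrm{sinc}(x) = \sin x / x$ with
$\mathrm{sinc}(0) = 1$. Two conventions are worth stating explicitly:

* the propagation exponent is the complex $e^{-ikr}$ of an outgoing wave
  under the $e^{+i\omega t}$ time convention (a real decay cannot form
  interference traps), and
* under that convention the focusing phase law is
  $\phi_n = s\,2 m \pi (n-1)/N + k r_n$ — the **+** sign on the focusing
  term pre-advances each element so all arrivals are in phase at the
  focus. (With the opposite time convention the same law is written with
  $-k r_n$; using the wrong sign for the chosen convention visibly
  destroys off-centre foci and twin traps.)

$S_w$ is a hydrophone-calibration scale with no effect on any
patterning result, because force fields are normalized downstream; it
defaults to 1.

Drive states implemented: order-$m$ Bessel/vortex fields (order 0 is a
plain focus; the low-intensity core radius grows with $m$ — see
`bessel_ring_radius()`), twin traps (focusing plus a $\pi$ phase
inversion across a cancellation axis, with on-axis elements off), and
sub-aperture standing waves with a $k r_{sw}$ plane-wave curvature
correction and $\pm 2\pi/3$ phase stepping for conveyor transport.

## Forces and particle dynamics

Particles are 90 µm diameter polystyrene spheres in water
($c_0 = 1500$ m/s, $\rho_0 = 997$ kg/m³, $\mu_0 = 0.89$ mPa·s,
$c_p = 2047$ m/s, $\rho_p = 1050$ kg/m³), small relative to the
wavelength, with positive acoustic contrast: they migrate to pressure
nodes. The radiation force is the negative gradient of the Gor'kov
potential

$$U = \frac{4 r_p^3}{3}\left[f_1 \tfrac12 \kappa_0 \langle p^2\rangle
  - f_2 \tfrac34 \rho_0 \langle v^2\rangle\right],
  \qquad f_1 = 1 - \kappa_p/\kappa_0,\quad
  f_2 = \frac{2(\rho_p - \rho_0)}{2\rho_p + \rho_0},$$

with $\langle p^2\rangle = |p|^2/2$, $\langle v^2\rangle = |v|^2/2$ for
complex amplitudes and $v = \nabla p / (-i\omega\rho_0)$ by central
differences. For these materials $f_1 = 0.490$ and $f_2 = 0.0342$. The
leading factor is kept as $4 r_p^3/3$; the conventional $4\pi r_p^3/3$
variant sits behind `conventional_prefactor = TRUE`. The distinction is
immaterial here because every simulation rescales each state's force
field to a common ceiling (`normalize_force()`, default 10 nN), the
simulation stand-in for per-state source calibration.

Dynamics follow the explicit update
$x_{t+\Delta t} = x_t + \dot x_t\Delta t + F_e \Delta t^2/m_v$ (velocity
updated with the same-step force), with virtual mass
$m_v = \tfrac43\pi r_p^3(\rho_p + \rho_0/2) = 5.91\times10^{-10}$ kg and
$F_e$ the radiation force minus quasi-steady sphere drag

$$|F_d| = \tfrac12 \rho_0 \pi r_p^2 C_d |\dot x|^2,\qquad
  C_d = \frac{24}{Re}\Big(1 + \tfrac{3}{16}Re\Big)^{1/2},\qquad
  Re = \frac{2 r_p \rho_0 |\dot x|}{\mu_0},$$

written as $\tfrac12\rho_0\pi r_p^2 C_d\,\dot x|\dot x|$ so that the
$Re \to 0$ limit is the Stokes drag $6\pi\mu_0 r_p \dot x$ (the
speed-independent single-$\dot x$ form sometimes quoted is dimensionally
a misprint). Neglected on purpose: acoustic streaming, substrate
friction, inter-particle and wall forces, and out-of-plane motion.

Numerical choices: the time step is
$\Delta t = \min(\Delta t_q/20,\ \tau/50)$ with
$\tau = m_v/(6\pi\mu_0 r_p) \approx 0.78$ ms the viscous relaxation
time; `step_particle()` refuses steps above $\tau/5$. Forces are
bilinearly interpolated from the grid (nearest-edge value outside it, or
zero for deliberately localized sub-grid fields). Particles are clamped
to the chamber radius minus the particle radius with velocity zeroed at
contact — cleared particles stay at the wall. Field grids use spacing
$\lambda/20$ (the resolution floor for the finite-difference force is
$\lambda/10$), covering the central 4 mm patterning region by default or
the full chamber for clearing studies. The ensemble integrator is
compiled (Rcpp); `integrate_particle()` is a readable R reference path
used to cross-check it.

One normalization subtlety: on grids that graze the transducer ring the
$1/\sqrt{r}$ near field is singular, and a raw grid maximum would crush
the usable force scale. `compile_schedule()` therefore normalizes over
nodes at least 0.3 mm inside the ring (0.7 mm for the conveyor strips).

## Impulse regimes

The control variable is the applied impulse
$I_{app} = \max(F_{ac})\,\Delta t_s$. The 1D bench
(`two_state_bench()`) switches between two ideal standing-wave force
fields $F_q(x) = -F_{max}\sin(2k(x - s_q))$ whose stable equilibria are
separated by $d$. The separation parameterizes an ambiguity: for ideal
counter-propagating sources a quarter-period source offset shifts the
node pattern by $\lambda/8$, not $\lambda/4$ (a $\lambda/4$ pattern
shift would make the two force fields cancel exactly, contradicting a
nonzero summed field), so the bench defaults to $d = \lambda/8$ and all
regime thresholds are defined relative to the measured $d$, making the
conclusions shift-independent.

Three regimes emerge, classified from the per-cycle motion (range of
positions per full schedule cycle, averaged after discarding the first
20% of a 100-cycle window): **low** (motion < 5% of $d$; the particle
sits at the equilibrium of the dwell-weighted mean field
$F_{sum} = \sum_q F_q \Delta t_q / \sum_q \Delta t_q$), **high**
(motion > 95% of $d$; the particle settles in every state), and
**intermediate** between. The thresholds are configurable; 5%/95% make
the plateaus machine-classifiable. Simulation settings per regime (at
the 10 nN ceiling): 1 ms, 8 ms and 40 ms dwells. Switching must remain
far slower than the 2.35 MHz acoustic oscillation for the time-averaged
force model to hold; `compile_schedule()` warns below 100 acoustic
periods.

Motion-vs-impulse curves for different force ceilings collapse onto one
curve — impulse is the controlling variable. The collapse is exact in
the overdamped limit; the inertial dead time $m_v/(6\pi\mu_0 r_p)$ of
the 90 µm particle shifts the transition with $F_{max}$, so the residual
deviation grows with the spanned force range (measured on this bench:
about 7% of $d$ for a factor-2 span, about 14% for a factor-4 span).
`bench_regime_collapse()` defaults to a factor-2 span around 10 nN.

In the low regime, a switched schedule and a single static simulation of
its summed field must produce the same end positions. The summed field
is the *plain* dwell-weighted mean of the individually normalized state
fields, not renormalized — renormalizing the mean would make the static
simulation roughly threefold stronger than the time-averaged switched
one and break the equivalence for in-transit particles.
`bench_switched_vs_summed()` measures a mean end-position discrepancy of
about 1 µm ($\lambda/20 = 32$ µm is the acceptance bound) for 50
particles over 500 ms.

## Patterning and clearing toolbox

**Twin-trap lines.** A line is a switched sequence of twin traps with
the cancellation axis along the line, counted by
$N_{TT} = \mathrm{round}(3L/\lambda) + 1$ and equally distributed.
Nearest-integer rounding is used deliberately: it reproduces both
reference counts (10 traps for 2 mm, 8 for 1.5 mm at
$\lambda = 0.644$ mm) where ceiling reproduces neither; the cost is that
the spacing may exceed $\lambda/3$ by up to half a rounding step (the
2 mm line spaces at 2/9 mm ≈ 1.04·λ/3).

**Conveyor belts.** Three standing-wave states separated by a phase
offset of $2\pi/3$, added on one side of the array and subtracted on the
other, shift the node lattice by $\lambda/6$ per step (a given node
moves $\lambda/3$, which modulo the $\lambda/2$ lattice period is a
$\lambda/6$ lattice shift); trapped particles hop to the nearest node
and travel $\lambda/2$ per 3-step loop, in the direction set by
`offset_sign`. Applied in the high impulse regime.

**Focus sweeps.** Unidirectional rasters of order-0 foci at 0.1 mm point
and line spacing, in the intermediate regime: each focus pushes its
neighbourhood away without pulling cleared particles back.

**Bessel-order cycling.** An order-$m$ vortex has a force-free core
inside its first ring at radius
$r_1(m) \approx (m + 0.81 m^{1/3})/k$. Cycling the order up (default
9 → 20, 300 ms per state) marches the rings outward and ratchets
particles from the transport band $[r_1(9), r_1(20)]$ to beyond
$r_1(20) \approx 2.3$ mm; repetitions (with chirality alternating for
azimuthally even transport) catch particles that slip a ring. The core
is untouched by construction — that is why clearing around an existing
pattern starts at order 9, whose core covers the pattern. Cycling down
agglomerates the band inward. Long dwells are needed because the
normalized field is weak away from the first ring.

**Reshaping.** Formed lines are morphed in the low regime by small
increments — 0.1 mm per translation step, 5° per rotation step, and arc
radius ramps of 0.5/0.25/0.12 mm per step below 5/3/1 mm — with the trap
sweep direction alternating every step (a constant sweep direction drags
the pattern). The circle finale switches 2nd and 6th order Bessel
states; a formed circle can also be held by switching 5th/9th order
states.

**Per-particle removal.** Remaining stragglers are picked up one at a
time by an order-1 vortex stepped radially outward (0.15 mm per 20 ms
step). The vortex core fills in beyond a radius of about 3 mm in this
geometry, so extraction hands off at 2.2 mm to a localized sector
conveyor that carries everything in its strip to the chamber edge.
Removal fields live on sub-grids and are zero elsewhere, keeping
disturbance of the pattern local; identification passes repeat up to
three times.

## Letter study and the contrast metric

`form_letter()` composes the staged recipe: low-impulse skeleton traps
(0.5 s), two repetitions of interleaved Bessel-up clearing (9–14, 15–20)
with skeleton reinforcement, a sector-conveyor sweep of the mid-field to
the edge, a final reinforcement, and per-particle straggler removal.
Letter skeletons ('A', 'B', 'C', default height 2.2 mm) are polyline
approximations drawn for this package; all contrast numbers refer to
these skeletons, not to any external letter geometry.

The contrast metric `fraction_outside()` reports the percentage of
particles that are neither within `tolerance` of the skeleton nor within
`edge_margin` of the chamber wall. Neither threshold has a printed
reference value; the defaults — tolerance $\lambda/4$ (traps localize
particles well within a quarter wavelength) and edge margin $2\lambda$ —
are stated in every output and the metric should be read as
defaults-dependent. The letter benches seed the 500-particle ensemble
uniformly over the full chamber: the letter study is a chamber-scale
process (clearing transports particles far beyond the central 4 mm
field of view that the patterning benches use). With these settings,
low-impulse patterning alone leaves roughly 60% of particles off
pattern, and the full recipe brings the figure to at or near zero —
both numbers are recomputed, never asserted, by the test suite and by
`scripts/acceptance.R`.

## What the synthetic benches do and do not show

The ensembles are ideal: uniformly seeded, zero initial velocity,
non-interacting spheres of identical material with instantaneous,
error-free switching. Passing benches therefore demonstrate the control
logic and the force physics, not robustness to the effects a wet device
adds: static friction on the substrate (which sets a lower force bound
for any motion at all), inter-particle cohesion after agglomeration,
acoustic streaming for smaller particles, element-to-element output
variation, and a finite (tens of milliseconds) switching latency. Those
effects are why the corresponding experimental settings differ from the
simulation dwells; the experimental drive voltages map to force
ceilings via `voltage_to_force()` ($F \propto V^2$, 20 V ↦ 10 nN) but
the simulated recipes use the 10 nN ceiling throughout, matching the
study conditions of the simulated-pattern benchmark.

## Problem sizes

Default bench sizes were chosen to keep any single bench in the minutes
range on one core: 13 switching times × 3 force ceilings × 100 cycles
for the regime sweep; 50 particles × 500 ms for the equivalence bench;
500 particles across the full chamber, with full-chamber λ/20 field
grids (about 116 000 nodes × 64 elements per state), for the letter
study.
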