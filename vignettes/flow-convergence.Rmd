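---
title: "Quantifying mitral regurgitation from velocity fields: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitral regurgitation from velocity fields: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pisaflow)
```

## The problem

Mitral regurgitation (MR) is retrograde systolic flow from the left ventricle
into the left atrium through an incompetent mitral valve. Its severity is
graded from echocardiography, most commonly with the flow-convergence (PISA)
method: color Doppler shows the blood accelerating toward the orifice, and
the first aliasing contour — where the projected velocity equals the chosen
aliasing velocity $V_a$ — is read as a hemispherical shell of radius $r$.
Under the assumptions of an idealized half-space sink this gives

$$\mathrm{RFlow} = 2\pi r^2 V_a, \qquad
  \mathrm{EROa} = \mathrm{RFlow}/V_\mathrm{max}, \qquad
  \mathrm{RVol} = \mathrm{EROa}\cdot\mathrm{VTI},$$

with $V_\mathrm{max}$ the peak jet velocity and VTI its velocity–time
integral over systole. Real orifices are finite and often elongated, the
chamber is confined, and the Doppler probe measures only the beam-aligned
component — each of which breaks an assumption. This package provides the
estimator chain, a ground-truth integrator in the style of particle image
velocimetry (PIV) post-processing, potential-flow models of the convergence
zone with exact closed forms, and a synthetic pulsatile-jet generator, so
that every error trend of the method can be produced, measured and tested on
data with known truth.

## Units and coordinates

Orifice geometry is catalogued in mm (heights, widths, areas in mm²); all
flow-side quantities are clinical units — cm, cm/s, cm², ml, ml/s — and the
conversion happens only in the orifice accessors (`orifice_area_cm2()`,
`orifice_polygon_cm()`). The $x$ axis is the streamwise/beam axis with the
orifice plane at $x = 0$: the convergence zone occupies $x \le 0$, the jet
$x \ge 0$. $y$ is in-plane cross-stream, $z$ the plane-traversal axis. Times
are ms within one cardiac cycle (750 ms, i.e. 80 bpm, by default).

## Orifice models

Three parametric shapes cover the phantom catalog (`orifice_catalog()`),
which records the laser-cut phantoms' scanner-measured areas:

* **circle** — diameter $h$; area $\pi h^2/4$ exactly.
* **slit (pointed oval)** — a symmetric two-arc lens with chord $w$ and
  sagitta $h/2$ per arc, so the tips at $\pm w/2$ are sharp. Closed-form
  area $R^2(\theta - \sin\theta)$ with $R = (w^2+h^2)/(4h)$,
  $\theta = 2\arcsin(w/2R)$.
* **drop** — a disk of diameter $h$ joined to its tangent wedge, apex at
  distance $w$ from the blunt end; area
  $R^2(\pi-\varphi) + R\sqrt{d^2-R^2}$ with $R = h/2$, $d = w-R$,
  $\varphi = \arccos(R/d)$.

Non-circular areas are computed by polygonization (8192 boundary vertices)
and the shoelace formula; the tests check the polygons against the closed
forms. These are surrogate parametrizations — the phantoms' CAD outlines are
not published — and they track the scanner-measured areas to within about
1.5% (circles), 8% (slits) and 11% (drops); the drop model's worst case is
the smallest drop, where the measured cut is visibly fatter than the
disk-plus-wedge ideal. Polygons are counter-clockwise with the origin at the
area centroid.

## Convergence-zone flow models

The convergence zone upstream of a small orifice is smooth, nearly
irrotational flow, so potential-flow models with exact oracles stand in for
expensive simulation:

* **Half-space point sink** (`point_sink_field`): speed $Q/(2\pi R^2)$
  toward the origin. The PISA chain is *exact* on this field, which makes it
  the null model: any estimator deviation here is interpolation error, and
  the tests bound it by 0.5%.
* **Circular aperture** (`aperture_axial_profile`): the exact axial velocity
  of potential flow through a circular hole in a wall,
  $u(x) = Q/\bigl(2\pi(x^2+a^2)\bigr)$. It yields the closed-form error law
  $\mathrm{rel.err}(V_a) = -2\pi a^2 V_a/Q$ — linear underestimation growing
  with aliasing velocity and orifice size — which anchors the sensitivity
  analysis. The model is used on the axis only.
* **Panel sink sheet** (`sink_sheet_field`): uniform-strength point-sink
  panels over the orifice polygon (default 512, centroid-fan triangulation
  with radial bands; strengths sum exactly to $Q$). This carries the orifice
  *shape* into the near field while reducing to the point sink far away. A
  uniform-density sheet is not the exact aperture solution (the exact
  aperture has an inverse-square-root edge density): on the axis the uniform
  circular sheet is $Q/(\pi a^2)\,(1 - x/\sqrt{x^2+a^2})$, which exceeds the
  exact-aperture profile substantially in the near field and approaches it
  only in the far field. The tests assert that closed form, not a near-field
  agreement with the aperture model.
* **Wall-image confinement** (`confined_sink_field`): mirror-image sinks
  across chamber walls at $y,z = \pm H$ (square-duct image lattice truncated
  at a configurable reflection order). Images elevate the far field, so the
  isovelocity contour at low $V_a$ sits too far out and PISA
  *over*-estimates — combined with the finite-aperture underestimation at
  high $V_a$ this produces the characteristic error curve with an interior
  zero crossing.

Conservation is testable: the flux of any of these models through nested
hemispheres recovers $Q$ (Gauss–Legendre in the polar angle, periodic rule in
azimuth; `hemisphere_flux`).

## The clinical estimator

`beam_project()` forms the beam-aligned velocity component, positive toward
the probe. `pisa_radius()` scans from the orifice centroid along the $-x$
flow axis — the radius is read on the centerline of the aliasing envelope,
as on the machine display — while the *measured component* is beam-projected,
so a tilted probe reduces the on-ray velocity by the cosine of the tilt and
the chain underestimates accordingly. The radius is the farthest contiguous
super-threshold sample, refined by linear interpolation between the
bracketing samples; contiguity from the orifice guards against detached
noise islands. Aliasing velocities above the on-ray maximum, or whose
contour leaves the grid, raise informative errors (the sensitivity sweep
records them as flags instead).

$V_\mathrm{max}(t)$ is the per-phase maximum projected velocity within 20 mm
of the orifice on the jet side (the convergence side is used as a fallback
when a steady convergence-only field is analyzed); VTI is its trapezoidal
time integral over the systolic window. The window is explicit where known
(the generator's systole), otherwise the contiguous interval where
$V_\mathrm{max}(t)$ stays above 10% of its peak. `pisa_estimate()` freezes
the radius at the phase of peak velocity, mirroring clinical practice; a
phase-averaged variant is available via `phase_mode = "average"`.

## The PIV-style reference

The reference regurgitant volume integrates the streamwise velocity over the
exit station: per plane $\int u\,dy$ (trapezoidal), across planes
trapezoidal in $z$, and for circular orifices a single mid-plane revolved,
$\int u\,2\pi|y|\,dy$. The station is the first cell downstream of the
orifice plane. `reference_rvol()` then integrates $\dot V(t)$ over systole.
Plane-count convergence depends on the per-plane flux profile: it vanishes
continuously at the orifice's short-axis edges, and with 5 equispaced planes
across the large slit the trapezoid is visibly biased; at the bench's 7
layers the change to 9 layers is within 2%, and 9 vs 33 within 1%, which is
what the tests assert.

Uncertainty follows PIV practice: each phase is an ensemble of noisy frames,
and `bootstrap_ci()` resamples frames with replacement within each phase,
recomputing RVol per replicate (the flux is linear in the field, so
per-frame fluxes are computed once). The reported interval is the
ensemble-mean RVol ± twice the replicate standard deviation ("2σ"), with a
normal-2σ rather than percentile convention. Default 1000 replicates;
at least 200 are required, and at least 2 frames per phase.

## The synthetic-data generator

The generator is the package's stand-in for the pulsatile rig plus PIV
chain, and its defaults are the bench conditions: 42 phases over a 750 ms
cycle, 0.5323 mm vector spacing, 100 frames per phase for ensembles, and a
jet waveform with the measured morphology — a local maximum at 210 ms from
the starting vortex, the global maximum at 245 ms, then an exponential-like
decay.

**Waveform.** `waveform()` composes four analytic kernels (Gaussian lobes at
the two peaks, a narrow dip kernel between them, and a decay kernel whose
Gaussian rise blends into an exact $e^{-t/\tau}$ tail), then solves the four
amplitudes from $U(t_l)=U_l$, $U(t_g)=U_g$, $U'(t_l)=U'(t_g)=0$, so both
peak values are exact and both peaks are true stationary maxima. A quintic
smoothstep window confines the curve to systole with vanishing first and
second derivatives at both ends. Physiological flow curves are smooth, and
this construction keeps the waveform resolvable by the 42-phase sampling:
the trapezoidal integral of the sampled waveform agrees with the exact
integral to about $10^{-3}$ — the kernel time scales (12–24 ms) sit at the
sampling resolution, which is as sharp as a double-peaked 35 ms-separation
morphology allows. Defaults $U_l = 155$, $U_g = 212$ cm/s put the
large-circle phantom's regurgitant volume at the moderate-regurgitation
scale (≈ 35 ml) observed for such orifices; $\tau = 80$ ms and systole
[130, 530] ms complete the cycle.

**Exit profile.** The jet exit velocity is
$u(y,z,t) = U(t)\,c\,(1+\beta\hat\rho^2)$ inside the orifice and zero
outside, where $\hat\rho$ is the normalized boundary distance (0 at the
incenter, 1 at the rim; for all three shapes the inradius is $h/2$). With
$\beta > 0$ the maximum sits at the rim — the saddle-backed profile of
sharp-edged orifices, with center-to-max ratio $1/(1+\beta)$; $\beta = 0.3$
is the default, $\beta = 0$ gives a block profile.

**Flux calibration.** The amplitude $c$ is normalized *per generated grid*
so that the package's own station quadrature of the discrete field equals
$U(t)\cdot A$ exactly (axisymmetric rule for 2D circle fields, plane-stack
rule for 3D fields). The programmed regurgitant volume is then
$A\int U\,dt$ with the time integral by adaptive quadrature. The profile is
edge-discontinuous, so a continuum normalization would leave an
$O(\Delta y)$ gap — several percent at PIV spacing — between "programmed"
and "contained" volume; calibrating on the grid makes the programmed value a
property of the data a user actually receives. Non-circular orifices
require a $z$ axis (a mid-plane alone cannot program a full flux).

**PIV sampling.** `piv_sample()` resamples each phase onto the PIV grid
(spacing at least the native spacing; $z$ planes are kept) and adds i.i.d.
zero-mean Gaussian noise per frame, per vector, per component, all behind a
single integer seed; identical seeds give bit-identical ensembles. The
default cross-stream half-width of the exit grid (3 cm) reflects the
camera's field of view around the jet: the noise budget of a flux estimate
scales with the number of vectors integrated, so truncating the grid to the
orifice would understate the measurement uncertainty. What the generator
does *not* emulate: vena-contracta narrowing, jet spreading and entrainment,
out-of-plane loss, correlated PIV noise, orifice motion. Passing tests
therefore certify the estimator chain and its error laws on clean
convergence-zone physics, not PIV image processing on real jets.

## Sensitivity analysis

`error_curve()` evaluates the model velocity analytically along the scan ray
(step 5 mm/1000 = 0.005 cm; sink-sheet rays start two panel lengths off the
sheet to stay out of the panel near-field), extracts the radius per $V_a$,
and reports $(\mathrm{RFlow}-Q)/Q$. The default grid 5–60 cm/s in 1 cm/s
steps covers the recommended clinical range. The **optimal aliasing
velocity** is defined as the zero crossing of the error curve (linear
interpolation between bracketing points) — the unique definition on which
"optimal" produces zero flow error; monotone curves fall back to the
$|$error$|$-minimizing grid point, flagged as a boundary optimum. The
**admissible band** is the maximal contiguous interval around the optimum
with $|$error$| \le$ 20% (edges refined by interpolation).
`sweep_shapes_sizes()` runs catalogs of orifices — including the extra 16
and 20 mm circles used to visualize the size trend — and can rescale shapes
to equal area for pure shape comparisons. Note the physical ceiling: a
20 mm circle at 244.9 ml/s has an on-axis maximum below 40 cm/s, so high
aliasing velocities legitimately have no crossing and are flagged.

## Diagnostics and grading

`q_criterion()` computes $Q = \tfrac12(\|\Omega\|^2 - \|S\|^2)$ from
central-difference gradients of the in-plane 2×2 velocity-gradient tensor,
interior nodes only — the planar (2D2C) convention, since that is what
planar PIV measures. Solid-body rotation at rate $\omega$ gives
$Q = \omega^2$, pure shear gives 0, and the discretization converges at
second order on the Lamb–Oseen vortex (tested). `profile_metrics()` reports
the saddle index $u_\mathrm{center}/u_\mathrm{max}$ and the block-profile
excess $(V_\mathrm{max} w - \int u\,dy)/\int u\,dy$ — the fraction by which
the uniform-profile assumption behind EROa overstates the flow.

`grade_severity()` implements the published ASE boundaries with four grades
for RVol (< 30 / 30–44 / 45–59 / ≥ 60 ml) and EROa (< 0.20 / 0.20–0.29 /
0.30–0.39 / ≥ 0.40 cm²) and three for the vena contracta width. The source
table typesets three column labels over four value columns; we read it as
the standard four-class ASE scheme, splitting "moderate" from
"moderate-severe", with boundaries closed on the lower edge (the VCW
moderate band is the closed interval 0.3–0.7 cm as printed).

## Study orchestration

`run_study()` ties everything together per orifice: generate the jet series,
run the clinical chain at each configured $V_a$ (radius from the configured
convergence model at the peak-systolic flow rate $U_g A$), integrate the
reference RVol (with bootstrap uncertainty when noise is configured), grade
both, and report the signed relative deviation (negative = PISA
underestimates). With the ideal point-sink convergence model the two RVol
routes agree within 2% — the saddle factor cancels algebraically between
$V_\mathrm{max}$ and VTI — which is the end-to-end null control in the
tests; with the aperture or panel models the deviation grows with orifice
area, reproducing the method's documented failure mode. Configurations
serialize to JSON and reruns are bit-for-bit reproducible from config plus
seeds.

## Numerical choices, in one place

* Ray sampling: half the finest grid spacing for gridded fields, 0.005 cm
  for analytic models; crossing by linear interpolation; farthest
  *contiguous* super-threshold sample.
* Quadratures: trapezoidal for stations, planes and time (matching PIV
  practice); Gauss–Legendre × periodic for control surfaces; adaptive
  quadrature (`integrate`, rel.tol 1e-10) for the programmed waveform
  integral.
* Panel rule: centroid point-sink panels on a fan triangulation, ≥ 512
  panels; scan standoff two panel lengths.
* Test problem sizes: 0.25 mm grids near the scan ray, 1000-panel sheets in
  shape sweeps, 100-repetition coverage runs at 42 × 100 frame sampling —
  sizes at which every asserted tolerance has converged.
* Degenerate inputs: zero-flow series grade mild and return all-zero
  estimates; single-phase series represent steady flow and require an
  explicit window; empty orifice catalogs yield an empty report with a
  warning, not an error.

## Known limitations

The convergence-zone surrogates are potential flow: no jet-side turbulence,
no unsteady convergence, no leaflet motion. The sensitivity analysis
therefore reproduces the *structure* of the aliasing-velocity error (signs,
orderings, zero-crossing behavior) but its absolute optimal velocities
depend on chamber geometry and are configuration-specific. The 2σ bootstrap
quantifies frame-noise uncertainty only — discretization bias is separately
bounded by the noise-free tests but is not part of the interval. And the
drop phantom's parametric area sits ≈ 11% below the scanner measurement at
the smallest size, a known gap between the disk-plus-wedge surrogate and the
physical cut.
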