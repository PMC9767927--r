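---
title: "Models and methods for nanorod rotation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for nanorod rotation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnrtrack)
```

This vignette documents the models implemented in `gnrtrack`, the
assumptions behind them, the numerical choices that matter, and what the
synthetic-data tests do and do not establish about real recordings.

## The physical picture

A gold nanorod (GNR, 40 × 68 nm by default) carries a team of weakly
processive kinesin motors rigidly on its surface. Moving along a suspended
microtubule, the team's collective torque drives two coupled rotations of
the rod: an orbital (rolling) motion around the microtubule axis on a
left-handed helix of short pitch (~0.7 µm), and a yaw rotation about the
rod's short vertical axis at half the orbital angular rate, so the rod turns
180° per orbit. Dark-field polarization imaging reads the rod's in-plane
orientation out of two orthogonally polarized spots.

## Coordinate conventions

One set of conventions is used by the generator and every analyzer:

* X along the microtubule axis toward the plus end; Z vertical; Y completes
  a right-handed frame. In image terms, X right and Y up, viewed from +Z.
* Positive orbital angular velocity `omega_helix` denotes the left-handed
  orbit: the centre starts at the top of the orbit `(0, 0, h)` and moves
  toward +Y while advancing toward +X.
* Yaw is rotation about Z; `omega_yaw < 0` is clockwise in the image.
* In-plane orientations live on [0°, 180°) because the rod's polarized
  scattering is head–tail symmetric. Radians internally, degrees at every
  user-facing interface.

## Rigid-rod kinematics

The rod pose composes three ingredients: the helical centre trajectory
`(v t, h sin ωt, h cos ωt)`; the extrinsic rotation sequence roll(X) ·
pitch(Y, fixed at zero) · yaw(Z) applied to the tip/end offsets `±r(cos φ,
sin φ, 0)`; and the initial phase angle φ, defined at the top of the orbit.
`rod_pose()` evaluates the closed forms; `rod_pose_matrix()` evaluates the
literal matrix product, and the two are held equal to 1e-12 on random
parameter draws — the algebraic identity is a standing regression test.

The projected in-plane angle is computed as `atan2(Y_tip − Y_end,
X_tip − X_end)` folded to [0°, 180°), never through the equivalent
`arctan(cos · tan)` form, whose tangent poles are numerical traps. The angle
is undefined only where the projection collapses to a point (rod
momentarily vertical), a measure-zero set that is flagged per sample.

Three consequences of the model carry the analysis:

* With `|omega_yaw| = omega_helix / 2` the rod turns exactly 180° per
  orbit, so the polarization signal's period equals the orbital period and
  the *polarization pitch* equals the *helix pitch*.
* The apparent rotation of the projected angle depends on the (random)
  initial phase: counterclockwise near φ = 0°, clockwise near 90°,
  oscillatory near 45° and 135° for clockwise yawing (`classify_pattern()`),
  with the map mirrored for counterclockwise yawing. A series counts as
  unidirectional when its net unwrapped rotation per orbit is within 10% of
  ±180°; the threshold is this package's choice.
* With zero yaw the projected angle is periodic with the orbital period and
  never unidirectional, whatever the roll. A motor that neither orbits nor
  yaws (a protofilament-tracking control) keeps both the angle and the
  channel intensities constant.

## Polarimetry

The beam displacer splits the scattered light into a bottom and an upper
spot:

\[
I_{bottom} = I_0 \cos^2(\theta+\zeta)\cos^2(\theta+\zeta-\eta) + b,
\qquad
I_{upper} = I_0 \cos^2(\theta+\zeta)\sin^2(\theta+\zeta-\eta) + b .
\]

`I0` is the amplitude (counts), ζ the incident-beam polarization phase, η
the displacer phase, `b` the per-channel background; the reference
calibration used throughout the tests is `I0 = 127.5`, ζ = 99.3°,
η = 45.3°, `b = 19.5`. Both phases are identifiable modulo 180°.

**Calibration fitting.** The sum channel isolates `I0`, ζ and `b` through
`I0 cos²(θ+ζ) + 2b`, which is linear in `(1, cos 2θ, sin 2θ)`; a coarse grid
then seeds η, and the joint two-channel Levenberg–Marquardt fit refines all
four parameters (standard errors from the fit covariance). On a noiseless
sweep the recovery is exact to ≤ 1e-6 relative error; at 3-count channel
noise and a 10° sweep, η is recovered to well under a degree (both are
tests).

**Angle inversion.** `estimate_angle()` minimises the squared two-channel
misfit over θ by a 0.5° grid plus golden-section refinement. Analytic
inversion through the DOP is avoided because with `b > 0` the DOP is not
exactly `cos 2(θ+ζ−η)`. Pairs carrying no signal above background (the rod
near the optical null, `θ + ζ ≈ 90°`) are flagged undefined at a relative
threshold of 1e-3 of `I0`. On series, near-degenerate minima are resolved
toward the previous frame's angle (circular distance modulo 180°); the
first frame takes the smaller angle. The paper trail for these tie-breaks
is the round trip: inverting the model intensities of a synthetic track
reproduces the exact angle series to ≤ 0.5° RMS at zero noise.

**DOP–intensity ellipse.** As θ sweeps 180°, the point (summed intensity,
DOP) traces a closed conic. With `b = 0` the locus is exactly an ellipse;
with `b > 0` it is a quartic that remains nearly elliptical for `b ≪ I0`,
which is why an ellipse fit describes it well in practice. The fit is the
direct (ellipse-constrained, algebraic) least-squares method on
unit-box-scaled coordinates: deterministic, no initialisation, with the
constraint `4ac − b² = 1` selecting the single admissible eigenvector. The
reported `coverage` — the fraction of 10° bins of the eccentric anomaly
visited — separates continuous polarization rotation (full loop) from
oscillatory arcs.

## Spot tracking

Spots are fitted with axis-aligned elliptical 2D Gaussians plus a constant
offset (Levenberg–Marquardt, moment-based starts). Axis alignment matches
the astigmatic readout, whose axes are the camera axes. Channel intensity
is the integrated volume `2π A s_x s_y` rather than the peak amplitude, so
defocus reshapes but does not dim the measurement. Z comes from the width
ratio, `Z = 0.98 µm · (s_y/s_x − 1)` by default. Fits that end on the patch
border, with non-positive amplitude or width, or on a flat patch are
flagged unconverged; frames missing a converged spot pair are flagged in
the track and never interpolated. The moving-average smoother (default 15
frames at 100 frames/s) truncates its window at the series ends rather than
padding, so no phantom values appear.

## Trajectory quantification

* **Velocity** is the least-squares slope of X against time.
* **Cycle detection** places boundaries at successive upward zero crossings
  of the smoothed, mean-subtracted series, with linear interpolation of the
  crossing time and a hysteresis guard: a new boundary counts only after
  the series has dipped at least a quarter of its SD below the level,
  which rejects noise double-crossings. Partial cycles at the ends are
  discarded by construction.
* **Helix pitch** is the X displacement per Y cycle; **polarization pitch**
  per 180° of angle. For angle traces with net rotation, boundaries are the
  crossings of the mid-levels (start + 90° + 180°k) of the smoothed
  unwrapped series — mid-levels sit far from the plateau wobble of the
  coupled-rotation waveform, so they are crossed cleanly once per
  half-turn; traces without net rotation fall back to oscillation cycles of
  `cos 2θ`. The DOP, whose natural crossing level is zero, can substitute as
  the cycle signal when the angle is undefined over part of a track.
* **Supertwist correction**: the measured pitch composes the motor pitch
  with the microtubule supertwist reciprocally, so `correct_pitch()`
  inverts `1/P_meas = 1/P_motor + 1/P_mt` with the left-handed-positive
  sign convention and the supertwist table −3.4, −24.8, +6.8 µm for 12-,
  13- and 14-protofilament lattices. For sub-micrometre measured pitches
  the correction is a small perturbation (the bound is tested).
* **Yaw direction**: the Pearson correlation between the Y displacement and
  the angle series is negative for clockwise and positive for
  counterclockwise yawing. The angle series is unwrapped and linearly
  detrended before correlating. Detrending is this package's reading of the
  correlation rule: it removes the net-rotation ramp and exposes the
  orbit-locked modulation whose phase encodes the yaw sense at *every*
  initial phase angle (on the raw wrapped series the correlation's sign
  flips with φ at the unidirectional phases, and no universal rule is
  possible). Direction calls below `|r| = 0.3` are reported undetermined;
  the cut-off is this package's choice.
* **Statistics**: the direction count is tested against equal probability
  by an exact two-sided binomial test (doubled smaller tail, capped at 1 —
  identical to the central exact test at p = 1/2), and group comparisons
  use Welch's unequal-variance t test.

## Ratchet flux theory

While the two-state ratchet's potential is off, a particle released at
lateral offset `d` diffuses freely with density
`P(x; t) = exp(−(x−d)²/4t) / (2√(πt))` (lattice units, diffusion constant
1). Evaluated after `1/γ` units of time against barriers at `α` ahead and
`−(1−α)` behind, the fluxes take the erfc closed forms

\[
J_0 = \frac{\gamma}{4}\left\{\mathrm{erfc}\!\left[\frac{\alpha}{2}\sqrt{\gamma}\right]
    - \mathrm{erfc}\!\left[\frac{1-\alpha}{2}\sqrt{\gamma}\right]\right\},
\qquad
J_{\pm d} = \frac{\gamma}{4}\left\{\mathrm{erfc}\!\left[\frac{\alpha \mp d}{2}\sqrt{\gamma}\right]
    - \mathrm{erfc}\!\left[\frac{1-\alpha \pm d}{2}\sqrt{\gamma}\right]\right\}.
\]

The module's standing oracle holds these equal (to 1e-10) to the direct
quadrature `γ/2 · [P(X > α) − P(X < −1+α)]` of the density across a
parameter grid. Note the printed `γ/4` prefactor attaches a rate to what
quadrature yields as a probability times `γ/2`; the forms are implemented
verbatim as the fluxes are reported in these units. At the reference
parameters α = 0.53, γ = 160 s⁻¹, the net three-particle flux
`J(−d) + J0 + J(+d)` is minimised at `d = 0.5` (resolved unambiguously on a
0.005 grid), the backward branch dominates (`|J(−d)| > |J(+d)|`) on
(0, 1−α), and `σ = √(2/γ) ≈ 0.11` links the theory to the cargo
simulator's diffusion scale.

## Cargo Monte Carlo

Thirteen motors connect a rigid cargo to a 2D lattice through springs
(k = 1) anchored at joints riveted to the cargo. Per tick, bound motors
detach with probability 1/40 and detached ones rebind with probability
1/10 (the printed mean on/off times); a detached motor accumulates Gaussian
diffusion of SD 0.11 per tick around its joint. X is unbounded; 13 Y-sites
correspond to one circumference of the 13-protofilament track.

**Stepping rule.** The supplementary stepping pseudo-code is not part of the
source text, so the rule is this package's construction, chosen to mirror
the flux theory: at rebinding, the particle's displacement from its home
site — accumulated diffusion *plus the rotation-induced displacement of its
joint since detachment* (the theory's ±d offset) — is compared against the
asymmetric barriers (α_X = 0.12 ahead / 0.88 behind on X; α_Y = 0.58 toward
+Y / 0.42 toward −Y), and the motor lands on its previous site displaced by
one site per crossed axis. Every site change is therefore a counted step,
and with σ = 0 stepping is quenched (the only residual input is the tiny
rotational re-equilibration of the pose when the bound set changes).
Alternative readings (pure-diffusion test; full joint displacement
including translation) are each one line away in `cargo_tick()`; the first
decouples torque from lateral transport entirely and the second
double-counts cooperative strain.

**Balance.** After each tick the cargo pose solves `Σ k d_i = 0` and
`Σ l_i × k d_i = T_step · N_step`, with `l_i` the joint positions about the
centroid of the bound joints and `N_step` the number of motors that stepped
this tick. Closing the force equations reduces the moment to a single
sinusoid `A cos(θ + ψ)` in the rotation, solved exactly on its stable
branch with pose continuity — residuals are at machine precision rather
than an iteration tolerance. When `|T_step · N_step| > A` (the spring
team's maximum restoring moment; a fraction of a percent of stepping ticks
at T_step = −24 with the default joint circle of radius 2), no balanced
pose exists: the cargo takes the maximum-moment pose and the tick is
flagged `saturated`, with the residual reporting the unbalanced excess.
The moment is written in the standard r × F orientation, under which the
persistent rotation locked in by the detach/rebind cycle runs clockwise
for negative step torque, as the torque-generating motor requires; the
per-tick transient rotates the opposite way and relaxes. Joints sit
uniformly on a circle of radius 2 lattice units — the geometry is otherwise
unconstrained, and isotropic moment arms keep the moment equation
well conditioned.

**Calibration.** Under this stepping rule the printed parameter set yields
a net forward:leftward ratio near 100:19 rather than 100:13; the precise
ratio produced by a given α_Y is an implementation-detail quantity, so
`calibrate_step_ratio()` re-anchors the documented 100:13 operating point
by a bisection on α_Y with all other parameters held at their printed
values. `pitch_equivalent()` converts a ratio to a pitch under explicit
assumptions: 8-nm on-axis sites and a 13-site circumference, so 100:13
corresponds to `(100/13) · 13 · 8 nm = 0.8 µm`.

**Known deviation.** With torque the pose winds clockwise at roughly 2–3
turns per 13 Y-units traversed, rather than about one; the winding is also
weak relative to its run-to-run wander, and the torque-induced increase in
lateral spread is correspondingly marginal at moderate run counts. Both
trace to the same modelling choice this package makes explicit: the torque
enters the balance only in the tick in which steps occur and fully relaxes
afterwards, so detached motors sample the rotated pose only through
one-tick windows. The corresponding acceptance check on the rotation
period is expected to fail and is left failing rather than widened.

## The synthetic-data generator

`gen_track()` samples the kinematic model at 100 frames/s, evaluates the
two-channel intensities at the exact projected angle, and adds independent
Gaussian noise: 3 counts per channel and 10 nm per axis by default, with
the ground truth always returned alongside. The channel noise magnitude is
a free parameter of the generator (the source reports no measured value);
3 counts matches the scale of the calibration-fit uncertainties, and 10 nm
is a typical dark-field localization precision for gold particles of this
size. The orbit radius (default 35 nm ≈ microtubule radius + rod radius)
cancels from the angle model and only scales the rendered Y–Z excursions.
`gen_image_stack()` renders the two displacer spots as Gaussians of
constant `s_x · s_y` whose ratio encodes Z, on 42-nm pixels, 110-nm
in-focus PSF SD, and a 1.26-µm displacer offset.

The generator is additive-Gaussian throughout: no shot noise, no camera
pixelation artifacts beyond sampling, no polarization mixing beyond the
two-channel model, no Z dependence of the polarization, and no motor-level
stochasticity in the track (velocity and angular rates are constant within
a track). Passing tests therefore establish the *internal consistency* of
the pipeline — generator, forward models, inversions and quantifications
agree with each other and with independent oracles — not the behaviour of
the estimators under real-world noise structure.

## Problem sizes and determinism

Synthetic tracks in the tests run 6 s (601 frames, 3–4 orbital cycles) at
the reference speed; image-pipeline checks render 0.25–3.2 s stacks;
simulator checks pool 1e4–1.3e6 motor-ticks depending on the statistic, and
the torque-effect comparison uses 300 runs per condition. Every stochastic
path flows from a single integer seed (`set.seed` per generator or run),
so identical inputs are bit-identical, and the command-line wrappers write
a manifest (command, parameters, seed, package version) next to every
output.

## Limitations

* Pitching about the rod's third axis is not modelled (it is set to zero in
  the rotation sequence); yaw and pitch are not distinguishable in a
  polarization projection anyway.
* The angle estimator requires a calibrated two-channel model; it does not
  estimate ζ and η from a track.
* Single particle per field of view: the stack tracker associates exactly
  one displacer spot pair per frame.
* The cargo simulator's stepping rule is a documented reconstruction; its
  calibration constants, and the quantitative rotation period, carry that
  caveat.
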