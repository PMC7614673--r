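---
title: "Models and estimators in magsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in magsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magsense)
```

# The sensing problem

A millimetre-scale magnetized elastomer ribbon ("the robot") rests on a soft
tissue surface, anchored by two adhesive footpads with a responsive adhesive
patch at mid-body. A uniform external magnetic field exerts a distributed
torque on the programmed magnetization of the body; the resulting body
shapes, tracked by imaging, encode the mechanics of the tissue underneath.
Two inverse problems are implemented:

* **Static (adhesion).** A stepped field peels the patch off the surface.
  The last attached shape plus the threshold field determine the patch
  pull-off force `Fa`, and `Fa` maps to surface pH through an anchored
  calibration of the pH-responsive adhesive.
* **Dynamic (viscoelasticity).** Under a rotating field the interface strain
  amplitude tracks the substrate storage modulus through a calibrated power
  law, and its roll-off with actuation frequency carries the loss modulus
  through a time constant.

# Forward beam model

The body is an inextensible planar elastica of length $L$, width $w$,
thickness $t$, bending stiffness $EI$, $I = w t^3/12$. Its magnetization
profile $M(s), \phi(s)$ converts a uniform field $\mathbf B$ into a torque
density $\tau(s) = A\,[\mathbf M(s) \times \mathbf B]_z$ with the local
magnetization direction rotated by the body slope $\theta(s)$.

Equilibrium is expressed in far-segment form: at every material point, the
internal moment $EI\,\partial\theta/\partial s$ must equal the moment of all
loads (boundary reactions, gravity, magnetic torque) acting on the part of
the body beyond that point, taken about the point itself. Discretized at 65
nodes (0.1 mm spacing on the 6.5 mm body) with cubic midpoint stencils, this
gives a nonlinear system solved by a damped Newton iteration with
finite-difference Jacobians; the applied field (and, on curved substrates,
the curvature) is ramped by an adaptive continuation. Convergence is
declared at a scaled residual of $10^{-6}$, corresponding to moment
residuals around $10^{-14}\,$N·m and position residuals of nanometres —
comfortably below the measurement scales of the problem. Halving the mesh
changes the solution by $\lesssim 0.02\%$.

Boundary kinds mirror the experimental states: both footpads sliding on the
substrate (deployment sweeps), footpads pinned with the patch conforming to
the substrate ("pinned-fixed-pinned", the attached sensing state), and
footpads pinned with the patch free (detached).

## Parameters and defaults

| parameter | default | origin |
|---|---|---|
| $L \times w \times t$ | 6.5 × 2 × 0.15 mm | finalized design (TLR 0.023) |
| $E$ | 163 kPa | tensile test of the composite |
| $\rho$ | 2.5 g/cm³ | composite density |
| $M_0$ | 130 kA/m | see below |
| $\phi(s)$ | $2\pi s/L + \pi/2$ | single-period harmonic, see below |
| patch | 0.5 mm at mid-body | finite-segment contact |
| footpad distance (attached) | $d/L = 0.75$ | see below |

**Magnetization magnitude.** $M_0$ is not directly measurable after pulse
magnetization. Two independent anchors agree on ~130 kA/m: (i) the NdFeB
volume fraction implied by the composite density (≈ 0.22) times a remanent
magnetization of ~600 kA/m, and (ii) the requirement that the buckling
deployment reach footpad distance ratios down to 0.3 below 20 mT, which the
design sweep documents. At 62 kA/m the model only reaches $d/L \approx 0.41$
at 20 mT.

**Phase offset.** With the plain harmonic $\phi = 2\pi s/L$ a field along
$\pm y$ produces no net load/peel action on the patch in this model; the
quarter-turn offset makes $+y$ the loading direction and $-y$ the peeling
direction, matching the published field protocols. Only the offset relative
to the field axis is physical.

**Attached footpad distance.** The attached sensing configuration uses
$d/L = 0.75$. Deeply buckled configurations ($d/L$ 0.3–0.5) store so much
elastic energy that the springback *presses* the patch (~0.8 mN), which
would hide adhesions below that scale and contradicts the observation that
adhesion alone maintains the buckled shape at zero field. At $d/L = 0.75$
the rest pull-off demand is ~0.1 mN and the demand reaches > 1 mN before any
equilibrium fold on every curvature in ±250 m⁻¹, so the full adhesion range
0.13–0.82 mN detaches inside the stepped protocol band. The 0.3–0.5 range is
understood as the transient buckling deployment.

# Adhesion inversion

At the detachment threshold the body is in the attached state. For each half
of the body between a patch edge and a footpad, every sample $s_i$ yields a
linear equation in the unknown footpad reaction vector: measured
$EI\,\theta'(s_i)$ equals the far-segment moment of the reaction plus
gravity plus magnetic torque at the threshold field. The overdetermined
system (≈ 30 equations, 2 unknowns per half) is solved by least squares —
this uses every tracked sample and is what makes the estimator robust to
single-pixel tracking noise. Whole-body force balance then gives the
adhesive force, and `Fa` is its tensile component along the patch normal
(taken from the tracked shape itself, which makes the estimate
frame-independent up to the fixed gravity direction).

Detachment is detected as an inter-frame jump of the patch-region clearance
larger than twice the pixel pitch. The simulator locates the exact threshold
field by bisection inside the protocol step (treating the staircase
transition as quasi-static), so forward-simulated sequences are inverted
essentially exactly when noiseless (< 0.01%); the stepped *observation* of
`B_detach` in a real experiment would add a quantization error of up to one
step, which is part of what the repeatability figure absorbs.

The pH mapping is a piecewise-linear interpolation between tissue-specific
anchors (porcine stomach: 1.08 mN at pH 1 to 0.31 mN at pH 5; small
intestine: 0.58 mN at pH 4 to 0.11 mN at pH 8); extrapolation is an error
unless clamping is requested, and the reported band reflects the 1-pH-unit
sensitivity of the adhesive.

# Viscoelastic estimation

The dynamic observable is the mean interface normal strain over the central
40% of the body, $\bar\epsilon_{yy} = \int_{0.3L}^{0.7L}
\epsilon_{yy}\,ds / 0.4L$, where the signal-to-noise ratio is highest. The
calibrated forward law is

$$\mathrm{amp}(\bar\epsilon_{yy}) = k\,(E')^{a}\,B_y \Big/
  \sqrt{1 + (\omega\tau)^2}, \qquad \tau = k_\tau\,E'/E'',$$

with $k = 54.128$ Pa/mT, $a = -1.067$, $k_\tau = 0.0703$ s. The first-order
low-pass form is the simplest single-time-constant response consistent with
the frequency-sweep language of the source experiments and is isolated so a
different response model can replace it. $k_\tau$ is read literally as the
ratio of $\tau$ to $E'/E''$.

Estimation proceeds: amplitude per frequency (phase-folded half
peak-to-peak, robust to offsets; cycle boundaries from the waveform, not
the signal), $E'$ from the 0.1 Hz anchor, $\tau$ from the roll-off fit,
$E''$ = $k_\tau E'/\tau$. Because the synthetic world applies the roll-off
at 0.1 Hz too (non-negligible when $E'/E''$ is large), the anchor amplitude
is corrected by the fitted attenuation factor, iterated twice — this is a
consistency refinement of the "storage modulus from the low-frequency
record" rule, not a new estimator. Degenerate sweeps (no roll-off) return
$\tau = 0$ with a warning and a purely-elastic flag.

# Imaging and fields

Robot tracking: Otsu segmentation with modality-appropriate polarity plus a
class-separation guard (a featureless frame must raise a no-robot error,
not segment its noise), morphological closing, largest component,
principal-axis orientation, per-bin transverse centroids, arc-length
resampling and cubic smoothing splines. Image coordinates (y down) are
converted to the physics frame (y up) at the curve boundary. Tilt of the
robot plane about the imaging axis is corrected by
$u_y' = u_y/\cos\varphi$, $\varphi = \arcsin[(l - t)/w]$.

Digital image correlation uses 32 px windows on an 8 px grid with
normalized cross-correlation, parabolic sub-pixel refinement, and a 0.6
validity threshold; invalid points are flagged, never silently filled.
Scattered displacements are gridded by local plane fits (exact for linear
fields) and smoothed by a normalized Gaussian (constants preserved
exactly). The maximum-displacement map is the pointwise range magnitude
over time, invariant to frame order.

# Inclusion localization

A stiff inclusion under the contact line reduces the local deformation. The
detector removes a robust linear baseline (line through the edge medians),
computes a continuous wavelet transform with an L2-normalized Ricker mother
wavelet over 20 log-spaced widths (0.2–3 mm), and calls a detection at the
maximum absolute coefficient when it exceeds 4 robust standard deviations
(MAD) of the smallest-scale coefficients *and* persists three scale steps
away — an isolated noise maximum does not ride a scale ridge, and without
the persistence requirement the pure-noise false-alarm rate of the plain
4-MAD argmax is ~9%, above the intended ≤ 5%. Measured: 2/100 seeded noise
trials. Localization error on noiseless profiles stays below half the
inclusion diameter for 1–3 mm inclusions.

The synthetic inclusion substrate is a reciprocal-stiffness heuristic
(deformation ∝ 1/E′ smoothed by a Gaussian of width equal to the burial
depth), not an elasticity solve — sufficient to exercise the detector, and
labelled as such.

# What the synthetic world does and does not establish

The generators emulate: the stepped load/peel protocol with quasi-static
threshold crossing; substrate curvature (±250 m⁻¹ arcs); single-pixel
Gaussian tracking noise at 10 µm/px; the calibrated strain law with
first-order roll-off and per-record amplitude jitter; particle-seeded
fluorescence frames and x-ray-like body silhouettes with PSF blur and
Poisson+Gaussian noise at a contrast targeting SNR ≈ 39.

They do not emulate: adhesive chemistry and its contact-time kinetics,
viscoelastic constitutive PDEs (the calibration law *is* the material
model), post-detachment dynamics (detached frames are zero-field springback
or an explicit transient arch when that springback grazes an un-modelled
convex surface), robot–fluid interaction, or 3-D effects. A green recovery
test therefore establishes the correctness and noise robustness of the
estimators against their own stated forward models, not the fidelity of
those models to any particular tissue.

# Numerical choices and degenerate inputs

* Scaled Newton tolerance $10^{-6}$; continuation bisects on failure and
  aborts with a typed solver error at a fold (no silent branch jumping).
* Shapes built from noisy positions are smoothed by generalized
  cross-validation splines before differentiation; shapes from the solver
  carry their exact angles.
* A perfectly straight half leaves the tangential footpad reaction
  unidentifiable (it has no moment arm); it is reported as zero.
* Negative footpad reactions (footpads cannot pull) flag an inconsistent
  threshold frame — a warning by default, an error on request.
* Amplitude extraction folds whole cycles only; fewer than two cycles is an
  error, not a guess.

# Known limitations

* The elastica is planar; twist and out-of-plane buckling are out of scope.
* Substrate contact is idealized (pinned footpads, conforming patch);
  unilateral contact of the free body with the surface is not modelled.
* The quasi-static model cannot follow snap-through; protocols that reach
  an equilibrium fold before the detachment threshold raise a solver error
  rather than inventing a answer.
* The viscoelastic estimator inherits the calibration's power-law form;
  materials outside the calibrated stiffness range (≈ 1.9–51.2 kPa) are
  extrapolations.
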