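---
title: "Models and methods behind the tissue-force-microscopy twin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the tissue-force-microscopy twin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tifmtwin)
```

# What is being simulated

Tissue force microscopy measures the stress a small embryonic tissue exerts
by inserting a vertical cantilever (spring constant $k$) and comparing two
positions: the holder "chip" position $X_C$, sensed by a capacitor pair
around the piezo actuator, and the probe tip position $X_T$, imaged through
the tissue. The deflection gives force and stress,

$$F = k\,(X_T - X_C), \qquad \sigma = \frac{F}{A},$$

with $A$ the tissue contact area. This package builds a complete in-silico
version of the instrument and its specimen so that every downstream
software component — calibration, controllers, trackers, analysis — can be
tested against known ground truth.

# The plant: instrument and tissue

## Actuation and sensing

The chip position is `gain * voltage` plus an accumulated random-walk
drift whose increments over a step of $\Delta t$ seconds have standard
deviation `drift_rate * sqrt(dt)`; this is the slow piezo/mount creep that
motivates closed-loop position hold. Out-of-range voltages saturate (a
flag, not an error), as a real voltage controller's rails would.

The capacitor pair follows the parallel-plate law
$C_1 = c_0/(g_0 - x)$, $C_2 = c_0/(g_0 + x)$ with independent Gaussian
readout noise; the difference $\Delta C = 2 c_0 x / (g_0^2 - x^2)$ is
strictly increasing and antisymmetric in $x$, and
`capacitance_difference_to_position()` inverts it analytically as the
ground-truth reference for the empirical lookup table.

Defaults (2 µm/V gain over ±75 V, 200 µm gap, 2000 pF·µm coefficient,
0.004 pF readout noise, 0.02 µm/√s drift) give ±150 µm of travel — enough
for a loading run in which the tissue front advances ~100 µm — with a
capacitance slope of 0.1 pF/µm, i.e. a sensing noise floor of ~0.04 µm per
raw reading.

## The tissue law

No constitutive equation is available for these tissues at this scale, so
the twin uses the minimal phenomenology that reproduces the observed
behaviour — displacement that rises quickly, slows, and stalls. The front
advances with a linear (Hill-like, degree 1) force–velocity law,

$$v = v_0\left(1 - \frac{\sigma_r}{\sigma_a}\right),$$

clamped at zero when the resisting stress $\sigma_r = k\delta/A$ reaches
the active capacity $\sigma_a$ (the stall), and exceeding $v_0$ when
$\sigma_r < 0$ (an assisting load accelerates elongation). With the chip
held, the deflection converges to the fixed point
$\delta_\infty = \sigma_a A / k$ — the algebraic oracle used throughout the
tests.

Two extensions serve the lateral-compression scenario. The capacity can
dissipate, $\dot\sigma_a = -\sigma_a/\tau_d$. A pure clamp would then
freeze the measured stress at its peak (a stalled probe holds its
deflection forever), so the model also includes a passive viscous channel:
when $\sigma_r > \sigma_a$ the front retreats at
$(\sigma_r - \sigma_a)/\eta$. The measured stress then tracks the decaying
capacity with a small lag $\tau_r = \eta A / k$ and decays with the same
timescale $\tau_d$, which is what the dissipation-recovery tests exploit.
The default $\eta = \infty$ reproduces the clamped law exactly.

Contact is no-slip: the tip is pinned to the front (insertion through the
tissue makes slip unlikely at these scales). Coordinates are one
dimensional, positive in the direction the tissue pushes.

An optional cell-density field rides on the front flow with a
flux-conservative first-order upwind scheme; flux is blocked at the foil
interface and at the domain boundaries, so total cell number is conserved
to machine precision while cells pile up against the advancing foil and
thin out beyond it — the pattern the ROI-intensity proxy is tested
against.

Time stepping is fixed-step explicit (default 0.1 s); the dynamics are
hours-slow (the stall rise time is $\delta_\infty/v_0 \approx 8$ min in the
axial scenario), so stiffness is not a concern and multi-hour runs may use
coarser steps (the presets use 1–2 s inner-loop periods).

# Synthetic imaging and localization

Frames are rendered at 0.5 µm/px (16-bit grayscale): a dark tip/foil
profile in brightfield, or a Gaussian spot for dye-labelled tips in
fluorescence, on a static smooth background texture. All profiles are
symmetric in the measurement axis so the intensity centroid of the clean
profile equals the true position by construction — sub-pixel coverage is
computed analytically (rectangles, Gaussians) or by fine sub-row
integration (triangles). Depth degrades contrast: a Gaussian blur whose
s.d. grows linearly with the imaging depth $D_I$ (default 2 px per 100 µm;
the real attenuation-vs-depth curve is tissue-dependent and is left as a
free fixture parameter). Sensor noise is Gaussian read noise plus
Poisson-scaled shot noise.

Two interchangeable localizers are provided, since the original real-time
segmentation algorithm is a free implementation choice:

* **centroid** (default): Otsu threshold → connected components →
  component nearest the prior → intensity-weighted centroid. A local
  background plane fitted around the component is subtracted first;
  without it, static background texture biases the centroid by a fixed
  offset.
* **template**: normalized cross-correlation against a reference patch
  with parabolic sub-pixel peak refinement; the patch records the
  sub-pixel offset it was extracted with so absolute positions remain
  unbiased.

At high SNR (shallow depth, faint texture) the centroid estimator is
unbiased to ~0.01 px with ~0.02 px RMSE; at the default texture level the
RMSE grows to ~0.1–0.2 px, and it rises monotonically with imaging depth —
tip tracking is deliberately the dominant error source, as it is in the
real instrument. Multiplying the high-SNR RMSE (~0.01 µm) by the softest
spring constant (0.01 N/m = 10 nN/µm) puts the force resolution near
0.1 nN, comfortably below the 1 nN design sensitivity.

Tracking uses the previous fix plus a constant-velocity prediction as the
prior; dropouts up to 3 frames (configurable) are bridged by
constant-velocity interpolation, longer runs stay lost, and a trace losing
more than half its frames is flagged. The gap policy is a robustness
choice for feedback control under transient occlusion.

# Calibration and control

The lookup table pairs the averaged capacitance difference with the imaged
chip position over a voltage sweep and fits monotone Hyman-spline
interpolants both ways; a leave-one-out round-trip error is recorded, and
queries outside the calibrated range are refused rather than extrapolated.
With the default 25-point sweep and 10 frames per point the round trip is
accurate to well under 0.1 µm; a 15-point sweep would leave ~0.2 µm of
interpolation error near the nonlinear ends of the travel, which is why
the presets sweep 25 points.

Control is two-rate, reflecting the hardware: a fast inner loop on the
capacitance difference and a slower imaging-rate outer loop. The inner law
is a velocity-form PI on the voltage — the paper-facing behaviours
(rejecting constant drift, holding a setpoint) need integral action and
nothing more; gains default to a loop-gain rule (correct ~40 % of the
error per step) derived from the piezo gain and the capacitor slope, with
anti-windup from the velocity form plus voltage clamping. The raw
capacitance reading is low-pass filtered (EMA, α = 0.25) before the PI
law; the readout noise is high-rate while everything physical is
hours-slow, and without the filter the chip would chase sensor noise.

Constant-force loading converts the target into a deflection target
$\delta^* = F^*/k$, predicts the tip half an imaging period ahead from its
tracked velocity, and sets the chip target $X_T^{pred} - \delta^*$, plus
an outer integral trim on the *measured* deflection error. The trim is
what removes the residual bias from inner-loop tracking lag (the chip
chases a moving setpoint with a ~0.5 s time constant, which would
otherwise leave a few-percent force deficit at high elongation speeds);
with it, time-averaged force errors are below 1 % for targets from 10 to
500 nN.

Stall detection follows the displacement criterion: less than 0.5 µm of
tip motion over a 10-min sliding window (both configurable).

The insertion-angle alignment routine mimics the bench procedure: focus on
tip and base planes, localize both, rotate the arm to null the on-camera
horizontal displacement $h$; the residual is $\sin\theta_I = h/L$. With a
200 µm probe at 0.5 µm/px it converges in 2–3 iterations to residuals of
order $10^{-4}$, far inside the 0.05 acceptance threshold — the bound is
set by the localization noise floor divided by $L$.

# Stress estimation and the uncertainty budget

Contact areas: a foil contacts over `foil_width × min(D, foil_height)`; a
bare tip over the similar-triangles cross-section
$\tfrac12\,(w D/L)\,D$ below depth $D$; both are projected by
$\cos\theta_I$. Insertion depth comes from the difference of recorded
objective z positions and carries a practical ±20 µm uncertainty.

The relative stress uncertainty is decomposed into four components:

* **angle** — the projected-area bound $1 - \cos\theta_I$. The off-axis
  force fraction $\sin\theta_I$ is reported alongside but *not* folded
  into the stress total: it redirects part of the force rather than
  scaling the area, and no correction formula is applied.
* **depth** — the relative area change across $D \pm \Delta D$. It
  vanishes for a fully inserted foil (area no longer depends on $D$) and
  explodes quadratically for bare tips at shallow depth; when the area
  band spans a factor of ten the estimate is flagged as
  order-of-magnitude only.
* **fabrication** — foil cutting tolerance, 10–20 % (default 15 %).
* **tracking** — $k \cdot \mathrm{RMSE}/F$; unbounded (flagged) at zero
  force.

Components combine by worst-case sum by default — the budget is read as a
bound, not a 1-σ estimate — with quadrature as an option (always ≤ the
worst case). For a well-pre-adjusted 100 µm foil construct
($\theta_I = 15°$, foil fully inserted in a thin tissue, high-SNR
tracking) the total is ~19 %; a bare 40 µm tip at $D = 30 \pm 20$ µm is
order-of-magnitude only.

# Analysis conventions

Initial stress is the mean over the first 30 min after insertion
(configurable); the stalling stress is the mean over the latest contiguous
plateau — a region of the moving-average-smoothed trace (default width 5
samples) whose rate stays below a threshold and which spans at least
5 min. Requiring the *latest qualifying run*, rather than a plateau that
reaches the final sample, keeps single noise excursions in the rate from
discarding an otherwise clear plateau. Dissipation is declared when the
post-peak stress drops by more than 20 %, and a log-linear fit to the
declining segment recovers the decay timescale (within a few percent of
the configured $\tau_d$ because the passive-lag correction leaves the
decay constant unchanged). Group comparisons use Welch's unequal-variance
two-tailed t-test, with mean ± s.d. or s.e.m. at the caller's choice; two
zero-variance groups with equal means return $t = 0,\ p = 1$ by
convention.

Synthetic labelled-cell tracks follow a U-shaped planar flow out of the
posterior progenitor pool: an antero-posterior component that reverses
over the track and a constant medial-to-lateral component equal to
`lateral_base + lateral_per_nN × load` — exactly linear in the load by
construction, with independent per-cell noise. Defaults (6 µm/h baseline,
0.04 µm/h/nN, 0.5 µm per 5-min step noise) make a 175 nN load shift the
lateral speed by ~7 µm/h, detectable with power ≈ 1 at 30 tracks.

# Scenario presets and problem sizes

Three presets pin the study conditions (all parameters in
`inst/scenarios/*.yaml`):

* **axial_stall** — k = 0.2 N/m, 200 µm square foil, A = 4×10⁴ µm²,
  σ_a0 = 100 Pa, v0 = 150 µm/h, no dissipation; 2.5 h at a 1 Hz inner
  loop, imaging every 30 s, 0.1 µm tracking noise. Fixed point: 20 µm
  deflection, 100 Pa.
* **ppsm_compression** — k = 0.01 N/m triangular probe, A = 3×10³ µm²,
  σ_a0 = 56 Pa (stalling near 100 nN), v0 = 15 µm/h, τ_d = 2 h,
  η = 0.5 Pa·h/µm; 6 h at 0.5 Hz. Measured stress peaks in the tens of Pa
  and dissipates over hours.
* **constant_load** — k = 0.2 N/m fluorescent sharp tip, F* = 175 nN
  assisting (within the physiological 150–200 nN loading band), 15 min at
  a 5 Hz inner / 1 Hz imaging loop; elongation roughly doubles.

These rates are coarser than the instrument defaults (100 Hz / 2 Hz);
with hours-slow dynamics the discretization error is negligible and
multi-seed Monte-Carlo suites stay fast. Problem sizes used by the test
suite: 20-seed end-to-end stall recovery, 10-seed constant-force accuracy,
50-seed hold-mode drift rejection, 200-frame localization benchmarks,
1000-replicate null calibration of the t-test.

# What passing tests do and do not show

The synthetic tissue is a 1-D phenomenological stand-in: it reproduces
stall kinetics, dissipation, and load-dependent elongation and cell
deflection, but knows nothing of real tissue heterogeneity, 3-D geometry,
wound response, or the biology behind the dissipation (modelled
agnostically as exponential decay). The optics model blurs and adds noise
but has no physical point-spread function or tissue scattering. Passing
tests therefore validate the *measurement chain* — that the software
recovers what the plant truly does, at stated precision, under noise,
drift and occlusion — not the biological numbers themselves, which in a
real experiment depend on the specimen. Known limitations: no beam-bending
PDE (single-spring cantilever), no piezo hysteresis beyond drift, no slip
at the tissue contact, and intensity is only a relative density proxy with
no photometric calibration.
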