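---
title: "Quantitative cardiac phenotyping for adult zebrafish: models and methods"
author: "fishheart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative cardiac phenotyping for adult zebrafish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fishheart)
```

# Scope

Adult zebrafish are a workhorse model for dilated cardiomyopathy (DCM), but
their millimeter-scale, highly trabeculated hearts rule out much of the
mammalian echocardiography toolchain. This package implements the
quantitative phenotyping stack used for such models, at five levels of
organization:

1. **Ex vivo beating-heart mechanics** — a perfused, electrically paced
   isolated heart filmed in two orthogonal planes; biplane volumetry,
   ejection fraction (EF), fractional shortening (FS), fractional area
   change (FAC), radial strain, strain-rate velocities and the
   velocity-strain loop area.
2. **Doppler indices** — E and A diastolic inflow peaks, E/A ratio, and the
   myocardial performance index MPI = (IVCT + IVRT) / ET.
3. **Single-myofibril kinetics** — rates of calcium activation (k_ACT) and
   post-release-restretch force redevelopment (k_TR), biphasic relaxation
   (T_LIN, k_LIN, k_REL), maximal isometric tension, force-pCa Hill
   parameters, and rundown quality control.
4. **Morphometry** — ventricular surface area normalized to body weight
   (VSA/BW), tissue area fractions (trabecular density, intact-myofibril
   fraction), positive-nuclei percentages (TUNEL/PCNA), and single-cell
   areas.
5. **Cohort statistics** — critical swimming speed (Ucrit), Kaplan-Meier
   survival with log-rank testing, and group comparisons (t-test, one-way
   ANOVA with Tukey post hoc).

Because none of these stages can be validated against animal data inside a
software test, every input has a synthetic counterpart with analytic ground
truth (`simBeatingHeartVideo()`, `simMyofibrilTrace()`,
`simDopplerWaveform()`, `simSwimCohort()`, `simSurvivalCohort()`,
`simNucleiImage()`, and friends), and the test suite is organized around
parameter recovery.

# The beating-heart model and the biplane estimator

## Chamber model

The simulated ventricle is a prolate ellipsoid with equal short semi-axes
`a = b` and long semi-axis `c = rho * a` (default aspect ratio
`rho = 1.5`). Its volume follows a raised cosine between end-systolic (ESV)
and end-diastolic (EDV) volume at the pacing rate, end-diastole at `t = 0`:

    V(t) = ESV + (EDV - ESV) * (1 + cos(2 pi f t)) / 2

The raised cosine is a modelling choice: it is the simplest smooth waveform
with exactly one end-diastole and one end-systole per cycle. The ellipsoid
is chosen because the biplane area-length estimator

    V = 2/3 * A_AL * L_AL

(with `A_AL` the short-axis area `pi a^2` and `L_AL` the long-axis length
`2c`) is *exact* on it: `2/3 * pi a^2 * 2c = 4/3 pi a^2 c`. Any deviation
measured on rendered silhouettes is therefore attributable to segmentation
and pixel discretization alone, which is what makes end-to-end EF recovery
a meaningful test.

The default acquisition parameters mirror the target protocol: 2 Hz pacing,
66 fps, 3 s recordings (six cycles), with the geometry rendered at
0.025 mm/pixel on 160 x 160 frames so the end-diastolic ellipse spans about
100 pixels. Optical blur is Gaussian (`blur_sigma`, default 1 px) and pixel
noise is additive Gaussian applied last — the simplest degradations that
exercise robustness without modelling myocardial texture, which is out of
scope.

## Analysis chain

`summarizeHeart()` runs, per frame and plane:

* **Segmentation** (`segmentVentricle()`): Otsu global threshold on the
  intensity-rescaled frame, morphological closing, retention of the largest
  connected component, hole filling. The method in the original workflow is
  a hand-tuned edge detection; a global threshold plus largest-component
  rule was chosen here because it is deterministic, parameter-light, and
  testable against analytic shapes. Frames with no component above
  `min_area` (default 50 px) fail loudly.
* **Geometry** (`frameGeometry()`): area = pixel count x pixel_size^2;
  long-axis length = maximum caliper extent along the principal axis of the
  foreground pixels (+1 px for pixel width); radial profile = distances
  from the center of mass to the first off-mask sample along `n_rays`
  equally spaced rays (default 36, 0.5 px marching step).
* **Volumes**: the biplane formula applied to short-axis area and long-axis
  length, per frame.
* **Cycle detection** (`detectCycles()`): end-systoles as local minima of
  the volume trace with a minimum separation of 0.7 pacing periods (flat,
  quantization-induced plateaus admitted; ties break to the earlier
  frame), end-diastole as the maximum between consecutive end-systoles.
  A cycle count deviating from `duration * rate` by more than one is an
  error rather than a silent partial result.
* **Strain and velocity** (`strainVelocitySeries()`): radial strain is the
  fractional change of the mean ray length relative to its value at the
  cycle's own end-diastole, so strain is 0 at ED and negative in systole.
  Differentiation amplifies pixel noise, so strain is Savitzky-Golay
  smoothed (window 7, order 2 by default; window 1 disables) before the
  centered-difference velocity. Maximal contraction velocity is the most
  negative extremum, maximal relaxation velocity the most positive.
* **Velocity-strain loop** (`velocityStrainLoop()`): shoelace polygon area
  of the frame-ordered (strain, velocity) cycle, absolute value, so
  traversal orientation is irrelevant. For harmonic strain of amplitude
  `D` at angular frequency `w`, the loop is an ellipse of area
  `pi w D^2`, which anchors the convergence test. The loop area is
  reported in strain^2/s without further normalization, since no standard
  normalization exists for this index. A cycle whose endpoints differ by
  more than `loop_tol` (default 0.05 strain) yields `NA` for that cycle
  rather than a biased polygon.

At least three complete cycles are required and all reported indices are
arithmetic means over the analyzed cycles, matching the averaging
convention of the protocol (three cycles or more).

EF, FS and FAC are ratios of like quantities, so they are invariant to
pixel-size rescaling and to uniform intensity rescaling of the video; both
invariances are asserted in the tests.

# Doppler indices

`detectEAPeaks()` treats contiguous stretches of inflow velocity above 5%
of the trace maximum as lobes and pairs them sequentially (E then A within
each diastole); an odd lobe count or fewer than two lobes is an error, not
a guess. E/A is the ratio of mean E peak to mean A peak over complete
cycles.

For the interval indices the package takes valve-event annotations as
authoritative: IVCT = AV-valve closure to outflow-valve opening, ET =
outflow-valve open interval, IVRT = outflow-valve closure to AV-valve
opening, each averaged over annotated cycles, and
`MPI = (IVCT + IVRT)/ET` (`computeMPI()`). Without annotations these are
`NA`: an inflow trace alone does not expose the valve events, and the
operational boundary definitions on a zebrafish Doppler trace are not
standardized, so the package refuses to invent them. Rising MPI indicates
deteriorating global function; the package computes, it does not
interpret.

# Single-myofibril kinetics

The simulated transient is piecewise closed-form: passive force; a
mono-exponential rise at `k_act` toward `f_max` after the activation
switch; zero force during the release; mono-exponential redevelopment at
`k_tr` back to the plateau after the restretch; then biphasic relaxation —
linear decline of slope `k_lin_slope x developed force` for `t_lin`
seconds, then exponential decay at `k_rel` to the passive level. Defaults
(k_act = 3/s, k_tr = 4/s, k_rel = 10/s, t_lin = 50 ms, 1 kHz sampling,
10 C, sarcomere length 2.3 um) are representative of slow-skeletal-type
myofibril kinetics at low temperature.

Fitting decisions:

* `fitExponentialRise()` fixes the starting level at the supplied baseline
  and fits `(F_inf, k)` by Levenberg-Marquardt least squares, initialized
  at `k = ln 2 / t_half`. It serves both k_ACT (baseline = passive force)
  and k_TR (baseline = first post-restretch sample). A window whose rise
  is below `min_rise` fails as flat rather than returning a spurious rate.
* `fitRelaxationBiphasic()` chooses the linear-to-exponential breakpoint
  by grid search over sample times, minimizing total SSE with continuity
  enforced at the breakpoint; the grid is coarse-then-fine (about 100
  coarse candidates, then single-sample refinement), which is equivalent
  to the exhaustive search on the smooth SSE profiles encountered here and
  keeps the fit fast. The linear slope is reported normalized by the
  developed force, so `k_lin` has units 1/s and is comparable across
  fibers of different strength. Two guards make the exponential sub-fit
  honest: its RMSE must stay below 5% of the developed force, and the
  fitted rate must resolve at least two time constants within the window —
  a pure linear decline therefore fails loudly instead of yielding a
  meaningless small rate. A window that genuinely rises in more than 20%
  of its (block-averaged) course draws a non-monotonicity warning; the
  block averaging, with a 1%-of-developed-force threshold, keeps
  sample-level noise jitter in the relaxed tail from masquerading as a
  rise.
* `computeTension()` requires an explicit cross-sectional area (no default
  is assumed); `1 nN/um^2 = 1 mN/mm^2` makes the unit conversion exact.
* `fitHill()` fits `F = F_max / (1 + 10^(n_h (pCa - pCa50)))` with pCa50
  initialized at the half-max point and `n_h = 2`, bounded so pCa50 stays
  within the tested range plus one unit. The default simulated grid is
  pCa 5.5-6.0 in 0.1 steps, the activating-buffer range of the target
  protocol.
* `qcRundown()` implements the exclusion rule for fiber deterioration: a
  developed-tension decline of more than 20% across a contraction set
  excludes the fiber.

All fits are deterministic (no random restarts); rates are invariant to
uniform force rescaling and to time-origin shifts, as asserted in the
tests.

# Morphometry

All morphometric measures reduce to pixel counting after deterministic
thresholding, and the generators construct images where the expected
counts are exact: scattered-pixel binary fields with an exact foreground
count, non-overlapping disc nuclei with a known positive subset, and
labeled square cells of known area. `nucleiFraction()` filters connected
components to areas within `[20, 2000]` px (at ~1 um/px) before
classification, so debris and merged clumps are excluded deterministically
and reported in the diagnostics instead of silently polluting the
denominator. ROIs are caller-supplied (the original workflow outlines them
manually); automatic Otsu thresholding is recomputed inside the ROI, which
makes every fraction invariant to intensity rescaling.

# Cohort statistics

`computeUcrit()` implements the Brett incremental-protocol form

    Ucrit = U_i + dU * (t / T)

with `U_i` the speed of the last fully completed stage, `dU` the stage
increment (default 8.66 cm/s), `t` the time swum into the final stage and
`T` the stage duration (default 150 s); division by body length gives the
normalized value. The printed formula in some protocol descriptions swaps
the symbols of the increment and the final-stage speed, which is
dimensionally inconsistent with the Brett form those protocols cite; this
package implements the standard Brett form, which reproduces the worked
example 17.66 + 8.66 x 75/150 = 21.99 cm/s. The swim-cohort generator
inverts this map exactly, so recovery is to machine precision.

Kaplan-Meier estimation and the log-rank test delegate to the survival
package (`survfit`/`survdiff`), i.e. the standard O-E form with
hypergeometric variance and chi-squared reference on `groups - 1` degrees
of freedom; ties follow the standard simultaneous-risk-set convention, and
censored times tied with events remain at risk through the event. An
all-censored cohort is an error (the statistic is undefined), not a
p-value. Group comparisons use the pooled-variance unpaired two-tailed
t-test for two groups and one-way ANOVA with Tukey's HSD beyond that;
mixed-model (repeated measures) designs are intentionally outside the
computational core — the package emits tidy per-trial tables that external
mixed-model tooling can consume.

# What the simulations do and do not establish

The generators reproduce the *geometry and kinetics* of the target
protocols — paced periodicity, biplane projection, transient shapes, lobe
timing, stepwise exhaustion, exponential survival — under additive
Gaussian noise. They deliberately do not model myocardial texture,
speckle, spectral Doppler physics, optical distortion of the mirror
system, stain variability, or non-exponential hazards. Passing the
recovery tests therefore establishes that the estimators are correct and
numerically stable on well-posed inputs of realistic scale and noise; it
does not certify segmentation performance on real histology or real video,
where manual ROI review remains part of the workflow.

Problem sizes in the tests and the acceptance script are chosen to
exercise each estimator at the scale of the target protocols (3 s videos
at 66 fps, 7 s transients at 1 kHz, 10-50 simulation replicates, 1000
null-simulation runs for the log-rank type-I check) while keeping the full
suite runnable in a couple of minutes on a laptop.

# Worked example

```{r example}
library(fishheart)

sim <- simBeatingHeartVideo(cardiacSimParams(edv = 4, esv = 2,
                                             noise_sd = 0, blur_sigma = 0,
                                             seed = 11))
summarizeHeart(sim$video)

fit <- fitMyofibrilKinetics(simMyofibrilTrace(myofibrilSimParams())$trace)
str(fit[c("k_act", "k_tr", "t_lin", "k_lin", "k_rel", "max_tension")])

dopplerIndices(simDopplerWaveform(dopplerSimParams(e_peak = 10,
                                                   a_peak = 5))$waveform)

computeUcrit(150 + 75, body_length = 4)
```

# Known limitations

* The two simulated planes are exactly orthogonal and share a frame clock;
  the mirror geometry of a real rig is only approximately so.
* The FS reported from video uses long-axis lengths only, matching the
  stated definition `FS = (L_d - L_s)/L_d`; echo-style FS from chamber
  diameters is a different quantity.
* Segmentation assumes a bright chamber on a darker background with a
  bimodal histogram; it is not a general cardiac segmenter.
* IVCT/IVRT/ET require annotations; the package does not detect valve
  events from inflow traces.
* The velocity-strain loop area has no standardized normalization; values
  are comparable within, not across, acquisition settings.
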