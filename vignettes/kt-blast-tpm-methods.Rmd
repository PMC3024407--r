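---
title: "Methods: simulating k-t BLAST accelerated tissue phase mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating k-t BLAST accelerated tissue phase mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kttpm)
```

This vignette is the package's own account of the models and numerical
choices behind its pipeline: what is simulated, which parameters matter,
what the tests can and cannot establish about real data, and where the
design was genuinely open.

## The measurement being simulated

Tissue phase mapping (TPM) measures myocardial velocity with
velocity-encoded phase-contrast cine MRI. Bipolar gradients imprint a
phase proportional to velocity; a four-point referenced scheme (one
reference segment, one segment per spatial direction, acquired in
consecutive heart beats) turns phase differences into the
three-directional velocity of every pixel at every cardiac phase:

$$v = \frac{\arg\!\big(S_\mathrm{enc}\,\overline{S_\mathrm{ref}}\big)}{\pi}\,\mathrm{VENC},$$

with VENC = 30 cm/s (the velocity that produces a phase of $\pi$).
Velocities at or beyond VENC would wrap; the simulator treats them as an
error rather than aliasing them, because the phantom is constructed to
stay well inside the encoding range.

The acquisition is segmented and navigator gated: each heartbeat
contributes 3 phase-encode lines plus one startup echo per cardiac phase,
preceded by a 12 ms black-blood saturation module, giving the phase
interval $(3+1)\times 7.1 + 12 = 40.4$ ms. The usable window is 90% of
the RR interval minus navigator (15.5 ms) and feedback (5 ms), which at
60 bpm fits 21 phases. All of this is deterministic arithmetic,
implemented in `protocol_params()` and friends and reproduced exactly by
the test suite, including the full scan-time table for k-t factors 1–7.
Two calibrated constants deserve mention: the accelerated scan carries a
fixed 13-beat training/preparation overhead and the non-accelerated scan
1 preparation beat. The timing model with exactly these constants and the
floor/ceiling placement in `nominal_scan_beats()` is the unique rounding
scheme consistent with the whole published table; both constants are
exposed as configuration fields because their decomposition (training
lines vs. preparation) is not documented anywhere.

## The phantom and its motion model

The synthetic subject is a short-axis left ventricle: a myocardial
annulus around a blood pool (suppressed by black-blood saturation, so it
carries almost no signal), plus a rectangular slab of static tissue used
by the background correction, and air elsewhere. Geometry defaults:
120 × 120 matrix at 2 mm pixels (240 mm field of view), end-diastolic
endocardial/epicardial radii 20/36 mm.

The default matrix is 120 rather than a power of two for a structural
reason: the x-f alias geometry of the sheared k-t lattice is exact only
when the phase-encode count is divisible by R, and 120 divides by every
default factor except 7 (the R = 7 arm rounds to 119 lines at fixed
field of view, a < 1% pixel-size change). This mirrors the protocol's own
"multiple integer" treatment of the cardiac phase count and is preferable
to approximating fractional alias shifts.

Velocity waveforms are sums of two opposite-signed raised-cosine (Hann)
pulses — one systolic, one diastolic — plus the constant that makes the
cycle integral exactly zero (no net displacement over a heartbeat). Pulse
amplitudes are solved so the waveform attains exactly the configured peak
values at the configured times. The family is smooth, periodic with a
continuous first derivative, and analytically integrable, which makes the
wall motion consistent by construction: the annulus radii follow the
displacement integral of the radial waveform, so masks and velocities
cannot disagree. Sign conventions, stated in all outputs: radial velocity
positive toward the blood-pool centroid (systolic contraction positive),
longitudinal velocity positive toward the apex.

Default peak velocities (radial +3.5/−3.0 cm/s, longitudinal +8/−7 cm/s,
systolic peak at 0.15 and diastolic at 0.55 of the imaged window, pulse
width 0.25) are of healthy-volunteer order but are *model inputs*, not
reproductions of any measured subject — no published per-subject velocity
table exists to pin them. The cohort generator draws each subject's
parameters uniformly from configurable ranges around these values to
stand in for inter-volunteer variability.

The imaged window (0.9 s at 60 bpm) is treated as the full cycle of the
waveforms: phase $i$ of $n$ sits at fraction $(i-1)/n$ of that window.
Through-plane motion changes no pixel's slice membership (thin-slice
approximation), and the background phase error is modeled
phenomenologically as a plane (offset plus row/column slopes, default
0.3 rad offset and ±0.004–0.006 rad/pixel), not as eddy-current physics.

## Sampling, training data and the unaliasing filter

Images map to Cartesian k-space through centered, unitary 2-D discrete
Fourier transforms (DC at 0-based index $n/2$; round trips are exact to
machine precision, a property the tests assert). Complex Gaussian noise
is added per k-space sample; `noise_sd` is the standard deviation of a
complex sample against a myocardial magnitude of 1, with default 0.05.

The sheared lattice samples, at cardiac phase $t$ (0-based), every R-th
phase-encode line starting at offset $t \bmod R$; over any R consecutive
phases every line is acquired exactly once. In x-f space (image row ×
temporal frequency) this lattice folds each point onto $R-1$ partners at
circular shifts $(q\,n_y/R,\; q\,n_t/R)$, $q = 0..R-1$, with weights of
magnitude $1/R$. The package does not trust that formula blindly:
`kt_psf()` computes the kernel numerically by pushing a unit x-f impulse
through the exact sampling chain, and the test suite verifies the
analytic shifts and weights against it. The phase-count divisibility
($n_t \bmod R = 0$) is guaranteed by the protocol's multiple-integer
rule; the line-count divisibility is arranged by the experiment geometry
described above.

The training stage is modeled as the 11 central phase-encode lines of the
same simulated acquisition at full temporal sampling
(interleaved-training approximation — whether the original protocol used
a separate low-resolution scan or interleaved lines is not documented
beyond its constant duration). Zero-filling those lines, reconstructing,
and Fourier-transforming along time gives the expected squared x-f
magnitude $\theta^2(y, x, f)$.

Reconstruction of an undersampled series proceeds per encoding:

1. **Baseline protection.** Each line is sampled uniformly in time, so
   its temporal average over acquired phases estimates the static
   (DC) signal. That baseline is subtracted from the acquired samples,
   reconstructed directly, and restored after unaliasing; the DC bin of
   $\theta^2$ is excluded from the residual filtering. This keeps the
   dominant static anatomy out of the filter.
2. **Unaliasing.** For every alias set with measured (zero-filled) value
   $d$ and lattice weights $w_q$, each true value is estimated as
   $$\hat s_b = \theta^2_b\, \overline{w_b}\,
     \Big(\sum_j |w_j|^2 \theta^2_j + \psi\Big)^{-1} d,$$
   a regularized least-squares solve that allocates the measured energy
   according to the training prior. With $\psi > 0$ the filter never
   amplifies: re-aliasing the estimates gives
   $|\sum_b w_b \hat s_b| \le |d|$.
3. The temporal inverse transform and baseline restoration yield the
   image series.

$\psi$ defaults to the mean squared magnitude in the outer k-space
corners of the acquired data — a standard noise-floor estimate —
overridable as a scalar. $\theta^2$ smoothing along f is available
(boxcar) but off by default. At R = 1 there is no aliasing and the
function returns the direct transform; the Wiener-style filter would
otherwise shrink noiseless data, which is both unnecessary and
undesirable there.

The same filter explains the package's central phenomenology: the prior
is low-resolution in y and the regularization suppresses weak temporal
harmonics, so sharp velocity transients are attenuated increasingly with
R — peak velocities shrink, curves smooth, and the peak factor falls
below one. This is the mechanism under study, not an artifact to be
removed.

## Quantification

Velocity maps come from the referenced phase difference; pixels with zero
magnitude carry no phase and are flagged invalid and excluded from mask
means (their count is logged on the curve object). A plane is fitted to
the static-tissue values of each map by least squares and subtracted
everywhere — the linear background correction. In this simulator the
injected plane is common to reference and encoded segments and therefore
cancels in the phase difference (the correction then removes residual
numerical trends); for externally supplied data with encoding-specific
phase errors the correction is load-bearing, and the plane itself is
observable in the reference-segment phase, which is how the parameter
recovery is tested.

Radial curves are myocardial-mask means of the in-plane velocity
projected onto unit vectors toward the blood-pool centroid; longitudinal
curves are mask means of the through-plane component, apex positive.
Ground-truth masks from the generator stand in for active-contour
segmentation; user-supplied masks are accepted for external data. Curves
are interpolated by a *periodic* cubic spline (value and first derivative
continuous across the cycle wrap) onto a uniform grid, default step
0.01 ms as printed in the original description — almost certainly a
misprint for 0.01 s, but implemented as printed and configurable, since
the cost is negligible. The zero-integral correction is a constant shift
by the dense-curve mean (the accumulated phase over a full cycle must
vanish); it is idempotent and its magnitude is retained on the object.

Peak detection takes the signed largest-magnitude extremum in the
systolic window, the opposite-signed extremum in the diastolic window,
their difference $\Delta v$, and the diastolic peak time; ties break to
the earliest time. The search windows were genuinely open — the original
analysis never defines them. The default is a half-cycle split, but a
blind split is fragile: a subject whose diastolic lobe straddles the
boundary can have its peak assigned the wrong sign, flipping the peak
factor even between noise-free repeats. The cohort experiment therefore
places the boundary at the midpoint between the subject's known systolic
and diastolic peak times — the in-silico analogue of an analyst reading
systole and diastole off the ECG — and shares those windows across all
arms of that subject.

## Comparison statistics

Between a reference acquisition (seq. 1) and a test acquisition (seq. 2),
per direction: peak factor $PF = \Delta v_2 / \Delta v_1$ (ideally 1),
normalized RMSD (root-mean-square deviation of the dense curves divided
by the non-accelerated $\Delta v$), Pearson correlation of the dense
curves, and Bland–Altman statistics (mean, n−1 standard deviation, and
mean ± 1.96 sd limits — the limits are an addition; the original tables
report mean and sd only) of $\Delta v$ and of the diastolic time-to-peak
difference, all oriented seq. 2 − seq. 1. The printed correlation
formula in the source description lacks a $1/n$ factor; it is implemented
as standard Pearson so that the stated ideal value of 1 actually holds.
Group comparisons use the unpaired, two-tailed, equal-variance (pooled)
t-test with significance at 0.05, and no multiple-testing correction, as
in the original analysis. Whether the reported standard deviations used
n or n−1 is unstated; n−1 is adopted throughout.

## The cohort experiment

`run_experiment()` simulates, per subject: two non-accelerated
acquisitions (the reproducibility arm, mirroring a reference group) and
one acquisition per k-t factor, each with an independent noise
realization, then reconstructs, quantifies and compares everything
against the first non-accelerated scan. Defaults: 10 subjects, R = 2…7,
120 × 120 matrix, 21 phases (fewer where the multiple-integer rule
bites), noise 0.05, spline step 0.01 ms. A full default run takes about
two minutes on one CPU; these sizes were chosen so the whole study runs
comfortably at desk scale while keeping per-curve noise far below the
effects under study. Determinism is end-to-end: all randomness derives
from the configuration seed, and the provenance log records seed, sizes
and a configuration hash. Sequence-order randomization of an in-vivo
session has no analogue here (there is no physiological drift model);
this is noted rather than guessed at.

## What the tests do and do not show

The oracle tests establish that the implementation solves the model it
claims to solve: the reconstruction equals an explicit per-alias-set
regularized solve with dense DFT matrices to 10⁻⁸, the noise-free
pipeline returns ground-truth waveforms and background parameters to
10⁻⁶, and every statistic matches a direct-formula computation to 10⁻¹⁰.
The cohort-level findings — peak factor near 1 for repeats and falling
with R, nRMSD rising from ~0.02 to ~0.16, diastolic timing preserved
within one phase interval through R = 6 — reproduce the *direction* of
the published in-vivo findings, and that is all they can reproduce: the
phantom has no trabeculation, torsion, strain gradients, coil
sensitivities, off-resonance, flow artifacts or respiratory-gating
residuals, its velocity pulses are sharper than real myocardial curves
(which makes the simulated peak factors fall faster with R than the
published ones), and its thermal reproducibility is better than
physiological test-retest variability. Numerical agreement with the
published volunteer tables is therefore out of reach by construction, and
no such agreement is claimed.

## Known limitations

* Exact alias sets require the phase-encode count divisible by R; the
  experiment arranges this by geometry, but `reconstruct_ktblast()`
  refuses other inputs rather than approximating.
* The filter details of the original vendor implementation ($\psi$
  choice, baseline handling, training apodization) are unpublished;
  results are comparable at trend level only.
* Velocity aliasing, multi-coil reconstruction (k-t SENSE), view sharing
  and iterative/compressed-sensing methods are out of scope.
* The background model is a plane; genuinely nonlinear phase errors are
  only absorbed by the zero-integral shift, as in the original analysis
  chain.
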