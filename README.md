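# kttpm

Simulation and quantification of **k-t BLAST accelerated myocardial tissue
phase mapping (TPM)** in R.

TPM is a velocity-encoded phase-contrast cine MRI technique: bipolar
gradients make the spin phase proportional to tissue velocity, so a
referenced four-point acquisition (one reference segment plus one segment
per spatial direction, VENC = 30 cm/s) yields the three-directional
velocity of the myocardium at every cardiac phase. The technique is slow —
about 225 heartbeats for a single short-axis slice — which motivates
k-t BLAST undersampling: every R-th phase-encode line is acquired on a
sheared k-t lattice, and the resulting aliasing in x-f space (image
position × temporal frequency) is resolved with a low-resolution,
fully-time-sampled training estimate of the signal variance. Acceleration
is not free: the unaliasing filter temporally smooths the data and abrades
sharp velocity peaks, so the package's central question is *how much
quantitative motion information survives at which acceleration factor*.

`kttpm` provides the complete in-silico pipeline for that question, aimed
at MR physicists and methods researchers:

* **Protocol timing** — deterministic arithmetic of the segmented,
  navigator-gated acquisition: phase interval
  `(k-lines/segment + startup echo) · TR + saturation module`, the maximum
  phase count per heartbeat, phase counts forced to multiples of R, and
  nominal scan durations per k-t factor.
* **Synthetic data** — a dynamic short-axis left-ventricle phantom
  (myocardial annulus, black-blood pool, static-tissue slab) with smooth
  periodic radial and longitudinal ground-truth waveforms that integrate
  to zero displacement; four-point velocity encoding with a linear
  background phase plane; complex Gaussian k-space noise.
* **Sampling and reconstruction** — centered unitary Fourier encoding,
  the sheared k-t lattice, training-scan extraction (11 central lines),
  and the x-f unaliasing filter
  `s_b = θ²_b w̄_b (Σ_j |w_j|² θ²_j + ψ)⁻¹ d`
  with baseline (temporal-average) protection, where `θ²` is the
  training-derived signal variance and `ψ` the noise variance.
* **Quantification** — referenced phase-difference velocity maps, linear
  background correction from static tissue, myocardial-mask-mean radial
  (toward the blood-pool centroid) and longitudinal (toward the apex)
  velocity curves, periodic cubic-spline resampling, zero-integral shift,
  systolic/diastolic peak detection.
* **Comparison statistics** — peak factor `PF = Δv_seq2 / Δv_seq1`,
  normalized RMSD (`RMSD / Δv_no-kt`), curve correlation, Bland–Altman
  agreement of `Δv` and of the diastolic time-to-peak, and pooled
  two-sample t-tests against the reproducibility arm.

Everything is a tidy verb: curves, features and cohort tables are tibbles,
results plot with `autoplot()`, and experiment objects support
`broom::tidy()` / `broom::glance()`.

## Worked example

```r
library(kttpm)

# protocol arithmetic at 60 bpm
p <- protocol_params()
phase_interval(p)
#> [1] 40.4
protocol_table(p)
#> # A tibble: 7 × 4
#>       R phases scan_beats scan_time_s
#>   <int>  <int>      <int>       <dbl>
#> 1     1     21        225         225
#> 2     2     20        125         125
#> 3     3     21         85          85
#> 4     4     20         69          69
#> 5     5     20         57          57
#> 6     6     18         49          49
#> 7     7     21         45          45
```

The non-accelerated scan needs 225 beats; R = 2 needs 125, a 1.8-fold
speed-up (44.4% shorter). Gains shrink with R because the training stage
is a constant overhead.

A single accelerated acquisition, end to end:

```r
m   <- motion_model()                          # ground-truth waveforms
ph  <- build_phantom(m, n_phases = 20)         # 120 x 120 cine phantom
enc <- encode_velocity(ph, background_coeffs = c(0.3, 0.004, -0.006))
k   <- to_kspace(enc, noise_sd = 0.05, seed = 1)

pat <- make_kt_pattern(120, 20, R = 2)         # sheared lattice
und <- undersample(k, pat)
tr  <- acquire_training(k, 11)                 # central training lines
svm <- estimate_signal_variance(tr, psi = estimate_noise_psi(und))
rec <- reconstruct_ktblast(und, pat, svm)

q <- quantify_arm(rec, ph, venc_cm_s = 30)
q$features
#> # A tibble: 2 × 5
#>   direction    v_p_sys v_p_dias delta_v t_dias_ms
#>   <chr>          <dbl>    <dbl>   <dbl>     <dbl>
#> 1 radial          2.54    -2.22    4.76      494.
#> 2 longitudinal    6.10    -5.48   11.6       495.
autoplot(q$curves$radial)
```

Compared with the ground truth (radial peaks +3.5/−3.0 cm/s, longitudinal
+8/−7 cm/s), the R = 2 reconstruction already underestimates the peaks —
the temporal-smoothing cost of unaliasing — while the diastolic peak time
(truth 495 ms) is preserved to a few ms.

The full cohort study (10 synthetic subjects, two non-accelerated repeats
plus one acquisition per R ∈ 2…7):

```r
e <- run_experiment(experiment_config(seed = 1))
dplyr::filter(tidy(e), metric == "pf", direction == "radial")
#> # A tibble: 7 × 9
#>   metric arm   direction  mean     sd     n loa_lower loa_upper  p_value
#>   <chr>  <chr> <chr>     <dbl>  <dbl> <int>     <dbl>     <dbl>    <dbl>
#> 1 pf     kt2   radial    0.704 0.0344    10        NA        NA 1.38e-13
#> 2 pf     kt3   radial    0.575 0.0324    10        NA        NA 1.37e-16
#> 3 pf     kt4   radial    0.442 0.0372    10        NA        NA 3.85e-18
#> 4 pf     kt5   radial    0.323 0.0612    10        NA        NA 5.13e-17
#> 5 pf     kt6   radial    0.273 0.0244    10        NA        NA 1.02e-21
#> 6 pf     kt7   radial    0.232 0.0209    10        NA        NA 1.49e-22
#> 7 pf     ref   radial    0.996 0.0322    10        NA        NA NA
autoplot(e, metric = "nrmsd")
```

The reproducibility arm self-compares to PF ≈ 1.00 while the accelerated
arms underestimate the velocity range progressively with R; nRMSD grows
from ~0.02 (repeats) to ~0.16 at R = 7 and the diastolic time-to-peak
shift stays below one phase interval through R = 6 — the qualitative
fingerprint of acceleration-induced temporal smoothing. (This synthetic
phantom is deliberately harsher on PF than a beating heart: its velocity
pulses are sharper than in-vivo curves.)

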