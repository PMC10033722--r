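---
title: "Measuring ECG signal propagation velocity by two-channel cross-correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ECG signal propagation velocity by two-channel cross-correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgvelocity)
```

## The measurement problem

Classical biopotential modelling treats the body as a volume conductor in
which the heart's potential appears instantaneously at every surface
electrode. If the ECG is instead treated as a low-frequency endogenous
electromagnetic wave propagating through dielectric tissue, its velocity is
finite and predictable from the tissue's refractive index,

$$ v(f) = \frac{c}{n(f)}, \qquad n(f) = \sqrt{\varepsilon_r(f)\,\mu_r}, $$

with $c = 3\times 10^8$ m/s and $\mu_r \approx 1$ for muscle. Because the
relative permittivity of muscle at 10 Hz — the heart's dominant spectral
band — is of order $10^8$, the predicted velocity is of order

$$ v = \frac{3\times10^8}{\sqrt{10^8}} = 30{,}000 \ \mathrm{m/s}, $$

an *upper bound*: $\varepsilon_r$ grows further below 10 Hz, where
measured dispersion data are essentially unavailable.

Experimentally the velocity is accessible with two electrodes along the
left arm — proximal at the collar bone, distal at the wrist, separation
$d$ — sampled fast enough (MHz rather than the usual kHz) that the
sub-millisecond inter-channel delay is resolvable. The delay $T$ is the
lag $\Delta s$ of the cross-correlation maximum times the sampling time
$T_s = 1/f_s$, and

$$ v = \frac{d}{T}. $$

This package implements that pipeline — tissue model, synthetic recordings
with implanted ground truth, preprocessing, lag estimation, and summary
statistics — so each stage is testable without access to the original
laboratory recordings.

## Tissue model

`permittivity_spectrum()` stores a dispersion table $(f_i, \varepsilon_{r,i})$.
Tissue permittivity spans many decades and is close to linear on log–log
axes, so interpolation between tabulated points is linear in
$\log f$–$\log \varepsilon_r$. Two policies govern extrapolation below the
lowest tabulated frequency, where no reliable data exist:

* `clamp` (default): hold the lowest-frequency value. Conservative — it
  preserves the 30,000 m/s value as a ceiling, matching its role as an
  upper limit for the measured velocity.
* `powerlaw`: extend the log–log slope of the two lowest points, for
  sensitivity analyses that assume the dispersion trend continues.

Above the highest tabulated frequency the value is always clamped; the
measurement band sits far below that edge, so the choice is immaterial.
Only the real, scalar permittivity is modelled: dielectric loss,
conductivity, and anisotropy are outside the velocity formula above, and
the amplitude transmittance of the tissue is deliberately left out of the
propagators (phase-only transfer), keeping morphology identical between
channels apart from dispersion.

The speed of light is fixed at $3\times10^8$ m/s rather than the exact SI
value so that round derived numbers (30,000 m/s) are reproduced exactly.

```{r}
muscle <- permittivity_spectrum(10, 1e8)
phase_velocity(10, muscle)
theoretical_delay(0.55, 10, muscle) # seconds across a 0.55 m arm
```

## Synthetic recordings and what they emulate

`simulate_recording()` builds a two-channel recording with known ground
truth:

1. **Morphology** — `render_ecg()` sums five Gaussian waves (P, Q, R, S, T)
   per beat. Defaults (R: 1.0 mV, $\sigma$ = 12 ms; Q/S: −0.15/−0.2 mV,
   $\sigma$ = 8 ms; P/T: 0.15/0.3 mV, $\sigma$ = 25/40 ms; RR = 1 s)
   resemble a lead-II beat; they are controllable conveniences, not
   physiological claims.
2. **Propagation** — the distal channel is the proximal one delayed either
   by a constant $d/v$ (`propagate_constant()`) or per frequency bin by
   $d/v(f)$ from the tissue model (`propagate_dispersive()`). Both use an
   exact frequency-domain phase ramp, so fractional-sample delays carry no
   interpolation error; the record is zero-padded past the delay before
   the transform and trimmed after, so circular wrap-around cannot reach
   the correlation peak. For dispersive runs the quoted ground-truth delay
   is the 10 Hz value (the dominant ECG band); it is exact only in
   constant-velocity mode.
3. **Noise** — independent white Gaussian streams per channel (correlated
   noise would bias the lag toward zero), scaled so the *realised* record
   SNR equals the target exactly (default 12.45 dB, the recording-grade
   value). Sub-seeds for the two streams derive deterministically from one
   master seed; everything is bit-reproducible.
4. **Mains residual** — `add_powerline()` adds a sinusoid (default 54 Hz)
   optionally gated to the QRS support, emulating the
   multiplicative-looking interference residue that survives a hardware
   notch filter.

What the generator does **not** emulate: heart-rate variability,
respiratory baseline wander, electrode contact impedance, muscle-noise
colour, or amplitude distortion of the QRS between channels. Passing the
recovery tests therefore demonstrates that the estimation chain is
correct and unbiased *under these idealised conditions*; it does not by
itself establish performance on laboratory recordings whose artefacts are
richer.

## Preprocessing

* `rolling_mean()` — centred rectangular moving average (the display
  filter for MHz-sampled traces; 5001 samples ≈ 1 ms at 5 MHz). Edges
  shrink symmetrically rather than padding.
* `estimate_snr_db()` — defines SNR as
  $10\log_{10}(P_\text{smooth}/P_\text{residual})$ with the rolling mean
  as the smooth/residual splitter, over the whole record. The window
  should be short against the narrowest ECG wave and long against the
  noise correlation time (about 1 ms of samples); then smooth ≈ signal
  and residual ≈ noise, with leakage and noise-averaging corrections of
  order $1/w$ — far below the 0.5 dB at which the estimate is verified.
  Whether whole-record or QRS-only SNR is the right convention is open;
  whole-record is used here and stated as such.
* `detect_trigger()` — steepest-slope triggering: local extrema of the
  absolute first difference of the smoothed trace above a fraction
  (default 0.5) of the global maximum slope, with a 0.3 s refractory
  period keeping the stronger of colliding candidates. Candidates inside
  one smoothing window of the record edges are excluded: the shrinking
  edge windows are under-smoothed and throw spurious slope spikes.
* The 0.1–200 Hz band-pass and 50 Hz notch that a hardware chain applies
  are available as optional zero-phase software stages
  (`apply_filters()`), **off by default** so synthetic tests exercise the
  estimator against the exact generator output.

## Lag estimation

`cross_correlate_fft()` computes the full linear cross-correlation
$c(k)=\sum_n \mathrm{ch1}[n]\,\mathrm{ch2}[n+k]$ via zero-padded FFTs
(2–3–5–smooth lengths); `cross_correlate_direct()` evaluates the defining
sum and serves as the independent oracle in the tests — the two agree to
$10^{-9}$ relative on randomised inputs. A peak at positive lag means the
distal channel lags the proximal one.

The peak search is restricted to the lag window the theory predicts:
delays between $d/v_\text{ceiling}$ (30,000 m/s) and $d/v_\text{floor}$
(100 m/s, configurable). The pipeline searches the symmetric window
$[-d/v_\text{floor},\,+d/v_\text{floor}]$ in samples so that a recording
whose distal channel *leads* surfaces as a flagged negative lag rather
than disappearing; the quality gate then rejects it as non-physical.
Windowing also suppresses the beat-period ambiguity peaks at multiples of
the RR interval.

Numerical conventions, chosen once:

* **Ties** at the correlation maximum break toward the smallest $|$lag$|$,
  then toward the positive lag — deterministic, and conservative in the
  sense of favouring the faster, theory-consistent velocity.
* **Sub-sample refinement** (parabolic, through the three points around
  the peak) is available but off by default, matching integer-sample lag
  reporting.
* **peak_corr** is normalised by $\sqrt{E_1 E_2}$ so the acceptance
  threshold (default 0.7) is scale-free. The rejection rule — peak
  correlation below threshold, or delay outside the physical window — is
  this package's measurable operationalisation of "distorted QRS
  morphology", which by itself is a judgement call rather than a
  computable test.
* The display-precision path `lag_to_velocity(..., delay_rounding = 1e-5)`
  rounds $T$ to hundredths of a millisecond before dividing, reproducing
  arithmetic quoted at display precision: $\Delta s = 65006$ at
  $f_s = 0.5$ GHz over $d = 0.55$ m gives $T_s = 2$ ns,
  $T = 0.13$ ms and $v = 4231$ m/s, while the full-precision value is
  4230.4 m/s.

```{r}
lag <- lag_estimate(65006, fs = 0.5e9)
lag_to_velocity(lag, 0.55, delay_rounding = 1e-5)$velocity
```

## Statistics and diagnostics

`aggregate_velocities()` reports n (accepted), mean, sample ($n-1$)
standard deviation, median and relative uncertainty $100\,s/\bar v$ over
accepted measurements only, with collected and rejected counts carried
alongside. The sample SD is declared rather than inferable: at
two-significant-figure display precision it is indistinguishable from the
population SD. Display rounding (two significant figures, integer
percent) lives only in `print()` and reports; computation keeps full
precision.

`distortion_frequency()` turns the spacing of prominent residual peaks
into a period and frequency (18.5 ms → 54 Hz), using the same
fractional-threshold local-maximum rule as the trigger.
`velocity_ratio()` contextualises a field velocity against a conduction
velocity such as the ~4 m/s of Purkinje fibres (1500/4 = 375).

## Validation scale and degenerate inputs

The test suite validates recovery at three scales, chosen to exercise the
real acquisition regimes while staying desk-sized: exact noiseless
recovery on a single-beat record at 5 MHz (an integer 2000-sample delay
over 0.6 m at 1500 m/s); 50-seed stochastic recovery on three-beat
records at 1 MHz and 12.45 dB, where the median recovered velocity must
fall within 5% of the implanted truth; and fast smaller-scale property
tests (50–100 kHz) for everything else. At a fixed SNR defined over the
full bandwidth, the in-band noise density falls as $f_s$ rises, so the
lag jitter at 1 MHz is several-fold smaller than a 100 kHz pilot would
suggest — the reduced-scale noisy test therefore runs at a
correspondingly higher SNR.

Degenerate inputs are errors, not silent results: all-zero signals for
SNR targets, delays longer than the record, even smoothing windows, empty
lag windows, correlation functions with no unique peak, non-positive
delays in the velocity conversion (the distal channel leading is reported
through the quality gate instead). A flat trace yields an empty trigger
set rather than an error.

## Known limitations

* The dispersion model is phase-only; amplitude transmittance and loss
  are not modelled, so simulated channels differ only by delay, noise and
  optional interference — real inter-channel morphology change is
  unrepresented.
* Ground truth for dispersive simulations is a single-frequency (10 Hz)
  delay; a broadband waveform has no single true delay, which is the
  physical reason the measured velocity distribution is wide.
* The permittivity table below 10 Hz is an extrapolation policy, not
  data.
* Whole-trace correlation is the default; a QRS-segmented mode can be
  emulated by windowing the channels before estimation.
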