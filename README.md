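# ssvepsr

Untrained SSVEP frequency decoding for brain–computer interfaces, with
stochastic-resonance feature enhancement.

Steady-state visual evoked potentials (SSVEPs) are occipital EEG oscillations
phase-locked to a flickering or moving visual stimulus; an SSVEP speller
decodes which of M simultaneously presented targets a user gazes at by
recognizing its frequency in a short EEG epoch. Ring-shaped
motion-checkerboard stimuli are comfortable for long sessions but elicit
almost no harmonic response and concentrate energy in a single spectral line,
which weakens the standard untrained recognizers (canonical correlation
analysis, CCA, and its filter-bank variant, FBCCA). `ssvepsr` implements an
enhancement route for this regime: reduce the multichannel epoch to one
dimension, pass it through an underdamped second-order stochastic-resonance
(USSR) filter that converts broadband noise energy into response energy at
the weak periodic drive, and recognize the frequency on the enhanced signal.

The package is aimed at BCI researchers who want a self-contained,
reproducible reference implementation of the method, its four
dimensionality-reduction baselines, and its evaluation metrics — runnable
entirely on synthetic data.

## The model

The USSR filter is the driven, damped double-well system

    x'' = a x − b x^3 − β x' + s(t) + n(t),

with potential `U(x) = −(a/2)x² + (b/4)x⁴` (wells at ±√(a/b), barrier
a²/(4b)), damping `0 < β < 1`, input `s(t)` and optional Gaussian noise
`n(t)` of intensity D. It is integrated by classical fixed-step fourth-order
Runge–Kutta, one step `h` per input sample, with the established parameter
combination `[a, b, β, h] = [0.1, 1, 0.35, 0.1]`. At an intermediate noise
level the system's hopping between wells synchronizes with a weak
sub-threshold periodic drive — stochastic resonance — which amplifies the
target line instead of suppressing the noise around it.

The pipeline has five stages:

1. **Band-pass** 3–40 Hz (zero-phase Butterworth, order 4).
2. **Reduce** the 8-channel epoch to 1-D: common average reference (CAR),
   PCA, classical MDS, locally linear embedding (LLE), or — the method's
   choice — the CCA spatial filter `w_xᵀX` fitted against the sine/cosine
   reference templates `Y_f` (harmonics j = 1..k of each candidate f).
3. **Enhance** with the USSR filter.
4. **Score** each candidate frequency: canonical correlation between the
   trajectory and `Y_f`, FBCCA's weighted sum `ρ̃ = Σᵢ wᵢ ρᵢ²` with
   `wᵢ = i^(−1.25) + 0.25`, or power spectral density analysis (PSDA).
5. **Classify** as the stimulus frequency with the maximal score, and report
   accuracy plus the information transfer rate

       ITR = (60/T) [log₂M + σ log₂σ + (1−σ) log₂((1−σ)/(M−1))]  bits/min.

The emulated recording setup is 8 occipital channels (POz, PO3–PO6, Oz, O1,
O2) at 1000 Hz, 3 s stimulation epochs, and 35 targets from 3 to 20 Hz in
0.5 Hz steps; the synthetic generator adds a weak first harmonic and
1/f-plus-white background noise at a configurable per-channel SNR.

## Worked example

```r
library(ssvepsr)

# one synthetic trial: gaze target 11.5 Hz, default -16 dB SNR
ep <- generate_epoch(synthetic_config(f_target = 11.5, seed = 42))
ep
#> <eeg_epoch> 8 channels x 3000 samples @ 1000 Hz (3 s), true_freq = 11.5 Hz

fe   <- bandpass(truncate_epoch(ep, 2))            # 2 s decision window
bank <- make_template_bank(stimulus_grid(), k = 2, fs = 1000, n_samples = 2000)

cca_score(fe, bank)
#> <score_spectrum> cca over 35 candidates; peak 0.7504 at 11.5 Hz
ussr_pipeline_score(fe, bank, reducer = "cca")
#> <score_spectrum> cca_ussr over 35 candidates; peak 0.7451 at 11.5 Hz

compute_itr(0.9429, M = 35, T = 2)                 # 94.29% accuracy at 2 s
#> [1] 135.689
```

Both scorers put their peak at the true 11.5 Hz target, so `classify()`
returns 11.5 for each; `compute_itr()` converts an accuracy into bits/min
(94.29% at 2 s with 35 targets is 135.69 bits/min).

A small benchmark over one trial per target, comparing plain CCA with the
CCA-USSR composite across decision windows:

```r
eps <- generate_dataset(stimulus_grid(), 1, synthetic_config(f_target = 3, seed = 1), seed = 7)
data_length_sweep(eps, lengths = c(2, 1), methods = c("cca", "cca_ussr"))
#>     method data_length_s n_trials accuracy_pct itr_bits_per_min n_ties
#> 1      cca             2       35        60.00            63.70      0
#> 2 cca_ussr             2       35        68.57            78.97      0
#> 3      cca             1       35        34.29            51.51      0
#> 4 cca_ussr             1       35        40.00            66.35      0
```

The stochastic-resonance stage lifts accuracy over plain CCA at both window
lengths on this noise regime (the ITR column is always Eq.-consistent with
its accuracy column; shorter windows pay less time per decision, which is why
ITR can rise while accuracy falls).

A shell front end wrapping the same functions ships in `inst/cli/ssvepsr`
(subcommands `decode`, `benchmark`, `fixtures`, `spectrum`).

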