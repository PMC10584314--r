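---
title: "SSVEP decoding with stochastic-resonance feature enhancement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSVEP decoding with stochastic-resonance feature enhancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepsr)
```

## The problem

An SSVEP brain–computer interface presents M flickering or moving targets,
each tagged by a frequency; gazing at one entrains occipital EEG at that
frequency and its harmonics. Decoding reduces to recognizing which candidate
frequency dominates a short multichannel epoch. Motion-checkerboard stimuli
(radially contracting/expanding ring checkerboards) are visually comfortable
but evoke almost no harmonic content and concentrate energy in one narrow
line, so harmonic-hungry recognizers such as FBCCA underperform. The approach
implemented here enhances the single weak line instead: project the epoch to
one dimension, drive a bistable oscillator with it, and recognize the
frequency on the oscillator's output.

## The bistable filter

The underdamped second-order stochastic-resonance (USSR) model is

$$\ddot x = a x - b x^3 - \beta \dot x + s(t) + n(t),$$

a particle in the double-well potential $U(x) = -\tfrac{a}{2}x^2 +
\tfrac{b}{4}x^4$ with viscous damping $\beta$, driven by the reduced EEG
signal $s(t)$ and (optionally) Gaussian noise $n(t)$ with
$\langle n(t_1) n(t_2)\rangle = 2D\,\delta(t_1 - t_2)$. The wells sit at
$\pm\sqrt{a/b}$ with barrier height $a^2/(4b)$. For a weak, sub-threshold
periodic drive, noise-assisted hopping between the wells synchronizes with
the drive at an intermediate noise intensity — stochastic resonance — so the
output spectral amplitude at the drive frequency is a non-monotonic function
of $D$ with an interior maximum. `sr_noise_sweep()` demonstrates this on a
drive of amplitude 0.008 (below the static threshold $\approx 0.0122$ of the
default well).

### Parameters

| parameter | default | meaning |
|---|---|---|
| `a`, `b` | 0.1, 1 | potential shape; wells at ±0.316, barrier 0.0025 |
| `beta` | 0.35 | damping, underdamped regime (0, 1) |
| `h` | 0.1 | RK4 step per input sample |
| `D` | 0 | added Gaussian noise intensity |
| `x0`, `v0` | 0, 0 | initial state |
| `input_scale` | 1 | drive multiplier after standardization |

The `[a, b, beta, h] = [0.1, 1, 0.35, 0.1]` combination is the established
operating point for this model class and is taken as given, not re-optimized.

### Numerical choices

**Integration.** Classical fixed-step RK4 (compiled core), one step of size
`h` per input sample, drive held constant over a step's four stages
(zero-order hold; the continuous drive between samples is unknown, so any
intra-step rule is a modelling choice — ZOH is the simplest and is what the
step-refinement oracle in the tests assumes). With 1000 Hz data and `h = 0.1`
the integrator's internal time axis is 100× compressed relative to real
seconds. This secondary-sampling treatment is standard in stochastic-resonance
signal processing: the model is calibrated in its own time units (it is the
only reading under which `h` is a model parameter), and since one input
sample maps to one output sample, downstream correlation against templates on
the recording clock is unaffected.

**Input scaling.** Raw microvolt amplitudes are meaningless against a barrier
of 0.0025, so the reduced signal is standardized to zero mean, unit variance,
then multiplied by `input_scale` (default 1). This puts the drive well above
the static threshold — the filter operates as a driven nonlinear resonator
riding on the EEG's intrinsic noise, and `D = 0` by default: the recorded
background already supplies the $n(t)$ term. Both knobs are config-exposed;
the noise-sweep demonstration documents the sub-threshold regime where added
noise is essential.

**Initial conditions** default to the unstable equilibrium $x_0 = v_0 = 0$; a
divergence guard aborts if $|x|$ exceeds 10³ (with these defaults the system
is strongly dissipative and never approaches it). Equilibrium holding,
relaxation into a well against an h/100 reference, fourth-order convergence
on the damped-oscillator limit ($a < 0$, $b = 0$), and exact odd symmetry are
all asserted in the tests.

## Dimensionality reduction

The filter needs a 1-D input. Five reducers are implemented, all treating
time samples as points in channel space where a geometric view is needed:

- **CAR** — reference electrode (default Oz, closest to the generator of the
  SSVEP) minus the mean of all channels.
- **PCA** — first principal-component score series (`stats::prcomp`).
- **MDS** — first principal coordinate of the Euclidean distance structure.
  For Euclidean distances the double-centred Gram matrix shares its nonzero
  spectrum with the channels × channels scatter matrix, so the coordinate is
  computed from that 8 × 8 eigendecomposition in O(n) rather than from the
  n × n matrix; a `subsample` cap is kept as an option for API symmetry but
  is off by default because nothing is gained by it. Tests verify equality
  with `stats::cmdscale` on small instances.
- **LLE** — K-nearest-neighbour reconstruction weights (rows summing to 1,
  local Gram ridge `1e-3 · trace` when the neighbourhood is rank-deficient,
  the standard conditioning fix) followed by the bottom non-trivial
  eigenvector of $(I-W)^\top(I-W)$, standardized to zero mean and unit
  population variance. Default K = 40. This is O(n²)–O(n³), so points are
  capped at 2000 (even subsample, linear interpolation back).
- **CCA** — the method's choice: weights $w_x, w_y$ maximizing
  $\mathrm{corr}(w_x^\top X, w_y^\top Y_f)$ against the sine/cosine template
  $Y_f$ (rows $\cos 2\pi j f t, \sin 2\pi j f t$, $j = 1..k$, on the
  $t = 1/f_s, \dots, N/f_s$ axis shared by all modules). Solved as a
  whitened symmetric eigenproblem on covariance matrices with ridge
  `1e-8 · trace` for rank-deficient blocks; $\rho$ is reported non-negative
  and the sign of $w_x$ is fixed so the projection correlates non-negatively
  with the template's first row. Default k = 2 (fundamental plus first
  harmonic — all the motion-checkerboard regime offers).

**Scope of the CCA projection.** Whether one projection is fitted per
candidate frequency or a single best projection is reused is genuinely open;
the default (`cca_scope = "per_frequency"`) refits per candidate, because a
per-candidate projection is the only reading that produces a meaningful
correlation value at every point of a dense coefficient spectrum. The
`"single_best"` alternative is a config switch.

## Recognition and metrics

`cca_score` ranks candidates by first canonical correlation; `fbcca_score`
band-passes into N = 5 sub-bands (band i spanning 3i–40 Hz, a
harmonic-progressive design scaled to the 3–20 Hz stimulus range, fully
config-driven) and combines $\tilde\rho = \sum_i w_i \rho_i^2$ with
$w_i = i^{-1.25} + 0.25$; `psda_score` evaluates the discrete-time Fourier
amplitude exactly at each candidate (single-frequency evaluation rather than
FFT bins, because a 0.5 Hz grid at 1–3 s lengths does not align with bins),
summing fundamental and 2f power by default. Scoring a 1-D trajectory with
"CCA" is the maximal correlation between the trajectory and the best linear
combination of template rows — the definition of the coefficient spectrum,
evaluated over 1–40 Hz in 0.5 Hz steps (79 points) by
`coefficient_spectrum()`. Classification restricts to the 35 stimulus
frequencies and breaks exact ties toward the lower frequency (flagged).

A known identifiability caveat, visible in the tests: with k = 2 the template
at f/2 contains f as its harmonic row, so a *pure* sinusoid at f correlates
perfectly with both $Y_f$ and $Y_{f/2}$. Any first-harmonic content (the
generator's default 10%) or noise at 2f breaks the tie in favour of the true
target; the zero-harmonic noiseless case is an exact tie by construction.

Accuracy is exact-match percentage; `compute_itr` implements the Wolpaw rate
with the $0\log 0 = 0$ convention, making it finite on all of $[0, 1]$ and
exactly zero at chance $\sigma = 1/M$. Method comparisons use two-sided
paired t-tests (`paired_comparison`; identical inputs are the documented
degenerate case t = 0, p = 1). `data_length_sweep` truncates epochs to their
first T seconds — stimulus-onset-aligned, as an online BCI would — and
re-evaluates; published summary tables pair each accuracy with its ITR, and
the shipped 42-subject benchmark table is used in the tests as an arithmetic
regression fixture for that pairing (its summary row uses sample SD, and its
mean-ITR entries equal the ITR of the mean accuracy). ITR can rise as windows
shrink even while accuracy falls, because each decision costs less time.

## The synthetic generator

Real recordings of this paradigm are not redistributable, so the generator
emulates the recording setup: 8 occipital channels at 1000 Hz, 3 s epochs, 35
targets at 3–20 Hz in 0.5 Hz steps. Each channel is

$$g_c \, A \left[\sin(2\pi f t + \phi) + r \sin(4\pi f t + \phi_2)\right]
+ \text{noise},$$

with amplitude A = 5 µV (typical SSVEP scale), harmonic ratio r = 0.1 (the
near-absent harmonic content of the paradigm), per-channel gains $g_c$
jittered ±20% around 1 (a stand-in for the unknown scalp projection), seeded
random phases (deterministic override available for oracle tests), and
background noise = 1/f^α colored (α = 1) plus a white floor at 10% of the
colored power — the typical shape of resting EEG. Noise is scaled per channel
so the empirical SSVEP-to-background power ratio equals `snr_db` exactly.
Everything is bit-reproducible from a seed, with per-epoch seeds derived
deterministically from a dataset's master seed.

The default `snr_db = -16` was calibrated once so that the plain-CCA baseline
lands mid-range (~60–63% at T = 2 s over the 35-target grid), the regime in
which enhancement methods are interesting; it was frozen before the
evaluation properties were run. The generator does *not* model eye blinks,
electrode artifacts, non-stationarity, or inter-subject variability — so
passing tests demonstrate algorithmic correctness and qualitative behaviour
(enhancement over baseline, SNR monotonicity, resonance), not clinical-grade
performance on real EEG.

## Evaluation problem sizes

The shipped test-suite properties run at desk scale by design: noiseless
sweeps use one trial per target (35 epochs, 2 s windows); the SNR-robustness
ladder uses 3 levels × 50 epochs; the resonance sweep uses 9 noise levels × a
few thousand samples with a handful of replicates. These sizes give stable
qualitative conclusions (ties and reversals beyond a 5-point slack do not
occur) while keeping the whole suite under a couple of minutes.

## Known limitations

- The subharmonic tie described above is intrinsic to harmonic templates on
  zero-harmonic signals; classification over the stimulus grid inherits it
  only for targets at least twice the grid minimum (≥ 6 Hz) and only in the
  exactly-noiseless, exactly-zero-harmonic corner.
- USSR enhancement operates per candidate (with CCA reduction), making it
  ~35× the cost of plain CCA per epoch; MDS/LLE reducers are slower still and
  are baselines, not recommendations.
- The filter-bank sub-band edges are a design transplanted to this stimulus
  range; with near-zero harmonic content FBCCA is expected to add little, and
  the benchmark table reflects that.
- ITR assumes i.i.d. selections and a fixed decision time; it is the field's
  convention, not a capacity claim.
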