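---
title: "Time-frequency analysis of gene-circuit responsiveness and noise suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency analysis of gene-circuit responsiveness and noise suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfanet)
```

## The problem

A gene circuit that responds to an environmental signal faces a trade-off:
it should track genuine changes in the signal (responsiveness) while
ignoring fast fluctuations that carry no information (noise suppression).
Because the circuits are nonlinear and the inputs nonstationary, classical
transfer-function analysis does not apply; `tfanet` instead compares the
*time-frequency content* of stimulus and response directly.  A large
ensemble of random noisy stimuli is pushed through a kinetic model of the
circuit, each stimulus/response pair is transformed into a pair of
short-time Fourier spectrograms, and two scalar statistics summarize the
comparison:

* **Noise suppression** $\xi = \mu^{in}/\mu^{out}$, where $\mu$ is the
  band-power-weighted mean frequency of a spectrogram,
  $\mu = \sum_i f_i S_i / \sum_i S_i$ with $S_i = \sum_j X_{ij}$.  A
  low-pass circuit removes high-frequency input power, lowering
  $\mu^{out}$, so $\xi > 1$; $\xi < 1$ means the response contains
  harmonics absent from the input.
* **Responsiveness** $\rho$, the inverse symmetric Kullback–Leibler
  divergence between the unit-normalized distributions (across frequency
  bands) of the per-band total variation
  $V_i = \sum_j |X_{i,j+1} - X_{i,j}|$.  A response whose band-wise
  temporal activity mirrors the stimulus gives a small divergence and a
  large $\rho$.

Kolmogorov–Smirnov analogues ($\xi_2$, $\rho_1$) and a divergence on the
band sums ($\xi_1$) are computed alongside as robustness checks.

## Stimulus ensembles

Three stimulus families are generated on a uniform 1-min grid over
3000 min: piecewise-constant **block** signals (5–30 segments with
uniform random boundaries and levels), piecewise-linear **saw** signals
(same segmentation, linearly interpolated levels), and **sine** signals
(three sinusoids with log-uniform frequencies between 1/1500 and
1/20 cycles/min, random phases and amplitudes, affinely mapped into the
amplitude range).  All families receive additive white Gaussian noise
with standard deviation 5% of the maximum amplitude and are clipped to
the physical range $[0, A_{max}]$, since concentrations cannot be
negative.  Every stimulus is reproducible from an integer seed, and
ensemble seeds are derived deterministically from one master seed, so the
*identical* stimulus list can be replayed against different models —
all model comparisons in the package are matched-seed comparisons.

What the generator does *not* emulate: correlated (colored) noise,
stimulus families with heavy-tailed level distributions, and inputs whose
statistics drift over time.  Conclusions from the test-suite therefore
speak to circuit behavior under stationary white-noise-corrupted inputs,
not to arbitrary natural environments.

## Spectrograms

Signals are zero-meaned, split into Hamming-windowed frames of 256
samples with hop 128 (50% overlap; 129 bands, 22 frames for a
3001-sample signal), and transformed by the DFT; coefficients are squared
magnitudes (power).  Coefficients more than 80 dB below the spectrogram
maximum are zeroed, and the matrix is scaled by $1/(NM)$.  Every
downstream statistic is built from ratios or unit-normalized
distributions, so it is provably invariant to any uniform scaling of the
spectrogram (the test-suite asserts this); the scaling choice cannot bias
results.  The DC band participates in the band sums — after zero-meaning
it carries only frame-local mean power, which for slowly drifting signals
is genuine low-frequency content.

Numerical choices: divergences use additive smoothing
$\varepsilon = 10^{-12}$ with renormalization, and inverse divergences
are floored at $\varepsilon$ before inversion, capping $\rho$ and
$\rho_1$ at $10^{12}$ for identical distributions.  Capped values are
censoring artifacts, not measurements, so ensemble summaries exclude them
from moments and report their count.  The symmetric KL is the plain sum
of the two directed divergences (halving it would scale $\rho$ by a
constant and change no ordering).  Degenerate inputs — all-zero
spectrograms, zero-sum total-variation vectors — raise classed errors
rather than returning infinities.

## The three circuits

All models share canonical Hill kinetics: production terms are
$b + V\,\mathrm{act}(\cdot)\,\mathrm{rep}(\cdot)$ with
$\mathrm{act}(x) = x^n/(K^n + x^n)$,
$\mathrm{rep}(x) = 1/(1 + s\,(x/K)^n)$, and first-order decay.  The
loop-strength multipliers $s_{pos}, s_{neg} \ge 0$ scale the maximal rate
of the designated positive/negative regulatory arm (wild type $= 1$) and
form the axes of the sweep portraits.

**GAL** (galactose, stimulus 0–11.1 mM): galactose activates Gal3;
active Gal3 sequesters Gal80; free Gal80 represses Gal4 activity, which
drives Gal3 (positive feedback, $s_{pos}$), Gal80 (negative feedback,
$s_{neg}$) and the target gene.  All half-lives are 15 min, making the
circuit fast and responsive.

**OLE** (oleate, stimulus 0–4.25·10⁻⁶ M): oleate activates Oaf1
instantaneously; the Oaf1–Pip2 heterodimer drives *PIP2* (autoregulatory
positive feedback) and the target.  Adr1 adds a slower activating
feed-forward arm to both ($s_{pos}$); Oaf3 applies slow repression
($s_{neg}$).  The package reads the promoter logic as *competition at
the oleate-response element*: Oaf3 gates the heterodimer arm of the
target promoter, while the Adr1 arm binds independently.  Half-lives are
60 min (30 min for Oaf3), so the feed-forward arms imprint slow envelopes
on the output — the mechanistic source of the circuit's strong
noise suppression.  Variants: `adr1_delta` and `oaf3_delta` remove the
respective state and its arms; `no_positive_feedback` removes only
Pip2's self-upregulation (its own promoter is driven by Oaf1 at a fixed
low weight `c0`), leaving target regulation unchanged.

**LPS** (nuclear NF-κB, stimulus 0–1500 molecules/cell): NF-κB activates
ATF3 and C/EBPδ after discrete transcriptional delays (60 min and
240 min, the familiar first/second induction waves); the IL6-like target
requires both NF-κB and C/EBPδ (coherent type-1 arm) and is repressed by
ATF3 (coherent type-2 arm).  Because the delayed quantity is the input
itself, delays are realized on the stimulus pathway: the default
`history_interpolation` evaluates the interpolated stimulus at
$t - \tau$ with zero pre-onset history; `linear_chain` replaces the shift
by an $m$-stage first-order cascade (Erlang kernel with mean $\tau$),
integrated on an internal grid fine enough to resolve the stage time
constant and started from the same zero history.  The two coincide
exactly at $\tau = 0$ and converge as $m$ grows wherever the input is
smooth on the kernel's width.

Simulations run from the basal steady state (located by pre-integrating
the zero-stimulus system), with the stimulus linearly interpolated
between samples and `lsoda` tolerances `rtol = 1e-6`, `atol = 1e-8`.
Right-hand sides are compiled C code driven through `deSolve`'s forcing
mechanism.

## Parameter calibration

The published rate constants for these circuits live outside the sources
available to this package, so defaults are *implementation-calibrated*:
degradation half-lives between 15 and 60 min, Hill constants near the
middle of each state's steady operating range, and maximal rates that
drive the target at least five-fold above basal under a sustained maximal
stimulus.  Within those constraints the free parameters were tuned — on
small matched ensembles, against the qualitative orderings the package's
acceptance suite encodes (OLE filters more than GAL, GAL responds more
than OLE, each topology variant moves $\xi$ and $\rho$ in its documented
direction, weak-loop sweep cells trade suppression for responsiveness) —
and then frozen; the calibration was verified to be stable across
independent master seeds.  Stimulus-generator settings, STFT settings and
statistic definitions were fixed before calibration and never adjusted.

Two calibration notes deserve emphasis.  First, a near-bistable Pip2
gate (Hill 4 with low $K$) was rejected: residual feed-forward arms at
1% weight still flipped the gate, so weak-loop sweep cells failed to
approach the double-deletion limit.  The frozen gate (Hill 2, $K = 8$)
is monotone and the limit is smooth.  Second, the Oaf3 repression gates
only the heterodimer arm; when it multiplied the whole promoter, removing
Oaf3 barely changed the responsiveness distribution and the deletion
ordering had no attainable margin.

## The sweep portraits and screens

`sweep_loop_strengths()` evaluates a log-spaced $(s_{pos}, s_{neg})$ grid
(default $51\times51$ over $[10^{-2}, 10^{2}]$; tests and the acceptance
script use $7\times7$ with 30 stimuli per cell to keep runtimes in
minutes), reusing the identical stimulus list at every cell.  Per cell it
records mean $\xi$, $\rho$, response amplitude (max − min), and the
normalized-derivative distance between stimulus and response.  That
distance is 0 for identical signals, $\sqrt 2$ for uncorrelated
derivatives, and 2 for sign-inverted responses.  Because the white
stimulus noise dominates the input derivative, even faithful low-pass
responses sit near the orthogonality floor (distances 1.35–1.42 at wild
type), while genuinely reversed responses measure 1.6–2.0; the
non-physiological flag therefore uses a cutoff of 1.5, between the two
regimes, rather than $\sqrt 2$ itself.  Wild-type tolerance masks
(`wt_tolerance_mask()`, default ±15%) mark the parameter region whose
ensemble means stay within a relative tolerance of the wild-type values.

## Known limitations

* For the GAL calibration, sinusoidal stimuli are **not** the easiest
  family to denoise, unlike for OLE and LPS: the sine components extend
  to 1/20 cycles/min, inside the passband of any GAL parameterization
  fast enough to stay more responsive than OLE, so the responses retain
  the fundamentals and $\xi$ for sines stays below the block/saw values.
  Making GAL slow enough to reverse this destroys its responsiveness
  advantage.  The package reports the orderings as computed.
* Ensemble means of $\xi$ have heavy right tails (occasional stimuli
  with very low $\mu^{out}$); comparisons are therefore made on matched
  seeds, and per-family sample sizes below ~30 are noisy.
* The equilibrium finder is a fixed-length pre-integration, adequate for
  these monotone-decay systems but not a general root-finder.
* Rendering functions always write a delimited data twin next to each
  image; tests assert on the numbers, never on pixels.
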