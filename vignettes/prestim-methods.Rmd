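---
title: "Methods: prestimulus oscillation analysis with permutation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prestimulus oscillation analysis with permutation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prestim)
```

This vignette documents the statistical model behind `prestim`, the
choices that were genuinely open when building it, and what the synthetic
validation does and does not establish.

## The scientific question and the estimators

The package targets experiments in which an ambiguous multi-flash visual
sequence is perceived either veridically or illusorily from trial to
trial, while multi-sensor MEG/EEG is recorded. Two distinct hypotheses
about the prestimulus alpha rhythm (8–12 Hz) are tested by two distinct
estimators:

1. **Phase**: if the phase of ongoing alpha at stimulus onset biases
   perception, the phase distributions of illusion (ILL) and no-illusion
   (no-ILL) trials should concentrate at *opposite* angles. The
   phase-opposition sum quantifies this per sensor and time point:

   POS = ITC_ILL + ITC_no-ILL − 2·ITC_all,

   where ITC is the intertrial phase coherence (modulus of the mean unit
   phasor across trials). If both conditions lock to different phases,
   the condition-wise ITCs are high while the pooled phasors cancel, so
   POS → 2; if phase is irrelevant, all three terms estimate the same
   quantity and POS ≈ 0.

2. **Power**: if high prestimulus alpha power amplifies an individual's
   perceptual prior, then *across subjects* the ILL − no-ILL alpha-power
   difference should correlate with how illusion-prone the subject is
   (illusion rate, or the signal-detection criterion
   c = −(z(H) + z(FA))/2). This is a between-subject Spearman
   correlation at every sensor and time point.

Both estimators live on a sensors × time grid and inherit a massive
multiple-comparison problem, which is handled by spatiotemporal
cluster-based permutation testing with max-cluster-statistic correction.

### Why POS needs a two-level null

POS is biased upward at finite trial counts: the expected resultant
length of n uniform phases is ≈ √π/(2√n), so the condition-wise ITCs
(computed on subsets) exceed the pooled ITC in expectation even under the
null. The test therefore never compares POS against zero. Instead:

* *subject level*: condition labels are shuffled over trials (n = 1000 by
  default), preserving group sizes, and POS is recomputed for each
  shuffle — this reproduces the bias exactly;
* *group level*: each of n = 10,000 draws picks one shuffled map per
  subject uniformly at random and averages over subjects.

The observed group-average POS map is z-scored against this group null,
thresholded pointwise at its 2.5/97.5 percentiles (two-sided, α = 0.05),
clustered over space and time (minimal cluster size 10 points), and each
cluster's POS sum is compared with the distribution of the maximum
cluster statistic obtained by clustering the group-null draws themselves.
Trial counts are equalised per report × direction cell beforehand
(`equalize_trials()`), because POS compares subset ITCs whose bias
depends on n.

### The wavelet family

All time–frequency quantities use Morlet wavelets with a *fixed spectral
bandwidth* of 3 Hz, defined as twice the spectral standard deviation of
the Gaussian kernel. A wavelet with n cycles at frequency f has spectral
SD f/n, so the rule is n(f) = 2f/3 — linear in frequency with a constant
temporal SD of 1/(3π) ≈ 0.106 s. `cycles_for_frequency()` implements the
rule; this convention reproduces the printed cycle counts at 5.5, 10,
21.5 and 80 Hz. Kernels are truncated at ±4 temporal SDs and normalised
so a cosine of amplitude *a* yields coefficient modulus *a* (power a²)
and argument equal to the instantaneous phase. No baseline normalisation
is applied anywhere: the analysis is prestimulus-only, restricted to
−600..−200 ms — inside the epoch far enough that wavelet edge effects
and poststimulus leakage do not reach it. `morlet_transform(window=)`
computes the convolution directly at the requested output samples; it is
numerically identical to the full FFT path followed by
`extract_prestim()` (this equivalence is asserted in the tests).

## The synthetic cohort generator

With no public recordings of this paradigm available, the generator is
first-class, tested code that defines the conditions everything else is
validated under. Defaults mirror the study session: 5 blocks of 60 test
and 30 control trials per motion direction (900 trials), SOA 188 ms
inward / 272 ms outward, ITI uniform 0.8–1.3 s, epochs −0.8..+1.2 s at
333 Hz (generated directly at the post-downsampling rate; no filtering
chain is simulated), and baseline illusion rates drawn uniformly over
0.12–0.95 across subjects.

Each epoch is the sum of

* 1/f^a Gaussian noise (spectral exponent a = 1 by default, unit
  variance), shaped in the frequency domain;
* a sustained 10 Hz alpha oscillation with per-trial log-normal amplitude
  (`alpha_amplitude` = 1, i.e. alpha at the same scale as the noise;
  sdlog 0.4) and uniform random phase. On the *effect sensors* (default:
  the four central grid sites) all channels share one latent phase and
  amplitude per trial; elsewhere phase and amplitude are independent per
  channel, so no systematic phase or power effect can arise off the
  effect patch;
* a small evoked-like Gaussian transient (amplitude 1.5, SD 30 ms)
  peaking 100 ms after each flash onset.

The latent phase is defined at −400 ms (the centre of the prestimulus
window), so the injected value is exactly the instantaneous alpha phase
there. Behaviour couples to the latents through a logistic model:

p(ILL) = plogis( qlogis(base) + w_pow·(2·base − 1)·z_power +
                 w_phase·cos(φ − φ_pref) ),

with z_power the latent alpha power standardised within subject (making
coupling weights comparable across subjects). The graded bias weight
2·base − 1 (the subject's prior away from indifference, in [−1, 1]) makes
high alpha power push perception *toward the subject's own prior*, with a
strength proportional to how pronounced the prior is. We chose the graded
weight over a hard sign(base − 0.5) step because the step makes the true
between-subject correlation between power difference and illusion rate
top out well below the ρ ≈ 0.8 regime the recovery validation targets
(within-group rank order would be pure noise); no claim about the real
generative mechanism is intended — it is an artifact of the validation
design, chosen once. Control trials are answered correctly with fixed
probability 0.81, mirroring observed control accuracy. Response times are
log-normal (meanlog log 0.75 s test / log 0.6 s control, sdlog 0.6),
which puts roughly 2% of trials outside the 0.2–4 s rejection bounds, the
rejection rate the behavioural rule is meant to produce.

With both couplings at zero the cohort is an exact null for every
downstream test — the basis of the type-I validation.

What the generator does **not** emulate: sensor physics and realistic
field topographies, eye-blink/cardiac artifacts, non-stationary alpha
(the injected oscillation is sustained, so phase opposition extends over
the whole window rather than being temporally localised), correlated
noise between sensors, and any filtering/decimation chain. Passing tests
therefore establish the *statistical correctness* of the estimators and
their nulls, not performance on real recordings.

## Decisions made where the design was open

* **Bandwidth convention.** "Fixed 3 Hz bandwidth" is interpreted as
  2× spectral SD because that single linear rule reproduces four of the
  five printed cycle counts; the remaining printed value (35 cycles at
  37.5 Hz) is inconsistent with any linear rule through the other four
  (the rule gives 25) and is treated as a typo — the package does not
  guess an alternative.
* **Band edges** are inclusive when selecting wavelet centre frequencies
  (alpha 8–12 Hz keeps both 8 and 12).
* **Group-null sampling** draws one subject sample per group draw *with
  replacement* across draws; 10,000 draws from 1000-sample subject nulls
  would exhaust without-replacement sampling. `replace = FALSE` is
  available.
* **POS cluster thresholds** are computed per sensor–time point from the
  group-null percentiles (not pooled across points); pooling is not
  offered because per-point nulls respect the spatially inhomogeneous
  bias of POS.
* **Two-sided handling.** Positive and negative clusters are formed
  separately and pooled into a single max-|statistic| null, for the POS
  test, the correlation test (each tail of the t-transform at
  forming_alpha/2) and the power contrast.
* **Conjunction sign rule.** The conjunction map keeps the signed minimum
  absolute correlation where the two directions agree in sign and 0 where
  they disagree; only the magnitude rule is inherited from the original
  procedure, the sign rule is a package choice. The cluster statistic is
  the maximum over the cluster, with pointwise percentile thresholds from
  a null that permutes subjects *jointly* for both directions (preserving
  the between-direction dependence).
* **Power contrast permutation** flips the sign of each subject's paired
  difference map (the generic subject-level exchangeability argument for
  a paired contrast); the cluster-forming statistic is the one-sample t
  over subjects.
* **RT origin.** RTs are measured from the onset of the last flash, and
  the rejection bounds (0.2/4 s) are exposed as configuration, because
  the source description of the rejection rule references a different
  origin than the RT definition; the package takes one origin and makes
  the bounds tunable rather than asserting intent.
* **Edge correction** for H or FA ∈ {0, 1}: 1/(2N) replacement by
  default, log-linear ((count + 0.5)/(N + 1)) as an alternative; an error
  is raised if a degenerate rate arrives without its trial count.
* **Cluster p-values** are (count ≥ observed + 1)/(n_perm + 1), which
  cannot be zero and is mildly conservative.
* **Degenerate inputs.** ITC requires ≥2 trials; the circular mean errors
  on a (numerically) zero resultant; Spearman maps set r = 0 where a
  brain column is constant across subjects (the t-transform is clamped at
  |r| = 1 via a 1e−12 guard); permutation engines warn below 100
  permutations; subjects lacking any report × direction cell are dropped
  from group analyses with a warning and recorded in the report — at the
  full session size such cells cannot be empty for base rates in
  0.12–0.95, but scaled-down simulations can produce them.

## Problem sizes used in the validation

The statistical acceptance checks run on reduced-size cohorts chosen once
as this package's validation conditions: 13 subjects on an 8 × 8 grid
(64 sensors, 4-neighbour adjacency), single-block sessions of 25 test
trials per direction (the power-effect recovery uses two blocks of 30 to
stabilise per-subject power-difference maps), epochs −0.8..+0.2 s at
333 Hz analysed at the 10 Hz alpha centre frequency over the
−600..−200 ms window (133 samples), with 200 subject-level and 1000
group-level POS permutations and 200 cluster permutations per test. Under
these conditions the suite verifies: family-wise false-positive rate of
the combined POS + correlation arms ≤ 0.10 over 100 null cohorts;
recovery of injected phase opposition (coupling 2.5) and of an injected
power×bias effect (coupling 2, realising a true between-subject Spearman
around 0.8) at the injected sensors in ≥80% of 25 cohorts each; and
rank-uniformity of the corrected cluster p-value when a null draw is
inserted as the observed map (KS test at 0.01 over 200 repeats). The
analytic layer (cycle counts, session trial counts, POS closed forms,
criterion vs. an inverse-normal quantile computed by root-finding) is
checked exactly or to 1e−9.

## Known limitations

* Sensor-space only; no source reconstruction, head models or anatomical
  labels.
* The correlation and conjunction engines hold the brain maps fixed and
  permute the behavioural vector; exchangeability across subjects is
  assumed (no nuisance covariates).
* The synthetic alpha is strictly sinusoidal and sustained; estimators
  that exploit temporal localisation of phase effects are not stressed by
  the generator.
* Planar-pair support combines *power* (and POS maps) across channel
  pairs by Euclidean norm; it does not model the gradiometer forward
  field itself.
* The full-scale default permutation counts (10,000 group draws, 4000
  correlation permutations) are intended for real-sized analyses; the
  worked examples use reduced counts.
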