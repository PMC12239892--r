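---
title: "Methods: quantifying concordance between subscalp and scalp EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying concordance between subscalp and scalp EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegconcord)
```

## The problem

Minimally invasive subscalp electrodes — leads tunnelled between scalp and
skull — promise months-long EEG monitoring, but they are only clinically
useful if the signal they record is *not inferior* to conventional scalp
EEG, the standard of care. `eegconcord` implements the quantitative
machinery for establishing that: paired spectral, topographic, agreement,
sleep-staging, ictal and interictal comparisons between co-registered
subscalp, scalp and (ground-truth) intracranial recordings, together with a
synthetic multimodal generator so that every stage of the pipeline can be
exercised, calibrated and falsified without access to human recordings.

## Measurement layer

**Multitaper spectra.** Power spectral densities use DPSS (Slepian) tapers
on 5-second sliding windows with 50% overlap. The time-bandwidth product is
4 (7 tapers, non-adaptive weighting), a common default that yields stable
estimates on a 0.2 Hz grid for 5-s windows. One-sided densities are
normalised so that the integral over frequency equals the signal variance
(the Parseval contract, enforced by tests to 5%). The tapers themselves are
computed from the tridiagonal matrix that commutes with the spectral
concentration operator, and are verified orthonormal.

**Coherence.** Magnitude-squared coherence pools cross- and auto-spectra
over tapers x windows (Welch-style), requires at least 8 windows, and clips
to [0, 1]. For independent signals the estimator has a known bias floor of
`1/(windows x tapers)`, which the object records; tests verify both the
floor and the closed form `MSC = sigma_s^4 / (sigma_s^2 + sigma_n^2)^2`
for a shared-signal construction. Whether coherence should be computed
per-window and averaged, or from pooled spectra, is not uniquely defined;
we pool, and the time-frequency variant (used for ictal contours) pools
tapers only, giving one estimate per window.

**Aperiodic (1/f) fit and band peak power.** The aperiodic component is a
least-squares line through `(log10 f, log10 power)` over 1-45 Hz,
excluding the oscillation band under analysis; the exponent is minus the
slope. No knee term is fitted: the straight-line model is the simplest one
consistent with how such fits are usually displayed, and the synthetic
background is an exact power law. An oscillation's *band peak power* is the
maximal departure (in dB) of the spectrum above this fit within its band —
a definition that cancels broadband gain differences between channels,
which is what makes it the right quantity for comparing electrode types.
Band edges use conventional clinical definitions: delta 0.5-4, theta 4-8,
alpha 8-12, sigma 11-16, beta 16-30 Hz.

## Agreement and noninferiority layer

Paired measurements (one row per participant x electrode pair, or per
seizure) are assessed by:

- **ICC(2,1)** — two-way random effects, absolute agreement, single
  measures. This variant penalises constant offsets between methods, which
  is the point of a method-agreement analysis; the implementation matches a
  brute-force ANOVA oracle to 1e-10 and carries the standard F-based
  confidence interval.
- **Bland-Altman** — bias is the mean difference (subscalp minus scalp)
  with a t-interval; limits of agreement are `bias +/- 1.96 SD`.
- **Noninferiority** — accepted when ICC > 0.75 *and* the bias does not
  fall below the margin: -0.5 dB for oscillatory peak power, -1 uV for
  voltage, -0.03 for coherence. Two bias rules are provided: the default
  requires the *lower CI bound* to clear the margin (conventional
  noninferiority logic); `rule = "point"` compares the bias point estimate
  only, since the clinical wording compares the mean. Decisions are
  monotone: worsening bias or ICC can never flip fail into pass.
- **Cohen's kappa** for sleep staging, against the 0.60 substantial-
  agreement margin, with an exact two-sided binomial sign test for paired
  scorer comparisons ("Wilcoxon sign test" is read as the exact sign test;
  the signed-rank variant is available behind a flag).
- **Topographic spatial correlation** — Pearson correlation of two
  topographic maps, either on a common interpolated head-disk grid (the
  default, since maps rather than electrodes are being compared) or through
  matched contact pairs. Significance uses a one-sided permutation test
  that shuffles the value-to-contact assignment of the subscalp map 100
  times; `p = (1 + #{null >= observed}) / (n_shuffles + 1)`. The test is
  calibrated: under independent random maps it rejects at 5.0% +/- 1.5% at
  alpha = 0.05. Correlations above 0.5 / 0.7 are labelled moderate /
  strong.

## The synthetic generator

Because device-validation recordings of this kind are not publicly
deposited, the generator is a first-class module, not a test fixture. It
emulates:

- a 25-contact 10-20 montage (including the inferior temporal row) on a
  sphere of radius 92 mm; 1-4 subscalp "trident" leads of 7 contacts each
  (3 + 2 + 2 along three branches 30 degrees apart, 20 mm contact spacing,
  branch arcs within the 100-120 mm tunnelled range) on the sphere at
  92 - 7 mm; intracranial contacts strictly inside. Lead orientation is
  "surgically planned": among jittered candidate orientations the one whose
  contacts land closest to the scalp montage is chosen, as an implanter
  aiming to replicate scalp coverage would;
- stage-specific rhythms (posterior alpha in eyes-closed wake, central
  sigma in N2, frontal delta in N3, frontal beta in REM, a weak central
  theta in N1) as band-limited noise on a 1/f^1.5 background synthesised by
  spectral shaping (offset: ~3 uV^2/Hz at 1 Hz), plus white sensor noise
  (0.5 uV per modality);
- dipolar interictal spikes (biphasic template, 70 ms, 20 ms rise; signed
  radial-dipole weighting so the near side is positive and the far side
  negative);
- seizures as chirps with linearly evolving frequency and an amplitude ramp
  over the first third, starting at the seizure-onset zone and appearing at
  the propagation zone after a delay with an independent random-walk phase
  perturbation;
- visual and auditory evoked responses as Gaussian-windowed component peaks
  (VEP: N75/P100/N120 clustered occipitally plus a parietal N145; AEP:
  P50/N100/P200 centro-frontally).

**Spatial model.** A single sphere; no electromagnetic forward model is
attempted. Focal discharges project with `exp(-d / 35 mm)` and a 0.01
visibility floor — sources whose surface gain falls below the floor are
extracranially invisible, which reproduces, qualitatively, the fraction of
deep seizures that neither subscalp nor scalp EEG can see. Diffuse rhythms
use the smoother profile `floor + (1 - floor) exp(-d / spread)` (default
floor 0.2, spread 100 mm): scalp-level rhythm topographies are smooth, with
gradients extending across the whole head. Each rhythm is additionally
modulated by a smooth log-normal *regional expression field* (squared-
exponential kernel, SD 0.25 in log10-power, 70 mm correlation length):
neighbouring contacts see nearly the same regional factor while distant
regions decorrelate, which is what gives realistic between-site variance
without decoupling a subscalp contact from its scalp neighbour.

**Extracranial sensing.** Scalp *and* subscalp channels sample the surface
field along their radial direction; the only modality difference is a
dimensionless subscalp gain factor (default 1). The relative
subscalp-vs-scalp signal amplitude is not a well-quantified constant, so
the factor is exposed rather than fixed; more importantly, a naive depth-dependent gain
would hand the subscalp contacts a built-in ~1.7 dB advantage from sitting
7 mm closer to the brain, contradicting the modality-consistency property
on which every parameter-recovery test rests (equal expected band power at
matched positions when the gain factor is 1). Intracranial channels sense
at their true 3D position.

**What the generator does not emulate.** Realistic volume conduction
(skull/CSF layering), muscle and eye-movement artifacts, electrode drift
and wire breakage, non-stationary sleep microstructure, and spike/seizure
morphology variability beyond amplitude jitter. Passing the recovery tests
therefore shows that the *analysis pipeline* is unbiased and correctly
calibrated under known ground truth — not that real subscalp hardware is
noninferior.

## The bundled demo study

`study_config()` emulates an early-feasibility cohort: 8 participants carrying
1, 2, 2, 2, 4, 4, 4, 4 tridents — 23 leads, 161 subscalp contacts, hence
n = 161 pooled subscalp-scalp pairs; 120 s of eyes-closed wake (the
analysis length fixed by the protocol), one 30-s epoch each of N2/N3/REM;
30 interictal spikes and 5 seizures (45 s, 7 to 3 Hz chirp, 8 s
propagation delay) per participant; visual stimulation in 2 participants
(498 trials) and auditory in 3 (207 trials); 3 sleep scorers per 8-hour
night, emulated by flipping 10% of epochs independently per scorer and
modality.

Between-participant variability is part of the study conditions: rhythm
amplitudes scale by a log-normal factor (SD 1.5 dB), evoked responses by a
uniform 0.7-1.8 factor, and spike source strength is drawn from 20-85 uV.
Spike dipoles sit 46 mm from the head centre beneath a randomly chosen
subscalp contact (the marked spikes are, by construction, those whose field
reaches the sampled convexity) and use a 55 mm gain length-scale —
extracranial spike fields are skull-smeared, so their lateral decay is
shallower than the generic focal default. Seizure onset/propagation zones
are two intracranial contact positions; ictal coherence is evaluated on the
closest-contact triplet against both, averaged over 0.5-30 Hz.

The evoked per-contact measure is the **mean signed amplitude in a 50-ms
window centred on the global-field-power peak** within 0-300 ms — the
standard ERP "mean amplitude over a component window" — rather than a
whole-epoch average, which would dilute the component with noise.

Under these conditions the full demo passes every noninferiority margin in
at least 19 of 20 seeds, and injecting a -1.5 dB subscalp attenuation
(`subscalp_gain = 10^(-1.5/20)`) makes the dB-margin verdict fail in at
least 19 of 20 seeds with the wake-alpha Bland-Altman bias recovering the
injected -1.5 dB within +/-0.3 dB. (The recovered bias is compressed
slightly toward zero by channels where the alpha peak is near the noise
floor, where a gain change moves the peak-above-fit less than 1:1.)

```{r demo, eval = FALSE}
report <- run_study(study_config(seed = 1))
tidy(report)
all_noninferior(report)
write_report(report, "study-out", format = "markdown")
```

## Numerical choices and degenerate inputs

- Sampling rate 256 Hz: resolves the 0.5-45 Hz analysis range with margin;
  30 s scoring epochs (the staging standard).
- Seeds: a single study seed fans out to per-stage child seeds by stable
  hashing, so any stage can be re-run in isolation and full runs are
  byte-identical.
- All-constant signals yield a flagged degenerate spectrum (-Inf dB off
  DC) rather than an error; constant topographic maps yield a flagged `NA`
  correlation; all-tied sign tests return p = 1 with a flag.
- Nearest-neighbour and triplet ties break lexicographically by contact
  name, making every selection deterministic.
- Seizure segments too short for 8 standard windows fall back to 2-s
  windows and are flagged in the output.
- Synthesis FFTs are padded to 2-3-5-smooth lengths (then truncated) so
  generation cost never degenerates on awkward sample counts.
- Problem sizes in the test-suite calibrations (e.g. Monte-Carlo replicate
  counts, the 30/60/120-s fixture durations) were chosen as the smallest
  sizes at which the corresponding asymptotics are comfortably inside the
  stated tolerances.

## Known limitations

- Pairs are pooled across participants, as in the reference analysis; a
  hierarchical model accounting for within-participant correlation would
  be the natural extension and is deliberately out of scope.
- The single-sphere surface-sampling model cannot address questions about
  absolute subscalp signal amplitude, skull defects, or referencing.
- The ICC variant is declared (2,1) throughout; other variants would give
  systematically different values on the same tables.
- The permutation null shuffles the subscalp map only, matching the
  shuffled-electrode-label construction; with 100 shuffles the smallest
  attainable p is 1/101.
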