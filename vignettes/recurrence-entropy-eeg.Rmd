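---
title: "Recurrence-microstate entropy for multichannel EEG: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence-microstate entropy for multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recmicro)
```

## The scientific question

Repetitive, continuously fed-back movement such as stationary cycling is
expected to *synchronise* cortical activity: sensorimotor rhythms lock to the
movement, beta-band (20--30 Hz) power is suppressed, and the EEG becomes more
regular. A complexity measure should therefore read *lower* during cycling
than at rest, and lower with eyes closed (alpha synchronisation) than with
eyes open. `recmicro` implements a complete, reproducible pipeline for
testing exactly this on eight bipolar channels (F3-Fz, F4-Fz, C3-Cz, C4-Cz,
P3-Pz, P4-Pz, O1-A2, O2-A1) recorded in the four conditions rest/cycling
crossed with eyes open/closed.

Because no public recordings accompany this design, the package ships a
synthetic-cohort generator with the statistical structure the analysis
assumes. Every downstream stage is therefore testable end to end, with known
ground truth, on any machine.

## The statistic

For a segment $x_1,\dots,x_L$ the recurrence matrix is
$R_{ij} = \mathbf{1}\{|x_i - x_j| \le \varepsilon\}$ (embedding dimension 1:
the raw series is compared sample-by-sample, avoiding the delay and
embedding-dimension parameters that a Takens reconstruction would add). A
*microstate* is the $N \times N$ binary block of $R$ anchored at a random
pair $(i, j)$, encoded row-major as an integer in $[0, 2^{N^2})$. Sampling
$K$ anchor pairs gives an empirical distribution $p$ over microstates, and
its Shannon entropy

$$S(\varepsilon) = -\sum_i p_i \ln p_i$$

is maximised over a grid of thresholds:
$S_{\max} = \max_\varepsilon S(\varepsilon)$. (Some presentations of this
entropy omit the minus sign; it is of course required for $S \ge 0$ and is
always included here.) A periodic signal concentrates the microstate
distribution on few patterns (low $S_{\max}$); desynchronised, noisy signals
spread it (high $S_{\max}$). The estimator never materialises the full
recurrence matrix -- blocks are computed on the fly from the samples -- so a
segment of a thousand samples costs $O(K N^2 |\varepsilon\text{-grid}|)$.

Each 2-minute channel recording is split into 100 equal contiguous pieces
(trailing remainder discarded), $S_{\max}$ is computed per piece, and the
recording is summarised by the **median** over pieces. The median, not the
mean, is the response variable of the models -- it is robust to occasional
aberrant segments.

### Estimator parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `N` | 4 | microstate edge; $2^{16}$ possible patterns give a rich vocabulary while a sparse count table stays cheap. Bound: $S \le N^2\ln 2 \approx 11.09$ nats |
| `K` | 10000 | sampled anchors per segment; the plug-in entropy's sampling error scales like $\sqrt{2^{N^2}/K}$ for small blocks |
| `n_eps`, `q_range` | 20 grid points over the 5%--95% distance quantiles | the threshold grid lives on *quantiles of the segment's own pairwise distances*, which makes $S_{\max}$ exactly invariant to affine amplitude transforms $x \mapsto ax+b$ and hence comparable across subjects, channels and amplifier gains |
| `n_dist_pairs` | 2000 | size of the random distance subsample that estimates the quantile grid |
| log base | $e$ | entropies are in nats throughout |

Ties on the threshold grid break toward the smaller $\varepsilon$. A constant
segment (all pairwise distances zero) is reported as $S_{\max} = 0$ at
$\varepsilon = 0$ with a message. Per-segment sampling streams are derived
from `(seed, recording id, segment index)`, so results do not depend on
evaluation order and single segments can be recomputed exactly
(`max_entropy()` reproduces `median_entropy()`'s per-segment values
bit for bit).

## Signal conditioning

The conditioning chain mirrors standard practice for this kind of recording:
a 1--100 Hz acquisition band-pass, a 59--61 Hz mains band-stop, and a
3--35 Hz band-pass applied to cycling recordings. All filters are 4th-order
Butterworth designs applied forward--backward (`filtfilt`), i.e. zero-phase;
only the cutoffs are scientifically prescribed, so the family, order and
phase handling are package decisions documented here.

Two decisions deserve emphasis:

* **The 3--35 Hz filter is applied to cycling recordings only by default.**
  This matches the acquisition protocol the pipeline models, but it
  confounds preprocessing with condition: cycling recordings lose broadband
  content that rest recordings keep, which by itself depresses their entropy.
  The flag `apply_335_to_all = TRUE` symmetrises the chain for sensitivity
  analyses, and the pipeline's *null/calibration mode* (`null = TRUE`)
  switches it on automatically -- a type-I-error calibration is only
  meaningful when nothing but noise distinguishes the conditions, including
  the preprocessing.
* **Artifact screening runs on raw signals, before filtering,** because
  zero-phase filtering smears a step discontinuity into a pulse that is much
  harder to detect. A sample is flagged when its absolute first difference
  exceeds `z_thresh = 8` robust (MAD-scaled) standard deviations of the
  channel's first differences. The qualitative criterion being
  operationalised is the "erratic jump" of a failing skin--electrode
  contact; the robust z-score on first differences is its simplest faithful
  quantification, and at `z_thresh = 8` clean synthetic channels are
  essentially never flagged (the suite measures the false-positive rate on
  100 clean channels). Exclusion defaults to the *subject* level -- one
  flagged channel anywhere removes the whole subject, mirroring protocols
  in which whole individuals are dropped for electrode artifacts -- with
  `level = "recording"` available.

## The models and the permutation scheme

With median entropy as response, treatment coding, and reference levels
`rest` and `open`:

* **GLM1** (validation): `median_entropy ~ eyes + (1 | subject)` on the
  right-occipital channel, resting state only. Eyes-closed alpha should
  lower entropy there if the estimator works at all.
* **GLMM2**: `median_entropy ~ state * eyes + (1 | subject)` per
  (region, side); the `statecycling` coefficient is the cycling $-$ rest
  contrast and its negative sign is the hypothesis of interest.

Models are fitted by REML (`lme4`). When the random-intercept variance
collapses to zero the fit falls back to fixed effects with subject as a
factor, which leaves every within-subject contrast and its $t$ unchanged. On
balanced data the fixed-effect $t$ statistics have a closed form (cell-mean
contrasts over the within-subject mean square); the package uses that closed
form inside permutation loops and the test suite verifies it against
`lme4` to numerical accuracy, and against the textbook paired $t$ for the
two-cell design, where the equivalence is exact. Reported degrees of freedom
are the within-subject error degrees of freedom
$(n_\text{subjects}-1)(n_\text{cells}-1)$.

Inference is by **within-subject permutation** (10,000 repetitions by
default, two-sided): subjects are the exchangeability blocks implied by the
random intercept, so labels are shuffled only inside each subject -- eyes
labels for the eyes term, state labels within each eyes stratum for the
state term, and the joint cell labels for the interaction. The p-value uses
the add-one rule $p = (1 + \#\{|t^\ast| \ge |t_{obs}|\})/(1 + n_{perm})$, so
$p \ge 1/(n_{perm}+1) > 0$. If a design admits fewer distinct label
assignments than $1/\alpha$, the test warns and enumerates them exactly.
Per-region p-values are reported uncorrected (confirmatory per-electrode
contrasts); `holm = TRUE` adds a corrected column. Because one sentence-level
summary of "left and right central" could also mean pooled hemispheres,
`run_inference(pool_sides = TRUE)` adds a sensitivity variant in which sides
are averaged subject-wise before fitting.

## What the synthetic cohort emulates

Each channel is a sum of

1. $1/f$-shaped broadband Gaussian noise (spectral slope $\gamma = 1$,
   nominal 10 uV) -- desynchronised background;
2. an alpha (8--12 Hz) component, largest occipitally
   (O > P > C > F: 8, 5, 3, 2 uV), 60% narrowband noise and 40% tone,
   multiplied by `alpha_closed_gain` (default 2.5) when the eyes are closed;
3. a beta (20--30 Hz) component (3 uV) multiplied by `beta_cycling_atten`
   (default 0.5) during cycling;
4. during cycling, a deterministic pedaling-locked component: a ~1 Hz
   cadence with 8 harmonics decaying as $1/\sqrt{k}$, amplitude `pedal_amp`
   (default 6 uV). This is the single knob controlling the injected
   regularity, so the expected entropy drop is tunable and recoverable.
   Because the cycling band-pass removes content below 3 Hz, the harmonics
   carry the effect through preprocessing.

A per-subject log-normal multiplier (sd `subject_sd = 0.1` on the log scale)
scales the periodic components identically across a subject's four
recordings, giving median entropy the per-subject intercept that the
`(1 | subject)` term models. Step artifacts are injected into a random
subset of recordings at `artifact_rate = 0.07` per recording; with
subject-level exclusion this removes about a quarter of subjects in
expectation (roughly 6 of 24), a realistic attrition level for scalp
recordings on a moving participant.
Amplitudes are nominal microvolts: the entropy statistic is
amplitude-invariant by construction and the models only see entropy, so the
absolute scale is inert.

The generator's default effect sizes were fixed by the prescribed power
calibration: the state contrast must be detectable at $n = 18$ subjects with
power $\ge 0.8$, which `pedal_amp = 6` satisfies with a wide margin (the
acceptance suite measures the power over 50 replicate cohorts). Seeding is
hierarchical -- one root seed, one substream per (subject, state, eyes) and
per segment -- so cohorts are bit-reproducible and extendable without
reshuffling existing subjects.

What it does **not** emulate: volume conduction and channel correlation,
eye-blink/EMG/ECG artifacts (only step jumps), non-stationary drifts, or any
physiologic coupling between conditions. Passing tests on this cohort show
that the estimator and the inference behave correctly *given* the assumed
structure -- occipital alpha, beta suppression, movement-locked regularity --
not that real EEG satisfies those assumptions.

## Problem sizes used by the automated checks

The test suite and `scripts/acceptance.R` choose sizes so each property is
tested where it actually binds:

* directional findings (occipital closed < open; cycling < rest on all eight
  region-sides; cycling+closed lowest) are verified on a full-size cohort --
  18 retained subjects, 2-minute recordings at 1000 Hz, 100 segments,
  $N = 4$, $K = 10^4$;
* the type-I/power calibration runs on reduced cohorts (one occipital
  channel, 6-s recordings, 20 segments, $K = 10^3$, 1000 permutations,
  200 null and 50 effect cohorts): exchangeability under the null and the
  presence of the injected effect do not depend on recording length, only
  the per-recording measurement noise does, and the power margin absorbs it;
* oracle equivalence (sampled vs exhaustive anchors) uses 100 segments of
  500 samples, where full enumeration is exact and cheap, with the
  total-variation bound $3\sqrt{2^{N^2}/K}$ evaluated at $N \in \{2, 3\}$
  (at $N = 4$ the bound exceeds 1 and is vacuous).

## Numerical and degenerate-input choices

* quantile grids use the standard interpolating (type-7) definition on a
  seeded random subsample of pairwise distances;
* $0 \ln 0 \equiv 0$ in the entropy; probabilities are validated to sum to 1
  within $10^{-9}$;
* a constant signal yields $S=0$ (message), an all-zero MAD disables jump
  screening (message), and an all-constant response table yields zero
  estimates, $t = 0$ and $p = 1$;
* permutation streams, generator streams and segment streams are all derived
  from one root seed via a string-hash (`derive_seed()`), so independent
  stages never share or reorder random draws.

## Limitations

* The entropy estimator's parameters ($N$, $K$, the threshold rule) are
  exposed rather than canonical: published applications of
  recurrence-microstate entropy vary in these, and absolute entropy values
  are only comparable within one configuration.
* The 16-bit EDF interchange quantises amplitudes (~$3\times10^{-5}$ of the
  channel range); entropies survive essentially unchanged but byte-level
  determinism holds only within one route (direct vs via-EDF).
* The asymmetric 3--35 Hz filter means the default state contrast mixes a
  physiological effect with a preprocessing effect; use
  `apply_335_to_all = TRUE` to separate them.
* With 18 subjects the state-swap permutation space is astronomically larger
  than 10,000, but for very small cohorts the exact-enumeration fallback
  changes the p-value's resolution; the add-one rule keeps it conservative.
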