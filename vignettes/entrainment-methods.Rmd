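---
title: "Measuring f0 entrainment in dyadic conversations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring f0 entrainment in dyadic conversations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(f0entrain)
```

## The measurement problem

When two people talk, their speech often drifts toward (or away from) each
other in pitch. `f0entrain` quantifies that drift for a two-speaker
conversation as a single signed number per acoustic feature, attributes it
to the individual speakers, and provides the regression layer used to
relate it to speaker characteristics such as diagnosis group, age and
language ability.

The pipeline assumes the raw material of a clinical conversation study:
hand-annotated Praat TextGrids marking every utterance of each speaker,
frame-wise f0 tracks sampled every 10 ms (from Praat, or estimated here by
autocorrelation), and a participant metadata table. Because such
recordings are rarely shareable, the package also contains a synthetic
dyad generator that produces all three inputs with *known* entrainment, so
every stage of the pipeline can be validated end to end.

## From annotation to features

Only linguistically meaningful speech enters the analysis. Non-linguistic
vocalisations (laughter, humming, vocal stereotypy) and silences are
flagged at parse time via a configurable label-exclusion set and masked
out of the pitch track by `filter_linguistic()`. The flag is fixed when
the TextGrid is read; no downstream code re-inspects label strings.
Interval membership is half-open `[start, end)` with a 1 ns tolerance, so
a frame on a shared boundary is never counted twice.

The conversation timeline is split into thirds of *elapsed time* (the
TextGrid's `xmax`), not thirds of accumulated speech: silences are
excluded from the feature frames but not from the clock, since elapsed
time is the only division both speakers share. For the first and last
third, each speaker's voiced, linguistic frames are summarised by

* the arithmetic **mean f0** (k = 1), and
* the **interquartile range** of f0 (k = 2), using linear-interpolation
  quantiles (R's default type 7).

A window with fewer than `min_frames = 50` voiced frames (0.5 s of
voicing) yields a flagged missing feature rather than an unstable number;
the dyad is then excluded from downstream statistics for that feature,
with a log record.

## The geometry of entrainment

For feature k the dyad is a point in the joint f0 plane: the start point
$S = (S1_s, S2_s)$ from the first third and the end point
$E = (S1_e, S2_e)$ from the last, participant on axis 1. Entrainment is
scored against a reference line through the origin:

* the **matching line** $l_1$: $S2 = S1$ (slope 1), or
* the **half-matching line** $l_2$: $S2 = \tfrac12 S1$ (slope ½), used
  when an adult female partner converses with a teenage boy — the pairing
  whose registers sit roughly an octave apart, so that pitch matching is
  physiologically an octave offset.

With $d_1$ and $d_2$ the perpendicular distances of $S$ and $E$ to the
line,

$$\Delta_{\mathrm{ent}} = d_1 - d_2,$$

positive when the dyad moved closer to the line (convergence), negative
for divergence. Changes of 1 Hz or less in magnitude are classified as
maintenance (the band is inclusive); the count of "converging"
conversations uses a separate, strict 2 Hz threshold. Both are
config-exposed.

Each speaker's share of the change is their **responsibility**
$d_3/(d_3+d_4)$ and $d_4/(d_3+d_4)$, where $d_3 = |S1_e - S1_s|$ and
$d_4 = |S2_e - S2_s|$ are the along-axis changes. The **signed
contribution** multiplies responsibility by the sign of
$\Delta_{\mathrm{ent}}$; the **adjusted contribution** multiplies by
$\Delta_{\mathrm{ent}}$ itself (so the two speakers' adjusted
contributions always sum to the dyad-level change).

Design choices worth stating explicitly:

* "Distance to either $l_1$ or $l_2$" is implemented as distance to the
  *single* dyad-appropriate line chosen from the speaker classes; an
  option (`min_over_lines = TRUE`) scores against the nearer of the two
  lines for sensitivity analysis.
* For $l_2$ the lower-register speaker is placed on the halved axis; the
  `reference_line` object normalises axis order internally (distance of
  $(a,b)$ to the slope-½ line equals distance of $(b,a)$ to the slope-2
  line), so callers never reorder their data.
* Whether a child (pre-voice-change boy) with an adult female partner
  should use $l_2$ is genuinely open; the default is no — $l_2$ is
  restricted to the teen-boy/adult-female pairing.
* If $E$ overshoots to the opposite side of the line, the literal
  $d_1 - d_2$ formula applies; no reflection correction.
* An auxiliary raw-gap change $|S1_s-S2_s| - |S1_e-S2_e|$ is exported
  alongside the perpendicular measure, because group-level Hz values
  quoted in prose summaries of such analyses can live on either scale.
* A degenerate dyad in which neither speaker moved ($d_3 + d_4 = 0$)
  reports an even (0.5, 0.5) split with a flag instead of 0/0.

## Pitch tracking

The primary path consumes precomputed pitch tracks (CSV or Praat
PitchTier), so the estimator can never silently change published numbers.
When only audio is available, `estimate_f0()` implements a windowed
normalised-autocorrelation tracker: ~3 periods of the band floor per
window, 10 ms hop, peak search restricted to the speaker class's band
(children 100–450 Hz, teenage girls 100–400 Hz, teenage boys 50–350 Hz;
adult partners default to the nearest stated band), parabolic peak
interpolation, and a 0.45 voicing threshold on the normalised peak. On
synthetic periodic signals it recovers the true frequency within 1%
across 100–400 Hz. Like any autocorrelation tracker it can report
harmonically related values for signals far outside the search band; the
band contract only guarantees estimates within `[floor, ceiling]`.

## The statistical layer

The regression layer freezes the study's final model specifications
rather than re-running stepwise selection, for reproducibility:

| family | outcome | final predictors |
|---|---|---|
| `conversation_level` | dyad $\Delta_{\mathrm{ent}}$ | group, age, CELF, group×age |
| `contribution_level` | participant signed contribution | group, CELF |
| `adjusted_level` | participant adjusted contribution | group, CELF, group×age |
| `f0_range_family` | IQR-feature $\Delta_{\mathrm{ent}}$ | full set |

Every family also reports the full model with gender, non-verbal IQ and
conversation partner. Group is coded with ASD as the reference level, so
the group term is the NT effect. The partner factor is an unordered
categorical; with few conversations per partner it can be aliased, in
which case the family runner drops it with a warning. p-values are
two-sided from the t distribution with residual df; contribution outcomes
are on the signed-fraction scale (−1…1), not percentages. One-way group
comparisons are computed from the between/within sum-of-squares
definitions (so degenerate inputs give F = 0 exactly), and Cohen's d is
recovered from a two-group F as $d = \mathrm{sign}\cdot\sqrt{F(1/n_1 +
1/n_2)}$.

## What the generator emulates — and what it does not

`simulate_dyad()` works backwards from the geometry: it draws the two
registers, places the start point, and moves it by *exactly* the
programmed perpendicular drift, splitting the along-axis movement by the
programmed responsibility. Third-wise mean targets are then rendered to
frames (target + Gaussian noise inside alternating 1–5 s utterances
separated by 0.5–2 s pauses), and the turn structure to a gap-filled
two-tier TextGrid. Because drift is implemented in feature space, the
ground truth is exact: at zero noise the pipeline recovers the programmed
$\Delta_{\mathrm{ent}}$ and split to machine precision, which is what the
recovery tests assert.

Further generator behaviour:

* ASD participants emit occasional non-linguistic intervals (default 0.5
  per minute) whose frames sit at twice the register — an unfiltered
  pipeline is therefore measurably biased, making the exclusion rule
  testable.
* The participant's movement is modulated by the CELF score
  (`celf_effect`, default −0.1 Hz per point above the group mean),
  oriented so better language always means less convergence; the
  modulation is mean-zero, leaving group means unbiased.
* The IQR feature is generated flat by default, mirroring a null
  f0-range effect; an `iqr_drift` knob exists for power studies.
* Registers are redrawn (bounded retries) when a draw would place the
  start point too close to the line to accommodate the programmed drift,
  or push targets outside the speaker's pitch band; an infeasible
  configuration errors.
* Covariates follow the study summaries: age uniform on 9–15, CELF
  88 ± 12.43 (ASD) vs 109 ± 11.56 (NT), non-verbal IQ 107 ± 9.8 vs
  110 ± 9.05, genders 1:3 female:male, partners drawn from nine
  assistants. `paper_preset()` sets the per-group drifts to −6 Hz (ASD)
  and +4 Hz (NT), 12 dyads per group.

The generator's frame noise SD (5 Hz) and register SD (10 Hz) are
documented assumptions — within-conversation f0 variance of real speakers
is not otherwise constrained here. The synthetic speech is *not*
naturalistic: f0 is piecewise-constant per third plus white noise, there
is no intonation contour, no turn-taking latency structure, and no
content. Passing recovery tests therefore demonstrates that the pipeline
measures what the geometry defines, not that real conversations behave
like the generator.

## Numerical and sizing choices

Simulation-based tests run at reduced problem sizes (60–120 s
conversations, 3–12 dyads per group) chosen so the suite completes in a
few minutes while leaving thousands of voiced frames per window; the
full-scale validation (600 s, 12 dyads per group, 10 seeds) lives in the
recovery test and the acceptance script, where ten averaged seeds put the
Monte-Carlo error of group means well under the 1 Hz check. All
randomness flows from a single seed per run; a rerun with the same config
and seed is file-identical.

## Known limitations

* Turn-level (interpausal-unit) entrainment and synchrony measures are
  out of scope; the measure here is linear convergence over the whole
  conversation.
* Overlapping speech is retained for both speakers; the annotation
  convention for overlap is a study-level decision the package does not
  impose.
* The TextGrid writer emits the long text dialect only (the parser reads
  both long and short); Praat binary Collection files are not read.
* WAV file IO is not included: the estimator consumes bare PCM samples,
  and `render_waveform()` produces them for closed-loop tests.
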