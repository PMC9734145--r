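---
title: "Analysing expressive MIDI performance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing expressive MIDI performance: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midiexpress)
```

## The scientific problem

When a skilled pianist demonstrates an expressive technique to a student,
do they exaggerate exactly the sound parameters that carry that technique?
`midiexpress` implements a complete analysis chain for studies that compare
*teaching* and *performing* renditions of the same notated piece, captured
as MIDI. Two techniques are covered, each with two subcomponents:
articulation (legato vs. staccato) and dynamics (forte vs. piano). The
chain runs, in a fixed order: score alignment and error cleaning, feature
extraction, screening, and repeated-measures inference. A calibrated
synthetic cohort generator stands in for human data so that every stage is
testable end to end.

## Dependent variables

For cleaned, score-aligned trials the package computes:

* **IOI** (inter-onset interval, ms) — `onset(next) − onset(current)` over
  consecutively matched, score-adjacent note pairs; the tempo measure. A
  pair spanning a removed or missing note contributes no IOI.
* **KOT** (key-overlap time, ms) — `offset(current) − onset(next)`.
  Positive values mean the keys overlap (smooth, legato-like); negative
  values mean a gap (sharp, staccato-like).
* **KOR** (key-overlap ratio) — KOT divided by the trial's mean IOI, used
  when participants play at different nominal tempi so articulation is
  measured relative to the beat. The trial mean IOI is computed *before*
  outlier screening (a deliberate choice; the alternative, post-screening
  means, changes KOR in the third decimal at default noise levels).
* **KV** (key velocity, 0–127) — the MIDI loudness proxy, per note.
* **KV transition difference** — at score positions where the dynamics
  notation switches, `KV(following) − KV(current)`; forte-to-piano is
  expected negative, piano-to-forte positive.

Notes the score marks as outside the analysis subdivision, or without an
expressive notation, are excluded from every dependent variable. An
interval whose two notes carry different notations is labelled
`transition` and kept out of both subcomponent pools: the alternative
(assigning boundary intervals to the first note's notation) contaminates
each pool with mixture values, and nothing in the design requires it. KV
is a per-note measure, so this choice does not affect it.

## Alignment and pitch-error taxonomy

Performed pitch sequences are aligned to the score by global unit-cost
edit distance on pitch symbols only (timing is ignored; repeated pitches
are distinct symbols at distinct positions). The three edit operations map
one-to-one onto the error taxonomy: insertion = *extra* tone, deletion =
*missing* tone, mismatch = *substituted* tone, so
`edit distance = |extra| + |missing| + |substituted|` holds by
construction. Among equally minimal alignments the tie-break is fixed —
match over substitution over missing over extra, resolved left-to-right —
which makes cleaning deterministic and reproducible (of two identical
consecutive performed tones competing for one notated tone, the second is
the extra). The dynamic programme is implemented in C++; the test suite
checks it against an independent brute-force minimiser on a thousand
random sequence pairs.

Offsets get their own check: a note held too long makes the release order
contradict the press order. Among matched notes ordered by onset, every
note whose offset rank differs from its onset rank is flagged and removed.
This per-note rank rule is idempotent — notes whose ranks agree are
mutually consistent, so a second pass removes nothing — which gives the
cleaning step as a whole its idempotence. Ordinary legato overlap never
trips the rule, because a small overlap does not change release order.

A trial is invalidated entirely (performer did not follow the score, or
stopped early) when the edit distance exceeds 25% of the score length or
fewer than 75% of score notes are matched. These thresholds are this
package's operationalisation of a judgment call that, in the lab, is made
by inspection; they are exposed as arguments of `clean_performance()`.

## Screening rules

* **Tempo-based participant exclusion.** A participant whose grand-mean
  IOI lies outside 2 standard deviations (n−1 denominator) of the cohort
  mean is excluded; the boundary itself is retained. With fewer than three
  participants the rule is skipped with a warning.
* **3-SD outlier removal.** Values of each dependent variable more than 3
  SD from that variable's mean are removed in a single, non-iterative
  pass. The scope over which mean and SD are taken defaults to
  variable-wide (pooled across participants and conditions, within an
  experiment × technique), with a per-participant option; the choice is
  recorded in the screening report. Because the pooled KOT distribution is
  strongly bimodal (legato vs. staccato), the variable-wide rule is
  conservative for KOT — a property worth knowing when comparing scopes.
  Re-running the rule on its own output could remove more values; the
  pipeline applies it exactly once, and tests pin the removed fraction on
  default synthetic cohorts below 5% for every variable.

## Inference

* **IOI**: the paired teaching-vs-performing comparison of participant
  mean IOIs is gated by a Shapiro–Wilk test on the paired differences
  (α = 0.05): non-normal differences route to a two-tailed Wilcoxon
  signed-rank test with effect size `r = |Z|/√n` (normal approximation
  with continuity and tie corrections; for n < 10 with tie-free
  differences the exact p is used and Z back-derived from it), otherwise
  a paired t with Cohen's `d = mean(diff)/sd(diff)` — a definition that
  satisfies `d = t/√n`.
* **KOT/KOR, KV, transition differences**: a 2 × 2 fully within-subjects
  ANOVA (Condition × Subcomponent, or Condition × TransitionType) on
  participant-cell means. With 2-level factors sphericity corrections are
  moot, so none are applied. The sum-of-squares decomposition and the
  generalized eta squared
  `η²G = SS_effect / (SS_effect + all subject-related SS)` are implemented
  in the package and validated in the tests against base R's
  `aov()`/`Error()` strata as an independent oracle.
* **Post-hoc contrasts**: all six pairwise contrasts among the four cell
  means, each as a paired-difference t with df = n−1 (the multivariate
  within-subject error structure), Tukey-adjusted over a family of four
  means via the studentized range. The two condition-within-subcomponent
  contrasts are highlighted; both unadjusted and adjusted p-values are
  reported. Under a global null the *adjusted* single-contrast rejection
  rate is conservative by construction; type-I calibration at α is a
  property of the *unadjusted* contrast p, and that is what the
  calibration test asserts (the adjusted rate is asserted to be no
  larger).

Cohort-level descriptives are participant-mean based throughout: each
participant contributes one value per cell, and M/SD/Mdn/IQR are taken
across participant means, matching repeated-measures reporting. Under the
`exp1` profile time variables are analysed in ms with raw KV; under
`exp2` the IOI is normalized by the nominal tempo and KOT is replaced by
KOR. KV is never normalized — normalization applies to time variables
only.

## The synthetic cohort generator

`generate_cohort()` emulates the factorial design: participants × 2
conditions × 2 techniques × 8 trials (32 trials per participant), on
deterministic fixture scores — 6 measures of isochronous sixteenths at 80
qbpm (`exp1`) or 12 measures of eighths at a participant-chosen tempo of
100/110/120 qbpm (`exp2`), with notation laid out in one-measure runs so
both subcomponents and both transition directions occur repeatedly. The
fixture pitch content is an arched C-major pattern; no analysis depends on
the specific pitches beyond monophony and alignability.

The generative model, per note: onsets accumulate the nominal IOI scaled
by a participant tempo factor and (under teaching, articulation) a
condition tempo factor, plus zero-mean Gaussian timing noise; each offset
is placed at the *next* onset plus the target key overlap (base +
teaching shift + participant effect + note noise), so configured overlap
targets are exactly recoverable by the feature extractor; velocities
follow per-notation targets analogously, rounded to integers and clipped
to 1–127 (clipping is counted and is below 0.1% at defaults). Pitch
errors are injected per trial at the observed per-category rates (extra
6.28%, missing 5.07%, substituted 0.30%), and a small per-note shock rate
(0.2%) produces genuine outliers for the screening stage to find.

Calibration choices worth surfacing:

* Condition-effect magnitudes and subcomponent baselines follow the
  observed per-condition means (e.g. staccato overlap −128.34 ms
  performing with a −5.45 ms teaching shift; forte/piano velocities near
  82/61). The legato teaching shift (+1.89 ms) was not significant in the
  source data and is therefore gated off by default
  (`kot_shift_applied["legato"] = FALSE`, override with
  `apply_nonsig_shifts = TRUE`).
* Observed between-participant SDs conflate participant-level and
  note-level variability, which the data cannot separate; defaults split
  the variance 70/30 (participant/note). This is a calibration stand-in,
  not an empirical claim.
* The `exp1` dynamics-technique overlap baselines (forte +20 ms, piano
  −20 ms) are chosen values: only the direction (more overlap under
  forte) is constrained by the source results, which print no means for
  them.
* Because participant effects are additive and identical across the four
  cells, they cancel from the within-subject error terms; F statistics on
  default synthetic cohorts are therefore much larger than in real data,
  where participants also vary in how they realise each subcomponent.
  Contrast *estimates*, effect directions and type-I calibration are
  unaffected, and those are what the acceptance checks assert. Passing
  tests on this generator consequently show correctness of the chain, not
  realism of every second-moment property of human performance.
* Timing noise is Gaussian by default (the minimal assumption consistent
  with the parametric tests); `timing_noise = "lognormal"` produces
  skewed differences to exercise the Wilcoxon branch.
* Randomness uses one seed with per-participant substreams derived
  deterministically from it, so cohorts are bit-reproducible and stable
  under changes of `n_participants`.
* A repeated pitch under legato would require a same-pitch overlap, which
  neither a physical key nor note-on/note-off pairing can realize; the
  generator truncates the earlier note just before the re-press. In the
  fixture scores repeated pitches occur only at notation boundaries,
  whose intervals are excluded from the subcomponent pools, so target
  recovery is unaffected.

## Numerical and I/O choices

* All times are carried as milliseconds (doubles) after parsing; MIDI
  ticks are an I/O detail. Writing uses format-0 SMF at 480 ticks per
  quarter, so a write/read round trip preserves times to within one tick
  (1.56 ms at 80 qbpm); pitch and velocity are preserved exactly.
  `write_cohort()` additionally emits a full-precision note table CSV,
  which `read_cohort()` prefers, so ingest mode reproduces in-memory
  statistics exactly.
* Note-on with velocity 0 is a note-off; pairing is first-in-first-out
  per pitch; a dangling note-on is a hard error naming pitch and onset.
  Overlapping same-pitch notes are rejected on write.
* Degenerate inputs are handled explicitly: zero-variance paired
  differences give a degenerate t result (p = 1, d = 0); a null ANOVA
  effect with zero error SS reports F = 0; zero-SD groups are exempt from
  outlier removal; post-hoc contrasts with zero error variance warn and
  report boundary p-values.

## Problem sizes used by the test suite

The Monte-Carlo checks run at the design's own sizes where that is cheap
(parameter recovery: 200 replicate cohorts of 31 participants,
articulation cells only) and at a reduced participant count where the
replicate count matters more than per-replicate size (type-I calibration:
1000 null cohorts of 10 participants). Both sizes are stated here as the
package's choices; the calibration properties they check are
size-invariant.

## Known limitations

* Alignment is pitch-only; timing-aware alignment (e.g. DTW) and
  polyphony are out of scope, as are ornaments.
* The generator does not model phrase-final lengthening, slowing at
  transition points, or participant-by-subcomponent random effects (see
  above); its purpose is verification of the analysis chain, not
  performance synthesis.
* Loudness is key velocity, not dB or sones; pedal and other controller
  events are ignored.
* The removed-note fraction is reported without interpreting whether
  "corrected" responses in comparable human datasets were removed or
  relabelled; users comparing against archival data should check both
  readings.

## A worked run

```{r, eval = FALSE}
cfg <- default_config("exp1")
report <- run_pipeline(config = cfg)
report$stats$articulation$kot_posthoc
write_report_bundle(report, "out")
```
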