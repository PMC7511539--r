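---
title: "Scoring and analyzing piano motor-sequence learning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and analyzing piano motor-sequence learning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pianoskill)
```

## The problem

`pianoskill` implements the analysis pipeline of a two-arm experiment on
explicit motor-sequence learning: novices learn a short piano melody, are
randomized to a single bout of high- or low-intensity interval cycling
(HIIT / LIIT, prescribed from each participant's maximal power output
W~max~), and are re-tested 1 hour, 24 hours and 7 days later, plus on a new
melody (transfer). The package covers the four computational layers of such
a study: performance scoring, exercise-protocol arithmetic, a synthetic
learner cohort for end-to-end testing, and the rank-based longitudinal
statistics.

## Scoring model

A target melody is an ordered pitch sequence with note values and a tempo;
the study melodies are 12 notes over the five pitches A4–E5, quarter and
eighth notes, 75 bpm. The expected inter-onset interval (IOI) of note $i$
is $v_i \cdot 60 / \mathrm{bpm}$ seconds, where $v_i$ is the note value in
beats; a 12-note melody has 11 expected IOIs.

**Pitch accuracy.** Sub-sequences of the target performed in the correct
order are identified by a longest-common-subsequence (LCS) alignment of the
performed and target pitch sequences. Pitch accuracy is

$$100 \times \frac{|\mathrm{matched\ notes}|}{\max(n_\mathrm{target},\, n_\mathrm{performed})},$$

the longer denominator penalizing excessive notes. Among equal-cardinality
alignments the *leftmost* one is used (earliest feasible performance index,
then earliest feasible target index). This tie-break matters only for rhythm
scoring, which depends on *which* occurrences were matched; making it
deterministic makes scores reproducible. The matcher is validated against an
exhaustive enumeration of all common subsequences for sequences up to length
8.

**Rhythm accuracy.** An interval is correct when it is within 10% faster or
slower than expected, boundary inclusive (a $10^{-9}$ relative guard absorbs
floating-point noise at the boundary). Each matched note after the first is
judged against the *preceding matched note*: the observed interval is the
onset difference of the two performance events, the expected interval the sum
of expected IOIs spanning their target indices. Referencing the preceding
correct note stops one early timing error from cascading through the trial.
The denominator is $\max(n_\mathrm{target}-1,\, n_\mathrm{performed}-1)$.

Two readings of the rule for the *first* matched note are defensible, so both
are implemented:

* if its target index is 1, it anchors the timing grid and receives no
  judgment — there is no IOI before the first melody note, and judging it
  would allow 12 correct judgments over an 11-IOI denominator;
* if its target index is greater than 1 (the performance starts with wrong
  notes), its onset is judged against the melody's tempo grid
  (`first_note = "grid"`, default) or counted correct unconditionally
  (`first_note = "always"`). Only the `"always"` variant makes scores
  invariant to shifting the whole performance in time.

A uniform rendition at tempo $T$ of a 75-bpm melody deviates by
$|75/T - 1|$ on every interval, so it is fully within tolerance iff
$T \in [75/1.1,\ 75/0.9]$; rounded to whole bpm this is 68–83, and 58–107
under the legacy 30% criterion — both recomputed by
`acceptable_tempo_range()` (rounding is half-away-from-zero, the only scheme
consistent with both printed ranges).

## MIDI input/output

Performances are ordered keypress events (MIDI pitch, onset seconds,
optional duration). A minimal Standard MIDI File reader/writer (formats 0
and 1) is included: the writer emits one note-on/note-off pair per event
with a set-tempo meta event, the reader converts ticks to seconds through
the file's tempo map and pairs note-offs for durations. Round trips
preserve onsets within one tick. Simultaneous presses are serialized by
ascending pitch so event order is total; time zero is the end of the
four-beat count-in, and the reader can subtract a count-in offset for
capture setups whose clock starts earlier. Only note events and tempo are
interpreted; everything else is skipped structurally.

## Exercise protocol layer

The graded exercise test starts at 100 W (men) or 50 W (women) and climbs
30 W per 2-minute stage; W~max~ is the power of the last fully completed
stage. VO~2peak~ attainment requires at least one of: VO~2~/HR plateau
across the final two stages (defaults: rise < 1.5 ml/kg/min or < 4 bpm —
the criterion names no threshold, so these conventional values are exposed
as arguments), RER strictly above 1.1, cadence failure, or volitional
exhaustion. The 19-minute interval test is warm-up (2 min at 5% W~max~),
three repetitions of 2-min low + 3-min high intervals, and a 2-min
cool-down; HIIT cycles at 60/90% W~max~ and LIIT at 8/12%, the same 2:3
low:high ratio. The dose bookkeeping for participants who stop early sums
elapsed time inside high segments; recorded doses above the scheduled 9
minutes occur in the packaged dose table, so logs are not assumed bounded by
the printed schedule.

## Synthetic cohort

The generator emulates the study's structure exactly: 13 HIIT / 12 LIIT
participants; acquisition blocks 1–3 with 5 test trials each, blocks 4–6
with 5 test trials each; a stop rule after three consecutive pitch-perfect
test trials (evaluated from the end of block 3 onward — a qualifying run
inside blocks 1–3 ends practice once the minimum three blocks are complete,
and only if it is still the most recent run); three 10-trial retention
sessions with the learner state frozen at the end of acquisition; and six
transfer blocks on a second melody with no early stop. Listen and training
trials carry no dependent measures and are not simulated.

Each learner follows an exponential law for per-note correctness,
$p(t) = a - (a - p_0)e^{-rt}$ over test trials $t$; incorrect notes are
deleted or substituted (uniformly over the other four pitches), extra notes
arrive Poisson at uniformly random positions, and IOIs are perturbed by
unit-mean lognormal noise whose coefficient of variation decays
exponentially with practice. The closed-form lognormal tail probability
gives an independent oracle for the mean rhythm accuracy, which the tests
check at CV = 0.05.

The default population is deliberately heterogeneous — asymptotes
$1 - 0.4 \cdot \mathrm{Beta}(1,3)$, learning rates lognormal around 0.10,
initial correctness 0.10–0.50 — so some synthetic learners reach ceiling and
stop at criterion while others never master the sequence, mirroring the wide
variability reported in novice melody learners (about half of default
cohorts stop early). Musical training is lognormal (median ≈ 8 months,
capped at 60), range-matched to the packaged participant table. Group
effects enter additively on the percent scale, truncated to [0, 100]: a
retention offset for HIIT at the delayed sessions, a per-block transfer
slope boost for HIIT, and a consolidation gain of 5 rhythm points at the
delayed sessions for *both* groups (the study-pattern sleep-dependent
consolidation signal). Defaults set the two group effects to zero — the
null configuration of the study's retention finding.

What the generator does *not* emulate: listen/training-trial behavior,
fatigue or session-order effects within a session, the familiarization
phase, and any physiological coupling between the exercise bout and
learning (effects are injected directly on the accuracy scale). Passing
tests therefore validate the scoring and statistical machinery, not any
biological claim.

## Statistical layer

Accuracy percentages are heavily tied and often truncated at 100, so the
longitudinal models are rank-based: the response is replaced by mid-ranks
over all observations and a linear mixed model with a participant random
intercept is fitted to the ranks (REML, sum-to-zero contrasts). Fixed
effects are tested with Type III Wald F statistics; denominator degrees of
freedom follow the containment scheme — between-subject effects (group,
musical training) against the subject stratum, within-subject effects
(session, block, group interactions) against the within-subject residual.
With 25 participants and 4 sessions this reproduces the familiar
F(3, 69), F(1, 22) and F(3, 72) shapes. A non-significant (p > 0.05)
highest-order group interaction is dropped and the model refitted; pairwise
least-squares contrasts on the rank scale are reported without multiplicity
adjustment, with raw-scale cell means alongside for interpretation.
A one-observation-per-subject design collapses the model to ordinary
rank-transform ANOVA, which the tests exploit as an oracle.

Rank models do not estimate percent-scale trends, so transfer learning
rates are summarized separately by `block_slopes()`: a linear mixed model on
the *raw* percent scale with group × numeric-block, reported in percentage
points per block per group.

Session summaries follow the study: each participant's end-of-acquisition
value is the mean of their final 10 test trials (participants stop at
different trial counts, so a fixed window is comparable across them);
retention sessions are 10-trial means.

The classical machinery wraps the standard implementations: pooled-variance
t-tests (df = 23 for 13 vs 12), Wilcoxon rank-sum with mid-ranks,
Lilliefors-corrected Kolmogorov–Smirnov normality checks, and the
noncentral-t sample-size solution (`power.t.test`), cross-checked against
enumeration and Monte-Carlo oracles in the tests.

## Calibration experiments

Three simulation experiments back the statistical layer; their problem
sizes are the package's choices for routine verification:

* **Type I error** — 500 null cohorts at the study's size (13/12); the
  group × session interaction's rejection rate must lie inside the exact
  binomial 95% band around 5%. Under the null the group labels are
  exchangeable, so this checks the F approximation, not the generator.
* **Effect recovery** — 200 cohorts with a 10-point retention offset and a
  2.7 points/block transfer boost; the mean recovered effect must be within
  10% of truth. These runs use homogeneous mid-scale learners
  (p0 = 0.25, asymptote = 0.65, rate = 0.12), keeping scores near 55–70:
  an additive effect is not identifiable against the 0/100 truncation
  boundary, so recovery experiments are designed away from it — with the
  heterogeneous default population, part of any ceiling-adjacent offset is
  clipped, which is a property of percent-scale effects, not an estimator
  bias.
* **Power calibration** — 10,000 Monte-Carlo t-tests at the returned n
  (17 per group for a standardized difference of 1) and at n − 1, allowing
  three standard errors of Monte-Carlo noise on the attained-power side.

## Known limitations

* The original study melodies are published only as engraved figures; the
  packaged `study_melody()` objects are structurally equivalent synthetic
  stand-ins (12 notes, five pitches, 7 quarters + 5 eighths, 75 bpm), so
  note-level comparisons with the original stimuli are not possible.
* The containment-df Wald F is an approximation; its level is verified by
  simulation at the study's design size only.
* The packaged participant table retains all 25 rows; one published test
  reports 21 denominator df (implying two excluded observations not flagged
  in the table), which is documented rather than resolved.
* Rank-scale least-squares means are not back-transformable to percent;
  raw cell means are reported alongside as the descriptive complement.
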