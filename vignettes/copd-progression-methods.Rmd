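---
title: "Modelling COPD progression from clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling COPD progression from clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`copdatlas` estimates when, on a days-before-death axis, the documented
clinical picture of a COPD patient changes, and summarises what the notes
say in each of the resulting periods. This vignette explains the model, the
design decisions behind it, what the synthetic data generator does and does
not emulate, and the package's numerical choices and limitations.

## The data model

The unit of analysis is the **daily sample**: all of one patient's notes on
one calendar day, merged into a single document (pulmonary notes first,
then radiology, then cardiology) and anchored at `days_before_death =
death_date - note_date`. Day resolution is deliberate — the method asks
*when* the clinical picture changed, not at what hour — and death-anchoring
puts every patient on a common axis, which is what makes cohort-level
segmentation and the atlas possible.

Text handling is minimal by design: lowercasing, splitting on
non-alphanumeric runs, a frequency-ranked vocabulary of capacity `V` with
id 0 reserved for padding and id 1 for out-of-vocabulary tokens, and
truncation/post-padding to exactly `T` tokens. No negation detection,
concept normalisation, or section parsing is attempted; those would change
what the themes *mean* but not how the machinery works.

## The sequence model

Each encoded sample passes through an embedding (`V x v`), an LSTM with `L`
hidden units applying the standard gate equations per token, a row-major
flatten of the `T x L` hidden-state matrix, and a dense head. With `P > 1`
the head is a SoftMax over **death-window classes**
`min(floor(days_before_death / B), P - 1)`; with `P = 1` it is a sigmoid
mortality-risk output. The class mapping is the package's own construction:
the window length `B` is the experimenter's knob (30, 90 or 360 days being
the conventional settings), `P` caps the horizon, and everything older than
`(P-1)*B` days falls into the last class. This makes "predict the date
range containing death" well-defined and makes per-window evaluation
straightforward.

Training is plain mini-batch gradient descent on cross-entropy. The loss,
optimiser and learning rate are deliberately simple — there is no
evidence a fancier optimiser changes the scientific conclusions at this
scale, and plain SGD keeps runs exactly reproducible from a seed. Three
numerical choices matter:

* **Initialisation**: embeddings uniform in ±0.05, gate and dense weights
  Glorot-uniform, forget-gate bias 1 (the standard retention
  initialisation), all drawn from the run's seed.
* **Gradient clipping** at global norm 5 (configurable): early epochs on
  separable planted data otherwise produce occasional exploding steps.
* **Batching**: batches are *shuffled* fixed-size subsets (default 32).
  Batching by initial time window — one batch per `B`-day window, the
  `N = D/B` arrangement — is implemented (`batch = "window"`) but not the
  default: window batches are class-homogeneous, and in controlled runs at
  identical budgets they stalled at roughly a third of the held-out
  accuracy that shuffled batches reach. Homogeneous-label batches make the
  head oscillate instead of discriminate.

Learning rates around 0.1–0.3 with `L` of 8–16 and `v` of 16–64 are
appropriate for the synthetic corpora used in the tests; the package
default (0.01) is conservative for unknown real corpora.

## Irregular time-lapse segments

The timeline is cut into `N` consecutive initial windows of `B` days,
window 0 adjacent to death, pooling all patients (the atlas is a cohort
object; per-patient segmentation would require far denser per-patient
histories than clinical reality provides). A **boundary signal** marks
windows that open a new segment; runs of windows between marks merge into
irregular time-lapse segments, so the signal and the segmentation are in
bijection once window 0 is forced to 1.

The signal comes from a dedicated sigmoid head (weights `(T*L) x 1`) on the
mean flattened LSTM representation of each window's samples. The head needs
a training target, and no boundary labels exist in real data, so it is
fitted to a self-supervised change statistic: the cosine distance between
consecutive windows' mean representations, with a window labelled
"boundary" when its distance is a robust outlier (median + 3 MAD across the
cohort's windows). A mean-plus-standard-deviation cut was tried first and
rejected: the boundary spikes themselves inflate both the mean and the
standard deviation, and on planted three-stage corpora it reliably missed
the second of two true boundaries, whereas the MAD rule recovers the
planted segmentation exactly in ten out of ten seeded runs. Empty windows
emit 0 — absence of notes is never treated as evidence of change. The 0.5
decision threshold is configurable.

Two honest caveats. First, the head distils a change-point heuristic into
the architecture rather than discovering boundaries from the class loss
alone; the heuristic, not the head, carries the statistical content.
Second, segment edges are quantised to multiples of `B` by construction,
so a stage change mid-window is attributed to the nearest window edge.

## Evaluation protocol

The split is 70:30 **by patient**, never by sample — daily samples of one
patient are heavily correlated, and a sample-level split would leak.
Accuracy for the sequence model is the class-match rate (equivalently: the
predicted `B`-day range contains the true death offset). The reference
models are linear regression and support-vector regression from
bag-of-words counts to a continuous days-before-death value, scored by the
within-window rule `|predicted - actual| <= B`, boundary inclusive —
"within a window" is read as closed because a prediction exactly one
window-length off is the edge of the stated tolerance, and the choice is
applied consistently to both baselines.

Coarser windows are easier: a 90-day labelling of the same corpus (two
classes over a 180-day horizon) is learned at least as accurately as the
30-day six-class labelling. The package checks this trend by training one
model per window setting, as in the conventional accuracy tables; mapping
fine predictions onto coarse classes would make the inequality a tautology
rather than a measurement.

## Themes and representative sentences

Per segment, sentences (split on `.`, `!`, `?` before whitespace) are the
documents of a latent Dirichlet allocation model fitted by a collapsed
Gibbs sampler written for this package (C++, symmetric priors
`alpha = beta = 0.1`, 200 sweeps by default, seeded through R's RNG so fits
are reproducible). One LDA per segment — rather than one global fit — is
the point of the exercise: the atlas asks what each period talks about,
and a global model would smear late-stage vocabulary into early segments.
Defaults of 5 topics and 10 theme words per topic are unprincipled but
harmless knobs; planted-vocabulary recovery in the tests is insensitive to
them.

A sentence **represents** a theme when its fraction of theme words reaches
30% — the 3-or-4-theme-words regime for 10–14-word clinical sentences. Four
details are pinned down deliberately: the fraction uses the *sentence's
own* length (not a corpus average, which would make a sentence's status
depend on unrelated text); repeated theme words count once (clinical
boilerplate repeats); the threshold is boundary-inclusive (3 hits in
exactly 10 tokens qualifies); and each sentence is attributed to its
best-hitting topic, ties to the lower topic index. Ranking is by fraction,
then hit count, then first occurrence, deduplicated on exact text, top
`k = 10` kept per segment for the `n = 7` segments nearest death.

## The synthetic corpus generator

Real corpora of this kind cannot be shared, so the generator is a
first-class module and defines the package's study conditions. It plants:
latent stages as day intervals before death (strictly decreasing
boundaries ending at 0); pairwise-disjoint per-stage theme vocabularies
plus a shared background vocabulary; sentences of 10–14 words with a
configurable stage-word fraction (default 0.4, comfortably above the 30%
representative threshold so that planted signal is recoverable but diluted
realistically); Poisson note counts per patient-day (default rate 0.05 per
day, roughly 18 encounters in a patient's final year) boosted threefold
inside the final stage, reflecting the clinical observation that
encounters densify near death; and uniformly mixed note types. All death
dates sit at one simulation origin, since every analysis is relative to
death. Test problem sizes — cohorts of 40–200 patients, vocabularies of
300–500 tokens, documents of 80–100 tokens, 180-day horizons — were chosen
once as the smallest sizes at which the planted structure is unambiguous.

What the generator does **not** emulate: realistic clinical language
(negation, abbreviations, section headers), inter-patient variability in
stage timing (all patients share the cohort's boundaries), note-type
specific content, and vocabulary drift within a stage. Passing tests
therefore demonstrate that the machinery recovers structure that is
genuinely present at realistic density and dilution — not that it would
recover the messier structure of real notes, where stage boundaries vary
per patient and themes overlap.

## Degenerate inputs and tie-breaks

Vocabulary ties break lexicographically; prediction ties break toward the
class nearest death; an empty initial window inherits signal 0; a segment
with no sentences stays in the atlas (with a warning) so the timeline
remains complete; a segment with fewer distinct sentences than topics is an
error with the advice to merge segments; `P = 1` models refuse window
accuracy. Checkpoints are JSON with weights printed via `%.17g`, which
round-trips IEEE doubles exactly and keeps files diffable and
byte-deterministic.

## Known limitations

* Plain SGD needs a corpus-appropriate learning rate; there is no
  adaptive schedule.
* Cohort-level segmentation assumes stage boundaries are roughly shared
  across patients; strong individual variation in progression speed will
  blur the change statistic.
* The representative-sentence rule inherits LDA's bag-of-words view: a
  sentence can represent a theme while negating it.
* Runtime is CPU-bound single-threaded R/BLAS; the intended scale is
  cohort experiments of a few thousand daily samples, not the full
  multi-million-note registries that motivate the method.
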