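# copdatlas

Chronic obstructive pulmonary disease (COPD) progresses over years, but the
clinical record of that progression lives mostly in free-text notes —
pulmonary function interpretations, chest X-ray reports, electrocardiogram
reports — written at irregular intervals that themselves carry signal:
encounters cluster as patients deteriorate. `copdatlas` is an R package for
modelling and visualizing that progression on a days-before-death axis. It
is aimed at clinical-informatics researchers who have (or can simulate) a
longitudinal note corpus with death dates and want an interpretable summary
of how documented signs and symptoms shift as death approaches.

The package implements a two-step method:

1. **Irregular time-lapse segmentation.** Each patient-day's notes are
   merged into one *daily sample*, integer-encoded over a frequency-ranked
   vocabulary of size *V*, and padded to *T* tokens. A four-layer sequence
   model — embedding (*V x v*), LSTM (*L* hidden units), flatten, dense —
   is trained by mini-batch gradient descent on cross-entropy to predict
   the death-window class `min(floor(days_before_death / B), P - 1)`, the
   *B*-day window before death in which the sample was written (a sigmoid
   head estimates mortality risk when *P* = 1). The LSTM follows the
   standard gate equations: input, forget and output gates
   `sigmoid(W_h h_{t-1} + W_x x_t + b)`, modulation gate `tanh(...)`,
   memory `c_t = f * c_{t-1} + i * g`, hidden state `h_t = o * tanh(c_t)`;
   per sample the dimension chain is `(T) -> (T,v) -> (T,L) -> (T*L) -> (P)`.
   A dedicated sigmoid boundary head over the flattened LSTM output then
   emits a 0/1 signal per initial *B*-day window; runs of windows between
   1s merge into *irregular time-lapse segments* — long where the notes
   are stationary, short where their content shifts.
2. **The COPD atlas.** For the *n* (= 7) segments closest to death, a
   latent Dirichlet allocation sampler fits per-segment themes, and each
   segment keeps its top *k* (= 10) *representative sentences* — sentences
   whose fraction of theme words reaches 30%, i.e. 3–4 theme words in a
   typical 10–14-word clinical sentence. The atlas is rendered on a spiral
   timeline (death at the center, one revolution per 360 days) against the
   equal-window "regional classifier" baseline, plus JSON and Markdown
   reports.

Real clinical corpora of this kind are confidential, so the package ships a
synthetic-corpus generator with planted stage vocabularies and known stage
boundaries; every claim the test suite makes is checked against that
planted truth. Linear-regression and support-vector baselines
(bag-of-words to days-before-death) and the patient-level 70:30 evaluation
protocol are included.

## Worked example

```r
library(copdatlas)

cfg <- synthetic_config(n_patients = 60,
                        stage_boundaries_days = c(120, 60, 0),
                        horizon_days = 180, seed = 11)
corp <- generate_corpus(cfg)
corp
#> Synthetic COPD note corpus: 892 notes, 60 patients, 3 stages over 180 days

vocab <- build_vocab(corp$notes, V = 500)
samples <- make_samples(corp$notes, corp$deaths, vocab, B = 30, P = 6, T = 100)
split <- split_samples(samples, 0.7, seed = 2)

model <- copd_lstm(split$train, L = 8, v = 16, epochs = 25,
                   learning_rate = 0.2, seed = 3)
lstm_accuracy(model, split$test)
#> LSTM: prediction accuracy 47.21% on 233 held-out samples

sig <- segment_signal(model, samples)
sig
#> Boundary signal over 7 initial 30-day windows (death-first):
#>   1 0 1 0 1 0 0
segs <- signal_to_segments(sig)
segs
#> 3 irregular time-lapse segments (B = 30 days), death-first:
#>   [60, 0) days before death  (windows 0,1)
#>   [120, 60) days before death  (windows 2,3)
#>   [210, 120) days before death  (windows 4,5,6)

atlas <- build_atlas(segs, corp$notes, corp$deaths, n = 7, k = 10,
                     n_topics = 2, seed = 4)
render_spiral(atlas, equal_window_baseline(210, 30), "atlas.svg")
```

The held-out accuracy (47.2% here against a 16.7% chance level for six
classes — samples within one planted stage share a vocabulary, so two of
the six 30-day windows are indistinguishable by construction) says the
model has located samples in time from text alone; the
boundary signal `1 0 1 0 1 0 0` merges seven 30-day windows into three
segments whose edges (days 60 and 120) coincide with the planted stage
boundaries; the atlas then summarises each recovered segment with its
LDA theme words and highest theme-fraction sentences.

The same pipeline is scriptable:

```sh
Rscript inst/cli/copdatlas.R all --out run1 --n-patients 60 --seed 11 \
    --epochs 25 --lr 0.2 --hidden 8 --embed 16 --maxlen 100 --vocab 500
```

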