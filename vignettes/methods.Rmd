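---
title: "Extracting DWI high-signal regions from head-MRI report text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting DWI high-signal regions from head-MRI report text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dwispan)
```

## The problem

The free-text description section of a head-MRI report records signal
findings from several imaging sequences — DWI, FLAIR, T2WI, T1WI — and most
of those findings are attributed to the same or neighboring body parts.
High signal on diffusion-weighted imaging (DWI) is the key finding for
acute ischaemic stroke, so downstream decision support wants exactly the
body-part mentions reported as DWI-high, and none of the others. Plain
named-entity recognition finds *all* body parts; separating the DWI-high
ones from parts carrying FLAIR-high, T2WI-long or DWI-*equal* statements is
a fine-grained typing problem in which the surrounding clause, not the
mention itself, carries the class.

`dwispan` implements two systems for this task on character-level report
text, plus the corpus machinery around them:

* **Question-conditioned span extraction** (the primary method): the input
  is laid out as `(CLS, q_1..q_m, SEP, x_1..x_n)` where `q` is a fixed
  natural-language question (by default "find the DWI high-signal parts in
  the report", in Chinese) and `x` is the report. An encoder produces
  `E ∈ R^{n×d}` over the report characters; two learned projections
  `T_start, T_end ∈ R^{d×2}` give per-character boundary probabilities
  `P_start = softmax_row(E·T_start)` (column 1 = "is a boundary");
  row argmax binarizes them into indicator sequences; and start/end
  markers are paired by sequential matching in character order. Training
  minimizes the sum of the two per-position cross-entropies. Changing the
  question string retargets the extractor (e.g. to *all* body parts)
  without code change.
* **Two-step pipeline** (comparison system): stage 1 tags all body parts
  with BIOES sequence labeling (encoder emissions + linear-chain CRF,
  single `PART` label, legality enforced at decode through transition
  masking); stage 2 classifies each recognized mention as DWI-high vs
  other from concatenated mention/context mean representations. Stage-1
  errors propagate into stage 2 — the error-accumulation weakness the
  one-step extractor avoids, and the package's evaluation demonstrates.

## Conventions

All offsets inside the package are 0-based half-open `[start, end)`. The
span-pair decoder reports 1-based inclusive positions, the convention in
which its worked example is usually stated (`triples_to_inclusive()` /
`triples_from_inclusive()` convert). One widely quoted worked example of
sequential matching prints indicator sequences whose lengths disagree (10
start positions but 13 end positions, with prose stating ends 4 and 10);
the package follows the prose reading — length 10, ends `{4, 10}` — and
`match_spans()` reproduces exactly the spans `(2,4)` and `(7,10)`.

Argmax ties (rows exactly `(0.5, 0.5)`) resolve to "no boundary":
conservative extraction, and it makes the zero-initialized span head start
from the empty prediction. Sequential matching is greedy left-to-right:
each start marker takes the earliest unused end marker at or after it;
starts falling inside an already-formed span and unmatched markers are
discarded; crossing or nested pairs are never produced. The test suite
verifies this against exhaustive enumeration of all non-crossing pairings
for every indicator pair up to length 8.

## Text normalization and corpus I/O

Reports are normalized by removing whitespace (space, tab, CR, LF, and
full-width space U+3000 — the latter added because it is ubiquitous in CJK
clinical text; the set is a parameter) and lower-casing ASCII letters.
Annotation offsets are remapped so each annotation keeps covering its
(case-folded, whitespace-stripped) surface; an annotation consisting only
of removed characters raises an error rather than silently vanishing.
Corpora are read and written in BRAT standoff format (`.txt`/`.ann`); only
text-bound `T` entries are interpreted, other line types are skipped with
a warning. Gold spans are required to be non-overlapping — overlapping
input is rejected loudly, since BIOES cannot represent it.

## The synthetic corpus generator

The original hospital corpus is not publicly available, so the package
ships a generator that reproduces its *statistical profile* and its
central linguistic difficulty. Defaults state that world: on average 2
DWI-high mentions and 8 other part mentions per annotated description,
mean description length about 170 characters, hard cap 525. The printed
statistics are contradictory about the fraction of descriptions without
any annotated part (averages of 2 and 8 per description cannot coexist
with 90% of descriptions being empty under one denominator); the package
resolves this by modeling the *annotated* corpus — `empty_fraction`
defaults to 0 and is a free parameter.

Reports are assembled from statement templates over pluggable
vocabularies: body parts (optionally with laterality modifiers), modality
names (`dwi`, `flair`, `t2wi`, `t1wi`) and signal descriptors (high,
slightly-high, long, equal). Statement kinds:

* *dwi_high* — parts attributed DWI high (or slightly-high) signal;
* *distractor* — parts attributed a non-DWI-high signal, including the
  "DWI equal-signal" near miss;
* *multi_modality* — the same parts under two or more modalities; all the
  parts are labeled by whether any DWI-high attribution applies.

`shared_part_rate` controls both multi-modality statements and the
probability that a distractor reuses parts already reported DWI-high —
the "same part, different sequence" interference that motivates
question-conditioned extraction. `broken_writing_rate` omits the part
delimiter inside multi-part statements at a configurable rate, mirroring
a documented real-report error mode. Unannotated filler sentences pad each
report toward a truncated-normal target length.

Modeling choices the reference statistics do not constrain, chosen once:
mention counts are Poisson (conditioned on the report being non-empty),
target lengths truncated normal with 20% relative spread, statement group
sizes 1–3. Two vocabulary packs are bundled: a romanized default (no CJK
needed anywhere in tests) and a CJK pack mirroring real phrasing. The
romanized pack spells tokens as multi-character syllables, which inflates
text length relative to the 170-character CJK target (its annotated
content alone averages ≈220 characters); the CJK pack reproduces the
length statistics directly. Generation is reproducible: each report's RNG
stream is derived from the corpus seed and the report counter, so reports
can be generated independently and corpora are byte-identical across runs.

What a green test on this generator does *not* establish: real reports
have richer phrasing variety, typos, rare entities and genuinely
ambiguous attributions (e.g. "DWI iso-to-high signal"); the generator's
templates make the attribution cue locally decodable in a way real prose
only approximates. Results on synthetic corpora are statements about the
implementation, not clinical performance claims.

## Encoder architecture and the small-step-budget problem

The reference training setup — learning rate 3e-5, batch 32, 5 epochs,
Adam — presupposes a *pretrained* encoder being fine-tuned. This package
deliberately trains a small encoder from scratch (2 layers, d = 64 in the
acceptance configuration; pretrained weights are out of scope), which at
1,000 training reports gives only ~157 optimizer steps. Two design
consequences follow, both verified empirically during development:

1. **Informative features must exist at initialization.** A fully
   converged linear probe on a generic randomly-initialized transformer's
   features reached boundary recall below 0.3 — fixed random contextual
   features cannot express the decisive cue, which is an exact character
   n-gram ("dwi" + a high-signal descriptor) inside the current statement.
   The encoder therefore builds that structure in:
   * fastText-style *hashed character n-gram embeddings* (sizes 3 and 5 by
     default, 2048 buckets each) added to the character embedding, so
     every n-gram owns a distinct trainable direction from step 0;
   * fixed Gaussian relative-position attention biases per head: sharp
     exact-offset heads (a convolutional prior composing n-grams) in layer
     1, neighbor and statement-scale window heads (including directional
     ones — attribution cues follow the parts they describe) above.
     Content score weights start near zero, so initial attention is a pure
     positional mixer and content refinement is learned;
   * *statement-local* windows: report statements are independent
     attribution units, so window heads (bias sigma at least 2) are masked
     at statement delimiters (sentence-final punctuation, CLS/SEP). Error
     analysis without the mask showed span-start features polluted by the
     neighboring statement's modality cue — a start character's context
     window straddles the boundary — while sharp neighbor-offset heads may
     still cross it (a boundary's neighbor often *is* the delimiter);
   * attention *values* are computed from the raw residual stream while
     queries/keys use the RMS-normalized stream: with shallow learning,
     salience is carried by learned embedding norms, and pre-norm values
     would erase it before window averaging (adding this single property
     raised held-out strict F1 from 0.38 to 0.72 during development).
2. **Step size is parameterization-relative.** Under Adam the functional
   displacement per step is proportional to the learning rate in whatever
   parameterization the model uses (the observation behind maximal-update
   parameterization). The optimizer therefore exposes `update_scale`
   (default 500), an explicit multiplier calibrated so that the reference
   fine-tuning rate produces O(1) functional displacement over the
   reference budget when training from scratch. `beta2` defaults to 0.98
   (0.999 has a second-moment memory longer than the entire run) and the
   step size warms up linearly over the first 10% of steps. The reference
   values remain the recorded defaults of `training_config()`; the scale
   is an architecture-level choice, documented here and in the decisions
   record, not a silent change to them.

Other numerical choices: pre-norm residual blocks with RMS normalization;
the final representation is RMS-normalized and multiplied by a fixed
`output_gain` so span-head logits can traverse the probability range
within the step budget; cross-entropy clamps probabilities at 1e-12; the
loss is averaged per position and summed over the start and end heads (no
class re-weighting by default — an optional positive weight exists but is
off, matching plain cross-entropy); trailing PAD positions are trimmed
before encoding so padding never influences content rows; embedding
column 1 is constant 1, giving linear heads an intercept through the
residual path. The bidirectional recurrent encoder (tanh Elman cells, one
forward and one backward per layer, orthogonal-initialized recurrences)
sits behind the same contract and is exercised by the same shape,
padding, gradient and trainability tests.

All forward/backward passes are hand-written on base-R matrix algebra (no
deep-learning framework exists in the target environment) and verified
against central finite differences in the test suite.

## Two-step specifics

Stage 1 tags with the five-tag BIOES scheme over one PART label; the
typing decision is deferred entirely to stage 2, mirroring the classical
decomposition. Decoding masks illegal BIOES transitions (and illegal
start/end tags) with large negative scores, so emitted tag sequences
always decode without dropped fragments. Stage 2 represents a mention as
the concatenation of mean encoder rows inside the span and mean rows
outside it (window-restricted contexts are a configuration option, whole
report is the default; the reference description does not fix the context
scope, and feature fusion is plain concatenation). The encoder is
fine-tuned jointly with the linear typing layer; batches group whole
documents so each optimizer step encodes every batch document exactly
once. The recurrent-encoder variant of stage 2 uses the reference
settings for that family (lr 0.001, batch 256, 15 epochs); the
self-attention variant uses lr 3e-5, batch 32, 5 epochs.

## Evaluation

A prediction is correct only when document id, start and end all equal a
gold annotation's — strict triple matching. Precision is the matched
fraction of deduplicated predictions, recall the matched fraction of
gold, F1 their harmonic mean. Conventions where the formulas are
undefined: both sets empty scores 1.0 with an explicit `both_empty` flag;
one-sided emptiness scores 0; F1 is 0 when P + R = 0. `multi_seed_eval()`
retrains once per seed and reports per-seed metrics with the mean and
sample standard deviation of F1 (error bars are seed-based; whether the
reference error bars reflect seeds, folds or bootstrap is unstated, and
seeds are the reproducible choice). A failed seed run is excluded with a
warning rather than poisoning the aggregate.

## What the synthetic comparison does and does not show

The acceptance suite trains both systems on a shared distractor-rich
synthetic corpus over three seeds and compares strict F1. Two properties
are asserted:

1. *Error accumulation*: the two-step pipeline's end-to-end F1 never
   exceeds its own stage-2 F1 computed on gold mentions. This holds — any
   stage-1 imperfection can only subtract.
2. *Method ordering*: one-step extraction at least as good as the
   two-step pipeline. **This does not reproduce on the synthetic world**,
   and the suite reports it as a failure rather than hiding it. On
   template-generated text the BIOES tagger enjoys dense per-character
   supervision over a small closed part vocabulary and becomes
   near-perfect, so there are no stage-1 errors to accumulate; the span
   extractor, whose supervision is two sparse boundary labels per
   mention, is the one paying for the 5-epoch training budget. The
   reference ordering was measured on hospital text whose stage-1 errors
   come from messiness (broken writing, rare entities) that a
   template generator with an a-priori 5% broken-writing rate does not
   produce at scale. The generator's parameters state a world and are not
   adjusted to manufacture the ordering; the honest conclusion is that
   this directional property needs realistically messy stage-1 inputs,
   not that either implementation is wrong.

## Known limitations

* The synthetic world is easier than hospital text; headline numbers on
  it are not comparable to numbers reported on clinical corpora.
* The from-scratch encoder with ~157 optimizer steps is far below the
  capacity of a pretrained language model; the acceptance configuration
  is a desk-scale reproduction of the *pipeline*, not of
  pretrained-model accuracy.
* Discontinuous spans, BRAT relation/event layers, nested answers and
  multi-question batching are out of scope.
* "Broken writing" statements (parts concatenated without delimiters) are
  generated but remain genuinely hard — exactly as they are for the
  reference systems, where they are a documented error category.
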