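---
title: "Relation extraction from clinical text with sentence and dependency-path encoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relation extraction from clinical text with sentence and dependency-path encoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdprel)
```

## The task and the model

Clinical narratives assert relations between entity mentions — problems,
treatments and tests — inside single sentences: a treatment is administered
for a problem (TrAP), a test reveals a problem (TeRP), one problem indicates
another (PIP), and so on. `sdprel` classifies each admissible intra-sentence
mention pair into one of the eight relation classes of the i2b2-2010 task or
`None`, using a dual-branch recurrent network.

**Preprocessing.** Every mention span is collapsed to a single placeholder
token carrying its semantic type and its role for the candidate pair under
consideration: `tar_treatment` / `tar_problem` for the two targets,
`ent_<type>` for every other mention. The sentence

> She was maintained on [an epidural] and [pca] for [pain control]

becomes, for the pair (*an epidural*, *pain control*),

> She was maintained on tar_treatment and ent_treatment for tar_problem

Collapsing multi-token mentions to one token means position features are
measured to the mention as a whole rather than to a head word, and it
injects the entity type into the word sequence, which matters in a small
corpus where individual entity words are rare.

**Sentence branch.** Each token is represented by the concatenation of a
word embedding (default 100 dimensions, optionally seeded from a pretrained
word2vec text file) and two position embeddings (50 dimensions each) that
encode the token's signed distance to each target: for "She" above these
distances are −4 and −8. A bidirectional LSTM (200 hidden units per
direction) reads the sequence; the per-step output is the concatenation
h(t) = [h_f(t), h_b(t)].

**Dependency-path branch.** From a CoNLL-U parse of the sentence
(re-indexed onto the masked token sequence; a collapsed mention is
represented by the parse node of its last token) we extract the shortest
dependency path between the two target tokens by breadth-first search over
the undirected view of the edge set, keeping each step's original relation
label and traversal direction. For the example the path is

```
tar_treatment -nmod-> maintained -nmod-> tar_problem
```

Neighboring path words P_i, P_{i+1} are merged by a pairwise convolution:
the two word vectors are stacked into a 2 × n1 block and right-multiplied by
a shared transform M (n1 × n2, n2 = 200), giving m − 1 local features of
dimension 2·n2 for a path of m words. Each local feature is concatenated
with an embedding of the step's dependency relation type and the sequence is
read by a second Bi-LSTM.

**Classification.** Both branch encodings are pooled, concatenated, passed
through a fully-connected tanh layer (with dropout on its input at train
time) and a softmax output layer over the nine classes. Training minimizes
cross-entropy with Adam (defaults: learning rate 1e-5, batch size 32).

## Design choices in the open points

Several details of this architecture are underdetermined by its usual
description; the package resolves them as follows.

* **Shape of the path convolution.** Stating both that M is n1 × n2 and that
  a local feature lives in R^{2×n2} is only consistent with stacking the two
  word vectors row-wise and right-multiplying: `ConP_i = flatten([P_i;
  P_{i+1}] · M)`. `sdp_convolution()` implements exactly this and is tested
  against a per-pair matrix-product oracle.
* **Pooling.** Which timestep feeds the classifier is unspecified; the
  default is element-wise max over valid timesteps (robust and standard for
  relation classification), with final-state pooling available via
  `model_config(pooling = "final")`.
* **Path direction.** The traversal direction of each step (toward head or
  toward dependent) is recorded on every `sdp_path`, but it is not an input
  channel of the model: search is over the undirected graph view, which is
  the common reading of shortest-dependency-path features.
* **Tie-breaks.** In non-tree graphs several shortest paths can exist; the
  lexicographically smallest node sequence is returned so results are
  reproducible. In trees the path is unique (tested against exhaustive
  enumeration and an independent depth/LCA identity).
* **Degenerate paths.** A disconnected pair, or a pair whose path has fewer
  than two words, cannot feed the convolution; such instances use a single
  learned "no-path" placeholder step, so training never crashes on imperfect
  parses and the classifier falls back to sentence evidence.
* **Out-of-vocabulary handling.** Tokens absent from a pretrained embedding
  file are initialized uniformly in [−0.25, 0.25] (seeded); position and
  relation-type embeddings start uniformly in [−0.05, 0.05]; weight matrices
  use uniform Glorot initialization. Relative distances are clipped: values
  beyond ±`max_dist` (default 60) share one out-of-range embedding row.
* **Masking before or after parsing.** Parses are consumed for the original
  token sequence and re-indexed after masking (parse-then-collapse). A
  pluggable `parser` callback on `build_instances()` supports live parsing
  of the masked sequence instead; no parser ships with the package.
* **Epochs and stopping.** The training epoch count is a free choice
  (default 30); when a validation set is supplied the best-validation-micro-F
  parameters are kept, with optional early-stopping patience.
* **Class imbalance.** About two thirds of candidate pairs are unrelated;
  training runs on the natural distribution by default, with optional
  per-class loss weights (`train_config(class_weights = ...)`).
* **Micro-averaging.** `None` is excluded from the pooled true positives,
  false positives and false negatives, the standard convention for this
  task; a flag includes it for diagnostics. Cross-validation folds split at
  the document level so no document contributes to both training and test
  sentences of a fold.

## The synthetic corpus generator

The i2b2-2010 corpus is access-restricted, so the package ships a generator
(`generate_corpus()`, `write_fixture_suite()`) that emulates its structure
without any linguistic realism: documents of templated sentences with 1–5
typed mentions (multi-token with probability 0.3), random projective
dependency trees built by recursive splitting (always single-rooted, acyclic
and connected), candidate pairs under the same type-pair schema, and labels
drawn from the published class proportions (19,870 of 29,282 pairs
unrelated).

Its one scientific control is `sdp_signal_strength`: for every labeled pair
a class-specific trigger token is planted **on** the dependency path between
the targets with this probability, and off the path otherwise; an off-path
distractor trigger of a different class is always added when a free token
exists. Placements are path-aware — an off-path trigger never lands on the
path of any labeled pair, and a distractor's class never matches the label
of a pair whose path contains it — so that at full signal strength path
membership, not token presence, identifies the label. The filler-token count
grows with the mention count so that planting is feasible; the generator
redraws the tree (up to 200 attempts) until every on-path trigger has a free
interior slot.

What passing tests on this corpus show — and what they do not: a trigger
token whose *path membership* determines the label is exactly the kind of
evidence the path branch can represent and the sentence branch cannot
isolate, so the generator demonstrates that the implementation can exploit
syntactic structure when it is present. It says nothing about how much such
structure real clinical text contains; the published gains on the real
corpus (micro-F 74.34% versus 71.84% sentence-only) cannot be reproduced
here because the corpus and the MIMIC-III-trained embeddings are
access-restricted.

## Numerical implementation

The network, including backpropagation through both Bi-LSTMs, the pairwise
convolution, the embedding tables and the pooling, is implemented in batched
base-R matrix operations. Sequences are right-padded; masked steps carry
hidden and cell states through unchanged and masked positions are set to
−∞ before max pooling, so padding provably never influences an encoding
(tested). Analytic gradients are verified against central finite differences
to a relative error below 1e-4 on small configurations; identically seeded
runs are bitwise reproducible, with all randomness (initialization,
shuffling, dropout) flowing from one seed.

## Experiment sizes

The packaged experiments run at desk scale on one CPU. The ablation
experiment (`ablation_experiment()`) uses corpora of about 2,000 candidate
instances (150 documents), a small network (24-dimensional word embeddings,
24 hidden units, 8-dimensional position and relation-type embeddings) and 8
training epochs at learning rate 2e-3 — at this model size and epoch budget
the published learning rate of 1e-5 would barely move the parameters, so the
experiment uses a correspondingly larger step size while keeping the
published batch size of 32. Five seeds give five paired comparisons of
pooled 5-fold micro-F between the sentence-only and +SDP configurations; the
quantity of interest is the sign and size of the paired difference, not the
absolute F-measure, which at this scale is far below what full-size training
would reach.

## Known limitations

* Sentences are assumed pre-tokenized (whitespace); no tokenizer or sentence
  splitter is included.
* Only intra-sentence relations are modeled, matching the task definition;
  cross-sentence relation annotations are dropped with a warning.
* The i2b2-style reader expects token-offset coordinates; character-offset
  variants and XML exports are out of scope.
* The CoNLL-U reader consumes basic dependencies; enhanced or collapsed
  representations are not supported.
* Pure-R training is practical up to tens of thousands of instances at small
  model sizes; full-scale replication (200 hidden units, 30 epochs,
  ~30,000 instances) is possible but slow.
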