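---
title: "Methods: topic-enhanced embeddings and review-augmented clustering for risk-factor mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topic-enhanced embeddings and review-augmented clustering for risk-factor mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topicrisk)
```

## The problem

Short social-media comments by people with a chronic condition (the
motivating case is allergic rhinitis) often report *risk factors*: an
exposure or circumstance — pollen, cold air, dust mites, a habit — that
triggers or worsens symptoms. Individually these reports are anecdotes;
in aggregate, across tens of thousands of comments, they form a
catalogue of triggers, including ones outside the scope of clinical
studies. `topicrisk` implements the computational side of building that
catalogue: clean the comments, learn domain word vectors that pay extra
attention to risk-factor vocabulary, flag the comments that report a
risk factor, group the flagged comments into reviewable categories, and
name each category with keywords.

This vignette documents the modelling choices, their assumptions, every
tunable parameter that matters, and what the synthetic test world does
and does not establish.

## Preprocessing

Cleaning removes URLs, e-mail addresses, and — by a conservative
*whitelist* — any character that is not a letter, digit, underscore,
whitespace or basic punctuation. A whitelist was chosen over an emoji
blacklist because the space of symbol noise is open-ended; the cost is
that exotic but meaningful symbols are dropped too. Cleaning is
idempotent and never mutates the raw text.

Segmentation is whitespace/punctuation splitting with *user-dictionary
protection*: multi-word domain terms ("dust mites") are emitted as
single tokens. This is the Latin-script stand-in for a dictionary-aware
Chinese segmenter; the downstream algorithms are language-agnostic and
consume token sequences only.

Two parameters matter:

* `min_tokens` (default **3**) — the ultrashort filter. Comments with
  fewer tokens ("Thank you!") carry no analysable content. 3 keeps
  short symptom reports ("pollen headache today") while dropping
  pleasantries. No principled value exists; it is exposed as config.
* `min_count` (default **1**) — vocabulary pruning. The default keeps
  everything, since short-comment corpora are dominated by their top
  ranks anyway (`coverage_fraction()` measures this).

Vocabulary ranking breaks frequency ties lexicographically so that
ranks, indices and coverage statistics are deterministic.

## The topic dictionary

The dictionary maps words to topics with positive weights; risk-factor
words get a *large* weight (default **2.0** vs **1.0**). Construction
is semi-automated: seed words come from manually extracted risk-factor
phrases (or from the synthetic generator), and `expand_topic()` grows
the set by repeatedly adding each member's `topn` nearest embedding
neighbours by cosine.

Decisions where the procedure was open:

* **Stopping rule**: the expansion loop stops after `iterations` rounds
  or at a fixed point, whichever comes first — bounded and
  deterministic.
* **Neighbour rule**: the query word itself and words already in the
  set are never re-added; neighbours are a pure top-*n* cut
  (`similarity_floor` defaults to −1, i.e. no cosine cut-off).
* **Conflict rule**: a word reachable from two topics keeps the
  higher-weight assignment; on ties, first come wins. A word never
  belongs to two topics.

## The topic-enhanced embedding (TopicS)

The embedding is a Skip-gram model with an auxiliary task. For every
centre word in a sliding window of half-width `window` (*c*, default
**5**), the model predicts (a) each context word, and (b) the centre
word's topic, when the dictionary contains it. The joint loss is

$$L_s = L_{cont} + \lambda\, L_{topic},$$

with exact decomposition asserted at every logged step. Concretely:

* $L_{cont}$ is the mean negative log-likelihood of the context word
  given the centre word's input vector — a full softmax over the
  vocabulary when `negative = 0`, the standard negative-sampling
  objective (noise = unigram$^{0.75}$) when `negative > 0`. The
  automatic rule uses the full softmax up to 5000 words and 5 negative
  samples beyond.
* $L_{topic}$ is a softmax cross-entropy over topic classes computed
  from the centre word's input vector through a separate topic-output
  matrix, **multiplied by the word's dictionary weight** — this is how
  "a large weight on risk-factor words" enters the objective.
* Words absent from the dictionary contribute **no** topic loss by
  default: forcing them toward a background class would fabricate
  supervision. A (K+1)-class variant with a background class is
  available behind `include_background = TRUE`.

With $\lambda = 0$ the model *is* plain Skip-gram; the test suite
asserts the parameter trajectory matches an independent loop-based
Skip-gram implementation to $10^{-10}$ after 100 updates.

Numerical and schedule choices:

* **Training unit**: one SGD step per comment, on the mean loss over
  that comment's window pairs (and mean weighted topic loss over its
  dictionary centres). The source description of training — averaging
  window losses over a corpus sweep before backpropagation — is
  compatible with several granularities; per-comment batching keeps
  steps cheap, vectorizable and deterministic without an RNG-dependent
  pair order.
* **Learning rate** (default **0.5**, linear decay per epoch to 1%):
  deliberately larger than the classic per-pair word2vec 0.025, because
  a batch-mean gradient over ~100 pairs is ~100× smaller than the
  summed per-pair updates the classic rate was tuned for. The loss
  curves on the synthetic corpus are monotone at this rate.
* **Initialization**: input matrix uniform in $[-0.5/d, 0.5/d]$,
  output matrices zero, all under one seed; training is
  bitwise-reproducible per seed.
* **Sequence-length bookkeeping**: the training sequence length is the
  comment's token count. (Upstream descriptions sometimes conflate this
  with the number of *unique* corpus words; the implementation treats
  it as sequence length, which is the only reading under which the
  window enumeration is well defined.)
* **Dimension**: real-corpus studies sweep 100–400 and find ~100–150
  sufficient for domain-specific corpora; the synthetic world's 300-word
  vocabulary is well served by `dim = 50`, which the examples and tests
  use.
* No frequent-word subsampling by default (flag-free: the synthetic
  corpus is small; real corpora may want it — see Limitations).

## The convolutional classifier

Comments are embedded as a `max_len × d` matrix (tail truncation, zero
padding, out-of-vocabulary tokens as zero rows — the classifier is a
pure consumer of the embedding file, and embedding rows stay frozen
during training). Kernels of widths **2/3/4** (64 filters each, ReLU)
slide over the token axis across the full vector width; global max
pooling, a dropout of **0.5** on the pooled features, and an affine
2-class softmax complete the network. Adam at $10^{-3}$, batch 32, 10
epochs. These are standard TextCNN settings; none are critical on the
synthetic world (the test suite overfits a 20-item set to accuracy 1
and reaches mean CV recall ≥ 0.9 on the default 400-item set).

The decision threshold defaults to **0.5** and is exposed because
recall is usually the deployment priority in risk-factor screening —
missing a reported trigger costs more than reviewing a false positive.

Cross-validation is **stratified** (class ratio preserved within one
item per fold): with near-balanced annotation this is the faithful
reading of "divide into 10 subsets", and it removes fold-composition
variance from small validation sets. Zero-padding length is provably
irrelevant beyond the longest kernel reach: an all-zero window
activates exactly ReLU(bias), identically for every padding row, so
pooled features cannot change — asserted on random inputs.

## Clustering with a review pass (ClusterREV)

Documents are represented as the unweighted mean of their in-vocabulary
token vectors (a TF-IDF-weighted mean would also be defensible; the
unweighted mean matches the embedding-centric pipeline and keeps the
representation parameter-free). All-OOV or cancelled-to-zero documents
cannot be placed on the cosine sphere; they are quarantined and
reported, never clustered.

Single-pass clustering processes documents in input order: join the
category with the highest cosine to its evolving *centroid* if that
cosine reaches θ, else found a new category. Sources describe the match
criterion variously as minimal distance or maximal similarity; the
implementation uses **cosine similarity with threshold θ**, the
single-pass literature convention. θ is genuinely corpus-dependent and
never canonical; the default **0.5** is a permissive round value, and
the parameter is surfaced as the one knob a user must think about.

The review pass exists because single-pass clustering is order
sensitive: an early document can found a category that the right
centroid only drifts toward later. After the pass, every *singleton*
category is re-scored against all non-singleton centroids and merged
when the cosine reaches θ. Only singletons are re-traversed (merging
two singletons would recreate the original problem), one sweep only,
merged singletons are not revisited — so the category count and the
singleton count never increase, and termination is immediate. The test
suite carries a regression fixture where two arrival orders disagree
(ARI ≈ 0.64) and the review pass strictly increases their agreement.

The *manual* side of review is out of machine scope: the package emits
a report (sizes, most-central member texts, centroid-nearest words) and
ingests human decisions (merge/relabel) with id validation and an audit
log.

## Keywords

Each category is treated as one document. A co-occurrence graph
connects words whose token positions lie closer than `window_size`
(default **5**) apart, edges weighted by pair count, no self-loops. The
TextRank recurrence

$$S(u) = (1-d) + d \sum_{v \in N(u)} \frac{w_{uv}}{\sum_{x \in N(v)} w_{vx}} S(v)$$

is iterated from uniform scores with damping **0.85** to tolerance
$10^{-6}$ (cap 200 iterations); isolated nodes score exactly $1-d$.
Reported keyword weights are each word's **share of the category's
total score mass**, so a top-10 list sums to well below 1 (weights in
the few-percent range, the scale on which such tables are usually
printed). That normalization is a presentation decision, not a
mathematical necessity; raw scores are returned alongside.

## The synthetic world

The generator states the world the tests run in: **2 planted topics ×
50 words** over a **200-word Zipf(1.1)** background, **2000 comments**
of **5–15 tokens**, **50%** risk-labelled, **topic purity 0.9** (a risk
comment's token comes from its topic with probability 0.9), **5%**
ultrashort noise. Labels and counts are allocated exactly; everything
is reproducible per seed. The Zipf background mirrors the empirical
observation that a corpus's top-ranked words dominate token coverage;
purity 0.9 encodes that risk-factor comments also mention symptoms and
treatments, at a rate that still leaves the topics learnable.

What the generator does **not** emulate: discourse structure, grammar,
Chinese segmentation ambiguity, annotation noise, class imbalance
drift, or realistic vocabulary sizes. A green test therefore
establishes that the *algorithms* are implemented correctly and recover
planted structure under the stated noise — not that any particular
accuracy will transfer to a real platform corpus. Real-data headline
numbers (classifier accuracy, number of categories found) are functions
of private corpora and are deliberately not targets of this package's
tests.

## Degenerate inputs and tie-breaking

* Empty corpus, single-class training data, vocabulary smaller than
  `negative + 1`, untrained models where trained ones are required:
  errors with specific messages.
* A batch with context pairs but no dictionary centres has
  $L_{topic} = 0$ (not an error); a batch with neither pairs nor topic
  labels is an error.
* Similarity rankings break ties by vocabulary index; keyword rankings
  break ties lexicographically; vocabulary ranks break count ties
  lexicographically. All outputs are deterministic given seeds.

## Limitations

* The trainer is pure R (vectorized per-comment batches). It handles
  the tested scales in seconds but is not built for 10⁷-token corpora;
  frequent-word subsampling and a compiled kernel would be the first
  additions for real-platform scale.
* The full-softmax threshold (5000 words) and negative-sampling default
  (k = 5) follow word2vec practice, not a tuned study.
* `theta` has no default that can be trusted across corpora; inspect
  `glance()` of the cluster set (category count, singleton count) and
  the review report before believing a clustering.
* The classifier architecture slot is convolutional only; recurrent or
  transformer alternatives would plug in at the same interface
  (tokens + embedding → probability) but are not shipped.
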