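---
title: "Models and methods: neural topics, informed sentiment, and brand scores for tweet streams"
author: "infodemiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic generators do and do not emulate, the numerical choices, and
the known limitations.

## The problem

During an outbreak, public social-media streams carry early signal about
local case loads, sentiment shifts and emerging themes. Turning a raw
stream of short, noisy texts into that signal takes four coordinated
analyses: volume (who posts, where, when), sentiment (how they feel),
topics (what they discuss and how it evolves), and impact (which concepts
dominate the discourse network). `infodemiR` implements that stack with
two learned models — a semi-supervised neural topic model and an informed
sentiment classifier — plus the Semantic Brand Score over co-occurrence
networks, the metrics to evaluate all of them, and deterministic
synthetic corpora so the whole pipeline is testable offline.

## Text normalisation

`preprocessText()` lowercases, replaces URLs with the placeholder token
`xurl` *before* punctuation stripping (so the token survives), removes
@-mentions, collapses runs of three or more identical characters to two
("soooo" → "soo"), deletes apostrophes and maps all remaining
punctuation to separators, drops a bundled snowball-style English
stopword list (extended with the retweet marker "rt" and
apostrophe-stripped contraction forms), and stems with a Porter stemmer
implemented in the package. One revision to the classic stemmer is
deliberate: the trailing-`y` rule rewrites `y` to `i` only after a
consonant with at least two preceding letters, so "stay" stays "stay"
while "happy" still becomes "happi". Hashtag words are kept (minus the
`#`) — hashtags carry topical signal in short texts; this is
configurable. The function is idempotent on its own output, which the
test suite asserts.

Vocabulary building keeps terms with corpus frequency at least
`minCount` (default 5 — rare-word removal at tweet-corpus scale; tests
and small examples override it to 1–2) and excludes, by default, the
eight collection keywords of an outbreak query — terms present in nearly
every collected document would otherwise dominate every topic's top
words. Language filtering is accepted as an injectable predicate
defaulting to keep-all; location strings are mapped by an exact-match
gazetteer (city → state → country, unmatched → "oth").

## Prior sentiment scores

The knowledge channel scores **raw** text — casing, punctuation and
negation words carry the signal the rules need, so scoring precedes
preprocessing. The default scorer is a documented subset of the classic
lexicon-rule family: signed valence lookup per token; negation in a
3-token left window multiplies valence by −0.74 (flip and damp); a
booster in the window scales it multiplicatively; an ALL-CAPS matched
token in otherwise mixed-case text gains 0.733 emphasis; each
exclamation mark (up to four) amplifies matched mass by 0.292. Matched
positive and negative weight plus the count of unmatched content tokens
(booster and negator tokens are rule carriers, not sentiment mass) are
renormalised to a (positive, negative, neutral) simplex; no lexicon hit
gives (0, 0, 1). Any function with the same signature and simplex output
can replace the scorer — the classifier only sees the 3-vector.

## The informed sentiment classifier (INN)

Token ids pass through an embedding table into an LSTM; the final hidden
state h_n summarises the sequence and feeds a ReLU data head FC_d. The
prior 3-vector feeds a ReLU knowledge head FC_k. Their concatenation
enters a softmax output layer FC_s, trained with cross-entropy and Adam.
`usePrior = FALSE` removes FC_k entirely — the ablation shares the exact
data architecture, isolating the contribution of the prior channel.

Defaults (all in `innConfig()`): embedding 100, hidden 128, FC_d 64,
FC_k 16, pad/truncate length 64, batch 64, 10 epochs, Adam at 5e-3. The
forget-gate bias initialises at 1 (standard practice; keeps early memory
open). Empty sequences encode to the all-zero hidden state by
convention. Training is bit-deterministic given the seed: documents are
canonically ordered by id before seeded shuffling, so input order cannot
change the trajectory; predictions are batch-size invariant because
padding is masked. Checkpoints round-trip bit-exactly.

The informed-learning experiments in the test suite and acceptance
script use a deliberately small budget — 32/32/16/8 dimensions, length
16, 3 epochs — because the property of interest is the low-resource
regime: with 300 labelled documents whose labels agree with the lexicon
sign 80% of the time, the prior channel lifts mean held-out accuracy
above the ablation; with 20,000 labelled documents both models approach
the 0.8 agreement ceiling and the gap collapses below 0.01. Small widths
keep dozens of training runs inside a desktop compute budget without
changing the phenomenon.

## The semi-supervised neural topic model (SNTM)

The generative picture is LDA-like: T topics, each a distribution over V
vocabulary terms; each document a mixture over topics. Inference is
amortised with a VAE. The encoder concatenates the bag-of-words row with
a contextual document embedding projected to V dimensions (fusion is
disabled when `contextualDim = 0`), passes one softplus hidden layer
(width 100, dropout 0.2 during training), and emits μ and log σ². The
latent sample is z = μ + σ⊙ζ; σ is parameterised as exp(½ logvar) so it
is strictly positive by construction. Topic proportions are
θ = softmax(z), and the reconstruction is d̂ = softmax(θᵀβ): weights are
combined in natural-parameter space before one softmax — a product of
experts, which produces sharper, more coherent topics than averaging
per-topic distributions. A linear classifier head reads the latent
representation — by default the topic proportions θ = softmax(z) during
training (softmax(μ) at inference) — and turns partial labels into
discriminative structure; unlabelled documents contribute no
classification loss. Reading θ rather than raw z is a deliberate choice
(`classifierInput` switches between the two): pressure to separate
classes in raw z can be absorbed by an arbitrary rotation of the latent
space, whereas on the simplex it must sharpen the topic axes themselves,
which is what semi-supervision is for.

Two objectives are provided. The default is the literal form
`|y − ŷ| + ‖d − d̂‖² + KL`, with y one-hot and d the L1-normalised
count row. A `prodldaLikelihood` switch substitutes multinomial
cross-entropy reconstruction (counts against log d̂) and cross-entropy
classification, the established practice for product-of-experts topic
models. Both share one analytic backward pass, verified against finite
differences to 1e-4 relative error. The cross-entropy form is what the
recovery analyses use: with the squared-error form on a simplex-scaled
row the per-entry gradients are O(1/V²), so the KL term dominates early
training and topic separation is very slow; the cross-entropy form
scales with counts and separates planted topics within ~150 epochs at
V = 200.

For the semi-supervised comparisons the classification term is weighted
by `labelWeight = 20` (≈ the mean document length). The reconstruction
term sums over ~20 tokens per document while cross-entropy
classification is a single term of order 1 nat; near-equal weighting
leaves label information almost inert, and scaling the label term to the
same order as the reconstruction restores the intended supervision
without overwhelming it. The config default remains 1.0 (the equal
weighting the loss is written with).

Contextual embeddings are pluggable per-document vectors. The default
provider is `svdEmbeddings()`, a truncated SVD of the log-scaled
document-term matrix — deterministic and self-contained. A pretrained
sentence encoder can be substituted by supplying its vectors; nothing in
the model depends on the provider.

Inference uses θ = softmax(μ) with no sampling. `topWords()` ranks β
rows with lexicographic tie-breaks. Number of topics: 5–50 is the
sensible search range for short-text corpora; the package exposes the
sweep (fit at several T, compare NPMI/IRBO) but deliberately does not
auto-select.

## Evaluation metrics

*NPMI coherence*: per topic, the mean over top-word pairs of
log(P(wi,wj)/(P(wi)P(wj))) / (−log P(wi,wj)), probabilities from
whole-document co-occurrence in the reference corpus, with ε = 1e-12
inside both logarithms; +1 for always co-occurring pairs, −1 in the
ε → 0 limit for never co-occurring ones. Words absent from the corpus
are smoothed and reported. *Embedding coherence*: mean pairwise cosine
of top-word embedding vectors, topics with fewer than two embedded words
skipped and reported. *Topic diversity*: 1 − mean pairwise rank-biased
overlap (extrapolated-tail RBO, persistence 0.9, the literature's
standard). *Classification*: accuracy, precision, recall, F1 for the
declared positive class, multi-class Cohen's kappa, and AUC as the
Mann–Whitney rank statistic over the positive-class probability (mean
ranks for ties; undefined for single-class labels, returned as NA with a
warning). The tests verify the metrics against caret and pROC to 1e-9
and against brute-force counting oracles.

## Co-occurrence networks and the Semantic Brand Score

The co-occurrence unit is the whole document — tweets are short; a token
window is available for longer documents. An edge's weight is the number
of documents in which the pair co-occurs (self-loops excluded); a
minimum-weight filter prunes rare pairs. Shortest paths are unweighted —
edge weights only feed the filter; the weighted-distance variant of the
source method is out of scope and documented as such. Connectivity is
unnormalised betweenness with unordered pairs counted once (so a star
centre with k leaves scores k(k−1)/2 — this fixes the pair-orientation
convention). Each SBS component is standardised over **all** nodes of
the slice's network (sample sd); a component with zero spread (e.g. a
single-node network, or a complete graph where all betweenness is zero)
contributes 0 with a warning. Concepts absent from a slice get raw
components of 0 standardised against the node population — the slice
minimum — so absence is ranked below every present node rather than
dropped.

## Spatio-temporal slicing

Weeks are ISO weeks starting Monday, as half-open intervals — a record
exactly on the boundary opens the new week; the analogous rule holds for
days. Slices partition the stream by construction, which the tests
assert as a conservation law. Empty period-location cells appear in
volume tables as 0 but in sentiment-ratio tables as NA (an undefined
ratio, not zero positivity). Topic evolution is per-slice inference
under one fitted model — mean θ per slice plus slice-local re-ranking of
each topic's global top words. A sequential dynamic topic model with
chained slice-specific word distributions is a different method,
deliberately not implemented; per-slice inference answers the
evolution-reporting question without it and is clearly labelled an
approximation.

## Synthetic generators

Each generator is a pure function of its arguments; the seed initialises
R's RNG at entry, so identical calls are byte-identical.

- *Planted topics*: T topics own disjoint anchor blocks (Zipf-weighted,
  holding 85% of topic mass) over a shared uniform tail; document-topic
  proportions are Dirichlet(0.2) (sparse, as short texts are);
  document lengths Poisson(20) floored at 3. Labels (argmax of the true
  θ) cover a configurable fraction. The realised token-topic draw counts
  are returned so tests can check convergence of empirical frequencies
  to the planted β within binomial standard errors.
- *Sentiment corpus*: each document plants 1–3 lexicon terms of one sign
  among neutral filler; the label agrees with the planted sign with
  probability `alignment` (default 0.8) — labels correlate imperfectly
  with the lexicon, as real annotation does. Degenerate toggles
  (single-class labels, empty documents) exercise the error paths.
- *Tweet stream*: weekly volumes follow a logistic rise (rate 0.8,
  midpoint week 12) into an exponential decay (from week 17, rate 0.35)
  over a 19-week window — quiet onset, burst, peak, slow fall, the shape
  of an outbreak conversation. Texts mix an "early" and a "late" topical
  word pool whose ratio shifts linearly across the window, plus lexicon
  terms, so volume, topic-evolution, sentiment and SBS analyses all have
  planted signal. Locations are drawn from a fixed categorical
  distribution over city/state/country labels.

What the generators do **not** emulate: real vocabulary scale and Zipfian
tails, code-switching and misspellings, user-level correlation, retweet
cascades, label noise structure beyond independent flips, or real
spatial correlation. Passing tests therefore demonstrate correctness of
the computations and the direction of the modelled effects (prior
knowledge helps most when labels are few; labels sharpen topics), not
performance claims about any real corpus.

## Numerical choices and problem sizes

Glorot-uniform initialisation; Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8);
softmax computed with row-max subtraction; probabilities floored at
1e-12 inside logarithms; dropout masks and reparameterisation draws come
from the same seeded stream as initialisation, so a single seed fixes
the entire trajectory. Ties in ranked term lists break
lexicographically; prediction ties break toward the lower class index.
The study sizes used by the packaged analyses — 2,000 documents / 200
terms / 5 topics at 150 epochs for recovery, 300 vs 20,000 labelled
documents for the informed-learning comparison, 200 random graphs of up
to 8 nodes for the connectivity oracle — were chosen so the full battery
runs on a single desktop core in minutes while leaving the measured
effects well clear of their decision thresholds.

## Known limitations

The stemmer and stopword list are fixed English defaults (both
overridable); token-level reproduction of any particular third-party
pipeline is not attempted. The default lexicon bundled for tests is
synthetic and small — real analyses should supply a full lexicon file in
the same TSV dialect. The SNTM trains full-batch-backprop in plain R:
fine for 10⁴–10⁵ short documents, not for 10⁷. AUC is defined for binary
tasks only. Location mapping is exact-match; free-text locations that
need fuzzy or NER-based resolution are out of scope. Weekly topic
evolution shares one β across slices, so it cannot show within-topic
word drift, only prevalence and slice-local word frequency changes.
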