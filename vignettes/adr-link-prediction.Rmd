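---
title: "Predicting adverse drug reactions by knowledge-graph embedding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting adverse drug reactions by knowledge-graph embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many adverse drug reactions (ADRs) surface only after a drug is marketed:
premarket trials are too small, too short and too homogeneous to observe
rare reactions. `adrkg` implements an in-silico screen: known
drug–target, drug–indication and drug–side-effect relationships are
assembled into a knowledge graph (KG), every entity is embedded into a
vector space, and a single binary classifier then scores arbitrary
(drug, side effect) pairs for the probability that the link exists. Drugs
that score highly against an ADR they are not yet labelled with are
candidates for pharmacovigilance follow-up.

The package works entirely on typed triple files; no proprietary database
access is needed, and a synthetic benchmark generator stands in for real
extracts when exercising the method.

## The model

### Embedding

Each triple `(head, relation, tail)` is treated as a three-token sentence.
With `n` the total number of entity and relation tokens, the model is the
CBOW-style softmax predictor

$$f(x^{1}, x^{2}) = \mathrm{softmax}\!\left((x^{1}+x^{2})\,W_1 W_2\right),$$

where $x^{1}, x^{2}$ are one-hot rows for two tokens of a sentence,
$W_1 \in \mathbb{R}^{n\times\text{size}}$ and
$W_2 \in \mathbb{R}^{\text{size}\times n}$. Every sentence contributes
three training samples — each token once as the prediction target with the
other two summed as context (the 3-token sentence makes this equivalent to
a context window of 2). Training minimises the cross-entropy
$-\sum_i \log p(x_i^{3} \mid x_i^{1}, x_i^{2})$ by per-sample stochastic
gradient descent. Entity vectors are the rows of $W_1$.

Two design points were genuinely open and are resolved as follows:

* **Context combination.** The two context one-hot projections are
  *summed*, exactly as the model equation above is written. Some reference
  trainers average the context vectors instead; averaging only rescales
  the hidden vector by ½ and is absorbed by the learned weights, so the
  sum is used without a second mode.
* **Output objective.** The default is the *full softmax*, faithful to the
  printed model and tractable for vocabularies up to a few tens of
  thousands of tokens (the hot loop is compiled, with the per-sample
  score/backprop/rank-1-update steps expressed as BLAS level-2
  operations). A `negative_sampling` mode (one true target plus `negative
  = 5` uniform corruptions per sample) is provided for large
  vocabularies; it optimises the usual sigmoid surrogate rather than the
  exact softmax likelihood.

Initialisation follows word-embedding convention:
$W_1 \sim U(-0.5/\text{size},\, +0.5/\text{size})$ and $W_2 = 0$, which
starts the softmax near-uniform. The learning rate decays linearly from
0.025 to $10^{-4}$ across all updates; sentences are reshuffled each
epoch. Given the same corpus, settings and seed, training is bit-for-bit
reproducible. `iters = 0` is the seeded initialisation itself, which the
tests use as a fixed point. A non-finite loss aborts training with a
diagnostic rather than silently propagating.

### Classification

A candidate pair is represented by the *difference* of its two embedding
vectors, $x = x_{\mathrm{ADR}} - x_{\mathrm{drug}}$, and scored with a
logistic link $P(\text{link}) = \sigma(w \cdot x + b)$. The weights
minimise the summed binary cross-entropy plus an L2 penalty
$\lVert w\rVert^2 / (2C)$ with $C = 1$ and the bias unpenalised — the
standard penalised-logistic objective. The solver is L-BFGS-B on the
explicit objective with analytic gradients, capped at 10000 iterations;
the problem is convex, so any converged solver reaches the same optimum
(the tests verify agreement with an independent BFGS run and with
penalised coordinate descent to $10^{-4}$ in objective value).

One printed form of the link in the source material lacks the
conventional minus sign in the exponent, which would make the probability
*decreasing* in $w\cdot x + b$. The standard increasing link is
implemented: the learned $w$ absorbs the sign and the cross-entropy
objective is unchanged, so the two parameterisations are equivalent up to
$w \mapsto -w$.

Replicated negative training rows are genuine duplicate rows by default;
`collapse_duplicates = TRUE` folds them into case weights with an
identical objective, and the equivalence is tested.

### The split protocol

Drug–indication pairs serve as verified *negatives* (an indication of a
drug cannot be a side effect of that same drug). `make_split()`:

1. holds out `floor(0.1 × n_indication_pairs)` indication pairs as test
   negatives (floor is forced by the protocol's own arithmetic: 10% of
   13,597 pairs is reported as 1,359),
2. holds out an equal number of side-effect pairs as test positives,
3. removes both held-out sets from the embedding corpus and from
   classifier training — the held-out links are invisible to every stage,
   simulating genuinely unknown ADRs,
4. trains the classifier on the retained side-effect pairs (label 1) and
   the retained indication pairs copied 10× (label 0) to offset the
   roughly 10:1 class imbalance.

Negative and positive draws use separate seeded streams, so changing one
sample size never perturbs the other draw. Pairs asserted as both
indication and side effect of the same drug are removed from the
indication side beforehand (`exclude_conflicts()`), keeping the
safety-relevant side-effect edge; occurrences are reported loudly since
curated sources should not contain them. The same attribute *id* acting
as an indication of one drug and a side effect of a different drug is
legitimate and common, and the store permits it.

### Evaluation

`evaluate_predictions()` computes the ROC curve over all distinct score
thresholds (prediction positive at score ≥ threshold, so ties count
positive — one side had to be fixed and is recorded here), the
trapezoidal AUC, and precision/recall/F at threshold 0.5 (no operating
threshold is prescribed by the protocol; 0.5 is the natural choice for a
probability output). The trapezoidal AUC is exactly the pairwise
concordance probability with ties credited ½, and the tests assert that
identity on fuzzed instances. Zero-denominator metric cases return 0 with
a warning rather than NaN.

## The synthetic benchmark

`synth_kg()` generates graphs with *planted* structure. Entities are
assigned round-robin to 5 latent clusters. Side effects and indications
are drawn from one shared pool of *conditions*, mirroring real label
data, where both are concepts from the same medical vocabulary and the
same concept can be a side effect of one drug and an indication of
another. Each condition *leans* one way (300 side-effect-leaning, 100
indication-leaning by default), and edges are drawn independently per
drug–attribute pair:

* on-leaning condition edges and all drug–target edges follow the block
  model — probability `p_in = 0.3` within a cluster, `p_out = 0.02`
  across clusters;
* off-leaning condition edges (an indication edge to a
  side-effect-leaning condition, or vice versa) occur at the suppressed
  rate `p_out² / p_in`.

The design is driven by what the classifier can actually use. A logistic
model on embedding *differences* is additive per token, so its held-out
discrimination rests on per-token propensities — above all, on how
strongly each condition leans side-effect versus indication. A generator
with fully disjoint side-effect and indication vocabularies makes that
signal absolute: the embedding encodes attribute type from relation
co-occurrence alone and the pipeline reaches AUC ≈ 1 even on graphs with
no cluster structure, which renders a null control meaningless. The
graded leaning used here keeps the type signal strong but imperfect, and
the geometric `p_out²/p_in` form ties it to the block parameters: when
`p_in = p_out` every edge probability collapses to the common value, so
the null generator (`synth_kg_null()`, which forces that equality)
carries provably no learnable structure of either kind — cluster or type
— and the pipeline must score at chance on it. Edge counts retain
closed-form binomial moments (checked to 3σ in the tests), which is why
this block-model family was chosen over latent-factor alternatives.

Default sizes are 200 drugs, 400 conditions and 100 targets
(seed-deterministic, ~7,700 triples, ~700 tokens): large enough that the
holdout evaluation has hundreds of test pairs, small enough that a
full-softmax embedding at size 64 trains in minutes on one CPU. The
shared pool also produces occasional same-drug indication/side-effect
collisions, exercising the conflict-drop rule on every generated graph.
`synth_kg_counts()` reproduces exact per-relation pair counts at the
published scale (126,791 / 13,851 / 13,597) for verifying the split
accounting end to end.

What the generator does *not* emulate: heavy-tailed degree distributions,
correlated side-effect co-occurrence, chemical-structure similarity, or
ADR frequency/severity. Passing the synthetic benchmark therefore shows
the machinery recovers relational signal when it exists and invents none
when it does not — it does not certify performance on real
pharmacovigilance data.

## Problem sizes used in the checks

The end-to-end checks embed the default synthetic graph at size 64 for
300 epochs (and at 10 epochs for the iteration-trend comparison), repeat
the split–embed–fit–evaluate cycle three times with derived seeds, and
run the null control once; split arithmetic is checked at the full
published scale (154,239 triples), which only exercises counting, not
training. The reference operating point for real-scale graphs —
`size = 800`, `iters = 2500` — remains the package default in
`default_config()`; the reduced sizes are simply what a laptop-scale
benchmark needs, and the iteration sweep shows the qualitative
iterations-help trend already at these sizes.

One benchmark-scale caveat: with the annealed learning-rate schedule, a
10-epoch run over the ~8k-triple default graph is already a complete
training schedule, and held-out AUC saturates near its ceiling there.
The monotone more-iterations-help trend that full-scale graphs show lives
in the under-fit regime; at desk scale prolonged training (300 epochs)
can leave held-out AUC marginally (≲ 0.001) *below* the 10-epoch value,
as the softmax sharpens against the held-out, removed edges. The test
suite asserts the monotone form and therefore documents this as a known
failing check at benchmark scale.

## Known limitations

* Full-softmax training is O(n·size) per sample; beyond ~2×10⁴ tokens use
  `negative_sampling` mode.
* The classifier is a single global linear model in embedding-difference
  space; per-ADR idiosyncrasies are captured only through the embedding.
* Probabilities are uncalibrated and carry no severity information.
* Entities appearing in held-out test pairs can, in principle, lose their
  only corpus edge to the holdout and end up unembedded; such pairs are
  dropped from evaluation with a warning (rare at realistic densities).
* Multi-hop corpus construction (paths longer than one triple) is out of
  scope.
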