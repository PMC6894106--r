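---
title: "Hybrid semantic relatedness ranking: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid semantic relatedness ranking: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbdrank)
```

## The problem

Literature-based discovery (LBD) asks which entity pairs are related even
though no single publication states the relation. The classic framing is
Swanson's ABC model: if a disease A co-occurs with intermediates B in one
part of the literature, and those same B entities co-occur with a gene C
elsewhere, the implicit pair (A, C) is a discovery candidate. Plain
co-occurrence ranking cannot surface such pairs (their direct count is
zero), and it is also biased toward whatever is popular: heavily studied
pairs accumulate counts regardless of how specific the association is.

`lbdrank` implements a hybrid score that addresses both problems. The
input is tabular entity-relation extraction output (one sentence-level
mention per line: PMID, sentence position, two typed entities, a relation
label), the kind of file produced by biomedical relation-extraction
pipelines. The package never performs NER or relation extraction itself.

## The score

For an unordered pair (A, C), let $c_d$ be the pair's mention count in
abstract $d$. The package aggregates

* $f = \sum_d c_d$ — the total co-occurrence frequency,
* $\alpha = \sum_{c_d \ge 2} c_d$ — mentions from abstracts where the
  pair repeats ("sum_same"),
* $\beta = \#\{d : c_d = 1\}$ — abstracts with exactly one mention
  ("sum_different"),

so $\alpha + \beta = f$ holds on every edge (a conservation law the test
suite checks on every generated corpus). With a semantic relatedness
score $S_{(A,C)}$ from an embedding model (or a precomputed table), the
direct score is

$$Y_{direct} = S_{(A,C)}\,(2\alpha + \beta),$$

which doubles the weight of repeat-mention evidence: a pair mentioned
twice in one abstract is treated as stronger evidence than the same pair
mentioned once in each of two abstracts.

For every shared intermediate $B_i$ of A and C, with leg frequencies
$a_i = f_{(A,B_i)}$ and $b_i = f_{(B_i,C)}$, the indirect relatedness is
the frequency-weighted mean
$S_i = [S_{(A,B_i)} a_i + S_{(B_i,C)} b_i]/(a_i + b_i)$, and the path
score multiplies it back by the link count:

$$X_i = S_{(A,B_i)}\,a_i + S_{(B_i,C)}\,b_i, \qquad
  Y_{indirect} = \sum_{i=1}^{n} X_i, \qquad
  Y = Y_{direct} + Y_{indirect}.$$

Only length-two paths are accumulated; longer chains dilute evidence
quality rapidly and are out of scope. A pair with no direct edge has
$Y_{direct} = 0$ but can still rank via $Y_{indirect}$ — that is the
LBD mechanism. Ranking applies min-max normalization
$(y - \min)/(\max - \min)$ over the candidate list; ties are broken
lexicographically on the candidate label so rankings are deterministic.
When every candidate scores the same, all normalized scores are set
to 1 (the list carries no ordering information, and 1 preserves the
"top item has score 1" invariant).

Two readings of $\alpha$ are possible from its verbal definition (a
count of abstracts, or of mentions). The package counts mentions:
summed occurrences over repeat-mention abstracts. Only this reading
makes $\alpha + \beta$ equal the total frequency, which the worked
direct-score example requires ($4123 + 1003 = 5126$ with
$0.427029 \times (2 \cdot 4123 + 1003) = 3949.59$). Each record line
counts as one mention, so the same pair extracted twice from one
abstract with different relation labels contributes 2; relation labels
are carried through but never weighted.

## Relatedness providers

The score is agnostic about where $S$ comes from; anything implementing
`relatedness(provider, x, y)` and `coverage(provider, x)` works. All
providers are symmetric with $S(x,x) = 1$ on covered entities, and
uncovered pairs default to $S = 0$, which silently drops that path's
contribution rather than inventing relatedness. Negative cosines pass
through unclamped.

* **`train_skipgram()`** — skip-gram with negative sampling, written in
  C++ with a self-contained RNG: single-threaded, bit-reproducible for a
  fixed seed. Defaults: dimension 100, window 5, 5 negatives, 5 epochs,
  initial learning rate 0.025 with linear decay, unigram$^{3/4}$
  negative table. These are standard small-corpus SGNS settings; the
  scoring layer is provider-pluggable, so none of them is load-bearing.
* **`train_specialized_skipgram()`** — the same objective supplemented
  with thesaurus contexts: at each center position whose token belongs
  to a synonym group, with probability `context_sample_rate` (default
  0.5) one extra (token, context) pair is trained, the context drawn
  uniformly from the token's group. With rate 0 the output is
  bit-identical to plain training under the same seed, which the tests
  assert — the specialization is a strict superset of the plain
  objective.
* **`build_coals()`** — COALS: ramped-window counts (weights
  $w - o + 1$ for offset $o$, default window 4 giving 4, 3, 2, 1),
  columns restricted to the most frequent tokens, cells replaced by the
  margin correlation statistic, negatives truncated to 0, square root
  of positives; similarity is the Pearson correlation of transformed
  rows. One published summary of COALS describes "summing" row
  correlations; we implement the canonical row-correlation similarity
  instead, as the summing variant is not well defined for a pair.
* **`build_random_indexing()`** — sparse ternary index vectors
  (`nonzeros` entries, half $+1$ half $-1$, default 8 in 300
  dimensions), context vectors accumulated over a symmetric unweighted
  window, cosine similarity.
* **`table_provider()`** — precomputed scores, used to run worked
  examples and to decouple scoring tests from training stochasticity.

Training corpora are entity-token sequences reconstructed per abstract
(two adjacent tokens per record, in sentence order) — not raw prose,
which the pipeline never sees.

A practical note on scale: on toy corpora (a few thousand tokens) SGNS
cosines are dominated by a global drift component for the first few
epochs — all vectors correlate with a shared direction and pairwise
cosines crowd toward 1. Structure emerges with longer training; the
test suite therefore uses 20 epochs on its 100-document fixtures.
Paired comparisons (specialized vs. plain under the same seed) are
robust to the drift and work at the 5-epoch default.

## The synthetic corpus generator

`synth_config()`/`synth_corpus()` generate the inputs every other module
consumes, with planted ground truth:

* a hub entity (the ranking target) with **direct pairs** firing per
  abstract at a configured rate; firing abstracts carry
  `1 + Bernoulli(multi)` mentions — the simplest process that exercises
  the $\alpha/\beta$ split;
* **hidden pairs** with zero direct co-occurrence, linked to the hub
  through exactly `m` dedicated intermediates (default 5), each leg
  firing at `leg_rate` (default 0.25 over 120 abstracts, i.e. about 30
  mentions per leg) with planted leg relatedness `strength` (default
  0.9);
* a **frequency-matched direct-only control**: a direct pair whose
  expected mention total equals the hidden pair's expected total leg
  mentions (`m * leg_rate` per abstract, rate capped at 1 with the
  surplus as repeat-mention probability). Co-occurrence ranking must
  prefer the control (the hidden pair scores 0); the hybrid score
  should prefer the hidden pair — the package's central qualitative
  claim, asserted across seeds;
* a **grouped synonym pair** with complementary abstract parities and
  different co-occurrence partners ("app" appears with the hub in
  even-numbered abstracts; "amyloid precursor protein" with a second
  disease in odd ones). The two tokens therefore never share an
  abstract and have disjoint contexts, emulating sub-literatures that
  use different names for one concept — precisely the situation where
  corpus-only training cannot align them and thesaurus specialization
  must;
* background noise records over filler entities at `noise_rate` 0.3.

Ground-truth pair statistics are tallied during emission, independently
of the aggregation code they are later compared against. What the
generator does **not** emulate: real mention-count distributions (heavy
tails over five orders of magnitude), polysemy, extraction errors,
correlated topics, or prose context. Passing tests demonstrate the
estimator's arithmetic and its qualitative behavior under the planted
regime, not performance on real literature.

## Numerical and design choices

* Entity labels are trimmed, case-folded, whitespace-collapsed;
  an optional thesaurus maps synonyms to the group's lexicographically
  smallest member. Without this the graph fragments ("APOE" vs
  "apoe "). Normalization is idempotent and all sorting uses radix
  (byte) order, so results are locale-independent.
* PMIDs may carry thousands separators in extraction output; they are
  stripped. A trailing empty field from a terminal `|` is tolerated.
* The default candidate universe for ranking is every entity with a
  direct edge *or* at least one intermediate to the target, since
  $Y_{indirect}$ is defined for indirect-only candidates;
  `direct_only = TRUE` restores a pure co-occurrence universe.
* Intermediate path weights $a_i$, $b_i$ are the legs' total
  frequencies $f$, not abstract counts.
* Top-k% evaluation: $k = \lceil \text{fraction} \times
  \text{list length} \rceil$; recall is $|hits|/|reference|$. The
  precision denominator in published uses of this protocol is
  ambiguous, so it is a switch: `min(k, |reference|)` (default,
  maximum-attainable-hits), plain `k`, or `|reference|`.
* Problem sizes in the test and acceptance suites (120–200 abstracts,
  20-node oracle graphs, 1000-draw property checks, 5 seeds per
  stochastic claim) are chosen so each claim is exercised well past
  sampling noise while the whole suite stays interactive.

## Limitations

* Only length-two (one-intermediate) paths contribute indirect
  evidence.
* Relation types are parsed and preserved but never weighted.
* The skip-gram trainer is single-threaded by design (bit-exact
  reproducibility beats wall-clock speed at the corpus sizes this
  package targets); for corpora of millions of abstracts a dedicated
  embedding toolkit is the right tool, and its scores can be fed in as
  a `table_provider`.
* Absolute score magnitudes are corpus-dependent (they scale with
  mention counts); only within-ranking comparisons and the min-max
  normalized scores are meaningful across corpora.
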