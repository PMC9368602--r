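---
title: "Methods: knowledge-network NodeRank for multi-label diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-network NodeRank for multi-label diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxrank)
```

## The problem

A patient's clinical record usually supports several simultaneous diagnoses:
the task is multi-label classification where one record maps to a *set* of
ICD-coded diseases. dxrank implements a knowledge-driven approach: instead of
learning a classifier per disease, it scores diseases by propagating evidence
through a manually curated, binary-weighted knowledge network (KN) that links
diseases to the diagnostic findings supporting them.

## The model

### Knowledge network

The KN is a strictly bipartite directed graph. Finding nodes (clinical
manifestations and auxiliary examination results) point at disease nodes.
Each edge carries the category of the finding *for that disease* —
`occasional` manifestation, `common` manifestation, or `auxiliary`
examination result — and a positive weight determined by a weight scheme.
The shipped schemes (`<113>`, `<123>`, `<135>`, `<137>`, `<139>`) weight
occasional/common/auxiliary as the digits suggest; the default is `<137>`:
occasional 1, common 3, auxiliary 7. Auxiliary results are instrument-based,
deep examinations and carry the strongest evidence.

Category is deliberately an **edge** attribute, not a node attribute. If a
finding had one global category, every out-edge of that finding would carry
the same weight, the out-weight normalisation below would reduce to
1/degree, and all weight schemes would yield identical predictions. A
symptom that is a common manifestation of one disease and only an
occasional one of another is also the clinically realistic case.

### Per-patient subnetwork and the calibration pair

For each record, affirmed finding mentions are matched into the KN (exact
surface match first, then a pluggable string-similarity fallback, default
character-bigram Dice with threshold 0.5). The patient subnetwork contains
the matched findings, every KN disease adjacent to at least one of them,
and the connecting edges. Two reserved nodes are added: a *gold standard*
source wired by a single edge (weighted like an auxiliary result) to a
*standard disease* node. This pair represents a hypothetical disease
supported by exactly one conclusive, dedicated test; its score calibrates
the output threshold per record, which is what lets different patients
receive different numbers of labels.

### NodeRank

Scores follow an edge-weighted PageRank variant:

$$\mathrm{NR}(v) = (1-d) + d \sum_{u \to v} \mathrm{NR}(u)\,
\frac{w(u,v)}{\sum_{u \to j} w(u,j)}$$

with damping $d = 0.85$ by default. The $(1-d)$ term is *not* divided by
the node count, so source nodes (findings, the gold standard) converge to
exactly $1-d$. A disease is predicted iff
$\mathrm{NR}(D) \ge \mathrm{NR}(\text{standard disease})$.

On the bipartite subnetworks this has a useful closed form. Every finding
scores $1-d$, so

$$\mathrm{NR}(D) = (1-d) + d(1-d)\, r(D), \qquad
r(D) = \sum_{f \to D} \frac{w(f,D)}{\mathrm{outweight}(f)},$$

the *support ratio* exposed by `support_ratio()`. The threshold node has
$r = 1$ exactly, hence the threshold is $(1-d)(1+d)$ for every subnetwork
and every $d$, and a disease is predicted iff $r(D) \ge 1$ — independent of
$d$. The damping factor therefore moves scores but never the predicted
set on these DAGs; we keep it because the ranking (used by the ranking
metrics) and any future cyclic extensions depend on it. Because the
subnetwork contains *all* KN diseases adjacent to each matched finding, a
finding's out-weight inside the subnetwork equals its KN out-weight; tests
assert this equivalence.

### Extraction and negation

The default tagger is greedy forward maximum matching against a lexicon
(longest term first, non-overlapping), emitting BIO tags; `tokenize()` uses
character granularity for Han-script text and whitespace tokens otherwise.
A linear-chain CRF backend (`crf_score()`, `crf_log_likelihood()`,
`crf_decode()`) accepts externally produced emission/transition matrices,
so a trained neural tagger can replace dictionary matching without touching
the rest of the pipeline; training is explicitly out of scope.

Negation: a mention becomes negated when a cue (e.g. 无, "no", "denies")
ends at most `window` tokens before the mention starts, or occurs inside
its span. The in-span clause is our reading of clinically frequent patterns
like "pain-free"; it is configurable in effect because cue lists are
user-supplied. `window` defaults to 2 tokens, matching the "last two
characters" convention common in Chinese clinical NLP. Negated mentions are
removed before matching — they never contribute evidence.

### Evaluation

The five standard multi-label metrics are implemented over a fixed label
space $Q$: Hamming loss (symmetric-difference rate), one-error (top-label
miss rate), ranking loss (mis-ordered gold/non-gold pairs, *ties count as
losses*), average precision (mean precision at each gold label's rank) and
micro-averaged precision/recall/F1 pooled over labels. Average precision
normalises per record by the gold-set size (the standard definition);
`normalize = "label_space"` divides by $Q$ instead for comparability with
sources using that variant. Ranks use a deterministic total order —
strictly greater score first, ties by ascending label id — and all other
tie-breaks in the package are likewise by ascending identifier:
determinism over arbitrariness.

Diseases absent from a record's subnetwork receive score 0 and are never
predicted. When the evaluation label space is given explicitly, predictions
outside it are ignored rather than counted as false positives.

`kfold_split()` provides the five-fold protocol: ids are shuffled under a
seed and partitioned into folds whose sizes differ by at most one. The KN
is fixed evidence, not fitted, so folds only partition the evaluation.

## Numerical choices

- NodeRank iterates Jacobi updates from a uniform start of 1 with
  tolerance $10^{-10}$ and a 100-iteration cap, erroring with the residual
  on non-convergence. On the bipartite subnetworks the fixed point is
  reached after two sweeps; the cap matters only for user-supplied cyclic
  graphs.
- The threshold identity $(1-d)(1+d)$ holds algebraically; in floating
  point the iterated value can differ by one ulp (observed at
  $d = 0.85$), so tests assert it at $10^{-12}$.
- The CRF log-partition uses the forward algorithm in log space with a
  stable log-sum-exp; Viterbi ties break towards the lowest tag index. A
  dangling `I` tag is repaired to `B` with a warning rather than rejected,
  to be robust to imperfect external taggers.
- Bigram Dice similarity is purely lexical: near-synonym pairs that share
  characters but no bigram (e.g. 腹部疼痛 vs 腹痛) score 0 and rely on the
  lexicon or a user-supplied semantic similarity function. This is a known
  limitation of the default, kept because the similarity strategy is
  pluggable.

## What the simulator emulates — and what it does not

`simulation_config()` defaults encode the study conditions the method
targets: a KN of 182 diseases, 1,146 manifestations and 513 auxiliary
results; 5,040 records drawn from 76 active diseases; gold-set sizes from a
zero-truncated Poisson whose rate is calibrated so the truncated mean is
3.62. The remaining generative choices are ours, fixed once and exposed as
parameters:

- per-disease edges: 2–4 common, 3–6 occasional, 1–3 auxiliary, drawn from
  shared pools; with probability 0.25 an occasional edge reuses another
  disease's common manifestation (the mixed-category sharing that makes
  weight schemes matter);
- emission probabilities 0.9 / 0.35 / 0.7 for common / occasional /
  auxiliary findings of a gold disease — common symptoms are usually
  recorded, occasional ones rarely, auxiliary tests often ordered;
- noise mentions: binomially, about 0.1 distractor findings per true
  mention, drawn from diseases outside the gold set;
- 10% of mentions flagged negated.

`render_text()` embeds surfaces in filler tokens with cues immediately
before negated surfaces, using vocabularies disjoint from the lexicon so
extraction round-trips exactly. Two regimes are designed for testing:
`exclusive_findings = TRUE` with guaranteed auxiliary emission makes
patients perfectly separable (the pipeline must recover gold sets exactly);
the shared-occasional/exclusive-auxiliary configuration reproduces the
qualitative weight-scheme finding that `<137>` dominates flat weights.

Synthetic corpora do **not** mimic real clinical prose, reporting habits,
label imbalance (the real corpus ranges from 76 to 2,958 occurrences per
disease), misspellings, or semantic synonymy. Passing tests demonstrate
algorithmic correctness and the designed qualitative behaviours, not
real-EHR performance; numbers computed on synthetic corpora are far better
than anything achievable on real records, where extraction quality and KN
coverage dominate.

## Problem sizes used by the shipped analyses

The package's evaluation script simulates the full study-scale corpus
(5,040 records, full-size KN) and runs the five-fold pipeline on it;
test fixtures use 10–50 patients and networks of 12–20 diseases, with the
oracle-equivalence suites running hundreds of small randomized instances
(graphs ≤ 30 nodes, CRF instances up to $4^6$ enumerated paths, corpora up
to 50 × 12 labels). These sizes were chosen so each property is checked
exhaustively where enumeration is feasible.

## Known limitations

- No tagger training; dictionary matching misses paraphrases unless the
  lexicon lists them.
- The default similarity is lexical (see above); no UMLS/SNOMED or
  embedding-based linking.
- The KN TSV stores nodes through edges, so isolated nodes do not survive
  a save/load round-trip.
- One-error's tie-break (lexicographically smallest top label) is a
  convention; with continuous NodeRank scores ties are rare but possible
  on structurally identical diseases.
- Reserved node ids are namespaced (`__STANDARD_DISEASE__`,
  `__GOLD_STANDARD__`) and rejected if a KN uses them.
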