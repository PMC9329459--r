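---
title: "Methods: desk-scale protein language modeling with protlm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale protein language modeling with protlm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

protlm implements, at a scale that trains in minutes on one CPU, the full
methodology of autoregressive protein language modeling: sub-word
tokenization, causal-LM training, calibrated stochastic decoding, and the
sequence-level evaluation battery (twilight-zone homology classification,
disorder/secondary-structure aggregation, similarity networks). This
vignette is the package's account of the underlying models, the parameters
that matter, the numerical choices made where the design was open, and what
the desk-scale tests do and do not demonstrate.

## The model

A protein sequence $W = (w_1, \dots, w_n)$ of tokens is modeled
autoregressively,

$$p(W) = \prod_{i=1}^{n} p(w_i \mid w_{<i}),$$

and the parameters are fit by minimizing the mean negative log-likelihood
per predicted token (nats) over the training corpus. The conditional
$p(w_i \mid w_{<i})$ is computed by a decoder-only transformer: learned
token and positional embeddings, pre-norm blocks of masked multi-head
self-attention and a GELU MLP with residual connections, a final layer norm
and a linear output head. The head is zero-initialized, so an untrained
model's next-token distribution is exactly uniform — this gives the suite
its analytic anchors (loss $\ln V$, perplexity $V$ for vocabulary size
$V$). Forward and backward passes are written directly in R matrix code;
the backward pass is verified against finite differences in development and
against analytic and closed-form losses in the tests.

Two configurations matter:

* **Desk default** (`lm_config()`): 4 layers, width 128, 4 heads, context
  256 tokens. The tests use even smaller models (1-2 layers, width 16-32,
  context up to 128), which are ample for the corpora below.
* **Full-scale preset** (`lm_config_full_scale()`): 36 layers, width 1280,
  20 heads, 512-token blocks, ~65k tokens per batch, vocabulary 50,256.
  This is the published large-model recipe, kept as a named configuration
  for documentation; training it is out of scope here and it is never
  exercised by the tests.

Optimization is Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, learning rate
$10^{-3}$ by default, constant schedule with an optional cosine decay).
Global gradient-norm clipping at 1.0 is a desk-scale stability aid. Corpora
are packed for training by joining encoded sequences with end-of-sequence
separators and chunking the stream into context-length blocks; a trailing
block shorter than two tokens carries no predictable position and is
dropped. Reproducibility is contractual at the level of seeds: the same
seed gives the same initialization, batch order, and loss trace on the same
hardware class (BLAS differences across hardware can perturb the last
bits).

## Tokenization

`bpe_train()` is classic byte-pair encoding over residue strings: each
sequence is one "word" (no whitespace pre-tokenization exists for
proteins), and the most frequent adjacent symbol pair is merged repeatedly
until the vocabulary is full or no pair occurs at least twice. Open choices
the algorithm's description leaves silent are fixed as follows:

* pair-count ties break lexicographically by (left, right), making
  training deterministic;
* vocabulary ids are dense from 0: specials (`<eos>`, `<unk>`), then the
  base alphabet sorted, then merged tokens in merge order;
* characters outside the base alphabet encode to `<unk>` (with a note
  counting them) instead of erroring, so natural data with rare codes
  passes through;
* `encode` never appends `<eos>`; sequence delimiting belongs to block
  packing, keeping `decode(encode(s)) = s` an exact identity.

At full scale a 50,256-token vocabulary yields sub-words of about four
residues; desk vocabularies (tens to hundreds of tokens) are used
everywhere in the tests, and `char_tokenizer()` provides the character-level
special case needed when model conditionals must align with per-residue
statistics.

## Decoding

All decoders are written against a *provider* interface — any function
mapping a context of token ids to a probability vector — so that exact
lookup-table fixtures plug in wherever a trained model does. For
stochastic sampling the per-step transform order is fixed and documented:

1. repetition penalty on the log-scores,
2. temperature,
3. top-k,
4. top-p (nucleus),
5. renormalize, then sample.

The repetition penalty follows the conditional-generation rule attached to
the published operating value 1.2: scores of tokens already in the context
are divided by the penalty when positive and multiplied when non-positive.
Applied to log-probabilities (all non-positive) this uniformly down-weights
seen tokens. Two practical consequences are documented here because they
shape the tests:

* the penalty's anti-repetition power requires *unseen* competitors. With
  a vocabulary much larger than the emission length (the sub-word regime:
  50k tokens vs 250-token windows) unseen tokens always remain and raising
  the penalty monotonically lowers repetition. When the whole alphabet has
  already been emitted, the same rule uniformly rescales all log-scores,
  which *sharpens* the distribution instead. The monotonicity fixture
  therefore uses a 40-symbol alphabet with a 25-token budget;
* an end-of-sequence token placed in the prompt (the default start token)
  is "seen" from step one and is penalized with everything else.

Top-k keeps the k most probable tokens (ties at the k-th probability break
toward the lower token id) and renormalizes; top-p keeps the smallest
probability-sorted prefix reaching cumulative mass p, always retaining at
least one token. Inside the sampling pipeline the effective k is clamped to
the vocabulary size so that full-scale grid presets (k up to 1000) can be
exercised against desk vocabularies; the standalone filter keeps its strict
contract. Beam search scores by summed log-probabilities of the transformed
distribution without length normalization (a switch enables it), retires
beams that emit end-of-sequence, and ranks retired and active beams
together; with exhaustive width it provably returns the global argmax,
which the tests check against brute-force enumeration of every reachable
emission. Emitted ids and decoded sequences exclude the terminating EOS
token, but its probability is included in the emission's total
log-probability (retired beams compete on it).

Generation defaults mirror the published pipeline: a 250-token emission
budget, and budget-exhausted (length-censored) emissions flagged
`terminated = FALSE` and removed by `filter_truncated()` before any
dataset-level statistic.

## Calibration by propensity matching

`grid_calibrate()` reproduces the sampling-parameter search: for every cell
of a (repetition penalty, top-k, top-p) grid it samples a fixed number of
sequences, drops censored emissions, and scores the L1 distance between the
amino-acid propensities of the survivors and a natural reference profile,
concentrated on the reference's seven most common residues (the
full-alphabet L1 is a secondary column). The published grid — penalty
1.1-3.0 in 0.1 steps, top-k 250-1000 every 50, top-p 0.70-1.00 in 0.05
windows, 100 sequences per cell — instantiates exactly
$20 \times 16 \times 7 = 2240$ cells and is available as
`grid_spec_paper()`. Rows are ranked ascending by focus distance with
deterministic (penalty, k, p) tie-breaks; cells whose emissions were all
censored are flagged rather than silently dropped. Beam-search cells are
excluded from the default grid (deterministic decoding produces repetitive,
propensity-poor sets); beam decoding remains available separately.
Reproducing the published optimum (k = 950, penalty 1.2) would require the
full-scale model and is explicitly not a goal; what the desk tests show is
that the machinery ranks faithful sampling above distorting parameter sets
on sources with known statistics.

## Evaluation statistics

**HSSP classification.** The twilight-zone boundary is the classic
two-piece curve $t(L) = 290.15\,L^{-0.562}$ for alignment lengths
$L \le 80$ and $24.8\%$ beyond, with all constants pluggable so alternative
parameterizations can be swapped in. The two pieces do not meet exactly:
$t(80) = 24.72$ against the 24.8 plateau, a $+0.078$-point step, so exact
monotonicity cannot hold at the junction; the tests therefore assert
monotone non-increase everywhere up to a half-point junction band, which
also guards against transcription errors in the constants. Classification
is strict ("over the curve" means identity strictly greater than the
threshold). Best-hit selection filters to above-curve hits and picks the
longest alignment, ties broken by higher identity (the inverse,
identity-primary rule is available behind a flag); with no survivor the hit
with the largest identity margin over its threshold is reported as
below-curve. Dataset summaries count no-hit queries as below the curve.
Hits are exchanged in a normalized TSV dialect (query, target, probability,
identity, alignment length, query coordinates) so the parser is not coupled
to any particular profile-search tool version; running such tools, and the
internals of disorder or secondary-structure predictors, are out of scope —
their per-residue outputs are parsed and aggregated (ordered content as the
percentage of residues under a 0.5 disorder score, IUPred convention,
configurable; secondary-structure content over residues with integer
confidence at least 5, derived from state probabilities as
$\min(9, \lfloor 10 \cdot \max p \rfloor)$).

**Similarity networks.** Nodes are sequences; an edge joins two sequences
when some alignment between them spans at least 20 residues with at least
70% search probability (both thresholds configurable, both directions of an
all-against-all table collapsing to one undirected edge). A query whose
qualifying alignments occupy non-overlapping query regions represents
multiple domains and is duplicated into one suffixed node per region;
"non-overlapping" is operationalized as interval overlap at most 10% of the
shorter alignment (configurable), generalized to any number of regions via
single-linkage clustering of intervals. Duplication is query-side only — a
sequence appearing solely as a target keeps its plain node — which is a
documented asymmetry of hit-table-driven construction. Components are
reported largest-first with lexicographic tie-breaks and are checked
against a hand-written breadth-first-search closure, with igraph standing
behind the graph container.

## The synthetic corpus generator

`markov_grammar()` defines first-order Markov sources with a declared
alphabet, row-stochastic transition matrix, initial distribution, and a
truncated-normal length distribution — the repertoire needed to test
tokenizer, LM, decoding and calibration end-to-end with known ground truth.
The generator emulates: residue-composition structure (stationary
distributions), local dependence (transition rows), and realistic length
profiles. It deliberately does not emulate long-range dependencies,
domain architecture, or any biophysical constraint of real proteins, so
passing grammar-recovery tests demonstrates that the training and
evaluation machinery is correct, not that a desk-scale model learns protein
grammar.

Reference sources are fixed in code so quoted numbers are stable:

* `two_state_grammar(stay = 0.9)`: alphabet {A, B}, entropy rate
  $-(0.9\ln 0.9 + 0.1\ln 0.1) = 0.3251$ nats/symbol — the closed-form
  target of the recovery check;
* `standard_test_grammar()`: a documented 3-symbol chain (rows A: 0.7, 0.2,
  0.1; B: 0.1, 0.8, 0.1; C: 0.2, 0.3, 0.5), conventionally sampled with
  seed 7.

The stationary distribution is computed by eigendecomposition refined by
power iteration to $10^{-10}$; irreducibility is checked as strong
connectivity of the positive-transition graph, and reducible chains are
rejected rather than silently analyzed.

`recovery_report()` compares a trained model against its source on a fresh
corpus, and its two statistics are deliberately *alphabet-renormalized*:
model conditionals are restricted to the grammar alphabet and renormalized
before computing (1) cross-entropy at interior transitions (current and
next token both grammar symbols) and (2) per-state total-variation distance
to the transition rows. The renormalization excludes the end-of-sequence
hazard, which the grammar does not model, and makes the statistics exact:
an untrained uniform model on a two-symbol grammar shows a loss gap of
exactly $\ln 2 - 0.3251 = 0.368$ nats and per-state TV of exactly 0.4. A
character-level tokenizer is required (conditional comparison is undefined
for multi-residue tokens).

## Dataset construction

Three dataset types mirror the generated/natural/random evaluation design:

* **generated** — decoded emissions, censored ones removed;
* **natural length-matched** — `length_matched_subsample()` draws seeded
  random n-subsets of a pool until the subset's length mean and sd are each
  within a tolerance (default 2 residues) of a reference's, with a 10,000
  iteration budget and the best attempt's moments reported on failure (the
  published comparison matched natural sequences to a generated set
  averaging 149.2 ± 50.9 residues);
* **random control** — `make_random_dataset()` concatenates symbols drawn
  uniformly from the 25-letter database alphabet (20 standard residues
  plus X, B, U, O, Z, alphabetically ordered for determinism), lengths from
  a truncated normal on [5, 267]. The truncation moments are not published;
  the default mean (5+267)/2 and sd (267−5)/6 make the untruncated range
  span six standard deviations, and both moments are configurable —
  including matching them to observed corpora — since either reading of
  "a normal distribution between 5 and 267" is defensible.

Validation splits hold out $\lfloor f N \rfloor$ records (the published
fraction is 10%); the floor rule is exact for the corpus sizes used and
documented for the rest.

## Problem sizes and tolerances used by the tests

The suite's heavier checks run at sizes chosen to finish comfortably on one
CPU while leaving wide statistical margins:

* *memorization*: a 12-residue sequence, 2-layer/width-32 model, 800 Adam
  steps at learning rate 3e-3 → loss below 0.01 nats (measured ≈ 0.0007);
* *grammar recovery*: 300 sequences (~39k tokens) from the stay-0.9 chain,
  2-layer/width-32/context-128 model, 600 steps at 1e-3 → |gap| < 0.05
  nats and per-state TV < 0.05 (measured ≈ 0.004 and ≈ 0.03 at seed 1);
* *decoding oracles*: 100 random fixtures with vocabulary ≤ 4 and budget
  ≤ 4, exhaustive beam vs complete enumeration, exact agreement required;
* *filters*: 1000 random vectors against direct-computation oracles at
  1e-12; penalty sweep 1.0 → 1.5 with 200 seeded emissions per setting;
* *BPE*: merge choices against a brute-force pair counter; 10,000 random
  sequences round-tripped exactly.

All stochastic assertions run under fixed seeds, so a passing result is a
deterministic property of the released code, and every seeded operation is
additionally asserted to be bit-reproducible across repeated calls.

## Known limitations

* Training is single-threaded R; it is meant for models up to a few
  hundred thousand parameters, not the full-scale preset.
* Bitwise reproducibility is claimed per hardware class only; different
  BLAS builds can differ in final bits.
* Query-side-only node duplication in network construction (above).
* The propensity-calibration distance is L1 on a focus set; it is a
  ranking device, not a statistical test, and radar-style visual
  comparison is left to the plotting layer.
* The HSSP curve constants are one parameterization of the twilight zone
  among several in the literature; they are arguments, not ground truth.
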