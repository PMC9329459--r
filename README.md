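# protlm

Desk-scale protein language modeling and sequence evaluation in R.

Generative protein language models treat amino-acid sequences as sentences:
a sequence $W = (w_1, \dots, w_n)$ of sub-word tokens is assigned
probability

$$p(W) = \prod_{i=1}^{n} p(w_i \mid w_{<i}),$$

where each conditional comes from a decoder-only transformer trained by
minimizing the mean negative log-likelihood per token, $-\tfrac{1}{T} \sum_i
\log p(w_i \mid w_{<i})$ (nats). New sequences are then *decoded* from the
model — greedily, by beam search, or by temperature/top-k/nucleus sampling
with a repetition penalty — and the decoding parameters are *calibrated* by
matching the amino-acid propensities of generated sets to natural
references. Generated sets are evaluated against natural and random
controls with twilight-zone (HSSP curve) classification of homology-search
hits, per-residue disorder and secondary-structure aggregation, and
sequence similarity networks whose connected components are the "islands"
of sequence space.

protlm implements this entire methodology as an R package for researchers
who want to study, teach or extend the machinery at a scale that trains in
minutes on one CPU: the tokenizer (byte-pair encoding over residues), the
transformer and its training loop (hand-written forward/backward in R
matrix code, Adam, gradient clipping), the full decoding and calibration
suite, the evaluation statistics, and first-order Markov sequence
simulators with closed-form entropy rates that give every training run an
exact target. Full-scale settings (36 layers, width 1280, vocabulary
50,256, top-k 950, repetition penalty 1.2, 250-token windows, the
2240-cell calibration grid) are preserved as named presets and defaults.

## Worked example

Train a small model on a Markov source whose entropy rate is known in
closed form, check that it recovers the source, and generate from it:

```r
library(protlm)

g <- two_state_grammar(0.9)        # alphabet {A,B}, stay-probability 0.9
entropy_rate(g)
#> [1] 0.325083

corpus <- sample_corpus(g, 300, seed = 7)
tok    <- char_tokenizer(g$alphabet)
split  <- split_dataset(corpus, 0.1, seed = 7)

cfg <- lm_config(vocab_size = length(tok$vocab), n_layers = 2, d_model = 32,
                 n_heads = 2, context_length = 128, batch_tokens = 1024,
                 seed = 7)
fit <- train_lm(language_model(cfg), split, tok, steps = 600)
glance(fit)
#> # A tibble: 1 × 4
#>   steps final_train_loss final_val_loss n_parameters
#>   <int>            <dbl>          <dbl>        <int>
#> 1   600            0.349          0.377        29572

recovery_report(fit, g, tok, n_eval = 100, seed = 999)
#> <recovery_report> cross-entropy 0.3266 vs entropy rate 0.3251 (gap +0.0016 nats/symbol, 12360 positions)
#> per-state total variation: A=0.0036, B=0.0023
```

The held-out loss (0.377 nats/token) includes end-of-sequence prediction;
restricted to symbol transitions the model's cross-entropy is 0.3266 nats,
within 0.002 of the source's optimum, and its conditional rows match the
true transition matrix to total-variation < 0.004 — the model has learned
the grammar. Generation uses the same budget-and-filter pipeline as at full
scale:

```r
gen <- generate(fit, tok, n = 5,
                config = decoding_config("sample", max_new_tokens = 250,
                                         seed = 42))
gen[, c("id", "n_tokens", "terminated", "logprob")]
#> # A tibble: 5 × 4
#>   id        n_tokens terminated logprob
#>   <chr>        <int> <lgl>        <dbl>
#> 1 gen_00001      234 TRUE         -94.1
#> 2 gen_00002      115 TRUE         -48.7
#> 3 gen_00003       36 TRUE         -12.4
#> 4 gen_00004       72 TRUE         -33.4
#> 5 gen_00005      250 FALSE        -88.4

propensity_profile(filter_truncated(gen))   # emission 5 was length-censored
#> <propensity_profile> 456 residues over 2 symbols
#>      A      B
#> 0.5658 0.4342
```

Downstream evaluation works from tables: `read_hits()` loads normalized
alignment-hit TSVs, `hssp_classify()` + `dataset_hssp_summary()` give the
fraction of queries with above-curve homologs, `build_graph()` +
`graph_components()` build the similarity network, and `grid_calibrate()`
ranks decoding-parameter cells by propensity distance (the full-scale grid
preset is `grid_spec_paper()`, 2240 cells). A thin command-line front end
over these functions is installed at `inst/cli/protlm`.

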