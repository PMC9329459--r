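test_that("repetition penalty divides positive and multiplies non-positive scores", {
  scores <- c(2.0, -1.0, 0.5, 3.0)
  out <- apply_repetition_penalty(scores, context_ids = c(0L, 1L), penalty = 1.2)
  expect_equal(out[1L], 2.0 / 1.2, tolerance = 1e-12) # 1.6667
  expect_equal(out[2L], -1.2, tolerance = 1e-12)
  expect_equal(out[3:4], scores[3:4]) # untouched: not in context

  expect_equal(apply_repetition_penalty(scores, c(0L, 2L), 1.0), scores)
  expect_error(apply_repetition_penalty(scores, 0L, 0.9), "penalty")
})

test_that("top-k filter matches the direct softmax/renormalization oracle", {
  probs <- softmax_vec(c(2, 1, 0, -1))
  out <- top_k_filter(probs, 2L)
  kept_mass <- sum(sort(probs, decreasing = TRUE)[1:2])
  expect_equal(out, c(probs[1:2] / kept_mass, 0, 0), tolerance = 1e-12)
  expect_equal(round(out[1:2], 3), c(0.731, 0.269))

  expect_equal(top_k_filter(probs, 4L), probs)
  expect_equal(top_k_filter(probs, 1L), c(1, 0, 0, 0))
  expect_error(top_k_filter(probs, 0L), "k must be")
  expect_error(top_k_filter(probs, 5L), "k must be")
})

test_that("top-p filter keeps the minimal nucleus and renormalizes", {
  probs <- c(0.6, 0.3, 0.1)
  expect_equal(top_p_filter(probs, 1.0), probs)
  expect_equal(top_p_filter(probs, 0.6), c(1, 0, 0))
  expect_equal(top_p_filter(probs, 0.7), c(0.6, 0.3, 0) / 0.9, tolerance = 1e-12)
  expect_error(top_p_filter(probs, 0), "p must be")
  expect_error(top_p_filter(probs, 1.5), "p must be")
})

test_that("filters match an independent oracle on random probability vectors", {
  oracle_topk <- function(p, k) {
    keep <- order(-p, seq_along(p))[seq_len(k)]
    q <- numeric(length(p)); q[keep] <- p[keep]; q / sum(q)
  }
  oracle_topp <- function(p, mass) {
    ord <- order(-p, seq_along(p))
    keep <- ord[seq_len(which(cumsum(p[ord]) >= mass - 1e-12)[1L])]
    q <- numeric(length(p)); q[keep] <- p[keep]; q / sum(q)
  }
  withr::with_seed(99, {
    for (i in 1:300) {
      V <- sample(2:12, 1)
      p <- softmax_vec(stats::rnorm(V, sd = 2))
      k <- sample(V, 1)
      expect_equal(top_k_filter(p, k), oracle_topk(p, k), tolerance = 1e-12)
      mass <- stats::runif(1, 0.05, 1)
      expect_equal(top_p_filter(p, mass), oracle_topp(p, mass), tolerance = 1e-12)
    }
  })
})

test_that("filters keep at least one token and preserve normalization", {
  withr::with_seed(7, {
    for (i in 1:50) {
      p <- softmax_vec(stats::rnorm(6, sd = 3))
      for (q in list(top_k_filter(p, 1L), top_p_filter(p, 0.001),
                     top_p_filter(top_k_filter(p, 3L), 0.4))) {
        expect_true(all(q >= 0))
        expect_gte(sum(q > 0), 1L)
        expect_equal(sum(q), 1, tolerance = 1e-12)
      }
    }
  })
})

test_that("greedy decoding walks a fixed conditional table deterministically", {
  # table provider over ids 0(eos),1,2: from start emit 2, after 2 emit 1,
  # after 1 emit eos
  tbl_provider <- function(context) {
    last <- context[length(context)]
    switch(as.character(last),
           "0" = c(0.1, 0.2, 0.7),
           "2" = c(0.2, 0.5, 0.3),
           "1" = c(0.8, 0.1, 0.1))
  }
  res <- greedy_decode(tbl_provider, prompt = 0L,
                       decoding_config("greedy", max_new_tokens = 10L))
  expect_equal(res$ids[[1L]], c(2L, 1L))
  expect_true(res$terminated)
  expect_equal(res$logprob, log(0.7) + log(0.5) + log(0.8), tolerance = 1e-12)
  expect_identical(res$ids,
                   greedy_decode(tbl_provider, 0L,
                                 decoding_config("greedy", max_new_tokens = 10L))$ids)

  eos_first <- fixed_provider(c(0.9, 0.05, 0.05))
  res2 <- greedy_decode(eos_first, 0L, decoding_config("greedy"))
  expect_length(res2$ids[[1L]], 0L)
  expect_true(res2$terminated)
})

test_that("beam width 1 equals greedy on random fixture providers", {
  for (seed in 1:10) {
    prov <- random_provider(V = 4L, seed = seed)
    cfg <- decoding_config("greedy", max_new_tokens = 4L)
    g <- greedy_decode(prov, 0L, cfg)
    b <- beam_search(prov, 0L, decoding_config("beam", beam_width = 1L,
                                               max_new_tokens = 4L))
    expect_identical(b$ids[[1L]], g$ids[[1L]])
    expect_equal(b$logprob[1L], g$logprob, tolerance = 1e-12)
  }
})

test_that("exhaustive beam search equals brute-force enumeration", {
  for (seed in 1:20) {
    V <- withr::with_seed(seed, sample(2:4, 1))
    L <- withr::with_seed(seed + 100, sample(2:4, 1))
    prov <- random_provider(V, seed = seed * 7L)
    oracle <- enumerate_emissions(prov, 0L, V, L)
    width <- length(oracle$logprob) # >= number of reachable sequences
    res <- beam_search(prov, 0L,
                       decoding_config("beam", beam_width = width,
                                       max_new_tokens = L))
    expect_equal(res$logprob[1L], oracle$logprob[1L], tolerance = 1e-9)
    expect_identical(res$ids[[1L]], oracle$ids[[1L]])
  }
})

test_that("beam search beats greedy on a garden-path distribution", {
  # token 2 looks best now but forces a poor continuation; token 1 leads to a
  # near-certain high-probability finish
  garden <- function(context) {
    last <- context[length(context)]
    if (last == 0L) c(0.02, 0.44, 0.54)      # greedy takes 2
    else if (last == 2L) c(1 / 3, 1 / 3, 1 / 3)
    else c(0.95, 0.04, 0.01)                 # after 1: eos almost surely
  }
  cfg_len <- 2L
  g <- greedy_decode(garden, 0L, decoding_config("greedy", max_new_tokens = cfg_len))
  b <- beam_search(garden, 0L, decoding_config("beam", beam_width = 3L,
                                               max_new_tokens = cfg_len))
  expect_gt(b$logprob[1L], g$logprob)
  oracle <- enumerate_emissions(garden, 0L, 3L, cfg_len)
  expect_equal(b$logprob[1L], oracle$logprob[1L], tolerance = 1e-12)
})

test_that("sampling is seed-reproducible and degenerates correctly", {
  prov <- repeat_provider(4L, stay = 0.6, eos_prob = 0.05)
  cfg <- decoding_config("sample", max_new_tokens = 30L, seed = 42L)
  r1 <- sample_decode(prov, 0L, cfg)
  r2 <- sample_decode(prov, 0L, cfg)
  expect_identical(r1, r2)

  # top_k = 1 is deterministic whatever the seed
  k1a <- sample_decode(prov, 0L, decoding_config("sample", top_k = 1L,
                                                 max_new_tokens = 10L, seed = 1L))
  k1b <- sample_decode(prov, 0L, decoding_config("sample", top_k = 1L,
                                                 max_new_tokens = 10L, seed = 777L))
  expect_identical(k1a$ids, k1b$ids)

  # temperature -> 0 recovers greedy (prompt on a symbol so no step is tied)
  tmp <- sample_decode(prov, 2L, decoding_config("sample", temperature = 1e-4,
                                                 max_new_tokens = 10L, seed = 5L))
  grd <- greedy_decode(prov, 2L, decoding_config("greedy", max_new_tokens = 10L))
  expect_identical(tmp$ids, grd$ids)
})

test_that("single-step sampling frequencies match the binomial bound", {
  prov <- fixed_provider(c(0.3, 0.7)) # id 1 with prob 0.7; id 0 is eos
  n <- 5000L
  draws <- vapply(seq_len(n), function(i) {
    r <- sample_decode(prov, 1L, decoding_config("sample", max_new_tokens = 1L,
                                                 seed = 1000L + i))
    r$terminated[1L]
  }, logical(1))
  p_hat <- mean(draws) # frequency of eos (prob 0.3)
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("repeat_rate counts distinct n-grams", {
  expect_equal(repeat_rate("ABABABAB", 2), 5 / 7, tolerance = 1e-12)
  expect_equal(repeat_rate("ABCDEFG", 2), 0)
  L <- 12L
  expect_equal(repeat_rate(strrep("A", L), 1), 1 - 1 / L, tolerance = 1e-12)
  expect_error(repeat_rate("AB", 3), "shorter")
})

test_that("raising the repetition penalty lowers mean bigram repetition", {
  # alphabet larger than the emission budget, as with real sub-word
  # vocabularies: unseen symbols always remain for the penalty to favour
  tok <- char_tokenizer(c(LETTERS, letters)[1:40])
  prov <- repeat_provider(40L, stay = 0.6, eos_prob = 0)
  mean_rr <- function(penalty) {
    mean(vapply(1:200, function(i) {
      r <- sample_decode(prov, 0L,
                         decoding_config("sample", repetition_penalty = penalty,
                                         max_new_tokens = 25L, seed = 5000L + i),
                         tokenizer = tok)
      repeat_rate(r$sequence, 2L)
    }, numeric(1)))
  }
  rr <- vapply(c(1.0, 1.25, 1.5), mean_rr, numeric(1))
  expect_true(all(diff(rr) <= 0))
})

test_that("generate emits decoded records ready for truncation filtering", {
  tok <- char_tokenizer(c("A", "B"))
  prov <- markov_provider(two_state_grammar(0.9), tok, eos_prob = 0.1)
  out <- generate(prov, tok, n = 8L,
                  config = decoding_config("sample", max_new_tokens = 15L, seed = 3L))
  expect_equal(nrow(out), 8L)
  expect_true(all(c("id", "sequence", "terminated", "logprob") %in% names(out)))
  expect_true(all(grepl("^[AB]*$", out$sequence)))
  kept <- filter_truncated(out)
  expect_true(all(kept$id %in% out$id[out$terminated]))
  # reproducible end to end
  out2 <- generate(prov, tok, n = 8L,
                   config = decoding_config("sample", max_new_tokens = 15L, seed = 3L))
  expect_identical(out, out2)
})
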