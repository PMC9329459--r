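#' Configure a decoding strategy
#'
#' Parameters for sequence emission from a next-token provider. For
#' stochastic sampling the transforms are applied in a fixed order at every
#' step: repetition penalty (on log-scores) -> temperature -> top-k ->
#' top-p -> renormalize -> sample. The default generation budget of 250 new
#' tokens is the decoding window used when building generated datasets;
#' emissions that exhaust it without reaching end-of-sequence are flagged
#' `terminated = FALSE` and later filtered out as length-censored.
#'
#' @param strategy `"sample"`, `"greedy"` or `"beam"`.
#' @param beam_width Beams kept per step (beam strategy; >= 1).
#' @param top_k Keep only the `k` most probable tokens (`NULL` disables).
#'   The published optimum for full-scale protein generation is k = 950.
#' @param top_p Nucleus mass in (0, 1]; 1 disables.
#' @param temperature Positive softmax temperature; values below 1 sharpen.
#' @param repetition_penalty Scalar >= 1; 1 disables. 1.2 is the published
#'   operating point.
#' @param max_new_tokens Emission budget (>= 1).
#' @param seed Integer seed (required for sampling).
#' @return A `decoding_config` object.
#' @export
decoding_config <- function(strategy = c("sample", "greedy", "beam"),
                            beam_width = 1L, top_k = NULL, top_p = 1,
                            temperature = 1, repetition_penalty = 1,
                            max_new_tokens = 250L, seed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(top_k) && top_k < 1L) abort_param("top_k must be >= 1 (or NULL)")
  if (top_p <= 0 || top_p > 1) abort_param("top_p must be in (0, 1]")
  if (temperature <= 0) abort_param("temperature must be positive")
  if (repetition_penalty < 1) abort_param("repetition_penalty must be >= 1")
  if (max_new_tokens < 1L) abort_param("max_new_tokens must be >= 1")
  if (beam_width < 1L) abort_param("beam_width must be >= 1")
  structure(list(strategy = strategy, beam_width = as.integer(beam_width),
                 top_k = if (is.null(top_k)) NULL else as.integer(top_k),
                 top_p = top_p, temperature = temperature,
                 repetition_penalty = repetition_penalty,
                 max_new_tokens = as.integer(max_new_tokens),
                 seed = if (is.null(seed)) NULL else check_seed(seed)),
            class = "decoding_config")
}

#' Apply a repetition penalty to a score vector
#'
#' For every token already present in the context, a positive score is
#' divided by `penalty` and a non-positive score multiplied by it (the
#' standard conditional-generation rule); other scores are unchanged. On
#' log-probabilities (all non-positive) this uniformly down-weights
#' context tokens.
#'
#' @param scores Numeric score (logit) vector over the vocabulary.
#' @param context_ids 0-based token ids already emitted or prompted.
#' @param penalty Scalar >= 1.
#' @return The transformed score vector.
#' @export
#' @examples
#' apply_repetition_penalty(c(2, -1, 0.5), context_ids = c(0, 1), penalty = 1.2)
apply_repetition_penalty <- function(scores, context_ids, penalty) {
  if (penalty < 1) abort_param("penalty must be >= 1")
  idx <- unique(as.integer(context_ids)) + 1L
  idx <- idx[idx >= 1L & idx <= length(scores)]
  v <- scores[idx]
  pos <- v > 0
  v[pos] <- v[pos] / penalty
  v[!pos] <- v[!pos] * penalty
  scores[idx] <- v
  scores
}

#' Keep the k most probable tokens
#'
#' Zeroes all but the `k` highest entries and renormalizes the survivors to
#' sum to one. Ties at the k-th probability are broken in favour of the
#' lower token id.
#'
#' @param probs Probability vector.
#' @param k Integer in `[1, length(probs)]`.
#' @return Filtered, renormalized probability vector.
#' @export
top_k_filter <- function(probs, k) {
  v <- length(probs)
  if (k < 1L || k > v) abort_param("k must be in [1, %d]", v)
  keep <- order(-probs, seq_along(probs))[seq_len(k)]
  out <- numeric(v)
  out[keep] <- probs[keep]
  out / sum(out)
}

#' Keep the smallest nucleus of cumulative mass p
#'
#' Retains the shortest prefix of probability-sorted tokens whose cumulative
#' mass reaches `p` and renormalizes; at least one token always survives.
#'
#' @param probs Probability vector.
#' @param p Cumulative mass in (0, 1].
#' @return Filtered, renormalized probability vector.
#' @export
top_p_filter <- function(probs, p) {
  if (p <= 0 || p > 1) abort_param("p must be in (0, 1]")
  ord <- order(-probs, seq_along(probs))
  cum <- cumsum(probs[ord])
  n_keep <- which(cum >= p - 1e-12)[1L]
  if (is.na(n_keep)) n_keep <- length(probs)
  keep <- ord[seq_len(max(1L, n_keep))]
  out <- numeric(length(probs))
  out[keep] <- probs[keep]
  out / sum(out)
}

#' Wrap a language model as a next-token provider
#'
#' A provider is any function mapping a 0-based id context to a probability
#' vector over the vocabulary; decoders are written against this interface
#' so fixture providers (lookup tables, exact grammar conditionals) plug in
#' wherever a model does. Contexts at or beyond the model's context length
#' are truncated to the most recent tokens (a sliding window).
#'
#' @param model A `language_model` or `protlm_fit`.
#' @return A function `function(context_ids) -> probability vector`.
#' @export
next_token_provider <- function(model) {
  model <- as_language_model(model)
  ctx <- model$config$context_length
  function(context_ids) {
    ids <- as.integer(context_ids)
    if (length(ids) >= ctx) ids <- ids[(length(ids) - ctx + 2L):length(ids)]
    next_token_distribution(model, ids)
  }
}

# one decoding step: raw provider probs -> transformed distribution
step_distribution <- function(provider, context, config) {
  raw <- provider(context)
  lg <- log(pmax(raw, 1e-300))
  if (config$repetition_penalty > 1) {
    lg <- apply_repetition_penalty(lg, context, config$repetition_penalty)
  }
  pr <- softmax(lg / config$temperature)
  if (!is.null(config$top_k)) pr <- top_k_filter(pr, min(config$top_k, length(pr)))
  if (config$top_p < 1) pr <- top_p_filter(pr, config$top_p)
  list(raw = raw, probs = pr / sum(pr))
}

generation_result <- function(ids, terminated, logprob, tokenizer = NULL) {
  ids <- as.integer(ids)
  seq_str <- if (is.null(tokenizer)) NA_character_ else bpe_decode(tokenizer, ids)
  n <- length(ids)
  tibble::tibble(ids = list(ids),
                 sequence = seq_str,
                 n_tokens = n,
                 terminated = terminated,
                 logprob = logprob)
}

#' Greedy decoding
#'
#' Emits the argmax token of the transformed distribution at every step,
#' stopping at the end-of-sequence token or the budget. Deterministic;
#' identical to beam search with `beam_width = 1`.
#'
#' @param provider A next-token provider (see [next_token_provider()]).
#' @param prompt Integer vector of 0-based prompt ids (typically the
#'   end-of-sequence id as a start token).
#' @param config A [decoding_config()].
#' @param eos Id of the end-of-sequence token (default 0).
#' @param tokenizer Optional `bpe_tokenizer` used to decode the emission.
#' @return One-row generation tibble: `ids` (list column, prompt excluded,
#'   terminating EOS excluded), `sequence`, `n_tokens`, `terminated`,
#'   `logprob` (total log-probability of the emitted tokens, including the
#'   terminating EOS, under the unmodified provider).
#' @export
greedy_decode <- function(provider, prompt, config = decoding_config("greedy"),
                          eos = 0L, tokenizer = NULL) {
  context <- as.integer(prompt)
  emitted <- integer(0)
  logprob <- 0
  terminated <- FALSE
  for (step in seq_len(config$max_new_tokens)) {
    sd_ <- step_distribution(provider, context, config)
    tok <- which.max(sd_$probs) - 1L
    logprob <- logprob + log(sd_$raw[tok + 1L])
    if (tok == eos) {
      terminated <- TRUE
      break
    }
    emitted <- c(emitted, tok)
    context <- c(context, tok)
  }
  generation_result(emitted, terminated, logprob, tokenizer)
}

#' Beam search decoding
#'
#' Maintains the `beam_width` highest-scoring partial emissions, scoring by
#' the sum of log-probabilities of the transformed distribution (no length
#' normalization unless `length_normalize = TRUE`). Beams that emit the
#' end-of-sequence token are retired and compete with active beams by total
#' log-probability. With a beam width at least the number of reachable
#' sequences the top result is the global argmax.
#'
#' @inheritParams greedy_decode
#' @param length_normalize Divide scores by emission length when ranking.
#' @return Generation tibble with one row per surviving beam, ranked by
#'   descending log-probability.
#' @export
beam_search <- function(provider, prompt, config = decoding_config("beam", beam_width = 4L),
                        eos = 0L, tokenizer = NULL, length_normalize = FALSE) {
  prompt <- as.integer(prompt)
  beams <- list(list(ids = integer(0), score = 0, logprob = 0, done = FALSE))
  for (step in seq_len(config$max_new_tokens)) {
    if (all(vapply(beams, `[[`, logical(1L), "done"))) break
    cand <- list()
    for (b in beams) {
      if (b$done) {
        cand[[length(cand) + 1L]] <- b
        next
      }
      sd_ <- step_distribution(provider, c(prompt, b$ids), config)
      for (tok in which(sd_$probs > 0) - 1L) {
        cand[[length(cand) + 1L]] <- list(
          ids = if (tok == eos) b$ids else c(b$ids, tok),
          score = b$score + log(sd_$probs[tok + 1L]),
          logprob = b$logprob + log(sd_$raw[tok + 1L]),
          done = tok == eos)
      }
    }
    rank_score <- vapply(cand, function(b) {
      if (length_normalize) b$score / max(1L, length(b$ids) + b$done) else b$score
    }, numeric(1L))
    tie_key <- vapply(cand, function(b) {
      paste(formatC(c(b$ids, if (b$done) -1L else integer(0)), width = 6, flag = "0"),
            collapse = " ")
    }, character(1L))
    beams <- cand[order(-rank_score, tie_key)][seq_len(min(config$beam_width, length(cand)))]
  }
  rank_score <- vapply(beams, `[[`, numeric(1L), "score")
  beams <- beams[order(-rank_score)]
  dplyr::bind_rows(lapply(beams, function(b) {
    generation_result(b$ids, b$done, b$logprob, tokenizer)
  }))
}

#' Stochastic sampling decoding
#'
#' Draws each token from the transformed distribution (penalty ->
#' temperature -> top-k -> top-p -> renormalize). Bit-reproducible under the
#' config seed.
#'
#' @inheritParams greedy_decode
#' @return One-row generation tibble (see [greedy_decode()]).
#' @export
sample_decode <- function(provider, prompt, config, eos = 0L, tokenizer = NULL) {
  if (is.null(config$seed)) abort_param("sampling requires a seed in the decoding config")
  context <- as.integer(prompt)
  emitted <- integer(0)
  logprob <- 0
  terminated <- FALSE
  withr::with_seed(config$seed, {
    for (step in seq_len(config$max_new_tokens)) {
      sd_ <- step_distribution(provider, context, config)
      tok <- sample.int(length(sd_$probs), 1L, prob = sd_$probs) - 1L
      logprob <- logprob + log(sd_$raw[tok + 1L])
      if (tok == eos) {
        terminated <- TRUE
        break
      }
      emitted <- c(emitted, tok)
      context <- c(context, tok)
    }
  })
  generation_result(emitted, terminated, logprob, tokenizer)
}

#' Generate sequences from a model
#'
#' High-level emission: runs the configured decoder `n` times (for sampling,
#' each emission uses a seed derived as `config$seed + i - 1`) and decodes
#' tokens to residue strings. Combine with [filter_truncated()] to drop
#' budget-censored emissions.
#'
#' @param model A `language_model`, `protlm_fit`, or provider function.
#' @param tokenizer A `bpe_tokenizer`.
#' @param n Number of sequences to emit.
#' @param config A [decoding_config()].
#' @param prompt Prompt ids; defaults to the end-of-sequence id as a start
#'   token.
#' @return Generation tibble with columns `id`, `sequence`, `n_tokens`,
#'   `terminated`, `logprob`.
#' @export
generate <- function(model, tokenizer, n = 1L,
                     config = decoding_config("sample", seed = 1L),
                     prompt = NULL) {
  provider <- if (is.function(model)) model else next_token_provider(model)
  eos <- eos_id(tokenizer)
  if (is.null(prompt)) prompt <- eos
  rows <- purrr::map(seq_len(n), function(i) {
    res <- switch(config$strategy,
      greedy = greedy_decode(provider, prompt, config, eos, tokenizer),
      beam = beam_search(provider, prompt, config, eos, tokenizer)[1L, ],
      sample = {
        cfg_i <- config
        cfg_i$seed <- config$seed + i - 1L
        sample_decode(provider, prompt, cfg_i, eos, tokenizer)
      })
    res$id <- sprintf("gen_%05d", i)
    res
  })
  dplyr::relocate(dplyr::bind_rows(rows), "id")
}

#' Proportion of repeated n-grams in a sequence
#'
#' `1 - distinct n-grams / total n-grams`: 0 for an all-distinct string and
#' approaching 1 for degenerate repetition (the failure mode of greedy
#' decoding that repetition penalties counteract).
#'
#' @param sequence A residue string with `nchar(sequence) >= n`.
#' @param n N-gram length.
#' @return Proportion in `[0, 1)`.
#' @export
#' @examples
#' repeat_rate("ABABABAB", 2) # 5/7
repeat_rate <- function(sequence, n = 2L) {
  L <- nchar(sequence)
  if (L < n) abort_contract("sequence shorter than n-gram length")
  starts <- seq_len(L - n + 1L)
  grams <- substring(sequence, starts, starts + n - 1L)
  1 - length(unique(grams)) / length(grams)
}
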