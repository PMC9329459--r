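# shared fixtures: toy next-token providers and brute-force oracles

# provider ignoring context: always the same distribution
fixed_provider <- function(probs) {
  force(probs)
  function(context) probs
}

# deterministic pseudo-random provider: the distribution is a fixed function
# of the context (polynomial hash), so repeated queries agree
random_provider <- function(V, seed) {
  force(V); force(seed)
  function(context) {
    h <- 0
    for (t in context) h <- (h * 31 + t + 1) %% 1000003
    withr::with_seed(as.integer(seed + h), softmax_vec(stats::rnorm(V)))
  }
}

softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# provider with a strong preference for repeating the last emitted symbol;
# ids: 0 = eos, 1 = unk (never emitted), offset.. = symbols
repeat_provider <- function(n_sym, stay = 0.8, eos_prob = 0.03, offset = 2L) {
  function(context) {
    V <- offset + n_sym
    p <- numeric(V)
    last <- context[length(context)]
    if (last >= offset) {
      p[(offset + 1L):V] <- (1 - eos_prob - stay) / (n_sym - 1L)
      p[last + 1L] <- stay
    } else {
      p[(offset + 1L):V] <- (1 - eos_prob) / n_sym
    }
    p[1L] <- eos_prob
    p
  }
}

# exact conditionals of a markov grammar laid out over a char_tokenizer
# vocabulary (eos = 0, unk = 1, alphabet from 2), with a constant
# end-of-sequence hazard
markov_provider <- function(grammar, tokenizer, eos_prob = 0.01) {
  alpha_ids <- unname(tokenizer$vocab[grammar$alphabet])
  function(context) {
    V <- length(tokenizer$vocab)
    p <- numeric(V)
    last <- context[length(context)]
    pos <- match(last, alpha_ids)
    row <- if (is.na(pos)) grammar$initial else grammar$transitions[pos, ]
    p[alpha_ids + 1L] <- (1 - eos_prob) * row
    p[1L] <- eos_prob
    p
  }
}

# exhaustive enumeration of every emission reachable within `budget` steps:
# sequences may terminate with EOS at any step (its probability counts
# toward the log-probability) or run the full budget unterminated.
# Returns a data.frame of all outcomes, best first.
enumerate_emissions <- function(provider, prompt, V, budget, eos = 0L) {
  out <- list()
  recurse <- function(ids, logprob) {
    probs <- provider(c(prompt, ids))
    for (tok in 0:(V - 1L)) {
      if (probs[tok + 1L] <= 0) next
      lp <- logprob + log(probs[tok + 1L])
      if (tok == eos) {
        out[[length(out) + 1L]] <<- list(ids = ids, logprob = lp, terminated = TRUE)
      } else if (length(ids) + 1L >= budget) {
        out[[length(out) + 1L]] <<- list(ids = c(ids, tok), logprob = lp,
                                         terminated = FALSE)
      } else {
        recurse(c(ids, tok), lp)
      }
    }
  }
  recurse(integer(0), 0)
  key <- vapply(out, function(o) paste(formatC(c(o$ids, if (o$terminated) -1L else integer(0)),
                                               width = 6, flag = "0"), collapse = " "),
                character(1L))
  lp <- vapply(out, `[[`, numeric(1L), "logprob")
  ord <- order(-lp, key)
  list(ids = lapply(out[ord], `[[`, "ids"),
       logprob = lp[ord],
       terminated = vapply(out[ord], `[[`, logical(1L), "terminated"))
}

# brute-force most-frequent adjacent pair over raw strings
most_frequent_pair <- function(seqs) {
  pairs <- unlist(lapply(seqs, function(s) {
    if (nchar(s) < 2L) return(character(0))
    substring(s, 1:(nchar(s) - 1L), 2:nchar(s))
  }))
  tab <- table(pairs)
  top <- names(tab)[tab == max(tab)]
  sort(top)[1L]
}

# independent connected-components oracle: BFS closure over an edge list
bfs_components <- function(nodes, edges_from, edges_to) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(edges_from)) {
    adj[[edges_from[i]]] <- c(adj[[edges_from[i]]], edges_to[i])
    adj[[edges_to[i]]] <- c(adj[[edges_to[i]]], edges_from[i])
  }
  seen <- character(0)
  comps <- list()
  for (n in nodes) {
    if (n %in% seen) next
    queue <- n
    comp <- character(0)
    while (length(queue) > 0L) {
      cur <- queue[1L]
      queue <- queue[-1L]
      if (cur %in% comp) next
      comp <- c(comp, cur)
      queue <- c(queue, setdiff(adj[[cur]], comp))
    }
    comp <- sort(comp, method = "radix")
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- comp
  }
  reps <- vapply(comps, `[`, character(1L), 1L)
  comps[order(-lengths(comps), reps, method = "radix")]
}

# tiny trained-model cache shared across test files (built once per run)
trained_two_state <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- two_state_grammar(0.9)
      corpus <- sample_corpus(g, 300, seed = 7)
      tok <- char_tokenizer(g$alphabet)
      split <- split_dataset(corpus, 0.1, seed = 7)
      cfg <- lm_config(vocab_size = length(tok$vocab), n_layers = 2L,
                       d_model = 32L, n_heads = 2L, context_length = 128L,
                       learning_rate = 1e-3, batch_tokens = 1024L, seed = 7L)
      fit <- train_lm(language_model(cfg), split, tok, steps = 600L,
                      eval_every = 300L)
      cache <<- list(grammar = g, tokenizer = tok, fit = fit, split = split)
    }
    cache
  }
})
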