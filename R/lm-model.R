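#' Configure a decoder-only causal language model
#'
#' Architecture and optimizer hyperparameters for the autoregressive
#' transformer. The desk-scale defaults (4 layers, width 128, 4 heads,
#' context 256) train in minutes on a CPU; [lm_config_full_scale()] is the
#' full-scale preset (36 layers, width 1280, block size 512) kept for
#' reference and never exercised by the test suite.
#'
#' @param vocab_size Vocabulary size (>= 2).
#' @param n_layers Number of transformer blocks.
#' @param d_model Model width; must be divisible by `n_heads`.
#' @param n_heads Attention heads.
#' @param context_length Maximum tokens per block (>= 2).
#' @param learning_rate Adam step size (default 1e-3).
#' @param adam_beta1,adam_beta2 Adam momentum coefficients.
#' @param batch_tokens Tokens per optimization step; the number of blocks per
#'   batch is `max(1, floor(batch_tokens / context_length))`.
#' @param grad_clip Global gradient-norm clip (desk-scale stability aid).
#' @param seed Integer seed for parameter initialization.
#' @return An `lm_config` object.
#' @export
lm_config <- function(vocab_size, n_layers = 4L, d_model = 128L, n_heads = 4L,
                      context_length = 256L, learning_rate = 1e-3,
                      adam_beta1 = 0.9, adam_beta2 = 0.999,
                      batch_tokens = 4096L, grad_clip = 1, seed = 1L) {
  if (vocab_size < 2L) abort_param("vocab_size must be >= 2")
  if (context_length < 2L) abort_param("context_length must be >= 2")
  if (d_model %% n_heads != 0L) abort_param("d_model must be divisible by n_heads")
  if (learning_rate < 0) abort_param("learning_rate must be non-negative")
  structure(list(vocab_size = as.integer(vocab_size),
                 n_layers = as.integer(n_layers),
                 d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads),
                 context_length = as.integer(context_length),
                 learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 batch_tokens = as.integer(batch_tokens),
                 grad_clip = grad_clip,
                 seed = check_seed(seed)),
            class = "lm_config")
}

#' Full-scale configuration preset
#'
#' The published large-model recipe: 36 layers, width 1280, 20 heads,
#' 512-token blocks, Adam with learning rate 1e-3 and about 65k tokens per
#' batch. Provided as a named preset for documentation and configuration
#' export; training at this scale is outside the package's desk budget.
#'
#' @param vocab_size Vocabulary size (default 50,256, the full BPE preset).
#' @return An `lm_config`.
#' @export
lm_config_full_scale <- function(vocab_size = 50256L) {
  lm_config(vocab_size = vocab_size, n_layers = 36L, d_model = 1280L,
            n_heads = 20L, context_length = 512L, learning_rate = 1e-3,
            batch_tokens = 65536L)
}

#' Initialize a language model
#'
#' Decoder-only transformer with learned positional embeddings, pre-norm
#' blocks (layer norm -> masked multi-head self-attention -> residual; layer
#' norm -> GELU MLP -> residual), a final layer norm and a linear output
#' head. The head is zero-initialized, so a freshly initialized model's
#' next-token distribution is exactly uniform.
#'
#' @param config An [lm_config()].
#' @return A `language_model` (config + named parameter list).
#' @export
language_model <- function(config) {
  V <- config$vocab_size; d <- config$d_model; ctx <- config$context_length
  L <- config$n_layers
  params <- withr::with_seed(config$seed, {
    p <- list(
      wte = matrix(stats::rnorm(V * d, 0, 0.02), V, d),
      wpe = matrix(stats::rnorm(ctx * d, 0, 0.02), ctx, d)
    )
    res_sd <- 0.02 / sqrt(max(2 * L, 1))
    for (i in seq_len(L)) {
      pre <- sprintf("L%d.", i)
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- rep(0, d)
      p[[paste0(pre, "wq")]] <- matrix(stats::rnorm(d * d, 0, 0.02), d, d)
      p[[paste0(pre, "wk")]] <- matrix(stats::rnorm(d * d, 0, 0.02), d, d)
      p[[paste0(pre, "wv")]] <- matrix(stats::rnorm(d * d, 0, 0.02), d, d)
      p[[paste0(pre, "wo")]] <- matrix(stats::rnorm(d * d, 0, res_sd), d, d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- rep(0, d)
      p[[paste0(pre, "w1")]] <- matrix(stats::rnorm(d * 4 * d, 0, 0.02), d, 4 * d)
      p[[paste0(pre, "b1")]] <- rep(0, 4 * d)
      p[[paste0(pre, "w2")]] <- matrix(stats::rnorm(4 * d * d, 0, res_sd), 4 * d, d)
      p[[paste0(pre, "b2")]] <- rep(0, d)
    }
    p$lnf_g <- rep(1, d)
    p$lnf_b <- rep(0, d)
    p$head_w <- matrix(0, d, V)
    p$head_b <- rep(0, V)
    p
  })
  structure(list(config = config, params = params), class = "language_model")
}

#' @export
print.language_model <- function(x, ...) {
  cat(sprintf("<language_model> %d layers, d_model %d, %d heads, context %d, vocab %d (%s parameters)\n",
              x$config$n_layers, x$config$d_model, x$config$n_heads,
              x$config$context_length, x$config$vocab_size,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1L)))
}

as_language_model <- function(model) {
  if (inherits(model, "protlm_fit")) return(model$model)
  if (inherits(model, "language_model")) return(model)
  abort_param("expected a language_model or protlm_fit")
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv_sd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv_sd
  list(y = add_bias(xhat * rep(g, each = nrow(x)), b), xhat = xhat, inv_sd = inv_sd)
}

layernorm_bwd <- function(dy, xhat, inv_sd, g) {
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv_sd
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# forward pass over one block of 0-based ids; returns logits (T x V) and,
# when cache = TRUE, the intermediates the backward pass needs
lm_forward <- function(model, ids, cache = FALSE) {
  cfg <- model$config
  p <- model$params
  T_ <- length(ids)
  if (T_ < 1L) abort_contract("empty context")
  if (T_ > cfg$context_length) {
    abort_contract("context of %d tokens exceeds context_length %d",
                   T_, cfg$context_length)
  }
  if (any(ids < 0L) || any(ids >= cfg$vocab_size)) {
    abort_contract("token ids must be in [0, vocab_size)")
  }
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  x <- p$wte[ids + 1L, , drop = FALSE] + p$wpe[seq_len(T_), , drop = FALSE]
  caches <- if (cache) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d.", l)
    a <- layernorm_fwd(x, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    q <- a$y %*% p[[paste0(pre, "wq")]]
    k <- a$y %*% p[[paste0(pre, "wk")]]
    v <- a$y %*% p[[paste0(pre, "wv")]]
    ocat <- matrix(0, T_, d)
    ps <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      s <- tcrossprod(q[, cols, drop = FALSE], k[, cols, drop = FALSE]) / sqrt(dh)
      s[upper.tri(s)] <- -Inf
      pr <- row_softmax(s)
      ocat[, cols] <- pr %*% v[, cols, drop = FALSE]
      if (cache) ps[[h]] <- pr
    }
    att <- ocat %*% p[[paste0(pre, "wo")]]
    x_mid <- x + att
    b <- layernorm_fwd(x_mid, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    h1 <- add_bias(b$y %*% p[[paste0(pre, "w1")]], p[[paste0(pre, "b1")]])
    hact <- gelu(h1)
    mlp <- add_bias(hact %*% p[[paste0(pre, "w2")]], p[[paste0(pre, "b2")]])
    x_out <- x_mid + mlp
    if (cache) {
      caches[[l]] <- list(a = a, q = q, k = k, v = v, p = ps, ocat = ocat,
                          b = b, h1 = h1, hact = hact)
    }
    x <- x_out
  }
  f <- layernorm_fwd(x, p$lnf_g, p$lnf_b)
  logits <- add_bias(f$y %*% p$head_w, p$head_b)
  if (cache) list(logits = logits, f = f, caches = caches, ids = ids) else logits
}

# backward pass; dlogits is T x V; returns named gradient list matching params
lm_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  p <- model$params
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  T_ <- nrow(dlogits)
  g <- list()
  g$head_w <- crossprod(fwd$f$y, dlogits)
  g$head_b <- colSums(dlogits)
  dfy <- tcrossprod(dlogits, p$head_w)
  lnf <- layernorm_bwd(dfy, fwd$f$xhat, fwd$f$inv_sd, p$lnf_g)
  g$lnf_g <- lnf$dg; g$lnf_b <- lnf$db
  dx <- lnf$dx
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("L%d.", l)
    cc <- fwd$caches[[l]]
    # MLP block
    dmlp <- dx
    g[[paste0(pre, "w2")]] <- crossprod(cc$hact, dmlp)
    g[[paste0(pre, "b2")]] <- colSums(dmlp)
    dhact <- tcrossprod(dmlp, p[[paste0(pre, "w2")]])
    dh1 <- dhact * gelu_grad(cc$h1)
    g[[paste0(pre, "w1")]] <- crossprod(cc$b$y, dh1)
    g[[paste0(pre, "b1")]] <- colSums(dh1)
    dby <- tcrossprod(dh1, p[[paste0(pre, "w1")]])
    ln2 <- layernorm_bwd(dby, cc$b$xhat, cc$b$inv_sd, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- ln2$dg
    g[[paste0(pre, "ln2_b")]] <- ln2$db
    dx_mid <- dx + ln2$dx
    # attention block
    datt <- dx_mid
    g[[paste0(pre, "wo")]] <- crossprod(cc$ocat, datt)
    docat <- tcrossprod(datt, p[[paste0(pre, "wo")]])
    dq <- matrix(0, T_, d); dk <- matrix(0, T_, d); dv <- matrix(0, T_, d)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      pr <- cc$p[[h]]
      doh <- docat[, cols, drop = FALSE]
      dp <- tcrossprod(doh, cc$v[, cols, drop = FALSE])
      dvh <- crossprod(pr, doh)
      ds <- pr * (dp - rowSums(dp * pr))
      dq[, cols] <- ds %*% cc$k[, cols, drop = FALSE] / sqrt(dh)
      dk[, cols] <- crossprod(ds, cc$q[, cols, drop = FALSE]) / sqrt(dh)
      dv[, cols] <- dvh
    }
    g[[paste0(pre, "wq")]] <- crossprod(cc$a$y, dq)
    g[[paste0(pre, "wk")]] <- crossprod(cc$a$y, dk)
    g[[paste0(pre, "wv")]] <- crossprod(cc$a$y, dv)
    day <- tcrossprod(dq, p[[paste0(pre, "wq")]]) +
      tcrossprod(dk, p[[paste0(pre, "wk")]]) +
      tcrossprod(dv, p[[paste0(pre, "wv")]])
    ln1 <- layernorm_bwd(day, cc$a$xhat, cc$a$inv_sd, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- ln1$dg
    g[[paste0(pre, "ln1_b")]] <- ln1$db
    dx <- dx_mid + ln1$dx
  }
  dwte <- matrix(0, cfg$vocab_size, d)
  agg <- rowsum(dx, group = fwd$ids)
  dwte[as.integer(rownames(agg)) + 1L, ] <- agg
  g$wte <- dwte
  dwpe <- matrix(0, cfg$context_length, d)
  dwpe[seq_len(T_), ] <- dx
  g$wpe <- dwpe
  g
}

#' Per-position logits for a token block
#'
#' Row `i` holds the unnormalized next-token scores given tokens `1..i`; by
#' causal masking it is unaffected by any token after position `i`.
#'
#' @param model A `language_model` or fitted object.
#' @param ids Integer vector of 0-based token ids (length at most the
#'   context length).
#' @return A `length(ids) x vocab_size` matrix.
#' @export
lm_logits <- function(model, ids) {
  lm_forward(as_language_model(model), as.integer(ids))
}

#' Next-token probability distribution
#'
#' Softmax of the final-position logits: a non-negative vector over the
#' vocabulary summing to one. A freshly initialized model (zeroed output
#' head) returns the uniform distribution.
#'
#' @param model A `language_model` or fitted object.
#' @param context Integer vector of 0-based token ids, with
#'   `1 <= length(context) < context_length`.
#' @return Numeric probability vector of length `vocab_size`.
#' @export
next_token_distribution <- function(model, context) {
  model <- as_language_model(model)
  if (length(context) < 1L) abort_contract("context must contain at least one token")
  if (length(context) >= model$config$context_length) {
    abort_contract("context of %d tokens too long for context_length %d (need room to predict)",
                   length(context), model$config$context_length)
  }
  logits <- lm_forward(model, as.integer(context))
  softmax(logits[nrow(logits), ])
}

#' Pack a corpus into fixed-size token blocks
#'
#' Sequences are encoded, joined by end-of-sequence separators into one token
#' stream, and chunked into blocks of `context_length` tokens (the packing
#' policy used for training). A trailing chunk shorter than two tokens is
#' dropped (it has no predictable position).
#'
#' @param tokenizer A `bpe_tokenizer`.
#' @param records A sequence record table or character vector.
#' @param context_length Block size in tokens.
#' @return List of integer id vectors, each of length at most
#'   `context_length`.
#' @export
blockize_corpus <- function(tokenizer, records, context_length) {
  seqs <- record_sequences(records)
  if (length(seqs) == 0L) return(list())
  eid <- eos_id(tokenizer)
  stream <- unlist(lapply(seqs, function(s) c(bpe_encode(tokenizer, s, quiet = TRUE), eid)))
  blocks <- unname(split(stream, ceiling(seq_along(stream) / context_length)))
  blocks[lengths(blocks) >= 2L]
}

#' Mean causal-LM loss over token blocks
#'
#' The training objective: the mean negative log-likelihood per predicted
#' token, `-(1/T) * sum log p(w_i | w_<i)`, in nats. A model that assigns
#' uniform probability over a vocabulary of size V scores exactly `log(V)`.
#'
#' @param model A `language_model` or fitted object.
#' @param blocks List of integer id vectors (each of length >= 2), or a
#'   single id vector.
#' @return Mean negative log-likelihood per token (nats).
#' @export
clm_loss <- function(model, blocks) {
  model <- as_language_model(model)
  if (!is.list(blocks)) blocks <- list(blocks)
  if (length(blocks) == 0L) abort_data("no blocks supplied")
  if (any(lengths(blocks) < 2L)) {
    abort_contract("every block needs length >= 2 (no predictable position otherwise)")
  }
  total <- 0
  n <- 0L
  for (b in blocks) {
    b <- as.integer(b)
    logits <- lm_forward(model, b)
    T_ <- length(b)
    pr <- row_softmax(logits[seq_len(T_ - 1L), , drop = FALSE])
    idx <- cbind(seq_len(T_ - 1L), b[-1L] + 1L)
    total <- total - sum(log(pr[idx]))
    n <- n + T_ - 1L
  }
  total / n
}

#' Perplexity over token blocks
#'
#' `exp` of the mean causal-LM loss; equals the vocabulary size for a
#' uniform model and 1 for a perfect memorizer.
#'
#' @inheritParams clm_loss
#' @return Perplexity (dimensionless, >= 1 in expectation).
#' @export
perplexity <- function(model, blocks) {
  exp(clm_loss(model, blocks))
}
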