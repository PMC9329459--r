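# loss and gradients over a batch of blocks, normalized per predicted token
lm_loss_grad <- function(model, blocks) {
  grads <- NULL
  total <- 0
  n_targets <- 0L
  for (b in blocks) {
    b <- as.integer(b)
    T_ <- length(b)
    fwd <- lm_forward(model, b, cache = TRUE)
    pr <- row_softmax(fwd$logits)
    idx <- cbind(seq_len(T_ - 1L), b[-1L] + 1L)
    total <- total - sum(log(pr[idx[, 1L] + (idx[, 2L] - 1L) * T_]))
    dlogits <- pr
    dlogits[idx] <- dlogits[idx] - 1
    dlogits[T_, ] <- 0
    g <- lm_backward(model, fwd, dlogits)
    if (is.null(grads)) {
      grads <- g
    } else {
      for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
    }
    n_targets <- n_targets + T_ - 1L
  }
  for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / n_targets
  list(loss = total / n_targets, grads = grads)
}

#' Train a language model by minimizing negative log-likelihood
#'
#' Adam optimization of the causal-LM objective over packed token blocks,
#' with global gradient-norm clipping. The training/validation corpora come
#' from a [split_dataset()] object so that held-out loss can never touch
#' training records (the split's disjointness is asserted). The returned
#' fit carries the updated model plus a per-step loss trace; the trace (and
#' the final parameters) are reproducible under a fixed seed on the same
#' hardware class.
#'
#' @param model A [language_model()] (or a previous fit, to continue).
#' @param split A `dataset_split`; `train` must be non-empty.
#' @param tokenizer A `bpe_tokenizer` compatible with the model vocabulary.
#' @param steps Number of optimization steps (>= 1).
#' @param eval_every Validation-loss cadence in steps.
#' @param max_val_blocks Cap on validation blocks scored per evaluation.
#' @param lr_schedule `"constant"` (default) or `"cosine"` decay to zero
#'   over `steps`.
#' @param seed Seed for batch order (defaults to the model config seed).
#' @param verbose Print progress every evaluation.
#' @return A `protlm_fit`: list with the trained `model`, the `trace` tibble
#'   (`step`, `train_loss`, `val_loss`) and the `config`.
#' @export
train_lm <- function(model, split, tokenizer, steps,
                     eval_every = 50L, max_val_blocks = 128L,
                     lr_schedule = c("constant", "cosine"),
                     seed = NULL, verbose = FALSE) {
  model <- as_language_model(model)
  lr_schedule <- match.arg(lr_schedule)
  if (steps < 1L) abort_param("steps must be >= 1")
  if (!inherits(split, "dataset_split")) abort_param("`split` must be a dataset_split")
  if (nrow(split$train) == 0L) abort_data("empty training set")
  if (any(split$validation$id %in% split$train$id)) {
    abort_contract("training and validation sets overlap")
  }
  cfg <- model$config
  if (length(tokenizer$vocab) != cfg$vocab_size) {
    abort_param("tokenizer vocabulary (%d) does not match model vocab_size (%d)",
                length(tokenizer$vocab), cfg$vocab_size)
  }
  seed <- check_seed(seed %||% cfg$seed)
  blocks_train <- blockize_corpus(tokenizer, split$train, cfg$context_length)
  if (length(blocks_train) == 0L) abort_data("training corpus produced no blocks")
  blocks_val <- blockize_corpus(tokenizer, split$validation, cfg$context_length)
  if (length(blocks_val) > max_val_blocks) {
    blocks_val <- blocks_val[seq_len(max_val_blocks)]
  }
  nb <- max(1L, cfg$batch_tokens %/% cfg$context_length)
  params <- model$params
  m_state <- lapply(params, function(p) p * 0)
  v_state <- m_state
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  trace <- vector("list", steps)
  withr::with_seed(seed, {
    for (step in seq_len(steps)) {
      idx <- sample.int(length(blocks_train), nb, replace = TRUE)
      lg <- lm_loss_grad(model, blocks_train[idx])
      gn <- sqrt(sum(vapply(lg$grads, function(g) sum(g * g), numeric(1L))))
      scale <- if (gn > cfg$grad_clip) cfg$grad_clip / gn else 1
      lr <- cfg$learning_rate
      if (lr_schedule == "cosine") lr <- lr * 0.5 * (1 + cos(pi * (step - 1) / steps))
      for (nm in names(params)) {
        g <- lg$grads[[nm]] * scale
        m_state[[nm]] <- b1 * m_state[[nm]] + (1 - b1) * g
        v_state[[nm]] <- b2 * v_state[[nm]] + (1 - b2) * g * g
        mhat <- m_state[[nm]] / (1 - b1^step)
        vhat <- v_state[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
      model$params <- params
      val <- NA_real_
      if (length(blocks_val) > 0L && (step %% eval_every == 0L || step == steps)) {
        val <- clm_loss(model, blocks_val)
        if (verbose) {
          message(sprintf("step %d: train %.4f, val %.4f", step, lg$loss, val))
        }
      }
      trace[[step]] <- c(step = step, train_loss = lg$loss, val_loss = val)
    }
  })
  trace <- tibble::as_tibble(do.call(rbind, trace))
  structure(list(model = model, trace = trace, config = cfg),
            class = "protlm_fit")
}

#' @export
print.protlm_fit <- function(x, ...) {
  last_val <- rev(x$trace$val_loss[!is.na(x$trace$val_loss)])[1L]
  cat(sprintf("<protlm_fit> %d steps; final train loss %.4f, val loss %s\n",
              nrow(x$trace), x$trace$train_loss[nrow(x$trace)],
              if (length(last_val) && !is.na(last_val)) sprintf("%.4f", last_val) else "n/a"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training trace of a fitted language model
#'
#' @param x A `protlm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `train_loss`, `val_loss`.
#' @method tidy protlm_fit
#' @export
tidy.protlm_fit <- function(x, ...) {
  x$trace
}

#' One-row summary of a fitted language model
#'
#' @param x A `protlm_fit`.
#' @param ... Unused.
#' @return A tibble with the step count, final losses and parameter count.
#' @method glance protlm_fit
#' @export
glance.protlm_fit <- function(x, ...) {
  vals <- x$trace$val_loss[!is.na(x$trace$val_loss)]
  tibble::tibble(steps = nrow(x$trace),
                 final_train_loss = x$trace$train_loss[nrow(x$trace)],
                 final_val_loss = if (length(vals)) vals[length(vals)] else NA_real_,
                 n_parameters = n_parameters(x$model))
}

#' Plot a training loss trace
#'
#' @param object A `protlm_fit`.
#' @param ... Unused.
#' @return A ggplot of train (and, where evaluated, validation) loss by step.
#' @method autoplot protlm_fit
#' @export
autoplot.protlm_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  df <- df[!is.na(df$loss), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "optimization step", y = "loss (nats/token)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL

#' Save a model checkpoint as plain text
#'
#' Writes the configuration and all parameter tensors to a JSON file
#' readable by [read_checkpoint()].
#'
#' @param model A `language_model` or `protlm_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(model, path) {
  model <- as_language_model(model)
  payload <- list(config = unclass(model$config),
                  params = lapply(model$params, function(p) {
                    if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                    else list(dim = NULL, data = as.numeric(p))
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [write_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return A `language_model`.
#' @export
read_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(lm_config, payload$config[c("vocab_size", "n_layers", "d_model",
                                             "n_heads", "context_length",
                                             "learning_rate", "adam_beta1",
                                             "adam_beta2", "batch_tokens",
                                             "grad_clip", "seed")])
  params <- lapply(payload$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2L) {
      matrix(p$data, p$dim[1L], p$dim[2L])
    } else {
      as.numeric(p$data)
    }
  })
  structure(list(config = cfg, params = params), class = "language_model")
}
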