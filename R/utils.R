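# internal helpers shared across modules

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# row-wise softmax of a matrix; -Inf entries map to exact zeros
row_softmax <- function(m) {
  mx <- apply(m, 1L, max)
  z <- exp(m - mx)
  z / rowSums(z)
}

add_bias <- function(m, b) {
  m + rep(b, each = nrow(m))
}

abort_param <- function(...) {
  rlang::abort(sprintf(...), class = "protlm_parameter_error")
}

abort_data <- function(...) {
  rlang::abort(sprintf(...), class = "protlm_data_error")
}

abort_format <- function(...) {
  rlang::abort(sprintf(...), class = "protlm_format_error")
}

abort_contract <- function(...) {
  rlang::abort(sprintf(...), class = "protlm_contract_error")
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_param("`seed` must be a single integer")
  }
  as.integer(seed)
}
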