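#' Amino-acid propensity profile of a sequence set
#'
#' Pooled relative residue frequencies over all sequences (frequencies sum
#' to one). Profiles are the currency of sampling-parameter calibration:
#' a generated set is judged by how closely its profile matches a natural
#' reference.
#'
#' @param records A sequence record table or character vector.
#' @return A `propensity_profile`: list with `frequencies` (named numeric,
#'   sorted by residue) and `n_residues`.
#' @export
propensity_profile <- function(records) {
  seqs <- record_sequences(records)
  if (length(seqs) == 0L || sum(nchar(seqs)) == 0L) {
    abort_data("cannot profile an empty sequence set")
  }
  counts <- table(unlist(strsplit(seqs, "", fixed = TRUE)))
  freqs <- sort_by_name(as.numeric(counts) / sum(counts), names(counts))
  structure(list(frequencies = freqs, n_residues = sum(counts)),
            class = "propensity_profile")
}

sort_by_name <- function(x, nms) {
  names(x) <- nms
  x[order(names(x), method = "radix")]
}

#' @export
print.propensity_profile <- function(x, ...) {
  cat(sprintf("<propensity_profile> %d residues over %d symbols\n",
              x$n_residues, length(x$frequencies)))
  print(round(x$frequencies, 4))
  invisible(x)
}

#' Tidy a propensity profile
#'
#' @param x A `propensity_profile`.
#' @param ... Unused.
#' @return A tibble with columns `residue` and `frequency`.
#' @method tidy propensity_profile
#' @export
tidy.propensity_profile <- function(x, ...) {
  tibble::tibble(residue = names(x$frequencies),
                 frequency = unname(x$frequencies))
}

#' The m most common residues of a reference profile
#'
#' Descending by frequency, with ties broken alphabetically. The calibration
#' distance concentrates on the seven most common residues of the natural
#' reference by default.
#'
#' @param reference A `propensity_profile`.
#' @param m Number of residues (at most the number with nonzero frequency).
#' @return Character vector of `m` residues.
#' @export
top_common_residues <- function(reference, m) {
  nz <- reference$frequencies[reference$frequencies > 0]
  if (m > length(nz)) {
    abort_param("m (%d) exceeds the %d residues with nonzero frequency",
                m, length(nz))
  }
  names(nz)[order(-nz, names(nz), method = "radix")][seq_len(m)]
}

#' L1 distance between propensity profiles on a focus set
#'
#' `sum(|f_gen(a) - f_ref(a)|)` over the residues in `focus`; residues
#' absent from a profile count as frequency zero. Symmetric and zero iff
#' the profiles agree exactly on the focus set.
#'
#' @param generated,reference `propensity_profile` objects.
#' @param focus Character vector of residues to compare on.
#' @return Non-negative scalar.
#' @export
propensity_distance <- function(generated, reference, focus) {
  fg <- generated$frequencies[focus]
  fr <- reference$frequencies[focus]
  fg[is.na(fg)] <- 0
  fr[is.na(fr)] <- 0
  sum(abs(fg - fr))
}

#' Specify a decoding-parameter calibration grid
#'
#' The Cartesian product of repetition penalties, top-k values and top-p
#' values, with a fixed number of sampled sequences per cell.
#' [grid_spec_paper()] reproduces the published search: penalty 1.1-3.0 in
#' steps of 0.1, top-k 250-1000 every 50, top-p 0.7-1.0 in windows of 0.05,
#' 100 sequences per cell — 20 x 16 x 7 = 2240 cells.
#'
#' @param repetition_penalties,top_ks,top_ps Non-empty numeric vectors.
#' @param samples_per_cell Sequences sampled per parameter set (>= 1).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(repetition_penalties, top_ks, top_ps,
                      samples_per_cell = 100L) {
  if (length(repetition_penalties) == 0L || length(top_ks) == 0L ||
      length(top_ps) == 0L) {
    abort_param("all grid axes must be non-empty")
  }
  if (samples_per_cell < 1L) abort_param("samples_per_cell must be >= 1")
  structure(list(repetition_penalties = repetition_penalties,
                 top_ks = as.integer(top_ks), top_ps = top_ps,
                 samples_per_cell = as.integer(samples_per_cell)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @export
grid_spec_paper <- function(samples_per_cell = 100L) {
  grid_spec(repetition_penalties = round(seq(1.1, 3.0, by = 0.1), 1),
            top_ks = seq(250L, 1000L, by = 50L),
            top_ps = round(seq(0.70, 1.00, by = 0.05), 2),
            samples_per_cell = samples_per_cell)
}

#' Enumerate the cells of a calibration grid
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per cell, in lexicographic
#'   (penalty, top_k, top_p) order.
#' @export
grid_cells <- function(grid) {
  tidyr::expand_grid(repetition_penalty = grid$repetition_penalties,
                     top_k = grid$top_ks,
                     top_p = grid$top_ps)
}

#' Calibrate sampling parameters by propensity matching
#'
#' For every grid cell, samples `samples_per_cell` sequences with that
#' parameter set (seeded per cell for reproducibility), drops
#' budget-censored emissions, profiles the survivors and scores the L1
#' distance to the reference profile on its `focus_m` most common residues
#' (the full-alphabet L1 is reported as a secondary column). Cells whose
#' emissions were all censored are flagged rather than dropped. Rows are
#' ranked ascending by focus distance, ties broken by
#' (penalty, top_k, top_p).
#'
#' @param model A `language_model`, `protlm_fit` or provider function.
#' @param tokenizer A `bpe_tokenizer`.
#' @param grid A [grid_spec()].
#' @param reference A `propensity_profile` of natural sequences.
#' @param seed Integer base seed; cell `i` samples with seeds derived from
#'   `seed + (i - 1) * samples_per_cell`.
#' @param focus_m Size of the focus residue set (default 7).
#' @param max_new_tokens Emission budget per sequence.
#' @param prompt Prompt ids (default: end-of-sequence start token).
#' @return A `calibration_grid` tibble: one row per cell with columns
#'   `repetition_penalty`, `top_k`, `top_p`, `n_sequences`,
#'   `distance_focus`, `distance_full`, `flagged`.
#' @export
grid_calibrate <- function(model, tokenizer, grid, reference, seed = 1L,
                           focus_m = 7L, max_new_tokens = 250L, prompt = NULL) {
  provider <- if (is.function(model)) model else next_token_provider(model)
  seed <- check_seed(seed)
  focus_m <- min(focus_m, sum(reference$frequencies > 0))
  focus <- top_common_residues(reference, focus_m)
  full <- names(reference$frequencies)
  eos <- eos_id(tokenizer)
  if (is.null(prompt)) prompt <- eos
  cells <- grid_cells(grid)
  spc <- grid$samples_per_cell
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cfg <- decoding_config("sample",
                           top_k = cells$top_k[ci],
                           top_p = cells$top_p[ci],
                           repetition_penalty = cells$repetition_penalty[ci],
                           max_new_tokens = max_new_tokens,
                           seed = 1L)
    gens <- purrr::map(seq_len(spc), function(j) {
      cfg$seed <- seed + (ci - 1L) * spc + (j - 1L)
      sample_decode(provider, prompt, cfg, eos, tokenizer)
    })
    gens <- dplyr::bind_rows(gens)
    kept <- gens[gens$terminated & nzchar(gens$sequence), , drop = FALSE]
    if (nrow(kept) == 0L) {
      out[[ci]] <- tibble::tibble(n_sequences = 0L, distance_focus = NA_real_,
                                  distance_full = NA_real_, flagged = TRUE)
    } else {
      prof <- propensity_profile(kept$sequence)
      out[[ci]] <- tibble::tibble(
        n_sequences = nrow(kept),
        distance_focus = propensity_distance(prof, reference, focus),
        distance_full = propensity_distance(prof, reference,
                                            union(full, names(prof$frequencies))),
        flagged = FALSE)
    }
  }
  res <- dplyr::bind_cols(cells, dplyr::bind_rows(out))
  res <- dplyr::arrange(res, .data$distance_focus, .data$repetition_penalty,
                        .data$top_k, .data$top_p)
  attr(res, "focus") <- focus
  class(res) <- c("calibration_grid", class(res))
  res
}

#' Plot a calibration grid
#'
#' Heat map of focus-set propensity distance over (top-k, repetition
#' penalty), faceted by top-p.
#'
#' @param object A `calibration_grid` from [grid_calibrate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot calibration_grid
#' @export
autoplot.calibration_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$top_k),
                               y = factor(.data$repetition_penalty),
                               fill = .data$distance_focus)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$top_p)) +
    ggplot2::labs(x = "top-k", y = "repetition penalty",
                  fill = "L1 distance\n(focus residues)") +
    ggplot2::theme_minimal()
}
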