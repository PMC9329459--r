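#' The 25-letter amino-acid alphabet
#'
#' The 20 standard residues plus the extended IUPAC codes X, B, U, O and Z
#' that occur in large sequence databases, in alphabetical order (the order is
#' fixed so that seeded operations over the alphabet are deterministic).
#'
#' @return Character vector of 25 single-letter codes.
#' @export
protein_alphabet <- function() {
  sort(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
         "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "B", "U", "O", "Z"))
}

#' Specify a sequence-length distribution
#'
#' Lengths are modelled as a normal distribution truncated to
#' `[min_len, max_len]` (out-of-range draws are resampled) and rounded to
#' integers. The defaults span 5-267 residues with mean `(5+267)/2` and
#' sd `(267-5)/6`, so that the untruncated range covers about six standard
#' deviations; both moments are configurable, e.g. to match an observed
#' corpus (149.2 +/- 50.9 residues is a typical generated-set value).
#'
#' @param min_len,max_len Inclusive length bounds (residues).
#' @param mean,sd Moments of the underlying normal (residues).
#' @return A `length_spec` object.
#' @export
length_spec <- function(min_len = 5L, max_len = 267L,
                        mean = (min_len + max_len) / 2,
                        sd = (max_len - min_len) / 6) {
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (min_len < 1L) abort_param("min_len must be >= 1")
  if (min_len >= max_len) abort_param("min_len must be < max_len")
  if (mean < min_len || mean > max_len) {
    abort_param("mean must lie in [min_len, max_len]")
  }
  if (sd <= 0) abort_param("sd must be positive")
  structure(list(min_len = min_len, max_len = max_len, mean = mean, sd = sd),
            class = "length_spec")
}

# truncated-normal integer lengths by resampling; assumes RNG already seeded
sample_lengths <- function(n, spec) {
  out <- integer(0)
  while (length(out) < n) {
    draw <- round(stats::rnorm(max(n - length(out), 16L), spec$mean, spec$sd))
    out <- c(out, draw[draw >= spec$min_len & draw <= spec$max_len])
  }
  as.integer(out[seq_len(n)])
}

#' Split records into training and validation sets
#'
#' Randomly holds out `floor(validation_fraction * N)` records as a
#' validation set (so 10% of 1000 records gives exactly 100); the remainder
#' train. The partition is disjoint, exhaustive and reproducible under a
#' fixed seed.
#'
#' @param records A sequence record table.
#' @param validation_fraction Proportion held out, in (0, 1).
#' @param seed Integer seed.
#' @return A `dataset_split` object: a list with tibbles `train` and
#'   `validation` plus the `seed` and `validation_fraction` used.
#' @export
split_dataset <- function(records, validation_fraction = 0.1, seed = 1L) {
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort_param("validation_fraction must be in (0, 1)")
  }
  n <- nrow(records)
  if (n < 2L) abort_param("need at least 2 records to split")
  seed <- check_seed(seed)
  n_val <- floor(validation_fraction * n)
  withr::with_seed(seed, {
    val_idx <- sort(sample.int(n, n_val))
  })
  structure(list(train = records[setdiff(seq_len(n), val_idx), , drop = FALSE],
                 validation = records[val_idx, , drop = FALSE],
                 seed = seed,
                 validation_fraction = validation_fraction),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d validation (fraction %.3f, seed %d)\n",
              nrow(x$train), nrow(x$validation), x$validation_fraction, x$seed))
  invisible(x)
}

#' Generate a random-residue control dataset
#'
#' Sequences built by concatenating symbols drawn independently and uniformly
#' from `alphabet`, with lengths from a truncated normal (see
#' [length_spec()]). This is the negative control against which generated
#' sequences are compared: it has the right length profile but no residue
#' statistics beyond the uniform marginal.
#'
#' @param n Number of sequences.
#' @param alphabet Character vector of distinct single-letter symbols
#'   (default: the 25-letter database alphabet).
#' @param spec A [length_spec()].
#' @param seed Integer seed.
#' @return A sequence record table with `source = "random"`.
#' @export
make_random_dataset <- function(n, alphabet = protein_alphabet(),
                                spec = length_spec(), seed = 1L) {
  if (n < 1L) abort_param("n must be >= 1")
  if (anyDuplicated(alphabet)) abort_param("alphabet symbols must be distinct")
  seed <- check_seed(seed)
  withr::with_seed(seed, {
    lens <- sample_lengths(n, spec)
    seqs <- vapply(lens, function(L) {
      paste(sample(alphabet, L, replace = TRUE), collapse = "")
    }, character(1L))
  })
  sequence_records(sprintf("random_%05d", seq_len(n)), seqs, "random")
}

#' Subsample records to match a reference length distribution
#'
#' Seeded rejection sampling over random `n`-subsets of `pool`: a subset is
#' accepted when its length mean and standard deviation are each within
#' `tolerance` residues of the reference's. If no subset qualifies within
#' `max_iter` attempts the best attempt's moments are reported in the error.
#'
#' @param pool Record table to subsample from (`nrow(pool) >= n`).
#' @param reference Record table whose length moments are the target.
#' @param n Subsample size.
#' @param tolerance Allowed absolute deviation of mean and sd (residues).
#' @param seed Integer seed.
#' @param max_iter Rejection-sampling budget.
#' @return `n` rows of `pool` (in pool order).
#' @export
length_matched_subsample <- function(pool, reference, n, tolerance = 2,
                                     seed = 1L, max_iter = 10000L) {
  if (nrow(pool) < n) abort_param("pool smaller than requested subsample")
  if (nrow(reference) == 0L) abort_param("reference must be non-empty")
  seed <- check_seed(seed)
  lens <- nchar(pool$sequence)
  target_mean <- mean(nchar(reference$sequence))
  target_sd <- stats::sd(nchar(reference$sequence))
  if (is.na(target_sd)) target_sd <- 0
  best <- NULL
  best_err <- Inf
  res <- withr::with_seed(seed, {
    found <- NULL
    for (i in seq_len(max_iter)) {
      idx <- sample.int(nrow(pool), n)
      m <- mean(lens[idx])
      s <- if (n > 1L) stats::sd(lens[idx]) else 0
      err <- max(abs(m - target_mean), abs(s - target_sd))
      if (err < best_err) {
        best_err <- err
        best <- c(mean = m, sd = s)
      }
      if (abs(m - target_mean) <= tolerance && abs(s - target_sd) <= tolerance) {
        found <- idx
        break
      }
    }
    found
  })
  if (is.null(res)) {
    abort_data(paste0("no length-matched subsample found in %d attempts; ",
                      "best attempt mean %.2f, sd %.2f (target %.2f +/- tol %.2f, %.2f)"),
               max_iter, best[["mean"]], best[["sd"]], target_mean, tolerance, target_sd)
  }
  pool[sort(res), , drop = FALSE]
}

#' Keep only generations that terminated naturally
#'
#' Generated sequences whose emission hit the token budget (the decoding
#' window) are length-censored and are removed before any downstream
#' statistics; only sequences that emitted an end-of-sequence token survive.
#'
#' @param generated A generation table with columns `sequence` and
#'   `terminated` (see [generate()]).
#' @return A sequence record table with `source = "generated"`.
#' @export
filter_truncated <- function(generated) {
  if (!all(c("sequence", "terminated") %in% names(generated))) {
    abort_param("`generated` must have `sequence` and `terminated` columns")
  }
  keep <- generated[generated$terminated & nzchar(generated$sequence), , drop = FALSE]
  ids <- if ("id" %in% names(keep)) keep$id else sprintf("gen_%05d", seq_len(nrow(keep)))
  sequence_records(ids, keep$sequence, "generated")
}
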