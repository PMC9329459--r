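#' Train a byte-pair-encoding tokenizer on protein sequences
#'
#' Classic BPE over residue strings: starting from single characters, the
#' most frequent adjacent symbol pair across the corpus is merged into a new
#' token, repeatedly, until the vocabulary reaches `vocab_size` or no pair
#' occurs at least twice. Each sequence is one "word" (there is no whitespace
#' pre-tokenization for proteins); ties in pair counts are broken
#' lexicographically by (left, right) so training is deterministic.
#'
#' Vocabulary ids are dense integers from 0: specials first (end-of-sequence,
#' unknown), then the base alphabet in sorted order, then merged tokens in
#' merge order. Specials are never produced by merges.
#'
#' @param corpus A sequence record table or character vector.
#' @param vocab_size Target vocabulary size (must be at least
#'   `|base alphabet| + |specials|`). The full-scale preset used for natural
#'   corpora is 50,256 tokens, which yields sub-words of about four residues;
#'   desk-scale vocabularies are much smaller.
#' @param specials Named character vector of special tokens; must contain
#'   `eos` and `unk`.
#' @return A `bpe_tokenizer`: list with `vocab` (named integer vector,
#'   token -> id), `merges` (tibble `left`, `right`, `token`, `rank`),
#'   `specials` and `alphabet`.
#' @export
#' @examples
#' tok <- bpe_train(c("ABABAB", "ABAB"), vocab_size = 5)
#' tok$merges
bpe_train <- function(corpus, vocab_size,
                      specials = c(eos = "<eos>", unk = "<unk>")) {
  seqs <- record_sequences(corpus)
  if (length(seqs) == 0L) abort_data("empty training corpus")
  if (!all(c("eos", "unk") %in% names(specials))) {
    abort_param("specials must include named 'eos' and 'unk' tokens")
  }
  alphabet <- sort(unique(unlist(strsplit(seqs, "", fixed = TRUE))))
  n_base <- length(alphabet) + length(specials)
  if (vocab_size < n_base) {
    abort_param("vocab_size (%d) below base alphabet + specials (%d)",
                vocab_size, n_base)
  }
  counts <- table(seqs)
  words <- strsplit(names(counts), "", fixed = TRUE)
  wts <- as.integer(counts)

  merges <- list()
  n_merges_wanted <- vocab_size - n_base
  while (length(merges) < n_merges_wanted) {
    pair_tab <- count_pairs(words, wts)
    if (nrow(pair_tab) == 0L || max(pair_tab$count) < 2L) break
    best <- pair_tab[pair_tab$count == max(pair_tab$count), , drop = FALSE]
    best <- best[order(best$left, best$right, method = "radix"), , drop = FALSE][1L, ]
    new_tok <- paste0(best$left, best$right)
    words <- lapply(words, merge_word, left = best$left, right = best$right,
                    new = new_tok)
    merges[[length(merges) + 1L]] <- c(best$left, best$right, new_tok)
  }
  merge_tab <- if (length(merges) > 0L) {
    m <- do.call(rbind, merges)
    tibble::tibble(left = m[, 1L], right = m[, 2L], token = m[, 3L],
                   rank = seq_len(nrow(m)))
  } else {
    tibble::tibble(left = character(), right = character(),
                   token = character(), rank = integer())
  }
  tokens <- c(unname(specials), alphabet, merge_tab$token)
  vocab <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(list(vocab = vocab, merges = merge_tab, specials = specials,
                 alphabet = alphabet),
            class = "bpe_tokenizer")
}

# weighted adjacent-pair counts across symbolized words
count_pairs <- function(words, wts) {
  lens <- lengths(words)
  keep <- lens >= 2L
  if (!any(keep)) {
    return(tibble::tibble(left = character(), right = character(), count = integer()))
  }
  lefts <- unlist(lapply(words[keep], function(w) w[-length(w)]))
  rights <- unlist(lapply(words[keep], function(w) w[-1L]))
  wrep <- rep(wts[keep], lens[keep] - 1L)
  key <- paste(lefts, rights, sep = "\x1f")
  agg <- rowsum(wrep, key)
  parts <- strsplit(rownames(agg), "\x1f", fixed = TRUE)
  tibble::tibble(left = vapply(parts, `[`, character(1L), 1L),
                 right = vapply(parts, `[`, character(1L), 2L),
                 count = as.integer(agg[, 1L]))
}

# replace adjacent (left, right) occurrences with `new`, left to right
merge_word <- function(w, left, right, new) {
  n <- length(w)
  if (n < 2L || !(left %in% w)) return(w)
  out <- character(n)
  j <- 0L
  i <- 1L
  while (i <= n) {
    if (i < n && w[i] == left && w[i + 1L] == right) {
      j <- j + 1L
      out[j] <- new
      i <- i + 2L
    } else {
      j <- j + 1L
      out[j] <- w[i]
      i <- i + 1L
    }
  }
  out[seq_len(j)]
}

#' Character-level tokenizer
#'
#' A zero-merge tokenizer whose vocabulary is the given alphabet plus
#' specials. Used wherever per-residue conditionals must align with model
#' tokens (e.g. Markov-grammar recovery checks).
#'
#' @param alphabet Character vector of single-character symbols.
#' @param specials As in [bpe_train()].
#' @return A `bpe_tokenizer` with no merges.
#' @export
char_tokenizer <- function(alphabet,
                           specials = c(eos = "<eos>", unk = "<unk>")) {
  if (any(nchar(alphabet) != 1L)) abort_param("alphabet symbols must be single characters")
  if (anyDuplicated(alphabet)) abort_param("alphabet symbols must be distinct")
  alphabet <- sort(alphabet)
  tokens <- c(unname(specials), alphabet)
  structure(list(vocab = stats::setNames(seq_along(tokens) - 1L, tokens),
                 merges = tibble::tibble(left = character(), right = character(),
                                         token = character(), rank = integer()),
                 specials = specials, alphabet = alphabet),
            class = "bpe_tokenizer")
}

#' @export
print.bpe_tokenizer <- function(x, ...) {
  cat(sprintf("<bpe_tokenizer> vocab %d (%d base + %d specials + %d merges)\n",
              length(x$vocab), length(x$alphabet), length(x$specials),
              nrow(x$merges)))
  invisible(x)
}

is_char_level <- function(tokenizer) {
  nrow(tokenizer$merges) == 0L && all(nchar(tokenizer$alphabet) == 1L)
}

eos_id <- function(tokenizer) {
  unname(tokenizer$vocab[[tokenizer$specials[["eos"]]]])
}

#' Encode a sequence into token ids
#'
#' Applies the tokenizer's merges in training order; decoding the result
#' reproduces the input exactly for in-alphabet sequences. Characters outside
#' the base alphabet map to the unknown token (a note reports how many).
#'
#' @param tokenizer A `bpe_tokenizer`.
#' @param sequence A single residue string.
#' @param quiet Suppress the unknown-character note.
#' @return Integer vector of 0-based token ids (no end-of-sequence token is
#'   appended; block packing adds separators).
#' @export
bpe_encode <- function(tokenizer, sequence, quiet = FALSE) {
  if (length(sequence) != 1L) abort_param("encode one sequence at a time")
  if (nchar(sequence) == 0L) return(integer(0))
  w <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  unknown <- !(w %in% tokenizer$alphabet)
  if (any(unknown)) {
    if (!quiet) {
      rlang::inform(sprintf("bpe_encode: %d character(s) outside the alphabet mapped to %s",
                            sum(unknown), tokenizer$specials[["unk"]]))
    }
    w[unknown] <- tokenizer$specials[["unk"]]
  }
  m <- tokenizer$merges
  for (r in seq_len(nrow(m))) {
    w <- merge_word(w, m$left[r], m$right[r], m$token[r])
  }
  ids <- unname(tokenizer$vocab[w])
  if (anyNA(ids)) abort_contract("internal error: symbol missing from vocabulary")
  ids
}

#' Decode token ids back into a residue string
#'
#' Concatenates token strings; special tokens are stripped.
#'
#' @param tokenizer A `bpe_tokenizer`.
#' @param ids Integer vector of token ids.
#' @return A residue string.
#' @export
bpe_decode <- function(tokenizer, ids) {
  if (length(ids) == 0L) return("")
  pos <- match(ids, tokenizer$vocab)
  if (anyNA(pos)) {
    abort_param("unknown token id(s): %s",
                paste(ids[is.na(pos)], collapse = ", "))
  }
  tokens <- names(tokenizer$vocab)[pos]
  paste(tokens[!(tokens %in% tokenizer$specials)], collapse = "")
}

#' Mean residues per token over a corpus
#'
#' Total residues divided by total tokens after encoding: 1.0 for a
#' character-level tokenizer, about 4 for a full-scale protein vocabulary.
#'
#' @param tokenizer A `bpe_tokenizer`.
#' @param corpus A sequence record table or character vector.
#' @return Residues per token (scalar).
#' @export
mean_token_length <- function(tokenizer, corpus) {
  seqs <- record_sequences(corpus)
  if (length(seqs) == 0L) abort_data("empty corpus")
  n_tokens <- sum(vapply(seqs, function(s) length(bpe_encode(tokenizer, s, quiet = TRUE)),
                         integer(1L)))
  sum(nchar(seqs)) / n_tokens
}

#' Serialize a tokenizer to plain-text files
#'
#' Writes `merges.txt` (one `left right` pair per line, in training order)
#' and `vocab.json` (token -> id map plus specials and alphabet) under `dir`.
#'
#' @param tokenizer A `bpe_tokenizer`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tokenizer <- function(tokenizer, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(paste(tokenizer$merges$left, tokenizer$merges$right),
             file.path(dir, "merges.txt"))
  jsonlite::write_json(list(vocab = as.list(tokenizer$vocab),
                            specials = as.list(tokenizer$specials),
                            alphabet = tokenizer$alphabet),
                       file.path(dir, "vocab.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a tokenizer serialized by [write_tokenizer()]
#'
#' @param dir Directory containing `merges.txt` and `vocab.json`.
#' @return A `bpe_tokenizer`.
#' @export
read_tokenizer <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "vocab.json"))
  vocab <- stats::setNames(as.integer(unlist(meta$vocab)), names(meta$vocab))
  lines <- readLines(file.path(dir, "merges.txt"))
  lines <- lines[nzchar(lines)]
  merge_tab <- if (length(lines) > 0L) {
    parts <- strsplit(lines, " ", fixed = TRUE)
    left <- vapply(parts, `[`, character(1L), 1L)
    right <- vapply(parts, `[`, character(1L), 2L)
    tibble::tibble(left = left, right = right, token = paste0(left, right),
                   rank = seq_along(left))
  } else {
    tibble::tibble(left = character(), right = character(),
                   token = character(), rank = integer())
  }
  structure(list(vocab = vocab,
                 specials = unlist(meta$specials),
                 alphabet = unlist(meta$alphabet),
                 merges = merge_tab)[c("vocab", "merges", "specials", "alphabet")],
            class = "bpe_tokenizer")
}
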