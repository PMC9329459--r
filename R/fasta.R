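#' Construct a table of sequence records
#'
#' The basic currency of the package: a tibble with one row per sequence and
#' columns `id`, `sequence` and `source`. `source` records which of the three
#' evaluation datasets a sequence belongs to: `"natural"` (database-derived),
#' `"generated"` (sampled from a language model) or `"random"` (residues drawn
#' independently from an alphabet).
#'
#' @param id Character vector of sequence identifiers.
#' @param sequence Character vector of residue strings (non-empty).
#' @param source One of `"natural"`, `"generated"`, `"random"`; recycled.
#' @return A tibble with columns `id`, `sequence`, `source`.
#' @export
#' @examples
#' sequence_records(c("a", "b"), c("MKV", "GG"))
sequence_records <- function(id, sequence, source = "natural") {
  source <- rep_len(as.character(source), length(id))
  bad_src <- setdiff(unique(source), c("natural", "generated", "random"))
  if (length(bad_src) > 0L) {
    abort_param("unknown source label(s): %s", paste(bad_src, collapse = ", "))
  }
  if (length(sequence) > 0L && any(!nzchar(sequence))) {
    abort_data("sequence records must have non-empty sequences (record %s)",
               paste(id[!nzchar(sequence)], collapse = ", "))
  }
  tibble::tibble(id = as.character(id), sequence = as.character(sequence),
                 source = source)
}

# accept either a record tibble or a bare character vector of sequences
record_sequences <- function(records) {
  if (is.data.frame(records)) {
    if (!"sequence" %in% names(records)) {
      abort_param("record table must have a `sequence` column")
    }
    records$sequence
  } else {
    as.character(records)
  }
}

#' Read a FASTA file into a sequence record table
#'
#' Multi-line bodies are joined and internal whitespace stripped; record order
#' is preserved. Malformed input errors rather than being silently skipped: a
#' non-header line before the first `>` reports its line number, and a header
#' with an empty body reports the offending record.
#'
#' @param path Path to a FASTA file.
#' @param source Source label attached to every record (see
#'   [sequence_records()]).
#' @return A tibble of sequence records; zero rows for an empty file.
#' @export
read_fasta <- function(path, source = "natural") {
  if (!file.exists(path)) abort_data("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  nonblank <- which(nzchar(trimmed))
  if (length(nonblank) == 0L) return(sequence_records(character(), character(), source))
  is_hdr <- startsWith(trimmed, ">")
  first <- nonblank[1L]
  if (!is_hdr[first]) {
    abort_format("malformed FASTA: line %d does not start with '>'", first)
  }
  hdr_pos <- which(is_hdr)
  ids <- sub("\\s.*$", "", sub("^>\\s*", "", trimmed[hdr_pos]))
  ends <- c(hdr_pos[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr_pos), function(i) {
    if (ends[i] < hdr_pos[i] + 1L) return("")
    body <- trimmed[(hdr_pos[i] + 1L):ends[i]]
    paste(gsub("\\s", "", body), collapse = "")
  }, character(1L))
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0L) {
    abort_format("FASTA record '%s' (line %d) has an empty body",
                 ids[empty[1L]], hdr_pos[empty[1L]])
  }
  sequence_records(ids, seqs, source)
}

#' Write sequence records to a FASTA file
#'
#' Bodies are wrapped at `width` columns (60 by default, the conventional
#' FASTA line length).
#'
#' @param records A sequence record table (or character vector of sequences).
#' @param path Output file path.
#' @param width Residues per body line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (!is.data.frame(records)) {
    records <- sequence_records(paste0("seq_", seq_along(records)), records)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", records$id[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))), con)
  }
  invisible(path)
}

#' Write a dataset manifest
#'
#' Tab-separated summary of a record table: id, length, source.
#'
#' @inheritParams write_fasta
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  manifest <- tibble::tibble(id = records$id,
                             length = nchar(records$sequence),
                             source = records$source)
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
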