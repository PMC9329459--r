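#' HSSP twilight-zone identity threshold
#'
#' The length-dependent sequence-identity boundary below which similarity no
#' longer implies homology. The default parameterization is the classic
#' two-piece curve `290.15 * L^(-0.562)` for alignments of up to
#' `plateau_length = 80` residues and a constant `plateau_value = 24.8%`
#' beyond it; all four constants are arguments so alternative twilight-zone
#' parameterizations can be swapped in. The two pieces meet within 0.1
#' percentage points at the junction.
#'
#' @param aln_length Alignment length(s) in residues (>= 1); vectorized.
#' @param a,b Power-law coefficients (`a * L^(-b)`).
#' @param plateau_length Length beyond which the plateau applies.
#' @param plateau_value Plateau threshold (percent identity).
#' @return Percent-identity threshold(s).
#' @export
#' @examples
#' hssp_threshold(80) # ~24.7
#' hssp_threshold(200) # 24.8
hssp_threshold <- function(aln_length, a = 290.15, b = 0.562,
                           plateau_length = 80, plateau_value = 24.8) {
  if (any(aln_length < 1)) abort_param("alignment length must be >= 1")
  ifelse(aln_length <= plateau_length, a * aln_length^(-b), plateau_value)
}

#' Construct a table of alignment hits
#'
#' The normalized hit record used throughout: one row per alignment with the
#' query and target identifiers, percent identity, alignment length,
#' search probability (percent) and 1-based query coordinates.
#'
#' @param query_id,target_id Character identifiers.
#' @param identity Percent identity in `[0, 100]`.
#' @param aln_length Alignment length in residues (>= 1).
#' @param probability Search probability in `[0, 100]`.
#' @param qstart,qend 1-based inclusive query coordinates (`qstart <= qend`).
#' @return A tibble of alignment hits.
#' @export
alignment_hits <- function(query_id, target_id, identity, aln_length,
                           probability, qstart = 1L, qend = qstart + aln_length - 1L) {
  h <- tibble::tibble(query_id = as.character(query_id),
                      target_id = as.character(target_id),
                      identity = as.numeric(identity),
                      aln_length = as.integer(aln_length),
                      probability = as.numeric(probability),
                      qstart = as.integer(qstart), qend = as.integer(qend))
  validate_hits(h)
  h
}

validate_hits <- function(h) {
  if (nrow(h) == 0L) return(invisible(h))
  if (any(h$identity < 0 | h$identity > 100)) abort_data("identity must be in [0, 100]")
  if (any(h$probability < 0 | h$probability > 100)) abort_data("probability must be in [0, 100]")
  if (any(h$aln_length < 1L)) abort_data("aln_length must be >= 1")
  if (any(h$qstart > h$qend)) abort_data("qstart must be <= qend")
  invisible(h)
}

#' Select the best hit for one query under the HSSP rule
#'
#' Hits strictly above the curve (identity greater than the threshold at
#' their alignment length) are possible matches; among them the longest
#' alignment wins, ties broken by higher identity (then target id, for
#' determinism — the result is invariant to input order). If no hit clears
#' the curve, the hit with the largest identity margin over its threshold is
#' reported with `above_curve = FALSE`; an empty input yields a no-hit
#' verdict.
#'
#' @param hits Alignment-hit tibble for a single query (may be empty).
#' @param ... Passed to [hssp_threshold()] to re-parameterize the curve.
#' @param longest_first If `FALSE`, invert the rule to identity-primary with
#'   length tie-break.
#' @return A one-row tibble with the selected hit's columns (NA when no hit),
#'   `threshold_at_length` and `above_curve`.
#' @export
select_best_hit <- function(hits, ..., longest_first = TRUE) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(tibble::tibble(query_id = NA_character_, target_id = NA_character_,
                          identity = NA_real_, aln_length = NA_integer_,
                          probability = NA_real_,
                          threshold_at_length = NA_real_, above_curve = FALSE))
  }
  validate_hits(hits)
  thr <- hssp_threshold(hits$aln_length, ...)
  above <- hits$identity > thr
  if (any(above)) {
    cand <- hits[above, , drop = FALSE]
    cthr <- thr[above]
    ord <- if (longest_first) {
      order(-cand$aln_length, -cand$identity, cand$target_id, method = "radix")
    } else {
      order(-cand$identity, -cand$aln_length, cand$target_id, method = "radix")
    }
    best <- cand[ord[1L], , drop = FALSE]
    bthr <- cthr[ord[1L]]
    is_above <- TRUE
  } else {
    margin <- hits$identity - thr
    ord <- order(-margin, -hits$identity, hits$target_id, method = "radix")
    best <- hits[ord[1L], , drop = FALSE]
    bthr <- thr[ord[1L]]
    is_above <- FALSE
  }
  tibble::tibble(query_id = best$query_id, target_id = best$target_id,
                 identity = best$identity, aln_length = best$aln_length,
                 probability = best$probability,
                 threshold_at_length = bthr, above_curve = is_above)
}

#' HSSP verdicts for every query in a hit table
#'
#' Applies [select_best_hit()] per query. Queries listed in `query_ids` but
#' absent from the table receive no-hit verdicts (counted below the curve in
#' summaries).
#'
#' @param hits Alignment-hit tibble (any number of queries).
#' @param query_ids Optional full set of query ids searched.
#' @inheritParams select_best_hit
#' @return A tibble with one verdict row per query.
#' @export
hssp_classify <- function(hits, query_ids = NULL, ..., longest_first = TRUE) {
  verdicts <- dplyr::bind_rows(lapply(split(hits, hits$query_id), function(h) {
    v <- select_best_hit(h, ..., longest_first = longest_first)
    v
  }))
  if (!is.null(query_ids)) {
    missing <- setdiff(query_ids, hits$query_id)
    if (length(missing) > 0L) {
      none <- select_best_hit(hits[0, , drop = FALSE])
      blank <- none[rep(1L, length(missing)), , drop = FALSE]
      blank$query_id <- missing
      verdicts <- dplyr::bind_rows(verdicts, blank)
    }
    verdicts <- verdicts[order(match(verdicts$query_id, query_ids)), , drop = FALSE]
  }
  verdicts
}

#' Summarize HSSP verdicts over a dataset
#'
#' The headline statistic of dataset-level homology evaluation: the fraction
#' of queries whose best hit lies above the curve (no-hit queries count as
#' below), plus the mean and standard deviation of best-hit identities over
#' queries that have a hit (NA when none do).
#'
#' @param verdicts Verdict tibble from [hssp_classify()] (columns
#'   `above_curve`, `identity`).
#' @return A one-row tibble: `n_queries`, `fraction_above`, `identity_mean`,
#'   `identity_sd`.
#' @export
dataset_hssp_summary <- function(verdicts) {
  if (nrow(verdicts) == 0L) abort_data("no verdicts to summarize")
  with_hit <- verdicts$identity[!is.na(verdicts$identity)]
  tibble::tibble(
    n_queries = nrow(verdicts),
    fraction_above = mean(verdicts$above_curve & !is.na(verdicts$identity)),
    identity_mean = if (length(with_hit)) mean(with_hit) else NA_real_,
    identity_sd = if (length(with_hit) > 1L) stats::sd(with_hit) else NA_real_)
}

#' Read a normalized alignment-hit table
#'
#' Parses the package's tab-separated hit dialect (header
#' `query_id target_id probability identity aln_length qstart qend`), a
#' tool-version-independent normalization of profile-search output.
#' Malformed rows error with their line number; nothing is silently skipped.
#'
#' @param path Path to the TSV file.
#' @return An alignment-hit tibble.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) abort_data("hit file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  expected <- c("query_id", "target_id", "probability", "identity",
                "aln_length", "qstart", "qend")
  if (length(lines) == 0L) {
    abort_format("hit file %s is empty (expected a header line)", path)
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, expected)) {
    abort_format("hit file header must be: %s", paste(expected, collapse = ", "))
  }
  if (length(lines) == 1L) {
    return(alignment_hits(character(), character(), numeric(), integer(), numeric()))
  }
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  parse_num <- function(x, field, line_no) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      abort_format("hit file line %d: cannot parse %s value '%s'",
                   line_no[which(is.na(v))[1L]], field, x[which(is.na(v))[1L]])
    }
    v
  }
  n_fields <- lengths(rows)
  if (any(n_fields != 7L)) {
    bad <- which(n_fields != 7L)[1L]
    abort_format("hit file line %d: expected 7 tab-separated fields, found %d",
                 bad + 1L, n_fields[bad])
  }
  m <- do.call(rbind, rows)
  line_no <- seq_len(nrow(m)) + 1L
  alignment_hits(query_id = m[, 1L], target_id = m[, 2L],
                 probability = parse_num(m[, 3L], "probability", line_no),
                 identity = parse_num(m[, 4L], "identity", line_no),
                 aln_length = parse_num(m[, 5L], "aln_length", line_no),
                 qstart = parse_num(m[, 6L], "qstart", line_no),
                 qend = parse_num(m[, 7L], "qend", line_no))
}

#' Write a normalized alignment-hit table
#'
#' @param hits An alignment-hit tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- hits[, c("query_id", "target_id", "probability", "identity",
                  "aln_length", "qstart", "qend")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Percent of residues predicted ordered
#'
#' Given per-residue disorder scores in `[0, 1]` (IUPred-style, short
#' option), the ordered content is the percentage of residues scoring below
#' the disorder cutoff (0.5 by IUPred convention; configurable).
#'
#' @param scores Numeric vector of per-residue disorder scores in `[0, 1]`.
#' @param cutoff Disorder cutoff; residues with `score < cutoff` count as
#'   ordered.
#' @return Percent ordered in `[0, 100]`.
#' @export
ordered_fraction <- function(scores, cutoff = 0.5) {
  if (length(scores) == 0L) abort_data("no disorder scores supplied")
  if (any(scores < 0 | scores > 1)) abort_data("disorder scores must be in [0, 1]")
  100 * mean(scores < cutoff)
}

#' Read a per-residue disorder score file
#'
#' Whitespace-separated `position residue score` rows, `#`-prefixed comment
#' lines ignored (the long/short output dialect of IUPred-style predictors).
#'
#' @param path File path.
#' @return A tibble with columns `position`, `residue`, `score`.
#' @export
read_iupred <- function(path) {
  if (!file.exists(path)) abort_data("disorder file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble::tibble(position = integer(), residue = character(),
                          score = numeric()))
  }
  parts <- strsplit(lines, "\\s+")
  if (any(lengths(parts) < 3L)) {
    abort_format("disorder file %s: expected 'position residue score' rows", path)
  }
  tibble::tibble(position = as.integer(vapply(parts, `[`, character(1L), 1L)),
                 residue = vapply(parts, `[`, character(1L), 2L),
                 score = as.numeric(vapply(parts, `[`, character(1L), 3L)))
}

#' Read a PSIPRED-style secondary-structure file
#'
#' Parses `.ss2`-format rows (`position residue state p_coil p_helix
#' p_strand`; `#` header lines ignored) and derives an integer confidence
#' 0-9 per residue as `min(9, floor(10 * max probability))` — the integer
#' confidence dialect used by [ss_content()].
#'
#' @param path File path.
#' @return A tibble with columns `position`, `residue`, `state` (one of
#'   H/E/C) and `confidence` (0-9).
#' @export
read_ss2 <- function(path) {
  if (!file.exists(path)) abort_data("secondary-structure file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble::tibble(position = integer(), residue = character(),
                          state = character(), confidence = integer()))
  }
  parts <- strsplit(lines, "\\s+")
  if (any(lengths(parts) < 6L)) {
    abort_format("ss2 file %s: expected 'position residue state pC pH pE' rows", path)
  }
  pmat <- t(vapply(parts, function(p) as.numeric(p[4:6]), numeric(3L)))
  tibble::tibble(position = as.integer(vapply(parts, `[`, character(1L), 1L)),
                 residue = vapply(parts, `[`, character(1L), 2L),
                 state = vapply(parts, `[`, character(1L), 3L),
                 confidence = pmin(9L, as.integer(floor(10 * apply(pmat, 1L, max)))))
}

#' Secondary-structure content at a confidence floor
#'
#' Percent helix (H), sheet (E) and coil (C) computed only over residues
#' whose prediction confidence is at least `min_conf` (5 by default); the
#' three percentages sum to 100 whenever any residue qualifies. When no
#' residue qualifies the result is NA, not zero.
#'
#' @param ss2_records A tibble with columns `state` (H/E/C) and
#'   `confidence` (integer 0-9), e.g. from [read_ss2()].
#' @param min_conf Minimum confidence (inclusive).
#' @return A one-row tibble: `helix`, `sheet`, `coil` (percent),
#'   `n_confident`.
#' @export
ss_content <- function(ss2_records, min_conf = 5L) {
  if (nrow(ss2_records) == 0L) abort_data("no secondary-structure records")
  bad <- setdiff(unique(ss2_records$state), c("H", "E", "C"))
  if (length(bad) > 0L) abort_data("unknown secondary-structure state(s): %s",
                                   paste(bad, collapse = ", "))
  keep <- ss2_records$confidence >= min_conf
  if (!any(keep)) {
    return(tibble::tibble(helix = NA_real_, sheet = NA_real_, coil = NA_real_,
                          n_confident = 0L))
  }
  st <- ss2_records$state[keep]
  n <- length(st)
  tibble::tibble(helix = 100 * sum(st == "H") / n,
                 sheet = 100 * sum(st == "E") / n,
                 coil = 100 * sum(st == "C") / n,
                 n_confident = n)
}
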