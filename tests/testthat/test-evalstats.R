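test_that("hssp_threshold follows the two-piece curve", {
  expect_equal(hssp_threshold(80), 290.15 * 80^(-0.562), tolerance = 1e-9)
  expect_equal(round(hssp_threshold(80), 1), 24.7)
  expect_equal(hssp_threshold(200), 24.8)
  expect_equal(hssp_threshold(81), 24.8)
  expect_error(hssp_threshold(0), "length")
  # the two pieces meet within half a percentage point
  expect_lt(abs(hssp_threshold(80) - hssp_threshold(81)), 0.5)
})

test_that("hssp_threshold is monotone non-increasing up to the junction band", {
  L <- 1:400
  t <- hssp_threshold(L)
  expect_true(all(diff(t) <= 0.5 + 1e-12))
  expect_true(all(diff(t[L < 80]) <= 0))
  expect_true(all(diff(t[L > 80]) <= 0))
})

test_that("select_best_hit prefers the longest above-curve alignment", {
  hits <- alignment_hits(query_id = c("q", "q"),
                         target_id = c("t1", "t2"),
                         identity = c(50, 90),
                         aln_length = c(100L, 12L),
                         probability = c(95, 95))
  # both above their thresholds (24.8 at L=100; 71.9 at L=12)
  v <- select_best_hit(hits)
  expect_true(v$above_curve)
  expect_equal(v$target_id, "t1")
  expect_equal(v$aln_length, 100L)

  # length ties broken by identity
  tie <- alignment_hits(c("q", "q"), c("a", "b"), c(60, 70), c(50L, 50L), c(90, 90))
  expect_equal(select_best_hit(tie)$target_id, "b")

  # inverse rule available
  expect_equal(select_best_hit(hits, longest_first = FALSE)$target_id, "t2")
})

test_that("select_best_hit handles empty input and below-curve hits", {
  v0 <- select_best_hit(alignment_hits(character(), character(), numeric(),
                                       integer(), numeric()))
  expect_true(is.na(v0$target_id))
  expect_false(v0$above_curve)

  below <- alignment_hits("q", "t", identity = 10, aln_length = 100L,
                          probability = 50)
  v <- select_best_hit(below)
  expect_false(v$above_curve)
  expect_equal(v$target_id, "t")
  expect_equal(v$threshold_at_length, 24.8)
})

test_that("select_best_hit is invariant to input order", {
  hits <- withr::with_seed(5, {
    alignment_hits(query_id = rep("q", 12),
                   target_id = sprintf("t%02d", 1:12),
                   identity = round(stats::runif(12, 5, 95), 1),
                   aln_length = sample(10:150, 12),
                   probability = round(stats::runif(12, 20, 100), 1))
  })
  v <- select_best_hit(hits)
  for (seed in 1:5) {
    perm <- withr::with_seed(seed, sample(nrow(hits)))
    expect_identical(select_best_hit(hits[perm, ]), v)
  }
})

test_that("dataset_hssp_summary counts no-hit queries as below the curve", {
  verdicts <- tibble::tibble(
    query_id = sprintf("q%02d", 1:10),
    identity = c(rep(50, 9), NA),
    above_curve = c(rep(TRUE, 9), FALSE))
  s <- dataset_hssp_summary(verdicts)
  expect_equal(s$fraction_above, 0.9)
  expect_equal(s$identity_mean, 50)

  none <- tibble::tibble(query_id = "q", identity = NA_real_, above_curve = FALSE)
  s0 <- dataset_hssp_summary(none)
  expect_equal(s0$fraction_above, 0)
  expect_true(is.na(s0$identity_mean))
})

test_that("summary moments match a hand recount on synthetic verdicts", {
  verdicts <- withr::with_seed(13, {
    n <- 20L
    id <- round(stats::runif(n, 10, 90), 1)
    thr <- hssp_threshold(sample(15:120, n, replace = TRUE))
    tibble::tibble(query_id = sprintf("q%02d", 1:n), identity = id,
                   above_curve = id > thr)
  })
  s <- dataset_hssp_summary(verdicts)
  expect_equal(s$fraction_above, sum(verdicts$above_curve) / 20)
  expect_equal(s$identity_mean, mean(verdicts$identity))
  expect_equal(s$identity_sd, sd(verdicts$identity))
})

test_that("hssp_classify produces one verdict per query including missing ones", {
  hits <- alignment_hits(query_id = c("a", "a", "b"),
                         target_id = c("t1", "t2", "t3"),
                         identity = c(80, 30, 5),
                         aln_length = c(40L, 90L, 60L),
                         probability = c(99, 99, 40))
  v <- hssp_classify(hits, query_ids = c("a", "b", "c"))
  expect_equal(v$query_id, c("a", "b", "c"))
  expect_equal(v$above_curve, c(TRUE, FALSE, FALSE))
  expect_true(is.na(v$identity[3L]))
  s <- dataset_hssp_summary(v)
  expect_equal(s$fraction_above, 1 / 3)
})

test_that("hit tables round-trip through the normalized TSV dialect", {
  hits <- alignment_hits(query_id = c("q1", "q2"), target_id = c("t1", "t2"),
                         identity = c(32.9, 55), aln_length = c(48L, 120L),
                         probability = c(97.5, 88), qstart = c(3L, 10L),
                         qend = c(50L, 129L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, f)
  back <- read_hits(f)
  expect_equal(as.data.frame(back), as.data.frame(hits))
  expect_equal(back$identity[1L], 32.9)
})

test_that("malformed hit rows error with their line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query_id\ttarget_id\tprobability\tidentity\taln_length\tqstart\tqend",
               "q1\tt1\t90\t50\t30\t1\t30",
               "q2\tt2\tnot_a_number\t50\t30\t1\t30"), f)
  expect_error(read_hits(f), "line 3")

  writeLines(c("query_id\ttarget_id\tprobability\tidentity\taln_length\tqstart\tqend",
               "q1\tt1\t90\t50"), f)
  expect_error(read_hits(f), "line 2")

  writeLines("bad\theader", f)
  expect_error(read_hits(f), "header")
})

test_that("ordered_fraction applies the disorder cutoff", {
  expect_equal(ordered_fraction(rep(0.1, 8), 0.5), 100)
  expect_equal(ordered_fraction(c(0.6, 0.6, 0.2, 0.2), 0.5), 50)
  expect_equal(ordered_fraction(c(0.2, 0.8), 0), 0)
  expect_error(ordered_fraction(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(ordered_fraction(numeric(0)), "no disorder scores")
})

test_that("read_iupred parses position/residue/score rows and feeds ordered_fraction", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# IUPred-style output", "# POS RES SCORE",
               "1\tM\t0.12", "2\tK\t0.55", "3\tV\t0.30", "4\tL\t0.70"), f)
  d <- read_iupred(f)
  expect_equal(d$position, 1:4)
  expect_equal(d$residue, c("M", "K", "V", "L"))
  expect_equal(ordered_fraction(d$score), 50)
})

test_that("ss_content counts only residues at or above the confidence floor", {
  recs <- tibble::tibble(state = c("H", "E", "C", "C"),
                         confidence = c(9L, 9L, 3L, 9L))
  s <- ss_content(recs, min_conf = 5L)
  expect_equal(unlist(s[, c("helix", "sheet", "coil")]),
               c(helix = 100 / 3, sheet = 100 / 3, coil = 100 / 3),
               tolerance = 0.01)
  expect_equal(s$n_confident, 3L)
  expect_equal(s$helix + s$sheet + s$coil, 100, tolerance = 0.01)

  all_h <- tibble::tibble(state = rep("H", 10), confidence = rep(9L, 10))
  expect_equal(ss_content(all_h)$helix, 100)

  expect_equal(ss_content(recs, min_conf = 0L)$n_confident, 4L)

  low <- tibble::tibble(state = c("H", "C"), confidence = c(2L, 3L))
  s_na <- ss_content(low, min_conf = 5L)
  expect_true(is.na(s_na$helix))
  expect_equal(s_na$n_confident, 0L)
})

test_that("read_ss2 derives integer confidences from state probabilities", {
  f <- withr::local_tempfile(fileext = ".ss2")
  writeLines(c("# PSIPRED-style VFORMAT", "",
               "1 M C 0.98 0.01 0.01",
               "2 K H 0.10 0.85 0.05",
               "3 V E 0.30 0.20 0.50"), f)
  d <- read_ss2(f)
  expect_equal(d$state, c("C", "H", "E"))
  expect_equal(d$confidence, c(9L, 8L, 5L))
  s <- ss_content(d, min_conf = 5L)
  expect_equal(s$n_confident, 3L)
})
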