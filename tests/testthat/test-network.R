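test_that("build_graph links only hits passing both thresholds", {
  hits <- alignment_hits(query_id = c("A", "B", "C"),
                         target_id = c("B", "C", "D"),
                         identity = c(50, 50, 50),
                         aln_length = c(30L, 10L, 25L),
                         probability = c(90, 90, 60))
  g <- build_graph(hits, min_aln = 20L, min_prob = 70)
  el <- igraph::as_edgelist(g$graph)
  expect_equal(nrow(el), 1L)
  expect_setequal(as.character(el[1L, ]), c("A", "B"))
  # every id in the table is a node, qualified or not
  expect_setequal(g$nodes$node, c("A", "B", "C", "D"))

  g0 <- build_graph(hits[0, ])
  expect_equal(igraph::vcount(g0$graph), 0L)
  expect_equal(igraph::ecount(g0$graph), 0L)
})

test_that("queries with non-overlapping alignment regions are duplicated", {
  hits <- alignment_hits(query_id = c("A", "A"),
                         target_id = c("B", "C"),
                         identity = c(50, 50),
                         aln_length = c(40L, 41L),
                         probability = c(90, 90),
                         qstart = c(1L, 100L), qend = c(40L, 140L))
  g <- build_graph(hits)
  expect_setequal(g$nodes$node, c("A#1", "A#2", "B", "C"))
  el <- igraph::as_edgelist(g$graph)
  edges <- apply(el, 1L, paste, collapse = "-")
  expect_setequal(edges, c("A#1-B", "A#2-C"))

  # heavily overlapping regions stay one node
  hits2 <- alignment_hits(query_id = c("A", "A"), target_id = c("B", "C"),
                          identity = c(50, 50), aln_length = c(40L, 35L),
                          probability = c(90, 90),
                          qstart = c(1L, 5L), qend = c(40L, 39L))
  g2 <- build_graph(hits2)
  expect_setequal(g2$nodes$node, c("A", "B", "C"))
})

test_that("both directions of an all-vs-all table collapse to one edge", {
  hits <- alignment_hits(query_id = c("A", "B"), target_id = c("B", "A"),
                         identity = c(50, 50), aln_length = c(30L, 30L),
                         probability = c(90, 90))
  g <- build_graph(hits)
  expect_equal(igraph::ecount(g$graph), 1L)
})

test_that("graph construction is invariant to hit order and threshold-monotone", {
  hits <- withr::with_seed(21, {
    n <- 40L
    ids <- sprintf("s%02d", 1:12)
    alignment_hits(query_id = sample(ids, n, replace = TRUE),
                   target_id = sample(ids, n, replace = TRUE),
                   identity = round(stats::runif(n, 10, 90), 1),
                   aln_length = sample(5:60, n, replace = TRUE),
                   probability = round(stats::runif(n, 30, 100), 1))
  })
  g <- build_graph(hits)
  perm <- withr::with_seed(3, sample(nrow(hits)))
  g_perm <- build_graph(hits[perm, ])
  expect_setequal(g$nodes$node, g_perm$nodes$node)
  canon <- function(gr) {
    el <- igraph::as_edgelist(gr$graph)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_equal(canon(g), canon(g_perm))

  stricter <- build_graph(hits, min_aln = 30L, min_prob = 85)
  expect_lte(igraph::ecount(stricter$graph), igraph::ecount(g$graph))
  expect_true(all(canon(stricter) %in% canon(g)))
})

test_that("components match a hand walk and sizes sum to the node count", {
  hits <- alignment_hits(query_id = "A", target_id = "B", identity = 50,
                         aln_length = 30L, probability = 90)
  extra <- alignment_hits(query_id = c("C", "D"), target_id = c("C2", "D2"),
                          identity = c(5, 5), aln_length = c(5L, 5L),
                          probability = c(10, 10)) # below thresholds: isolated
  g <- build_graph(dplyr::bind_rows(hits, extra))
  comps <- graph_components(g)
  expect_equal(comps[[1L]], c("A", "B"))
  expect_equal(lengths(comps), c(2L, 1L, 1L, 1L, 1L))
  expect_equal(sum(lengths(comps)), igraph::vcount(g$graph))
})

test_that("components agree with a BFS closure oracle on random graphs", {
  for (seed in 1:5) {
    hits <- withr::with_seed(seed, {
      n <- 60L
      ids <- sprintf("n%02d", 1:50)
      alignment_hits(query_id = sample(ids, n, replace = TRUE),
                     target_id = sample(ids, n, replace = TRUE),
                     identity = 50,
                     aln_length = sample(10:40, n, replace = TRUE),
                     probability = round(stats::runif(n, 40, 100), 1))
    })
    g <- build_graph(hits, min_aln = 20L, min_prob = 70)
    el <- igraph::as_edgelist(g$graph)
    oracle <- bfs_components(g$nodes$node, el[, 1L], el[, 2L])
    expect_equal(graph_components(g), oracle)
  }
})

test_that("bridge_report quantifies island merging by a linking sequence", {
  # two 2-node islands; a generated node links them into one 5-node component
  base <- alignment_hits(query_id = c("A", "C"), target_id = c("B", "D"),
                         identity = 50, aln_length = 30L, probability = 90)
  bridge <- alignment_hits(query_id = c("G", "G"), target_id = c("A", "C"),
                           identity = 50, aln_length = c(30L, 32L),
                           probability = 90,
                           qstart = c(1L, 10L), qend = c(30L, 41L))
  g_with <- build_graph(dplyr::bind_rows(base, bridge))
  g_without <- build_graph(base)
  rep_ <- bridge_report(g_with, g_without)
  expect_equal(rep_$largest_component, c(5L, 2L))
  expect_equal(rep_$n_components, c(1L, 2L))

  same <- bridge_report(g_without, g_without)
  expect_equal(same$n_components[1L], same$n_components[2L])

  # removing an articulation node increases the component count
  g_cut <- build_graph(base)
  expect_gt(bridge_report(g_with, g_cut)$n_components[2L],
            bridge_report(g_with, g_with)$n_components[2L] - 1L)

  expect_error(bridge_report(g_without, g_with), "absent")
})

test_that("graphs serialize to edge-list and node-attribute text files", {
  hits <- alignment_hits(query_id = c("A", "B"), target_id = c("B", "C"),
                         identity = 50, aln_length = 30L, probability = 90)
  g <- build_graph(hits, node_class = c(A = "natural", B = "generated",
                                        C = "natural"))
  ef <- withr::local_tempfile(fileext = ".tsv")
  nf <- withr::local_tempfile(fileext = ".tsv")
  write_graph_files(g, ef, nf)
  edges <- utils::read.delim(ef)
  nodes <- utils::read.delim(nf)
  expect_equal(nrow(edges), 2L)
  expect_equal(sort(nodes$node), c("A", "B", "C"))
  expect_equal(nodes$class[nodes$node == "B"], "generated")
})
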