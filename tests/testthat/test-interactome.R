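test_that("read_hippie parses well-formed rows and keeps the confidence score", {
  recs <- read_hippie(hippie_fixture())
  expect_s3_class(recs, "tbl_df")
  expect_equal(nrow(recs), 3)
  expect_equal(recs$confidence, c(0.92, 0.63, 0.73))
  # Entrez is the primary key, symbol only a fallback
  expect_equal(recs$protein_a[1], "3798")
  expect_equal(attr(recs, "n_skipped"), 0)
})

test_that("read_hippie skips unparseable and non-human rows with a count", {
  f <- hippie_fixture(extra = c(
    "BAD_HUMAN\tnotanumber\tKLC1_HUMAN\t3831\t0.9\t",   # bad id resolves via symbol
    "KIF5A_HUMAN\t3798\tKLC1_HUMAN\t3831\tnot_a_score\t",  # bad confidence
    "Kif5a_MOUSE\t16572\tKlc1_MOUSE\t16593\t0.9\tspecies:10090"  # non-human
  ))
  recs <- suppressMessages(read_hippie(f, strict = TRUE))
  # symbol fallback keeps the first extra row; the other two are skipped
  expect_equal(nrow(recs), 4)
  expect_true("BAD" %in% recs$protein_a)
  expect_equal(attr(recs, "n_skipped"), 2)
  lax <- suppressMessages(read_hippie(f, strict = FALSE))
  expect_equal(nrow(lax), 5)
})

test_that("read_hippie rejects empty streams and truncated tables", {
  f <- tempfile()
  writeLines(character(0), f)
  expect_error(read_hippie(f), "empty")
  writeLines("A_HUMAN\t1\tB_HUMAN\t2", f)
  expect_error(read_hippie(f), "confidence")
})

test_that("confidence filtering is inclusive and order-preserving", {
  recs <- tibble::tibble(protein_a = letters[1:3], protein_b = letters[4:6],
                         confidence = c(0.5, 0.63, 0.9))
  expect_equal(nrow(filter_by_confidence(recs, 0.63)), 2)
  expect_equal(filter_by_confidence(recs, 0)$confidence, recs$confidence)
  high <- tibble::tibble(protein_a = "a", protein_b = letters[2:4],
                         confidence = c(0.63, 0.70, 0.73))
  expect_equal(nrow(filter_by_confidence(high, 0.73)), 1)
  expect_error(filter_by_confidence(recs, 1.5), "threshold")
})

test_that("edge count after filtering is monotone non-increasing in threshold", {
  set.seed(7)
  recs <- tibble::tibble(protein_a = sample(letters, 200, TRUE),
                         protein_b = sample(LETTERS, 200, TRUE),
                         confidence = runif(200))
  counts <- vapply(seq(0, 1, by = 0.05),
                   function(t) nrow(filter_by_confidence(recs, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("build_interactome drops self-loops and keeps max-confidence duplicates", {
  recs <- tibble::tibble(protein_a = c("a", "b", "c"),
                         protein_b = c("b", "a", "c"),
                         confidence = c(0.7, 0.9, 0.95))
  g <- build_interactome(recs)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::edge_attr(g, "confidence"), 0.9)
  expect_error(build_interactome(tibble::tibble(protein_a = "a", protein_b = "a",
                                                confidence = 1)),
               "self-loop")
  four <- tibble::tibble(protein_a = c("a", "a", "b", "c"),
                         protein_b = c("b", "c", "c", "d"),
                         confidence = 0.8)
  expect_equal(igraph::ecount(build_interactome(four)), 4)
})

test_that("rebuilding from an edge dump reproduces identical counts and edges", {
  g <- test_graph(200, 2, seed = 5)
  dump <- interactome_edges(g)
  g2 <- build_interactome(dplyr::rename(dump, protein_a = node_a, protein_b = node_b))
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_identical(interactome_edges(g2), dump)
})

test_that("edge list writing round-trips through TSV", {
  g <- test_graph(50, 2, seed = 9)
  f <- tempfile(fileext = ".tsv")
  write_edge_list(g, f)
  g2 <- read_edge_list(f)
  expect_equal(interactome_edges(g2)$node_a, interactome_edges(g)$node_a)
  expect_equal(interactome_edges(g2)$confidence, interactome_edges(g)$confidence,
               tolerance = 1e-6)
})

test_that("shortest_distances matches hand BFS on the path fixture", {
  g <- path5()
  expect_equal(shortest_distances(g, "a", "d"), c(a = 3))
  expect_equal(shortest_distances(g, "a", c("a", "d")), c(a = 0))
  expect_equal(shortest_distances(g, "a", "a", exclude_self = TRUE), c(a = Inf))
  two <- igraph::make_graph(~ a - b, c - d)
  expect_equal(shortest_distances(two, "a", "c"), c(a = Inf))
  expect_error(shortest_distances(g, "zz", "a"), "zz")
})

test_that("shortest_distances agrees with a Floyd-Warshall oracle on small graphs", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    g <- random_small_graph(n)
    d_oracle <- fw_distances(g)
    nodes <- igraph::V(g)$name
    targets <- sample(nodes, sample(seq_len(n), 1))
    got <- shortest_distances(g, nodes, targets)
    want <- apply(d_oracle[, targets, drop = FALSE], 1, min)
    expect_equal(got, want)
  }
})

test_that("degree_histogram enumerates degrees and sums to the node count", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  h <- degree_histogram(tri)
  expect_equal(h, tibble::tibble(degree = 2L, n_nodes = 3L))
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- letters[1:5]
  hs <- degree_histogram(star)
  expect_equal(hs$n_nodes[hs$degree == 1], 4L)
  expect_equal(hs$n_nodes[hs$degree == 4], 1L)
  hp <- degree_histogram(path5())
  expect_equal(hp, tibble::tibble(degree = 1:2, n_nodes = c(2L, 3L)))
  expect_equal(sum(hp$n_nodes), 5)
})

test_that("gene lists read one identifier per line and skip comments", {
  f <- tempfile()
  writeLines(c("# disease genes", "KIF5A", "", "  MFN2  ", "#SPAST"), f)
  expect_equal(read_gene_list(f), c("KIF5A", "MFN2"))
})
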