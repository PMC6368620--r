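test_that("connectivity_pvalue matches hand-enumerable cases", {
  expect_equal(connectivity_pvalue(10, 3, 2, 0), 1.0)
  expect_equal(connectivity_pvalue(10, 3, 2, 2), 3 / 45)
  expect_error(connectivity_pvalue(10, 3, 2, 3), "k_s")
  expect_error(connectivity_pvalue(10, 3, 2, 1, omega = 1.5), "omega")
})

test_that("seed weighting strictly sharpens p-values for module-enriched candidates", {
  # weighting multiplies observed and expected module links alike, so the
  # p-value drops exactly when k_s exceeds its null expectation k * s0 / N —
  # the regime every top-ranked DIAMOnD candidate lives in
  grid <- expand.grid(N = c(50, 500, 2000), s0 = c(5, 20, 50), k = c(3, 10, 40))
  checked <- 0
  for (i in seq_len(nrow(grid))) {
    N <- grid$N[i]; s0 <- grid$s0[i]; k <- grid$k[i]
    for (ks in seq_len(min(k, s0))) {
      if (ks <= k * s0 / N) next
      checked <- checked + 1
      p1 <- connectivity_pvalue(N, s0, k, ks, omega = 1)
      p10 <- connectivity_pvalue(N, s0, k, ks, omega = 10)
      expect_lt(p10, p1)
    }
    expect_equal(connectivity_pvalue(N, s0, k, 0, omega = 10), 1.0)
  }
  expect_gt(checked, 100)
})

test_that("log-space evaluation survives degrees in the thousands", {
  lp <- connectivity_pvalue(15000, 3000, 3000, 2500, omega = 10, log_p = TRUE)
  expect_true(is.finite(lp) && lp < -100)
  expect_equal(connectivity_pvalue(15000, 3000, 3000, 2500, omega = 10), exp(lp))
  expect_error(connectivity_pvalue(15000, 200, 3000, 2500), "module size")
})

test_that("first DIAMOnD pick equals the exhaustive-enumeration argmin", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(6:10, 1)
    g <- random_small_graph(n, p = 0.5)
    if (igraph::ecount(g) < 3) next
    nodes <- igraph::V(g)$name
    seeds <- sample(nodes, 2)
    deg <- igraph::degree(g)
    cand <- setdiff(nodes, seeds)
    ks <- vapply(cand, function(v) {
      length(intersect(names(igraph::neighbors(g, v)), seeds))
    }, numeric(1))
    cand <- cand[ks > 0]
    if (length(cand) == 0) next
    ks <- ks[ks > 0]
    p_oracle <- vapply(seq_along(cand), function(i) {
      hyper_tail_enum(n, 2, deg[cand[i]], ks[i])
    }, numeric(1))
    ord <- order(p_oracle, -ks, deg[cand], cand)
    expected_first <- cand[ord[1]]
    dr <- diamond_expand(g, seeds, n_iter = 1, omega = 1)
    expect_equal(dr$steps$node[1], expected_first)
    expect_equal(dr$steps$p_value[1], p_oracle[ord[1]], tolerance = 1e-10)
  }
})

test_that("a star center as sole seed incorporates one leaf with k_s = 1", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", letters[1:4])
  dr <- diamond_expand(star, "hub", n_iter = 1, omega = 1)
  expect_equal(nrow(dr$steps), 1)
  expect_equal(dr$steps$seed_links, 1L)
  expect_true(dr$steps$node %in% letters[1:4])
})

test_that("every incorporated node touches the module and bookkeeping is exact", {
  g <- test_graph(500, 3, seed = 2)
  pm <- plant_module(g, 15, 0.9, rng_seed = 4)
  dr <- diamond_expand(g, pm, n_iter = 30, omega = 10)
  expect_true(all(dr$steps$seed_links >= 1))
  expect_true(all(dr$steps$seed_links <= dr$steps$degree))
  expect_equal(dr$steps$iteration, 1:30)
  m <- dr$module
  expect_equal(length(m$all_members), length(m$seeds_mapped) + length(m$diamond_nodes))
  expect_length(intersect(m$diamond_nodes, m$seeds_mapped), 0)
  expect_identical(dr$steps$node, m$diamond_nodes)
  # deterministic without an RNG
  dr2 <- diamond_expand(g, pm, n_iter = 30, omega = 10)
  expect_identical(dr$steps, dr2$steps)
})

test_that("expansion stops with a warning when candidates run out", {
  g <- igraph::make_graph(~ a - b - c)
  expect_warning(dr <- diamond_expand(g, "a", n_iter = 10, omega = 1), "exhausted")
  expect_equal(nrow(dr$steps), 2)
  lone <- igraph::make_graph(~ a - b, c - d)
  expect_error(diamond_expand(lone, "c", n_iter = 1), NA)
  isolated <- igraph::add_vertices(lone, 1, name = "z")
  expect_error(diamond_expand(isolated, "z", n_iter = 1), "no candidates")
})

test_that("omega changes the ranking in favor of module-connected nodes", {
  # node x: 2 links into the module out of degree 4; node y: 1 of 1
  g <- igraph::make_graph(~ s1 - x, s2 - x, x - o1, x - o2, s1 - y, s1 - s2)
  d1 <- diamond_expand(g, c("s1", "s2"), n_iter = 1, omega = 1)
  d10 <- diamond_expand(g, c("s1", "s2"), n_iter = 1, omega = 10)
  expect_equal(d1$steps$node, "y")   # low degree wins unweighted
  expect_equal(d10$steps$node, "x")  # seed links dominate when weighted
})

test_that("lcc_growth measures bridging by incorporated nodes", {
  g <- igraph::make_graph(~ a - x, x - b, a - a2, b - b2)
  seeds <- c("a", "a2", "b", "b2")
  dr <- suppressWarnings(diamond_expand(g, seeds, n_iter = 1, omega = 1))
  expect_equal(dr$steps$node, "x")
  expect_equal(lcc_growth(g, dr), 3)  # 2-node LCC -> 5-node LCC
  empty <- dr
  empty$module$diamond_nodes <- character(0)
  empty$module$all_members <- seeds
  expect_equal(lcc_growth(g, empty$module), 0L)
})
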