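# shared fixtures and independent oracles, all built in code

path5 <- function() igraph::make_graph(~ a - b - c - d - e)

# memoized synthetic interactome shared across tests in a file
test_graph <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 2000, m = 3, seed = 424242) {
    key <- paste("g", n, m, seed, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_scale_free(n, m, rng_seed = seed)
    }
    cache[[key]]
  }
})

# HIPPIE-style rows: name A, entrez A, name B, entrez B, score, annotation
hippie_fixture <- function(extra = character(0)) {
  lines <- c(
    "KIF5A_HUMAN\t3798\tKLC1_HUMAN\t3831\t0.92\texperiments:in vivo;species:9606",
    "SPAST_HUMAN\t6683\tATL1_HUMAN\t51062\t0.63\texperiments:two hybrid",
    "MFN2_HUMAN\t9927\tOPA1_HUMAN\t4976\t0.73\t",
    extra
  )
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# exhaustive Floyd-Warshall all-pairs oracle
fw_distances <- function(g) {
  n <- igraph::vcount(g)
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  dimnames(d) <- list(igraph::V(g)$name, igraph::V(g)$name)
  d
}

# brute-force upper-tail hypergeometric: enumerate all k-subsets of N
# elements where 1..s0 are "module", count those with >= ks module members
hyper_tail_enum <- function(N, s0, k, ks) {
  if (ks <= 0) return(1)
  subsets <- combn(N, k)
  mean(colSums(subsets <= s0) >= ks)
}

# brute-force ORA p-value: enumerate all query draws from the background
# where 1..set_size are the pathway, count draws with >= overlap hits
ora_p_enum <- function(bg_size, set_size, q_size, overlap) {
  if (overlap <= 0) return(1)
  subsets <- combn(bg_size, q_size)
  mean(colSums(subsets <= set_size) >= overlap)
}

# three-term is_a chain G -> C -> R
chain_dag <- function() {
  go_dag(
    tibble::tibble(id = c("R", "C", "G"), name = c("R", "C", "G"),
                   namespace = "biological_process"),
    tibble::tibble(child = c("C", "G"), parent = c("R", "C"), relation = "is_a")
  )
}

# two asymmetric paths from G to the root: is_a/is_a (0.64) vs
# part_of/part_of (0.36); max rule must give S(R) = 0.64
diamond_shaped_dag <- function() {
  go_dag(
    tibble::tibble(id = c("R", "P1", "P2", "G"), name = c("R", "P1", "P2", "G"),
                   namespace = "biological_process"),
    tibble::tibble(
      child = c("P1", "P2", "G", "G"),
      parent = c("R", "R", "P1", "P2"),
      relation = c("is_a", "part_of", "is_a", "part_of")
    )
  )
}

# random small graph with named nodes for property tests
random_small_graph <- function(n, p = 0.4) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- letters[seq_len(n)]
  g
}
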