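#' Generate a synthetic scale-free interactome
#'
#' Preferential attachment (Barabasi-Albert) generator producing a connected
#' undirected graph whose degree distribution decays as a power law — the
#' regime observed for confidence-filtered protein interaction networks. Each
#' new node attaches to `edges_per_node` existing nodes with probability
#' proportional to their degree. A configuration-model variant (power-law
#' degree sequence, no connectivity guarantee) is available behind the
#' `model` flag.
#'
#' @param n_nodes Number of nodes (>= 10).
#' @param edges_per_node Edges added per new node (>= 1); mean degree is about
#'   `2 * edges_per_node`.
#' @param rng_seed Integer seed; the same seed reproduces the identical edge
#'   set bit for bit.
#' @param model `"pa"` (preferential attachment, default) or
#'   `"configuration"`.
#' @param confidence_range Range from which per-edge confidence scores are
#'   drawn uniformly; defaults to the medium-to-top HIPPIE band
#'   `c(0.63, 1)`.
#' @return An undirected simple igraph with named nodes (`g0001`, ...) and a
#'   `confidence` edge attribute.
#' @export
#' @examples
#' g <- generate_scale_free(100, 2, rng_seed = 7)
#' igraph::vcount(g)
generate_scale_free <- function(n_nodes, edges_per_node, rng_seed,
                                model = c("pa", "configuration"),
                                confidence_range = c(0.63, 1)) {
  model <- match.arg(model)
  if (n_nodes < 10) abort("`n_nodes` must be >= 10")
  if (edges_per_node < 1) abort("`edges_per_node` must be >= 1")
  if (edges_per_node >= n_nodes) abort("`edges_per_node` must be < `n_nodes`")
  withr::with_seed(rng_seed, {
    if (model == "pa") {
      g <- igraph::sample_pa(n_nodes, m = edges_per_node, directed = FALSE)
    } else {
      kmin <- edges_per_node
      kmax <- max(kmin + 1, floor(sqrt(n_nodes)))
      ks <- kmin:kmax
      deg <- sample(ks, n_nodes, replace = TRUE, prob = ks^-2.5)
      if (sum(deg) %% 2 == 1) deg[1] <- deg[1] + 1
      g <- igraph::sample_degseq(deg, method = "configuration")
      g <- igraph::simplify(g)
    }
    width <- max(4, nchar(as.character(n_nodes)))
    igraph::V(g)$name <- sprintf(paste0("g%0", width, "d"), seq_len(n_nodes))
    igraph::E(g)$confidence <- stats::runif(igraph::ecount(g),
                                            confidence_range[1], confidence_range[2])
  })
  g
}

# grow a member set by biased neighborhood sampling; `forbidden` nodes are
# never added (existing members of `start` are kept regardless)
grow_member_set <- function(g, start, size, cohesion, forbidden = character(0)) {
  nodes <- igraph::V(g)$name
  members <- unique(start)
  available <- setdiff(nodes, union(members, forbidden))
  if (length(members) + length(available) < size) {
    abort(sprintf("cannot grow set to size %d: only %d nodes available",
                  size, length(members) + length(available)))
  }
  while (length(members) < size) {
    nbr <- unlist(lapply(igraph::adjacent_vertices(g, members), names),
                  use.names = FALSE)
    frontier <- setdiff(unique(nbr), union(members, forbidden))
    use_frontier <- length(frontier) > 0 && stats::runif(1) < cohesion
    pool <- if (use_frontier) frontier else setdiff(nodes, union(members, forbidden))
    if (length(pool) == 0) abort(sprintf("cannot grow set to size %d: pool exhausted", size))
    members <- c(members, sample(pool, 1))
  }
  members
}

#' Plant a disease-like module in a network
#'
#' Grows a seed set of the requested size by biased neighborhood sampling:
#' at each step, with probability `cohesion` the next member is drawn from
#' the neighbors of the current members, otherwise uniformly from all
#' remaining nodes. Cohesion is thus (approximately) the expected fraction of
#' members adjacent to at least one other member — the quantity the
#' largest-connected-component statistic responds to. `cohesion = 1` yields a
#' fully connected induced seed subgraph; `cohesion = 0` is uniform random
#' sampling, the null case.
#'
#' @param g An igraph interactome.
#' @param size Number of members (<= number of nodes).
#' @param cohesion Target fraction in \[0, 1\].
#' @param rng_seed Integer seed; same seed, same member set.
#' @param name Label for the resulting seed set.
#' @return A `seed_set` (see [map_seeds()]) whose members all map into `g`.
#' @export
plant_module <- function(g, size, cohesion, rng_seed, name = "planted") {
  if (size > igraph::vcount(g)) abort("`size` exceeds number of nodes")
  if (cohesion < 0 || cohesion > 1) abort("`cohesion` must be in [0, 1]")
  members <- withr::with_seed(rng_seed, {
    start <- sample(igraph::V(g)$name, 1)
    grow_member_set(g, start, size, cohesion)
  })
  map_seeds(g, members, name = name)
}

#' Plant a pair of modules with controlled overlap
#'
#' Generates two seed sets sharing exactly `overlap` members. For positive
#' overlap, a shared core is grown first and both modules extend it from its
#' network neighborhood, producing topologically overlapping modules
#' (negative separation score). For `overlap = 0` the two modules are grown
#' around a pair of anchors at maximal hop distance from each other, producing
#' separated modules (positive separation score).
#'
#' @param g An igraph interactome.
#' @param size_a,size_b Module sizes.
#' @param overlap Number of shared members, `<= min(size_a, size_b)`.
#' @param cohesion Neighborhood-growth bias, as in [plant_module()].
#' @param rng_seed Integer seed.
#' @return A `planted_scenario`: list with elements `graph`, `module_a`,
#'   `module_b` (seed sets), `planted_overlap`, `cohesion`.
#' @export
plant_overlapping_pair <- function(g, size_a, size_b, overlap, cohesion, rng_seed) {
  if (overlap > min(size_a, size_b)) abort("`overlap` must be <= min(size_a, size_b)")
  if (overlap < 0) abort("`overlap` must be >= 0")
  nodes <- igraph::V(g)$name
  sets <- withr::with_seed(rng_seed, {
    if (overlap > 0) {
      core <- grow_member_set(g, sample(nodes, 1), overlap, cohesion)
      a <- grow_member_set(g, core, size_a, cohesion)
      b <- grow_member_set(g, core, size_b, cohesion, forbidden = setdiff(a, core))
      list(a = a, b = b)
    } else {
      anchor_a <- sample(nodes, 1)
      d <- igraph::distances(g, v = anchor_a)[1, ]
      far <- names(d)[is.finite(d) & d == max(d[is.finite(d)])]
      anchor_b <- sample(far, 1)
      a <- grow_member_set(g, anchor_a, size_a, cohesion, forbidden = anchor_b)
      b <- grow_member_set(g, anchor_b, size_b, cohesion, forbidden = a)
      list(a = a, b = b)
    }
  })
  got <- length(intersect(sets$a, sets$b))
  stopifnot(got == overlap)
  structure(
    list(
      graph = g,
      module_a = map_seeds(g, sets$a, name = "planted_A"),
      module_b = map_seeds(g, sets$b, name = "planted_B"),
      planted_overlap = overlap,
      cohesion = cohesion
    ),
    class = "planted_scenario"
  )
}

#' @export
print.planted_scenario <- function(x, ...) {
  cat(sprintf(
    "Planted scenario: |A| = %d, |B| = %d, overlap = %d, cohesion = %.2f on %d-node graph\n",
    length(x$module_a$mapped), length(x$module_b$mapped),
    x$planted_overlap, x$cohesion, igraph::vcount(x$graph)
  ))
  invisible(x)
}

#' Hide a fraction of a seed set
#'
#' Splits a seed set into a visible part and a hidden part, for recovery
#' experiments: expansion is run on the visible seeds and judged by how early
#' it re-discovers the hidden members.
#'
#' @param seed_set A `seed_set` or a character vector of members.
#' @param fraction Fraction to hide, in \[0, 1\].
#' @param rng_seed Integer seed.
#' @return A list with character vectors `visible` and `hidden`
#'   (`hidden` and `visible` are disjoint and partition the input).
#' @export
hide_members <- function(seed_set, fraction, rng_seed) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1]")
  members <- if (inherits(seed_set, "seed_set")) seed_set$mapped else as.character(seed_set)
  n_hide <- round(fraction * length(members))
  hidden <- withr::with_seed(rng_seed, sample(members, n_hide))
  list(visible = setdiff(members, hidden), hidden = hidden)
}
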