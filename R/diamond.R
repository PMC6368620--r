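#' Hypergeometric connectivity significance of a candidate node
#'
#' The probability that a node of degree `k` has at least `k_s` of its
#' neighbors inside a module of size `s0`, when its neighbors are drawn at
#' random from a network of `N` nodes: the upper tail
#' `P(X >= k_s)` of a hypergeometric distribution with `s0` "module"
#' elements among `N`. This is the ranking statistic of the DIAMOnD
#' expansion.
#'
#' Seed weighting: with integer weight `omega >= 1`, links into the module
#' count `omega`-fold, which substitutes
#' `k_s -> omega * k_s`, `k -> k + (omega - 1) * k_s`,
#' `s0 -> omega * s0`, `N -> N + (omega - 1) * s0`
#' before the tail probability is evaluated. `omega = 1` recovers the plain
#' hypergeometric tail. With `k_s >= 1` the weighted p-value is strictly
#' smaller than the unweighted one, so connections to the module are
#' emphasized.
#'
#' All arguments are vectorized; computation is done on log scale so values
#' survive degrees in the thousands.
#'
#' @param N Network size (node count).
#' @param s0 Current module size.
#' @param k Candidate degree.
#' @param k_s Number of candidate neighbors inside the module (`0 <= k_s <=
#'   k`).
#' @param omega Integer seed weight (>= 1, default 1).
#' @param log_p Return the natural log of the p-value instead.
#' @return p-values in `(0, 1]` (`k_s = 0` gives exactly 1).
#' @export
#' @examples
#' connectivity_pvalue(N = 10, s0 = 3, k = 2, k_s = 2)  # 3/45
connectivity_pvalue <- function(N, s0, k, k_s, omega = 1, log_p = FALSE) {
  if (any(k_s > k)) abort("`k_s` cannot exceed `k`")
  if (any(k_s > s0)) abort("`k_s` cannot exceed the module size `s0`")
  if (any(k_s < 0) || any(k < 0)) abort("`k` and `k_s` must be non-negative")
  if (any(k >= N)) abort("`k` must be below the network size `N`")
  if (any(omega < 1) || any(omega != round(omega))) abort("`omega` must be an integer >= 1")
  ks2 <- omega * k_s
  k2 <- k + (omega - 1) * k_s
  s02 <- omega * s0
  N2 <- N + (omega - 1) * s0
  lp <- phyper(ks2 - 1, s02, N2 - s02, k2, lower.tail = FALSE, log.p = TRUE)
  if (log_p) lp else exp(lp)
}

#' Expand a seed set into a disease module with DIAMOnD
#'
#' Iterative DIseAse MOdule Detection: at each step, every non-member node
#' adjacent to the current module is scored with
#' [connectivity_pvalue()] (seeds and previously added nodes weighted by
#' `omega`), and the node with the most significant connectivity joins the
#' module. The process runs for `n_iter` iterations (or until no candidates
#' remain, with a warning). The recommended settings for disease-module
#' expansion are `omega = 10` and `n_iter = 200`.
#'
#' Ties at equal p-value are broken deterministically: higher `k_s`, then
#' lower `k`, then lexicographic node name. An `insertion_order` mode breaks
#' ties by node insertion order in the graph instead, for compatibility with
#' implementations that leave tie order to the container.
#'
#' @param g An igraph interactome.
#' @param seed_set A `seed_set` or character vector of seed node names.
#' @param n_iter Number of nodes to add (>= 1; default 200).
#' @param omega Integer seed weight (default 10).
#' @param ties `"ranked"` (default, documented rule) or `"insertion_order"`.
#' @return A `diamond_result`: list with `steps` (tibble: `iteration`,
#'   `node`, `degree`, `seed_links`, `p_value`) and `module`
#'   (an `expanded_module`: `seeds_mapped`, `diamond_nodes` in incorporation
#'   order, `all_members`, `provenance` tibble).
#' @export
diamond_expand <- function(g, seed_set, n_iter = 200, omega = 10,
                           ties = c("ranked", "insertion_order")) {
  ties <- match.arg(ties)
  if (n_iter < 1) abort("`n_iter` must be >= 1")
  ss <- as_seed_set(g, seed_set)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  adj <- adjacency_int(g)
  deg <- igraph::degree(g)
  in_module <- logical(n)
  seeds_int <- match(ss$mapped, nodes)
  in_module[seeds_int] <- TRUE
  # links into the current module, maintained incrementally
  ks <- integer(n)
  for (si in seeds_int) ks[adj[[si]]] <- ks[adj[[si]]] + 1L
  s0 <- length(seeds_int)

  steps <- vector("list", n_iter)
  added <- character(0)
  for (it in seq_len(n_iter)) {
    cand <- which(!in_module & ks > 0L)
    if (length(cand) == 0) {
      if (it == 1) abort("no candidates: no node is adjacent to the seed set")
      warn(sprintf("diamond_expand: candidates exhausted after %d of %d iterations",
                   it - 1, n_iter))
      steps <- steps[seq_len(it - 1)]
      break
    }
    lp <- connectivity_pvalue(n, s0, deg[cand], ks[cand], omega, log_p = TRUE)
    ord <- if (ties == "ranked") {
      order(lp, -ks[cand], deg[cand], nodes[cand])
    } else {
      order(lp, cand)
    }
    best <- cand[ord[1]]
    steps[[it]] <- tibble::tibble(
      iteration = it,
      node = nodes[best],
      degree = as.integer(deg[best]),
      seed_links = ks[best],
      p_value = exp(lp[ord[1]])
    )
    added <- c(added, nodes[best])
    in_module[best] <- TRUE
    ks[adj[[best]]] <- ks[adj[[best]]] + 1L
    s0 <- s0 + 1L
  }
  steps <- dplyr::bind_rows(steps)
  module <- structure(
    list(
      seeds_mapped = ss$mapped,
      diamond_nodes = added,
      all_members = c(ss$mapped, added),
      provenance = dplyr::bind_rows(
        tibble::tibble(node = ss$mapped, origin = "seed", iteration = NA_integer_),
        tibble::tibble(node = added, origin = "diamond",
                       iteration = seq_along(added))
      ),
      seed_name = ss$name,
      omega = omega
    ),
    class = "expanded_module"
  )
  structure(list(steps = steps, module = module), class = "diamond_result")
}

#' @export
print.diamond_result <- function(x, ...) {
  m <- x$module
  cat(sprintf("DIAMOnD expansion of '%s' (omega = %d): %d seeds + %d added = %d members\n",
              m$seed_name, m$omega, length(m$seeds_mapped),
              length(m$diamond_nodes), length(m$all_members)))
  if (nrow(x$steps) > 0) {
    cat("first incorporations:\n")
    print(head(x$steps, 5))
  }
  invisible(x)
}

#' @export
print.expanded_module <- function(x, ...) {
  cat(sprintf("Expanded module '%s': %d seeds + %d DIAMOnD nodes\n",
              x$seed_name, length(x$seeds_mapped), length(x$diamond_nodes)))
  invisible(x)
}

#' Growth of the largest connected component under expansion
#'
#' How many members the induced LCC gained through expansion: the LCC size
#' of the full expanded module minus the LCC size of the seeds alone.
#' Positive growth beyond the number of added nodes indicates that expansion
#' bridged previously fragmented seed components.
#'
#' @param g An igraph interactome.
#' @param expanded An `expanded_module` (or a `diamond_result`).
#' @return Integer LCC size difference.
#' @export
lcc_growth <- function(g, expanded) {
  if (inherits(expanded, "diamond_result")) expanded <- expanded$module
  stopifnot(inherits(expanded, "expanded_module"))
  if (length(expanded$diamond_nodes) == 0) return(0L)
  lcc_size(g, expanded$all_members) - lcc_size(g, expanded$seeds_mapped)
}
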