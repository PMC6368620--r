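#' Map a curated gene list onto an interactome
#'
#' Partitions a curated disease gene list into the subset present in the
#' network (`mapped`) and the absent remainder (`dropped`). Duplicated
#' identifiers are collapsed with a warning. Seed genes absent from the
#' interactome carry no topological information and are excluded from all
#' downstream statistics, but their identities are retained.
#'
#' @param g An igraph interactome.
#' @param listed Character vector of curated identifiers (non-empty).
#' @param name Disease label for the set.
#' @return A `seed_set`: list with elements `name`, `listed`, `mapped`,
#'   `dropped` (`mapped` and `dropped` partition `listed`).
#' @export
map_seeds <- function(g, listed, name = "seeds") {
  listed <- as.character(listed)
  if (length(listed) == 0) abort("`listed` must be non-empty")
  if (anyDuplicated(listed)) {
    warn(sprintf("map_seeds: %d duplicated identifier(s) collapsed",
                 sum(duplicated(listed))))
    listed <- unique(listed)
  }
  nodes <- igraph::V(g)$name
  mapped <- listed[listed %in% nodes]
  dropped <- setdiff(listed, mapped)
  if (length(mapped) == 0) abort("none of the listed identifiers map into the interactome")
  if (length(dropped) > 0) {
    inform(sprintf("map_seeds(%s): %d of %d identifiers absent from the interactome",
                   name, length(dropped), length(listed)))
  }
  structure(list(name = name, listed = listed, mapped = mapped, dropped = dropped),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("Seed set '%s': %d listed, %d mapped, %d dropped\n",
              x$name, length(x$listed), length(x$mapped), length(x$dropped)))
  invisible(x)
}

as_seed_set <- function(g, x, name = "seeds") {
  if (inherits(x, "seed_set")) x else suppressMessages(map_seeds(g, x, name = name))
}

#' Size of the largest connected component of an induced subgraph
#'
#' The primary localization statistic: the number of members in the largest
#' group of members connected by direct interactions.
#'
#' @param g An igraph interactome.
#' @param members Character vector of node names (subset of the graph).
#' @return Integer LCC size (1 for a single member with no intra-set edges).
#' @export
#' @examples
#' g <- igraph::make_graph(~ a - b - c - d - e)
#' lcc_size(g, c("a", "b", "e"))  # 2
lcc_size <- function(g, members) {
  members <- unique(as.character(members))
  if (length(members) == 0) abort("`members` must be non-empty")
  missing <- setdiff(members, igraph::V(g)$name)
  if (length(missing) > 0) {
    abort(paste0("members not in graph: ", paste(missing, collapse = ", ")))
  }
  sub <- igraph::induced_subgraph(g, members)
  max(igraph::components(sub)$csize)
}

# integer adjacency list (one entry per vertex) for the fast null loops
adjacency_int <- function(g) {
  lapply(igraph::as_adj_list(g), as.integer)
}

# LCC size over an integer member set using a precomputed adjacency list;
# avoids igraph subgraph construction inside randomization loops
fast_lcc <- function(adj, members, n_nodes) {
  k <- length(members)
  if (k == 1L) return(1L)
  pos <- integer(n_nodes)
  pos[members] <- seq_len(k)
  nbrs <- vector("list", k)
  for (i in seq_len(k)) {
    p <- pos[adj[[members[i]]]]
    nbrs[[i]] <- p[p > 0L]
  }
  comp <- integer(k)
  best <- 0L
  cur <- 0L
  for (i in seq_len(k)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      size <- 0L
      while (length(queue) > 0L) {
        v <- queue[[1L]]
        queue <- queue[-1L]
        size <- size + 1L
        for (w in nbrs[[v]]) {
          if (comp[w] == 0L) {
            comp[w] <- cur
            queue <- c(queue, w)
          }
        }
      }
      if (size > best) best <- size
    }
  }
  best
}

# log2-width degree bins; returns list(bin = per-node bin id, pools = nodes per bin)
degree_bins <- function(g) {
  deg <- igraph::degree(g)
  bin <- floor(log2(pmax(deg, 1)))
  list(bin = bin, pools = split(seq_len(igraph::vcount(g)), bin))
}

# sample a random node set matching the degree-bin profile of `target` (int
# indices); bins short of nodes borrow from progressively wider neighbors
sample_degree_matched <- function(bins, target) {
  need <- table(bins$bin[target])
  chosen <- integer(0)
  for (b in names(need)) {
    c_b <- need[[b]]
    bb <- as.integer(b)
    pool <- setdiff(bins$pools[[b]], chosen)
    width <- 1L
    while (length(pool) < c_b && width <= 64L) {
      extra <- unlist(bins$pools[as.character(c(bb - width, bb + width))],
                      use.names = FALSE)
      pool <- setdiff(unique(c(pool, extra)), chosen)
      width <- width + 1L
    }
    take <- min(c_b, length(pool))
    picked <- if (length(pool) == 1) pool else sample(pool, take)
    chosen <- c(chosen, picked)
  }
  chosen
}

#' Largest-connected-component significance of a seed set
#'
#' Tests whether the seeds agglomerate into a proto-module: the observed LCC
#' size is compared with a null distribution of LCC sizes from random node
#' sets of equal size. The default null draws nodes uniformly from the whole
#' network; a degree-binned variant (sampling within log-width degree bins)
#' is available for sensitivity analysis, since hub-heavy sets inflate LCCs.
#'
#' A seed set is classified as a proto-module when the z-score is at least
#' 1.6 and the empirical p-value is at most 0.05. The empirical p-value uses
#' the add-one rule `(r + 1) / (n_rand + 1)` where `r` counts null LCCs at
#' least as large as observed, so it is never exactly zero at finite
#' `n_rand`.
#'
#' @param g An igraph interactome.
#' @param seed_set A `seed_set` (or character vector of node names).
#' @param n_rand Number of randomizations (>= 100; default 10000).
#' @param rng_seed Integer seed for reproducible nulls.
#' @param null `"uniform"` (default) or `"degree_binned"`.
#' @return An `lcc_result`: list with `observed_size`, `null_mean`,
#'   `null_sd`, `z_score`, `empirical_p`, `n_randomizations`, `proto_module`,
#'   `null_sizes`, `seed_name`. `z_score` is `NA` when the null is
#'   degenerate (`null_sd = 0`); the p-value is still reported.
#' @seealso [lcc_size()], [proximity_significance()]
#' @export
lcc_significance <- function(g, seed_set, n_rand = 10000, rng_seed = NULL,
                             null = c("uniform", "degree_binned")) {
  null <- match.arg(null)
  if (n_rand < 100) abort("`n_rand` must be >= 100")
  ss <- as_seed_set(g, seed_set)
  members_int <- match(ss$mapped, igraph::V(g)$name)
  k <- length(members_int)
  n <- igraph::vcount(g)
  adj <- adjacency_int(g)
  observed <- fast_lcc(adj, members_int, n)
  bins <- if (null == "degree_binned") degree_bins(g) else NULL
  draw_null <- function() {
    vapply(seq_len(n_rand), function(i) {
      set <- if (null == "uniform") sample.int(n, k) else sample_degree_matched(bins, members_int)
      fast_lcc(adj, set, n)
    }, integer(1))
  }
  null_sizes <- if (is.null(rng_seed)) draw_null() else withr::with_seed(rng_seed, draw_null())
  null_mean <- mean(null_sizes)
  null_sd <- sd(null_sizes)
  z <- if (null_sd > 0) (observed - null_mean) / null_sd else NA_real_
  p <- (sum(null_sizes >= observed) + 1) / (n_rand + 1)
  structure(
    list(
      observed_size = observed,
      null_mean = null_mean,
      null_sd = null_sd,
      z_score = z,
      empirical_p = p,
      n_randomizations = n_rand,
      proto_module = isTRUE(!is.na(z) && z >= 1.6 && p <= 0.05),
      null_sizes = null_sizes,
      null_model = null,
      seed_name = ss$name,
      n_mapped = k
    ),
    class = "lcc_result"
  )
}

#' @export
print.lcc_result <- function(x, ...) {
  cat(sprintf("LCC of '%s': S = %d of %d seeds (null %.2f +/- %.2f over %d randomizations)\n",
              x$seed_name, x$observed_size, x$n_mapped, x$null_mean, x$null_sd,
              x$n_randomizations))
  cat(sprintf("  z = %s, empirical p = %.3g -> %s\n",
              ifelse(is.na(x$z_score), "undefined (null sd = 0)", sprintf("%.2f", x$z_score)),
              x$empirical_p,
              ifelse(x$proto_module, "proto-module (z >= 1.6, p <= 0.05)", "not a proto-module")))
  invisible(x)
}

#' Nearest-seed shortest distances within a seed set
#'
#' For each mapped seed, the hop distance to the nearest *other* mapped
#' seed. This shortest-distance statistic complements the LCC by also
#' crediting seeds that sit close to, but not directly adjacent to, the rest
#' of the module. Unreachable seeds (other component) are excluded from the
#' mean and counted.
#'
#' @param g An igraph interactome.
#' @param seed_set A `seed_set` or character vector with at least 2 mapped
#'   members.
#' @return A `proximity_result` (observed part only): `observed_ds` (named,
#'   `Inf` = unreachable), `mean_ds` over finite entries,
#'   `n_excluded_unreachable`; test fields are `NA` until
#'   [proximity_significance()] fills them.
#' @export
#' @examples
#' g <- igraph::make_graph(~ a - b - c - d - e)
#' seed_distances(g, c("a", "b", "e"))$observed_ds  # a:1 b:1 e:3
seed_distances <- function(g, seed_set) {
  ss <- as_seed_set(g, seed_set)
  if (length(ss$mapped) < 2) abort("need at least 2 mapped seeds for distance statistics")
  nd <- nearest_member_distances(g, ss$mapped, ss$mapped, exclude_self = TRUE)
  finite <- nd$dist[is.finite(nd$dist)]
  structure(
    list(
      observed_ds = nd$dist,
      mean_ds = mean(finite),
      n_excluded_unreachable = nd$n_unreachable,
      u_statistic = NA_real_,
      p_value = NA_real_,
      null_summary = NULL,
      method = NULL,
      n_randomizations = 0L,
      seed_name = ss$name
    ),
    class = "proximity_result"
  )
}

#' Shortest-distance significance of a seed set
#'
#' Builds a null distribution of nearest-neighbor distances from random node
#' sets of equal size and tests, one-sided, whether the observed distances
#' are stochastically smaller (seeds closer together than chance) with a
#' Mann-Whitney U test. By default all null distances across randomizations
#' are pooled into one reference sample; `null_stat = "means"` instead
#' compares the observed mean against the distribution of per-randomization
#' mean distances with an empirical add-one p-value.
#'
#' The U test uses the normal approximation with tie correction; for small
#' problems (combined sample size below 50) the exact distribution is used
#' when ties permit.
#'
#' @inheritParams lcc_significance
#' @param null_stat `"pooled"` (default) or `"means"`.
#' @return A `proximity_result` with `u_statistic`, `p_value`,
#'   `null_summary` and `method` filled in.
#' @export
proximity_significance <- function(g, seed_set, n_rand = 10000, rng_seed = NULL,
                                   null_stat = c("pooled", "means")) {
  null_stat <- match.arg(null_stat)
  if (n_rand < 100) abort("`n_rand` must be >= 100")
  ss <- as_seed_set(g, seed_set)
  res <- seed_distances(g, ss)
  k <- length(ss$mapped)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  draw_null <- function() {
    lapply(seq_len(n_rand), function(i) {
      set <- nodes[sample.int(n, k)]
      d <- nearest_member_distances(g, set, set, exclude_self = TRUE)$dist
      d[is.finite(d)]
    })
  }
  null_list <- if (is.null(rng_seed)) draw_null() else withr::with_seed(rng_seed, draw_null())
  obs <- res$observed_ds[is.finite(res$observed_ds)]
  if (null_stat == "pooled") {
    null_pool <- unlist(null_list, use.names = FALSE)
    if (length(null_pool) == 0) {
      abort("degenerate null: no finite nearest-neighbor distances in any randomization")
    }
    exact <- (length(obs) + length(null_pool)) < 50
    wt <- suppressWarnings(
      wilcox.test(obs, null_pool, alternative = "less", exact = exact, correct = TRUE)
    )
    res$u_statistic <- unname(wt$statistic)
    res$p_value <- wt$p.value
    res$null_summary <- summary(null_pool)
  } else {
    null_means <- vapply(null_list, function(d) {
      if (length(d) == 0) NA_real_ else mean(d)
    }, numeric(1))
    null_means <- null_means[!is.na(null_means)]
    if (length(null_means) == 0) {
      abort("degenerate null: every randomized set had only unreachable members")
    }
    res$p_value <- (sum(null_means <= res$mean_ds) + 1) / (length(null_means) + 1)
    res$null_summary <- summary(null_means)
  }
  res$method <- null_stat
  res$n_randomizations <- n_rand
  res
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("Seed shortest distances ('%s'): mean d_s = %.3f over %d seeds (%d unreachable excluded)\n",
              x$seed_name %||% "seeds", x$mean_ds,
              length(x$observed_ds), x$n_excluded_unreachable))
  if (!is.null(x$method)) {
    cat(sprintf("  %s null, %d randomizations: U = %s, one-sided p = %.3g\n",
                x$method, x$n_randomizations,
                ifelse(is.na(x$u_statistic), "-", format(x$u_statistic)), x$p_value))
  }
  invisible(x)
}
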