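#' Generate a toy ontology DAG
#'
#' Builds a rooted, full `branching`-ary tree of terms with `depth` levels
#' below the single root, as a minimal stand-in for a Gene Ontology
#' namespace. Edges point child to parent; relations are `is_a` by default,
#' with an optional fraction of `part_of` edges. With `extra_edges > 0`,
#' additional cross edges between non-adjacent levels are added so the result
#' is a genuine DAG rather than a tree (multiple paths to the root, as in
#' real GO).
#'
#' @param depth Levels below the root (>= 1); `depth = 3, branching = 2`
#'   gives 15 terms.
#' @param branching Children per internal term (>= 1).
#' @param p_part_of Probability that an edge is `part_of` instead of `is_a`.
#' @param extra_edges Number of extra child-to-grandparent-level edges.
#' @param namespace Namespace label applied to all terms.
#' @param rng_seed Integer seed (used when `p_part_of > 0` or
#'   `extra_edges > 0`).
#' @return A `go_dag` object (see [go_dag()]).
#' @export
#' @examples
#' dag <- generate_toy_ontology(3, 2)
#' nrow(dag$terms)  # 15
generate_toy_ontology <- function(depth, branching, p_part_of = 0,
                                  extra_edges = 0,
                                  namespace = "biological_process",
                                  rng_seed = 1) {
  if (depth < 1 || branching < 1) abort("`depth` and `branching` must be >= 1")
  n_terms <- sum(branching^(0:depth))
  ids <- sprintf("SY:%07d", seq_len(n_terms))
  # index arithmetic for a complete branching-ary tree, root at index 1
  child_idx <- 2:n_terms
  parent_idx <- (child_idx - 2) %/% branching + 1
  edges <- tibble::tibble(
    child = ids[child_idx],
    parent = ids[parent_idx],
    relation = "is_a"
  )
  withr::with_seed(rng_seed, {
    if (p_part_of > 0) {
      flip <- stats::runif(nrow(edges)) < p_part_of
      edges$relation[flip] <- "part_of"
    }
    if (extra_edges > 0) {
      lvl <- floor(log(pmax(seq_len(n_terms) * (branching - 1) + 1, 1),
                       base = max(branching, 2)))
      deep <- which(seq_len(n_terms) > 1 + branching)  # below level 1
      for (i in seq_len(extra_edges)) {
        ch <- sample(deep, 1)
        shallower <- setdiff(which(lvl < lvl[ch]), c(1, parent_idx[ch - 1]))
        if (length(shallower) == 0) next
        pa <- if (length(shallower) == 1) shallower else sample(shallower, 1)
        cand <- tibble::tibble(child = ids[ch], parent = ids[pa], relation = "is_a")
        trial <- dplyr::distinct(dplyr::bind_rows(edges, cand))
        trial_g <- igraph::graph_from_data_frame(trial[, 1:2], directed = TRUE)
        if (igraph::is_dag(trial_g)) edges <- trial
      }
    }
  })
  terms <- tibble::tibble(
    id = ids,
    name = paste0("toy term ", seq_len(n_terms)),
    namespace = namespace
  )
  go_dag(terms, edges)
}

#' Generate synthetic GO-style annotations
#'
#' Annotates each gene with a few terms drawn from the non-root terms of a
#' DAG, with evidence codes drawn from a given mix. Used to exercise the
#' evidence-code filter and the semantic-similarity machinery on synthetic
#' data.
#'
#' @param genes Character vector of gene identifiers.
#' @param dag A `go_dag`.
#' @param terms_per_gene Annotations per gene (capped at the number of
#'   available terms).
#' @param evidence_mix Named numeric vector of evidence-code probabilities;
#'   defaults to a mix of experimental (`EXP`), electronic (`IEA`) and
#'   physical-interaction (`IPI`) codes.
#' @param rng_seed Integer seed.
#' @return A tibble with columns `gene`, `term`, `evidence`.
#' @export
generate_annotations <- function(genes, dag, terms_per_gene = 3,
                                 evidence_mix = c(EXP = 0.6, IEA = 0.3, IPI = 0.1),
                                 rng_seed = 1) {
  stopifnot(inherits(dag, "go_dag"), terms_per_gene >= 1)
  pool <- setdiff(dag$terms$id, dag$roots)
  if (length(pool) == 0) pool <- dag$terms$id
  k <- min(terms_per_gene, length(pool))
  withr::with_seed(rng_seed, {
    purrr::map_dfr(genes, function(gene) {
      tibble::tibble(
        gene = gene,
        term = sample(pool, k),
        evidence = sample(names(evidence_mix), k, replace = TRUE, prob = evidence_mix)
      )
    })
  })
}

#' Generate a synthetic pathway collection
#'
#' Draws `n_sets` gene sets of a fixed size from a background universe, as a
#' stand-in for a KEGG/WikiPathways-style GMT collection.
#'
#' @param n_sets Number of pathways.
#' @param set_size Genes per pathway.
#' @param background Either an integer (size of a generated universe
#'   `bg0001...`) or a character vector of gene identifiers.
#' @param rng_seed Integer seed.
#' @param source Source tag recorded on every set.
#' @return A `pathway_db` (see [pathway_db()]).
#' @export
generate_gmt <- function(n_sets, set_size, background, rng_seed = 1,
                         source = "synthetic") {
  if (n_sets < 1 || set_size < 1) abort("`n_sets` and `set_size` must be positive")
  if (is.numeric(background) && length(background) == 1) {
    width <- max(4, nchar(as.character(background)))
    background <- sprintf(paste0("bg%0", width, "d"), seq_len(background))
  }
  background <- as.character(background)
  if (set_size > length(background)) abort("`set_size` exceeds the background size")
  sets <- withr::with_seed(rng_seed, {
    lapply(seq_len(n_sets), function(i) sample(background, set_size))
  })
  names(sets) <- sprintf("PW%04d", seq_len(n_sets))
  pathway_db(sets, background = background,
             source = stats::setNames(rep(source, n_sets), names(sets)))
}
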