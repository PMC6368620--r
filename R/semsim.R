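#' Construct a GO-style term DAG
#'
#' A typed directed acyclic graph of ontology terms with child-to-parent
#' edges of relation `is_a` or `part_of`, the substrate for Wang-method
#' semantic similarity. Acyclicity and the existence of a root for every
#' term are enforced.
#'
#' @param terms Tibble with columns `id`, `name`, `namespace`.
#' @param edges Tibble with columns `child`, `parent`, `relation`
#'   (`is_a` or `part_of`); all ids must appear in `terms`.
#' @return A `go_dag`: the two tibbles plus `roots` (terms with no parent).
#' @export
go_dag <- function(terms, edges) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent", "relation") %in% names(edges)))
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel) > 0) {
    abort(paste0("unsupported relation type(s): ", paste(bad_rel, collapse = ", ")))
  }
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown) > 0) {
    abort(paste0("edge references unknown term(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  if (nrow(edges) > 0) {
    gg <- igraph::graph_from_data_frame(edges[, c("child", "parent")], directed = TRUE,
                                        vertices = terms$id)
    if (!igraph::is_dag(gg)) abort("term graph contains a cycle; not a DAG")
  }
  roots <- setdiff(terms$id, edges$child)
  if (length(roots) == 0) abort("DAG has no root")
  structure(list(terms = terms, edges = edges, roots = roots), class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("GO-style DAG: %d terms, %d edges (%s), %d root(s), namespaces: %s\n",
              nrow(x$terms), nrow(x$edges),
              paste(names(table(x$edges$relation)), table(x$edges$relation),
                    sep = "=", collapse = ", "),
              length(x$roots),
              paste(unique(x$terms$namespace), collapse = ", ")))
  invisible(x)
}

#' Read an OBO 1.2 flat file
#'
#' Minimal reader for `[Term]` stanzas: `id`, `name`, `namespace`, `is_a`
#' and `relationship: part_of` lines. Obsolete terms are skipped.
#' Relationship types other than `part_of` (e.g. `regulates`) are ignored
#' with a count, as only `is_a`/`part_of` carry Wang weights.
#'
#' @param file Path to the OBO file.
#' @return A `go_dag`.
#' @export
read_obo <- function(file) {
  lines <- readr::read_lines(file)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  edges <- list()
  n_ignored_rel <- 0L
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(NULL)
    cur
  }
  for (line in lines) {
    line <- trimws(line)
    if (line == "[Term]") {
      t <- flush(cur)
      if (!is.null(t)) terms[[length(terms) + 1]] <- t
      cur <- list(id = NULL, name = "", namespace = "unknown",
                  parents = character(0), relations = character(0),
                  obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (startsWith(line, "[")) {  # some other stanza type
      t <- flush(cur)
      if (!is.null(t)) terms[[length(terms) + 1]] <- t
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(line)) next
    if (startsWith(line, "id:")) cur$id <- trimws(sub("^id:", "", line))
    else if (startsWith(line, "name:")) cur$name <- trimws(sub("^name:", "", line))
    else if (startsWith(line, "namespace:")) cur$namespace <- trimws(sub("^namespace:", "", line))
    else if (startsWith(line, "is_obsolete: true")) cur$obsolete <- TRUE
    else if (startsWith(line, "is_a:")) {
      target <- trimws(sub("!.*$", "", sub("^is_a:", "", line)))
      cur$parents <- c(cur$parents, target)
      cur$relations <- c(cur$relations, "is_a")
    } else if (startsWith(line, "relationship:")) {
      body <- trimws(sub("!.*$", "", sub("^relationship:", "", line)))
      parts <- strsplit(body, "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        cur$parents <- c(cur$parents, parts[2])
        cur$relations <- c(cur$relations, "part_of")
      } else {
        n_ignored_rel <- n_ignored_rel + 1L
      }
    }
  }
  t <- flush(cur)
  if (!is.null(t)) terms[[length(terms) + 1]] <- t
  if (length(terms) == 0) abort("no [Term] stanzas found in OBO file")
  if (n_ignored_rel > 0) {
    inform(sprintf("read_obo: ignored %d relationship line(s) of unsupported type", n_ignored_rel))
  }
  term_tbl <- tibble::tibble(
    id = vapply(terms, `[[`, character(1), "id"),
    name = vapply(terms, `[[`, character(1), "name"),
    namespace = vapply(terms, `[[`, character(1), "namespace")
  )
  edge_tbl <- purrr::map_dfr(terms, function(t) {
    if (length(t$parents) == 0) return(NULL)
    tibble::tibble(child = t$id, parent = t$parents, relation = t$relations)
  })
  # drop dangling edges to terms outside this file (e.g. cross-ontology refs)
  if (nrow(edge_tbl) > 0) {
    edge_tbl <- dplyr::filter(edge_tbl, .data$parent %in% term_tbl$id)
  }
  go_dag(term_tbl, edge_tbl)
}

#' Write a `go_dag` as an OBO 1.2 flat file
#'
#' @param dag A `go_dag`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_obo <- function(dag, file) {
  stopifnot(inherits(dag, "go_dag"))
  by_child <- split(dag$edges, dag$edges$child)
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(dag$terms))) {
    tm <- dag$terms[i, ]
    stanza <- c("[Term]",
                paste0("id: ", tm$id),
                paste0("name: ", tm$name),
                paste0("namespace: ", tm$namespace))
    e <- by_child[[tm$id]]
    if (!is.null(e)) {
      for (j in seq_len(nrow(e))) {
        stanza <- c(stanza, if (e$relation[j] == "is_a") {
          paste0("is_a: ", e$parent[j])
        } else {
          paste0("relationship: part_of ", e$parent[j])
        })
      }
    }
    out <- c(out, stanza, "")
  }
  readr::write_lines(out, file)
  invisible(file)
}

#' Read a GAF 2.x annotation file
#'
#' Extracts gene (column 2), GO term (column 5), evidence code (column 7)
#' and aspect (column 9) from a Gene Association File. Header lines starting
#' with `!` are skipped.
#'
#' @param file Path to the GAF file.
#' @return A tibble with columns `gene`, `term`, `evidence`, `aspect`.
#' @export
read_gaf <- function(file) {
  lines <- readr::read_lines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0) abort("no annotation rows in GAF file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9)) abort("GAF rows must have at least 9 tab-separated columns")
  tibble::tibble(
    gene = vapply(fields, `[[`, character(1), 2),
    term = vapply(fields, `[[`, character(1), 5),
    evidence = vapply(fields, `[[`, character(1), 7),
    aspect = vapply(fields, `[[`, character(1), 9)
  )
}

#' Write annotations as a GAF 2.1 file
#'
#' @param annotations Tibble with columns `gene`, `term`, `evidence` and
#'   optionally `aspect` (default `"P"`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gaf <- function(annotations, file) {
  stopifnot(all(c("gene", "term", "evidence") %in% names(annotations)))
  aspect <- if ("aspect" %in% names(annotations)) annotations$aspect else rep("P", nrow(annotations))
  rows <- sprintf("SYN\t%s\t%s\t\t%s\tSYN:0000000\t%s\t\t%s\t\t\tprotein\ttaxon:9606\t20260101\tSYN\t\t",
                  annotations$gene, annotations$gene, annotations$term,
                  annotations$evidence, aspect)
  readr::write_lines(c("!gaf-version: 2.1", rows), file)
  invisible(file)
}

#' Filter annotations by evidence code
#'
#' Removes annotation pairs with excluded evidence codes. Electronic
#' annotations (IEA) are weak, uncurated associations; physical-interaction
#' annotations (IPI) are circular when the genes under study were themselves
#' selected from a physical-interaction network — both are excluded by
#' default. Genes left without any annotation are flagged (attribute
#' `flagged_genes`) so downstream similarity code can exclude them by name.
#'
#' @param annotations Tibble with columns `gene`, `term`, `evidence`.
#' @param excluded Character vector of evidence codes to drop; default
#'   `c("IEA", "IPI")`. Empty vector = identity.
#' @return The filtered tibble, with attribute `flagged_genes`.
#' @export
filter_evidence <- function(annotations, excluded = c("IEA", "IPI")) {
  stopifnot(all(c("gene", "term", "evidence") %in% names(annotations)))
  out <- dplyr::filter(tibble::as_tibble(annotations), !(.data$evidence %in% excluded))
  flagged <- setdiff(unique(annotations$gene), unique(out$gene))
  if (length(flagged) > 0) {
    inform(sprintf("filter_evidence: %d gene(s) left without annotations", length(flagged)))
  }
  attr(out, "flagged_genes") <- flagged
  out
}

wang_default_weights <- c(is_a = 0.8, part_of = 0.6)

#' Wang S-values of a term's ancestor closure
#'
#' The semantic contribution of each ancestor to a term: the term itself has
#' S-value 1, and every ancestor `t` gets
#' `S(t) = max over children t' of t (within the closure) of w(t -> t') * S(t')`,
#' where the relation weights default to 0.8 for `is_a` and 0.6 for
#' `part_of`. Multiple paths are combined by the max rule, not summed.
#'
#' @param term A term id present in the DAG.
#' @param dag A `go_dag`.
#' @param weights Named relation weights.
#' @return Named numeric vector of S-values over the closure (term
#'   included); `sum()` of it is the semantic value SV of the term.
#' @export
#' @examples
#' dag <- go_dag(
#'   tibble::tibble(id = c("R", "C", "G"), name = id, namespace = "bp"),
#'   tibble::tibble(child = c("C", "G"), parent = c("R", "C"), relation = "is_a")
#' )
#' svalues("G", dag)  # G: 1, C: 0.8, R: 0.64
svalues <- function(term, dag, weights = wang_default_weights) {
  stopifnot(inherits(dag, "go_dag"))
  if (!term %in% dag$terms$id) abort(paste0("term not in DAG: ", term))
  # ancestor closure by upward BFS
  closure <- term
  frontier <- term
  while (length(frontier) > 0) {
    up <- dag$edges$parent[dag$edges$child %in% frontier]
    frontier <- setdiff(up, closure)
    closure <- c(closure, frontier)
  }
  s <- stats::setNames(rep(0, length(closure)), closure)
  s[term] <- 1
  ed <- dag$edges[dag$edges$child %in% closure & dag$edges$parent %in% closure, ]
  w <- unname(weights[ed$relation])
  # max-product relaxation; converges within the closure's longest path length
  for (pass in seq_len(length(closure) + 1)) {
    changed <- FALSE
    for (i in seq_len(nrow(ed))) {
      cand <- w[i] * s[ed$child[i]]
      if (cand > s[ed$parent[i]]) {
        s[ed$parent[i]] <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  s
}

#' Wang semantic similarity between two terms
#'
#' `Sim(a, b)` sums the S-values of the terms shared by the two ancestor
#' closures (from both sides) and normalizes by the two semantic values:
#' `Sim = sum_{t in common} (S_a(t) + S_b(t)) / (SV(a) + SV(b))`.
#' Terms must belong to the same namespace. Identical terms give 1; terms
#' sharing only the root give a small positive value.
#'
#' @param a,b Term ids.
#' @param dag A `go_dag`.
#' @param weights Named relation weights (see [svalues()]).
#' @return Similarity in \[0, 1\].
#' @export
term_sim_wang <- function(a, b, dag, weights = wang_default_weights) {
  ns <- dag$terms$namespace[match(c(a, b), dag$terms$id)]
  if (anyNA(ns)) abort("term(s) not in DAG")
  if (ns[1] != ns[2]) {
    abort(sprintf("terms belong to different namespaces (%s vs %s)", ns[1], ns[2]))
  }
  sa <- svalues(a, dag, weights)
  sb <- svalues(b, dag, weights)
  common <- intersect(names(sa), names(sb))
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

# term-by-term Wang similarity matrix with S-values computed once per term
term_sim_matrix <- function(terms_a, terms_b, dag, weights = wang_default_weights) {
  all_terms <- unique(c(terms_a, terms_b))
  sv <- lapply(all_terms, svalues, dag = dag, weights = weights)
  names(sv) <- all_terms
  out <- matrix(0, length(terms_a), length(terms_b),
                dimnames = list(terms_a, terms_b))
  for (i in seq_along(terms_a)) {
    sa <- sv[[terms_a[i]]]
    for (j in seq_along(terms_b)) {
      sb <- sv[[terms_b[j]]]
      common <- intersect(names(sa), names(sb))
      out[i, j] <- sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
    }
  }
  out
}

#' Best-match-average similarity between two genes
#'
#' Combines the pairwise Wang similarities of the two genes' term sets with
#' the best-match-average (BMA) rule: the mean of all row maxima and column
#' maxima of the term-similarity matrix,
#' `(sum_i max_j sim_ij + sum_j max_i sim_ij) / (n_rows + n_cols)`.
#'
#' @param g1,g2 Gene identifiers.
#' @param annotations Tibble with columns `gene`, `term` (already
#'   evidence-filtered, see [filter_evidence()]).
#' @param dag A `go_dag`.
#' @param namespace Restrict terms to this namespace (default
#'   `"biological_process"`); `NULL` keeps all.
#' @param weights Relation weights for [svalues()].
#' @return Similarity in \[0, 1\]. Errors if either gene has no surviving
#'   annotation in the namespace.
#' @export
gene_sim_bma <- function(g1, g2, annotations, dag,
                         namespace = "biological_process",
                         weights = wang_default_weights) {
  terms_of <- function(gene) {
    tm <- annotations$term[annotations$gene == gene]
    tm <- intersect(tm, dag$terms$id)
    if (!is.null(namespace)) {
      tm <- tm[dag$terms$namespace[match(tm, dag$terms$id)] == namespace]
    }
    if (length(tm) == 0) abort(paste0("gene has no usable annotation: ", gene))
    unique(tm)
  }
  ta <- terms_of(g1)
  tb <- terms_of(g2)
  m <- term_sim_matrix(ta, tb, dag, weights)
  bma(m)
}

bma <- function(m) {
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (nrow(m) + ncol(m))
}

#' Gene-by-gene semantic similarity matrix
#'
#' BMA-combined Wang similarities for all pairs of two gene lists, e.g.
#' DIAMOnD-added proteins against seed proteins. Genes without usable
#' annotations are dropped with a message.
#'
#' @param genes_a,genes_b Character vectors of gene identifiers (rows,
#'   columns).
#' @inheritParams gene_sim_bma
#' @return A numeric matrix with values in \[0, 1\]; diagonal entries are 1
#'   when the same annotated gene appears on both axes.
#' @export
semsim_matrix <- function(genes_a, genes_b, annotations, dag,
                          namespace = "biological_process",
                          weights = wang_default_weights) {
  usable <- function(genes) {
    keep <- vapply(genes, function(g) {
      tm <- annotations$term[annotations$gene == g]
      tm <- intersect(tm, dag$terms$id)
      if (!is.null(namespace)) {
        tm <- tm[dag$terms$namespace[match(tm, dag$terms$id)] == namespace]
      }
      length(tm) > 0
    }, logical(1))
    if (any(!keep)) {
      inform(sprintf("semsim_matrix: dropping %d unannotated gene(s)", sum(!keep)))
    }
    genes[keep]
  }
  genes_a <- usable(unique(genes_a))
  genes_b <- usable(unique(genes_b))
  if (length(genes_a) == 0 || length(genes_b) == 0) {
    abort("no annotated genes left on one axis")
  }
  terms_of <- function(gene) {
    tm <- intersect(annotations$term[annotations$gene == gene], dag$terms$id)
    if (!is.null(namespace)) {
      tm <- tm[dag$terms$namespace[match(tm, dag$terms$id)] == namespace]
    }
    unique(tm)
  }
  ta <- lapply(genes_a, terms_of)
  tb <- lapply(genes_b, terms_of)
  all_terms <- unique(c(unlist(ta), unlist(tb)))
  tmat <- term_sim_matrix(all_terms, all_terms, dag, weights)
  out <- matrix(0, length(genes_a), length(genes_b),
                dimnames = list(genes_a, genes_b))
  for (i in seq_along(genes_a)) {
    for (j in seq_along(genes_b)) {
      out[i, j] <- bma(tmat[ta[[i]], tb[[j]], drop = FALSE])
    }
  }
  out
}

#' Hierarchical clustering of a semantic-similarity matrix
#'
#' Agglomerative clustering on distance `1 - similarity`. Returns both the
#' dendrogram and a flat clustering, cut either into `k` groups or at height
#' `h` (default `h = 0.5`, i.e. similarity 0.5).
#'
#' @param mat Square symmetric similarity matrix in \[0, 1\].
#' @param linkage Linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @param k Number of flat clusters (overrides `h`).
#' @param h Cut height on the 1 - similarity scale.
#' @return A list with `hclust` (the tree) and `clusters` (named integer
#'   vector of flat cluster memberships).
#' @export
cluster_semsim <- function(mat, linkage = "average", k = NULL, h = 0.5) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) {
    abort("`mat` must be a square matrix")
  }
  if (max(abs(mat - t(mat))) > 1e-8) abort("`mat` must be symmetric")
  d <- as.dist(1 - mat)
  hc <- hclust(d, method = linkage)
  clusters <- if (!is.null(k)) cutree(hc, k = k) else cutree(hc, h = h)
  list(hclust = hc, clusters = clusters)
}
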