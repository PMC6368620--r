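#' Read a HIPPIE-style scored interaction table
#'
#' Parses a tab-delimited protein-protein interaction table in the layout used
#' by the HIPPIE database: UniProt-style name A, Entrez ID A, name B, Entrez
#' ID B, confidence score, free-text annotation. The confidence score
#' summarises the experimental support for each interaction and lies in
#' \[0, 1\]; HIPPIE's predefined levels put medium confidence at 0.63 (second
#' quartile) and high confidence at 0.73 (third quartile).
#'
#' Each protein is keyed by its Entrez ID when present; otherwise the gene
#' symbol derived from the UniProt-style name (the text before `"_HUMAN"`) is
#' used. A two-column mapping table (`id_map`, columns `from`, `to`) overrides
#' both. Rows whose identifiers or confidence cannot be parsed are skipped and
#' counted, never silently dropped. In strict mode, rows whose annotation
#' carries a species tag with no human entry are skipped as well.
#'
#' @param file Path to the tab-separated file (or a connection).
#' @param strict Logical; drop rows annotated as non-human (default `TRUE`).
#' @param id_map Optional data frame with columns `from` and `to` overriding
#'   the identifier derived from the row.
#' @param has_header Logical; set `TRUE` if the first line is a header.
#'
#' @return A tibble with columns `protein_a`, `protein_b`, `confidence`,
#'   `annotation`, one row per retained interaction record. The number of
#'   skipped rows is attached as attribute `n_skipped` and reported in a
#'   message.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("KIF5A_HUMAN\t3798\tKLC1_HUMAN\t3831\t0.92\t",
#'              "SPAST_HUMAN\t6683\tATL1_HUMAN\t51062\t0.63\t"), tsv)
#' read_hippie(tsv)
read_hippie <- function(file, strict = TRUE, id_map = NULL, has_header = FALSE) {
  lines <- readr::read_lines(file)
  if (has_header && length(lines) > 0) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort("empty interaction stream: no data rows found")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (max(ncols) < 5) {
    abort(paste0(
      "missing confidence column: expected >= 5 tab-separated columns ",
      "(name A, id A, name B, id B, confidence[, annotation]), found ", max(ncols)
    ))
  }

  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, character(1))
  name_a <- get_col(1); entrez_a <- get_col(2)
  name_b <- get_col(3); entrez_b <- get_col(4)
  conf <- suppressWarnings(as.numeric(get_col(5)))
  annotation <- get_col(6)
  annotation[is.na(annotation)] <- ""

  id_a <- resolve_identifier(name_a, entrez_a, id_map)
  id_b <- resolve_identifier(name_b, entrez_b, id_map)

  bad <- is.na(id_a) | is.na(id_b) | is.na(conf) | conf < 0 | conf > 1
  nonhuman <- if (strict) is_nonhuman_annotation(annotation) else rep(FALSE, length(lines))
  keep <- !bad & !nonhuman
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    inform(sprintf("read_hippie: skipped %d row(s) (%d unparseable, %d non-human)",
                   n_skipped, sum(bad), sum(nonhuman & !bad)))
  }
  out <- tibble::tibble(
    protein_a = id_a[keep],
    protein_b = id_b[keep],
    confidence = conf[keep],
    annotation = annotation[keep]
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

resolve_identifier <- function(name, entrez, id_map = NULL) {
  entrez <- trimws(entrez)
  entrez[!grepl("^[0-9]+$", entrez)] <- NA_character_
  symbol <- toupper(sub("_HUMAN$", "", trimws(name)))
  symbol[!nzchar(symbol)] <- NA_character_
  id <- ifelse(!is.na(entrez), entrez, symbol)
  if (!is.null(id_map)) {
    stopifnot(all(c("from", "to") %in% names(id_map)))
    hit_sym <- match(symbol, id_map$from)
    hit_ent <- match(entrez, id_map$from)
    hit <- ifelse(!is.na(hit_sym), hit_sym, hit_ent)
    id <- ifelse(!is.na(hit), id_map$to[hit], id)
  }
  id
}

is_nonhuman_annotation <- function(annotation) {
  has_species <- grepl("species:", annotation, ignore.case = TRUE)
  human <- grepl("species:\\s*(9606|homo sapiens|human)", annotation, ignore.case = TRUE)
  has_species & !human
}

#' Filter interaction records by confidence score
#'
#' Keeps records whose confidence is greater than or equal to `threshold`
#' (inclusive, so the canonical medium-confidence cut of 0.63 retains
#' interactions scored exactly 0.63). Row order is preserved.
#'
#' @param records A data frame with a `confidence` column, e.g. from
#'   [read_hippie()].
#' @param threshold Minimum confidence to keep, in \[0, 1\]. Default 0.63,
#'   HIPPIE's medium-confidence level; 0.73 is the high-confidence level.
#' @return The filtered tibble.
#' @export
filter_by_confidence <- function(records, threshold = 0.63) {
  stopifnot(is.data.frame(records), "confidence" %in% names(records))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single number in [0, 1]")
  }
  dplyr::filter(tibble::as_tibble(records), .data$confidence >= threshold)
}

#' Build an interactome graph from interaction records
#'
#' Turns a table of scored interactions into an undirected igraph object.
#' Self-interactions are dropped and duplicate node pairs (in either
#' orientation) are collapsed, keeping the maximum confidence — the
#' most-supported evidence wins.
#'
#' @param records A data frame with columns `protein_a`, `protein_b` and
#'   optionally `confidence` (assumed 1 if absent).
#' @return An undirected, simple igraph object with a `confidence` edge
#'   attribute. Node and edge counts are reported via [igraph::vcount()] and
#'   [igraph::ecount()].
#' @export
#' @examples
#' recs <- tibble::tibble(protein_a = c("a", "b"), protein_b = c("b", "a"),
#'                        confidence = c(0.7, 0.9))
#' g <- build_interactome(recs)
#' igraph::ecount(g)  # 1 edge, confidence 0.9
build_interactome <- function(records) {
  stopifnot(is.data.frame(records))
  nm <- names(records)
  if (!all(c("protein_a", "protein_b") %in% nm)) {
    if (all(c("node_a", "node_b") %in% nm)) {
      records <- dplyr::rename(records, protein_a = "node_a", protein_b = "node_b")
    } else {
      abort("`records` must have columns protein_a/protein_b (or node_a/node_b)")
    }
  }
  if (!"confidence" %in% names(records)) records$confidence <- 1
  edges <- tibble::tibble(
    a = as.character(records$protein_a),
    b = as.character(records$protein_b),
    confidence = as.numeric(records$confidence)
  )
  edges <- dplyr::filter(edges, .data$a != .data$b)
  if (nrow(edges) == 0) {
    abort("no edges survive self-loop removal; cannot build an interactome")
  }
  # canonical orientation so (a,b) and (b,a) collapse together
  flip <- edges$a > edges$b
  tmp <- edges$a[flip]; edges$a[flip] <- edges$b[flip]; edges$b[flip] <- tmp
  edges <- edges |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  stopifnot(igraph::is_simple(g))
  g
}

#' Dump an interactome as a sorted three-column edge table
#'
#' The companion to [build_interactome()]: returns edges as
#' `(node_a, node_b, confidence)` with `node_a < node_b` and rows sorted
#' lexicographically, so repeated dumps of the same graph are bit-identical.
#'
#' @param g An igraph interactome.
#' @return A tibble with columns `node_a`, `node_b`, `confidence`.
#' @export
interactome_edges <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  conf <- igraph::edge_attr(g, "confidence") %||% rep(1, nrow(el))
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  tibble::tibble(node_a = a, node_b = b, confidence = conf) |>
    dplyr::arrange(.data$node_a, .data$node_b)
}

#' Write / read a three-column edge list
#'
#' Plain TSV with columns `node_a`, `node_b`, `confidence`, as produced by
#' [interactome_edges()].
#'
#' @param g An igraph interactome (for writing).
#' @param file Path to the TSV file.
#' @return `write_edge_list()` returns `file` invisibly; `read_edge_list()`
#'   returns an igraph interactome.
#' @export
write_edge_list <- function(g, file) {
  readr::write_tsv(interactome_edges(g), file)
  invisible(file)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(file) {
  tbl <- readr::read_tsv(file, show_col_types = FALSE)
  build_interactome(dplyr::rename(tbl, protein_a = "node_a", protein_b = "node_b"))
}

#' Read a plain gene list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored; surrounding whitespace is trimmed.
#'
#' @param file Path to the list file.
#' @return A character vector of identifiers.
#' @export
read_gene_list <- function(file) {
  lines <- trimws(readr::read_lines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines
}

#' Shortest hop distances from source nodes to a target set
#'
#' Unweighted breadth-first hop counts from each source to its nearest target.
#' Unreachable sources are reported as `Inf`, never dropped. With
#' `exclude_self = TRUE` a node that is itself a target looks for the nearest
#' *other* target (the convention used by the localization statistics).
#'
#' @param g An igraph interactome.
#' @param sources,targets Character vectors of node names, subsets of the
#'   graph's nodes.
#' @param exclude_self Logical; if `TRUE`, a source does not count itself as a
#'   target (default `FALSE`, so a source inside `targets` is at distance 0).
#' @return A named numeric vector, one entry per source (`Inf` =
#'   unreachable).
#' @export
#' @examples
#' g <- igraph::make_graph(~ a - b - c - d - e)
#' shortest_distances(g, "a", "d")  # a: 3
shortest_distances <- function(g, sources, targets, exclude_self = FALSE) {
  nodes <- igraph::V(g)$name
  missing_s <- setdiff(sources, nodes)
  missing_t <- setdiff(targets, nodes)
  if (length(missing_s) > 0 || length(missing_t) > 0) {
    abort(paste0("identifiers not in graph: ",
                 paste(unique(c(missing_s, missing_t)), collapse = ", ")))
  }
  d <- igraph::distances(g, v = sources, to = targets)
  if (exclude_self) {
    self <- outer(rownames(d), colnames(d), "==")
    d[self] <- Inf
  }
  res <- apply(d, 1, min)
  stats::setNames(as.numeric(res), sources)
}

#' Degree histogram of an interactome
#'
#' @param g An igraph interactome (non-empty).
#' @return A tibble with columns `degree` and `n_nodes`; `sum(n_nodes)`
#'   equals the node count. A log-log view of this table is the standard
#'   check for the power-law decay expected of a scale-free interactome
#'   (see [plot_degree_distribution()]).
#' @export
degree_histogram <- function(g) {
  if (igraph::vcount(g) == 0) abort("empty graph")
  deg <- igraph::degree(g)
  tibble::tibble(degree = as.integer(names(table(deg))),
                 n_nodes = as.integer(table(deg))) |>
    dplyr::arrange(.data$degree)
}

# nearest-other-member hop distances used by localization and separation;
# returns list(dist = named numeric over `from`, n_unreachable = int)
nearest_member_distances <- function(g, from, to, exclude_self) {
  d <- igraph::distances(g, v = from, to = to)
  if (exclude_self) {
    self <- outer(rownames(d), colnames(d), "==")
    d[self] <- Inf
  }
  mins <- apply(d, 1, min)
  list(dist = stats::setNames(as.numeric(mins), from),
       n_unreachable = sum(!is.finite(mins)))
}
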