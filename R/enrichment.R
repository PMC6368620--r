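#' Construct a pathway collection
#'
#' Named gene sets with per-set source tags and a background universe.
#' Sets are harmonized against the background (genes outside it are
#' dropped); sets left empty are removed.
#'
#' @param sets Named list of character vectors.
#' @param background Character vector: the gene universe. Defaults to the
#'   union of all sets.
#' @param source Named character vector of source tags per set (recycled if
#'   length 1).
#' @return A `pathway_db`: list with `sets`, `source`, `background`.
#' @export
pathway_db <- function(sets, background = NULL, source = "custom") {
  stopifnot(is.list(sets), length(sets) > 0)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) abort("`sets` must be named")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(background)) background <- unique(unlist(sets, use.names = FALSE))
  background <- unique(as.character(background))
  sets <- lapply(sets, intersect, y = background)
  if (length(source) == 1) source <- stats::setNames(rep(source, length(sets)), names(sets))
  keep <- lengths(sets) > 0
  if (any(!keep)) {
    inform(sprintf("pathway_db: dropped %d empty set(s) after harmonization", sum(!keep)))
  }
  structure(list(sets = sets[keep], source = source[names(sets)[keep]],
                 background = background),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("Pathway collection: %d sets (sizes %d-%d) over %d background genes\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              length(x$background)))
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' GMT lines are tab-separated: set name, description, then one or more
#' genes. Duplicate genes within a set are collapsed; empty lines are
#' skipped with a warning; a line with fewer than three fields is an error
#' naming the line number.
#'
#' @param file Path to the GMT file.
#' @param background Optional background universe passed to
#'   [pathway_db()].
#' @param source Source tag for all sets in the file.
#' @return `read_gmt()` returns a `pathway_db`; `write_gmt()` returns
#'   `file` invisibly.
#' @export
read_gmt <- function(file, background = NULL, source = NULL) {
  lines <- readr::read_lines(file)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warn(sprintf("read_gmt: skipped %d empty line(s)", sum(blank)))
  }
  idx <- which(!blank)
  if (length(idx) == 0) abort("GMT file contains no gene sets")
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    abort(sprintf("malformed GMT line %d: expected name, description and >= 1 gene",
                  idx[which(short)[1]]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  pathway_db(sets, background = background,
             source = source %||% basename(file))
}

#' @rdname read_gmt
#' @param db A `pathway_db`.
#' @export
write_gmt <- function(db, file) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- vapply(names(db$sets), function(nm) {
    paste(c(nm, unname(db$source[nm]), db$sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, file)
  invisible(file)
}

#' Module-set algebra over two expanded disease modules
#'
#' The six gene sets used for pathway comparison of two expanded modules:
#' each module, their intersection (the shared *core*), their union (the
#' disease *spectrum*), and the two exclusive differences. Set sizes obey
#' `|spectrum| = |cmt2| + |hsp| - |core|`.
#'
#' @param cmt2_expanded,hsp_expanded `expanded_module` objects (or character
#'   vectors of members). Argument names follow the canonical two-disease
#'   use case; any two modules work.
#' @return A `module_sets`: list of the six character vectors (`cmt2`,
#'   `hsp`, `core`, `spectrum`, `cmt2_only`, `hsp_only`) plus a `sizes`
#'   tibble.
#' @export
module_sets <- function(cmt2_expanded, hsp_expanded) {
  members <- function(x) {
    if (inherits(x, "diamond_result")) x <- x$module
    if (inherits(x, "expanded_module")) x$all_members else unique(as.character(x))
  }
  cmt2 <- members(cmt2_expanded)
  hsp <- members(hsp_expanded)
  if (length(cmt2) == 0 || length(hsp) == 0) abort("both modules must be non-empty")
  out <- list(
    cmt2 = cmt2,
    hsp = hsp,
    core = intersect(cmt2, hsp),
    spectrum = union(cmt2, hsp),
    cmt2_only = setdiff(cmt2, hsp),
    hsp_only = setdiff(hsp, cmt2)
  )
  out$sizes <- tibble::tibble(set = names(out), size = lengths(out))
  structure(out, class = "module_sets")
}

#' @export
print.module_sets <- function(x, ...) {
  cat("Module sets:\n")
  print(x$sizes)
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway set, tests whether the query gene set overlaps it more
#' than expected when drawing `|query|` genes at random from the background
#' universe: upper-tail hypergeometric p-value for the observed overlap,
#' Benjamini-Hochberg FDR across all tested pathways, and the enrichment
#' ratio (observed / expected overlap). The background should be the gene
#' universe the query was drawn from — for interactome-derived modules, the
#' interactome's genes, not the genome.
#'
#' @param query Character vector of genes (will be intersected with the
#'   background).
#' @param db A `pathway_db`.
#' @param background Optional override of the database background.
#' @return A tibble (one row per pathway): `pathway`, `source`, `overlap`,
#'   `set_size`, `query_size`, `background_size`, `p_value`, `fdr`,
#'   `enrichment_ratio`, plus an `overlap_genes` list-column. Sorted by
#'   p-value; re-sort by `overlap` or `enrichment_ratio` as needed.
#' @export
#' @examples
#' db <- generate_gmt(5, 10, 200, rng_seed = 1)
#' ora(db$sets[[1]][1:6], db)
ora <- function(query, db, background = NULL) {
  stopifnot(inherits(db, "pathway_db"))
  bg <- unique(as.character(background %||% db$background))
  query <- unique(as.character(query))
  query_in <- intersect(query, bg)
  if (length(query_in) == 0) abort("query and background share no genes")
  if (length(query_in) < length(query)) {
    inform(sprintf("ora: %d query gene(s) outside the background ignored",
                   length(query) - length(query_in)))
  }
  n_bg <- length(bg)
  n_q <- length(query_in)
  rows <- purrr::map_dfr(names(db$sets), function(nm) {
    set <- intersect(db$sets[[nm]], bg)
    hit <- intersect(query_in, set)
    m <- length(set)
    ov <- length(hit)
    p <- if (ov == 0) 1 else phyper(ov - 1, m, n_bg - m, n_q, lower.tail = FALSE)
    expected <- n_q * m / n_bg
    tibble::tibble(
      pathway = nm,
      source = unname(db$source[nm]),
      overlap = ov,
      set_size = m,
      query_size = n_q,
      background_size = n_bg,
      p_value = p,
      enrichment_ratio = if (expected > 0) ov / expected else 0,
      overlap_genes = list(hit)
    )
  })
  rows$fdr <- p.adjust(rows$p_value, method = "BH")
  rows |>
    dplyr::relocate("fdr", .after = "p_value") |>
    dplyr::arrange(.data$p_value, dplyr::desc(.data$overlap))
}

#' Filter enrichment rows by FDR
#'
#' Keeps rows with `fdr <= threshold` (inclusive, so the canonical
#' `FDR <= 0.2` cut retains rows at exactly 0.2). An empty result is
#' returned, not an error, when nothing passes.
#'
#' @param rows A tibble from [ora()].
#' @param threshold FDR cutoff (default 0.2).
#' @return The filtered tibble.
#' @export
filter_fdr <- function(rows, threshold = 0.2) {
  stopifnot("fdr" %in% names(rows))
  dplyr::filter(rows, .data$fdr <= threshold)
}

#' Group enriched pathways by gene overlap
#'
#' Builds a pathway-similarity graph connecting two pathways when the
#' Jaccard coefficient of their gene sets exceeds `j_min` (strictly), and
#' returns its connected components — redundant pathways collapse into one
#' group, the structure an enrichment map visualizes.
#'
#' @param rows Significant enrichment rows (from [filter_fdr()]); must have
#'   a `pathway` column.
#' @param db The `pathway_db` the rows came from.
#' @param j_min Jaccard threshold (default 0.1; edges require `J > j_min`).
#' @return A tibble with columns `pathway`, `component` (integer group id)
#'   and `component_size`.
#' @export
pathway_jaccard_groups <- function(rows, db, j_min = 0.1) {
  stopifnot(inherits(db, "pathway_db"), "pathway" %in% names(rows))
  ids <- unique(rows$pathway)
  if (length(ids) == 0) abort("no significant pathways to group")
  sets <- db$sets[ids]
  k <- length(ids)
  edges <- NULL
  if (k > 1) {
    pairs <- combn(k, 2)
    jac <- apply(pairs, 2, function(ij) {
      a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
      length(intersect(a, b)) / length(union(a, b))
    })
    keep <- jac > j_min
    edges <- cbind(ids[pairs[1, keep]], ids[pairs[2, keep]])
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges %||% matrix(character(0), 0, 2)),
    directed = FALSE,
    vertices = ids
  )
  comp <- igraph::components(g)
  tibble::tibble(
    pathway = igraph::V(g)$name,
    component = as.integer(comp$membership),
    component_size = as.integer(comp$csize[comp$membership])
  ) |>
    dplyr::arrange(.data$component, .data$pathway)
}

#' Assign enriched pathways to the dominant disease module
#'
#' Classifies each pathway that is significant in at least one of the six
#' module sets by the combination of *exclusive* sets it is significant in:
#'
#' * significant in `cmt2_only` but not `hsp_only` -> `"CMT2-dominant"`;
#' * significant in `hsp_only` but not `cmt2_only` -> `"HSP-dominant"`;
#' * any other significant combination (core, spectrum, full modules, or
#'   both exclusive sets) -> `"AXONO"` (the shared spectrum).
#'
#' Pathways significant nowhere are excluded from the output.
#'
#' @param ora_results Named list of [ora()] tibbles, with names containing
#'   at least `cmt2_only` and `hsp_only` (typically all six:
#'   `cmt2`, `hsp`, `core`, `spectrum`, `cmt2_only`, `hsp_only`).
#' @param fdr_threshold Significance cutoff applied to each table
#'   (default 0.2, inclusive).
#' @return A tibble with columns `pathway`, `dominance`, and one logical
#'   column `sig_<set>` per input table.
#' @export
assign_dominance <- function(ora_results, fdr_threshold = 0.2) {
  stopifnot(is.list(ora_results), !is.null(names(ora_results)))
  if (!all(c("cmt2_only", "hsp_only") %in% names(ora_results))) {
    abort("`ora_results` must include tables named 'cmt2_only' and 'hsp_only'")
  }
  sig_sets <- lapply(ora_results, function(rows) filter_fdr(rows, fdr_threshold)$pathway)
  pathways <- sort(unique(unlist(sig_sets, use.names = FALSE)))
  if (length(pathways) == 0) {
    return(tibble::tibble(pathway = character(0), dominance = character(0)))
  }
  flags <- lapply(sig_sets, function(s) pathways %in% s)
  names(flags) <- paste0("sig_", names(sig_sets))
  dominance <- dplyr::case_when(
    flags$sig_cmt2_only & !flags$sig_hsp_only ~ "CMT2-dominant",
    flags$sig_hsp_only & !flags$sig_cmt2_only ~ "HSP-dominant",
    .default = "AXONO"
  )
  dplyr::bind_cols(tibble::tibble(pathway = pathways, dominance = dominance),
                   tibble::as_tibble(flags))
}
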