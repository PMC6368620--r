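#' Tidy and glance methods for axonmod result objects
#'
#' Broom-style accessors: `tidy()` returns the element-level table natural
#' to each result (per-seed distances, per-iteration incorporations, per-set
#' sizes), `glance()` a one-row summary of the test or fit.
#'
#' @param x An axonmod result object.
#' @param ... Unused.
#' @return A tibble.
#' @name axonmod_tidiers
NULL

#' @rdname axonmod_tidiers
#' @export
tidy.seed_set <- function(x, ...) {
  tibble::tibble(
    identifier = x$listed,
    status = ifelse(x$listed %in% x$mapped, "mapped", "dropped")
  )
}

#' @rdname axonmod_tidiers
#' @export
glance.seed_set <- function(x, ...) {
  tibble::tibble(name = x$name, n_listed = length(x$listed),
                 n_mapped = length(x$mapped), n_dropped = length(x$dropped))
}

#' @rdname axonmod_tidiers
#' @export
tidy.lcc_result <- function(x, ...) {
  tibble::tibble(null_lcc_size = x$null_sizes)
}

#' @rdname axonmod_tidiers
#' @export
glance.lcc_result <- function(x, ...) {
  tibble::tibble(
    seed_name = x$seed_name,
    n_mapped = x$n_mapped,
    observed_size = x$observed_size,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    z_score = x$z_score,
    empirical_p = x$empirical_p,
    proto_module = x$proto_module,
    n_randomizations = x$n_randomizations,
    null_model = x$null_model
  )
}

#' @rdname axonmod_tidiers
#' @export
tidy.proximity_result <- function(x, ...) {
  tibble::tibble(
    seed = names(x$observed_ds),
    distance = unname(x$observed_ds),
    reachable = is.finite(unname(x$observed_ds))
  )
}

#' @rdname axonmod_tidiers
#' @export
glance.proximity_result <- function(x, ...) {
  tibble::tibble(
    seed_name = x$seed_name %||% NA_character_,
    n_seeds = length(x$observed_ds),
    mean_ds = x$mean_ds,
    n_excluded_unreachable = x$n_excluded_unreachable,
    u_statistic = x$u_statistic,
    p_value = x$p_value,
    method = x$method %||% NA_character_,
    n_randomizations = x$n_randomizations
  )
}

#' @rdname axonmod_tidiers
#' @export
tidy.separation_result <- function(x, ...) {
  tibble::tibble(null_s_AB = x$null_scores)
}

#' @rdname axonmod_tidiers
#' @export
glance.separation_result <- function(x, ...) {
  tibble::tibble(
    set_a = x$name_a, set_b = x$name_b,
    size_a = x$size_a, size_b = x$size_b,
    d_AA = x$d_AA, d_BB = x$d_BB, d_AB = x$d_AB,
    s_AB = x$s_AB,
    z_score = x$z_score, p_value = x$p_value,
    overlap_nodes = x$overlap_nodes,
    classification = x$classification,
    null_model = x$null_model,
    n_randomizations = x$n_randomizations
  )
}

#' @rdname axonmod_tidiers
#' @export
tidy.diamond_result <- function(x, ...) {
  x$steps
}

#' @rdname axonmod_tidiers
#' @export
glance.diamond_result <- function(x, ...) {
  m <- x$module
  tibble::tibble(
    seed_name = m$seed_name,
    omega = m$omega,
    n_seeds = length(m$seeds_mapped),
    n_added = length(m$diamond_nodes),
    n_members = length(m$all_members),
    last_p_value = if (nrow(x$steps) > 0) x$steps$p_value[nrow(x$steps)] else NA_real_
  )
}

#' @rdname axonmod_tidiers
#' @export
tidy.module_sets <- function(x, ...) {
  x$sizes
}

#' @rdname axonmod_tidiers
#' @export
tidy.planted_scenario <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(module = "A", member = x$module_a$mapped),
    tibble::tibble(module = "B", member = x$module_b$mapped)
  ) |>
    dplyr::mutate(shared = .data$member %in% intersect(x$module_a$mapped,
                                                       x$module_b$mapped))
}
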