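# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a free-energy profile
#' @param x An `fe_profile` from [wham()].
#' @param ... Unused.
#' @return A tibble with `d`, `G`, `error` (finite bins only).
#' @export
tidy.fe_profile <- function(x, ...) {
  dplyr::filter(x$profile, is.finite(.data$G))
}

#' @rdname tidy.fe_profile
#' @return For `glance()`: one row with `n_bins`, `bin_width`, `iterations`,
#'   `converged`, `temperature`, `kT`.
#' @export
glance.fe_profile <- function(x, ...) {
  tibble::tibble(n_bins = sum(is.finite(x$profile$G)),
                 bin_width = x$bin_width, iterations = x$iterations,
                 converged = x$converged,
                 temperature = x$thermo$temperature, kT = x$thermo$kT)
}

#' Tidy a contact table
#' @param x A `contact_table` from [contact_map()].
#' @param ... Unused.
#' @return The underlying tibble, one row per contact pair.
#' @export
tidy.contact_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.contact_table
#' @return For `glance()`: one row with `n_pairs`, `n_recurrent`,
#'   `n_non_stable`, `cutoff`, `threshold`, `n_frames`.
#' @export
glance.contact_table <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x),
                 n_recurrent = sum(x$label == "recurrent"),
                 n_non_stable = sum(x$label == "non-stable"),
                 cutoff = attr(x, "cutoff"),
                 threshold = attr(x, "threshold"),
                 n_frames = if (nrow(x)) x$n_frames[1] else NA_integer_)
}

#' Tidy a dynamic network
#' @param x A `dynamic_network` from [build_network()].
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `weight`, `correlation`,
#'   `occupancy`).
#' @export
tidy.dynamic_network <- function(x, ...) x$edges

#' @rdname tidy.dynamic_network
#' @return For `glance()`: one row with `n_nodes`, `n_edges`,
#'   `n_components`, `persistence`, `cutoff`.
#' @export
glance.dynamic_network <- function(x, ...) {
  g <- as_igraph(x)
  tibble::tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
                 n_components = igraph::count_components(g),
                 persistence = x$persistence, cutoff = x$cutoff)
}

#' Tidy an umbrella dataset
#' @param x An [umbrella_dataset()].
#' @param ... Unused.
#' @return A tibble with one row per window: `window`, `center`, `k`, `n`,
#'   `mean`, `sd` of the sampled coordinate.
#' @export
tidy.umbrella_dataset <- function(x, ...) {
  w <- x$windows
  tibble::tibble(window = seq_len(nrow(w)), center = w$center, k = w$k,
                 n = w$n,
                 mean = vapply(w$samples, mean, numeric(1)),
                 sd = vapply(w$samples, stats::sd, numeric(1)))
}

#' @rdname tidy.umbrella_dataset
#' @return For `glance()`: one row with `n_windows`, `n_samples`,
#'   `temperature`, `sample_period`.
#' @export
glance.umbrella_dataset <- function(x, ...) {
  tibble::tibble(n_windows = nrow(x$windows),
                 n_samples = sum(x$windows$n),
                 temperature = x$thermo$temperature,
                 sample_period = x$sample_period)
}

#' Tidy a groove profile
#' @param x A `groove_profile` from [groove_widths()].
#' @param ... Unused.
#' @return The per-level summary tibble in long form: `level`, `groove`,
#'   `width`, `se`.
#' @export
tidy.groove_profile <- function(x, ...) {
  s <- x$summary
  dplyr::bind_rows(
    tibble::tibble(level = s$level, groove = "minor", width = s$minor,
                   se = s$minor_se),
    tibble::tibble(level = s$level, groove = "major", width = s$major,
                   se = s$major_se))
}
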