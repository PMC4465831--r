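# ggplot2 autoplot methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a free-energy profile
#'
#' G(d_min) with a +/- 1 error ribbon when per-bin errors are available.
#'
#' @param object An `fe_profile` from [wham()] (optionally [wham_error()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fe_profile <- function(object, ...) {
  tab <- tidy(object)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$d, y = .data$G))
  if (any(is.finite(tab$error)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$G - .data$error,
                   ymax = .data$G + .data$error),
      fill = "grey70", alpha = 0.6)
  p + ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = expression(d[min] ~ "(Å)"),
                  y = "G (kcal/mol)",
                  title = "Unbinding free energy profile")
}

#' Plot per-residue contact counts
#'
#' Bar chart of recurrent contact counts per protein residue, split by DNA
#' base/backbone partner.
#'
#' @param object A `contact_table` from [contact_map()].
#' @param which Passed to [per_residue_profile()] (default `"recurrent"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_table <- function(object, which = "recurrent", ...) {
  prof <- per_residue_profile(object, which = which)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$residue,
                                     y = .data$n_contacts,
                                     fill = .data$dna_class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "protein residue", y = "contacts",
                  fill = "DNA partner",
                  title = paste0("Per-residue ", which,
                                 " protein-DNA contacts"))
}

#' Plot a Rock/Tumble distribution
#'
#' 2D histogram of orientation samples (default 2 degree bins).
#'
#' @param object An `orientation_samples` tibble from [rock_tumble()].
#' @param bin Bin width in degrees (default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.orientation_samples <- function(object, bin = 2, ...) {
  h <- orientation_histogram(object, bin = bin)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$tumble_bin, y = .data$rock_bin,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "Tumble (deg)", y = "Rock (deg)", fill = "frames",
                  title = "Docking-helix orientation")
}

#' Plot groove widths along the duplex
#'
#' Mean minor/major groove width per base-pair level with +/- 1 SE ribbons.
#'
#' @param object A `groove_profile` from [groove_widths()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.groove_profile <- function(object, ...) {
  tab <- dplyr::filter(tidy(object), is.finite(.data$width))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$level, y = .data$width,
                                    colour = .data$groove,
                                    fill = .data$groove)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$width - .data$se,
                                      ymax = .data$width + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "base-pair level", y = "groove width (Å)",
                  title = "DNA groove widths",
                  subtitle = object$convention)
}
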