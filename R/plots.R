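#' Plot methods
#'
#' ggplot2 visualisations of the package's result objects: score
#' distributions for a catalog (latent sites vs annotated donors), a volcano
#' view of activation calls, and the composite exon-extension fold profile
#' with its confidence band.
#'
#' @importFrom ggplot2 autoplot
#' @name plots
NULL

#' @describeIn plots Score distributions of catalog sites and annotated donors.
#' @param object,x The object to plot.
#' @param ... Unused.
#' @method autoplot lss_catalog
#' @export
autoplot.lss_catalog <- function(object, ...) {
  donors <- attr(object, "donors")
  df <- bind_rows(
    tibble(score = object$score, group = object$site_class),
    if (!is.null(donors) && nrow(donors) > 0) {
      tibble(score = donors$score, group = "annotated 5'SS")
    }
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, colour = .data$group)) +
    ggplot2::geom_density() +
    ggplot2::labs(
      x = "donor score (log2 odds)", y = "density", colour = NULL,
      title = "Donor score distributions"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plots Extension-length distribution per site class.
#' @param catalog An `lss_catalog`.
#' @export
plot_extension_lengths <- function(catalog) {
  ggplot2::ggplot(
    as_tibble(catalog),
    ggplot2::aes(x = .data$extension_length, fill = .data$site_class)
  ) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "exon extension (nt)", y = "sites", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plots Volcano view of activation calls (geometric-mean usage
#'   fold vs combined p).
#' @method autoplot activation_calls
#' @export
autoplot.activation_calls <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(.data$defined) |>
    mutate(fold_plot = pmin(.data$fold_geomean, 64))
  ggplot2::ggplot(df, ggplot2::aes(
    x = log2(.data$fold_plot), y = -log10(.data$combined_p),
    colour = .data$called
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$site_class)) +
    ggplot2::labs(
      x = "log2 usage fold (geometric mean)", y = "-log10 combined p",
      colour = "called"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plots Composite median fold profile with 95% CI band.
#' @method autoplot composite_profile
#' @export
autoplot.composite_profile <- function(object, ...) {
  ggplot2::ggplot(object$composite, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median_fold)) +
    ggplot2::labs(
      x = "position in exon extension (nt)",
      y = "median coverage fold (case / control)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.lss_catalog <- function(x, ...) print(autoplot.lss_catalog(x, ...))

#' @export
plot.activation_calls <- function(x, ...) print(autoplot.activation_calls(x, ...))

#' @export
plot.composite_profile <- function(x, ...) print(autoplot.composite_profile(x, ...))
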