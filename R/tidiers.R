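#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mesh quality report
#'
#' @param x a [dihedral_quality()] report.
#' @param ... unused.
#' @return the histogram tibble (`bin`, `count`, `fraction`).
#' @export
tidy.quality_report <- function(x, ...) x$histogram

#' One-row summary of a mesh quality report
#'
#' @param x a [dihedral_quality()] report.
#' @param ... unused.
#' @return tibble with `mean_distortion`, `max_distortion`,
#'   `fraction_below_20`, `n_elements`, `n_nodes`.
#' @export
glance.quality_report <- function(x, ...) {
  tibble::tibble(
    mean_distortion = x$mean,
    max_distortion = x$max,
    fraction_below_20 = mean(x$distortions < 20),
    n_elements = x$n_elements,
    n_nodes = x$n_nodes)
}

#' Tidy a finite-element result
#'
#' @param x an [assemble_and_solve()] result.
#' @param ... unused.
#' @return tibble of nodal displacements (`node`, `ux`, `uy`, `uz`,
#'   `magnitude`, in mm).
#' @export
tidy.fe_result <- function(x, ...) {
  tibble::tibble(node = seq_len(nrow(x$u)),
                 ux = x$u[, 1], uy = x$u[, 2], uz = x$u[, 3],
                 magnitude = sqrt(rowSums(x$u^2)))
}

#' One-row summary of a finite-element result
#'
#' @param x an [assemble_and_solve()] result.
#' @param ... unused.
#' @return tibble with global maxima and the equilibrium residual.
#' @export
glance.fe_result <- function(x, ...) {
  tibble::tibble(
    max_displacement = max(sqrt(rowSums(x$u^2))),
    max_principal_stress = max(principal_values_batch(x$stress)[1, ]),
    max_principal_strain = max(principal_values_batch(
      x$strain, shear_engineering = TRUE)[1, ]),
    max_equivalent_strain = max(equivalent_strain(x$strain)),
    equilibrium_residual = x$equilibrium_residual)
}

#' Tidy a comparison study
#'
#' @param x a [run_comparison_study()] result.
#' @param ... unused.
#' @return the model x region metrics tibble.
#' @export
tidy.comparison_study <- function(x, ...) x$table

#' Histogram plot of dihedral-angle distortions
#'
#' @param object a [dihedral_quality()] report.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.quality_report <- function(object, ...) {
  h <- object$histogram
  h$bin <- factor(h$bin, levels = h$bin)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin, y = 100 * .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "dihedral distortion (degrees)",
                  y = "share of element edges (%)",
                  title = sprintf("mean %.1f deg, max %.1f deg",
                                  object$mean, object$max)) +
    ggplot2::theme_minimal()
}

#' Region-maxima plot for a comparison study
#'
#' @param object a [run_comparison_study()] result.
#' @param metric one of the metric column names (default
#'   `"max_displacement"`).
#' @param ... unused.
#' @return a ggplot of the metric per model, coloured by region.
#' @export
autoplot.comparison_study <- function(object, metric = "max_displacement",
                                      ...) {
  tab <- object$table
  tab$model <- factor(tab$model, levels = unique(tab$model))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$model,
                                    y = .data[[metric]],
                                    group = .data$region,
                                    colour = .data$region)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
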