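# Tidiers and plots for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an energy report into one row per labeled component
#'
#' @param x A `qmmm_energy` from one of the `assemble_*()` functions.
#' @param ... Unused.
#' @return Tibble: `component`, `energy` (kJ/mol), plus the total as an
#'   attribute-free final row is *not* included; use [glance.qmmm_energy()].
#' @export
tidy.qmmm_energy <- function(x, ...) {
  tibble::tibble(component = names(x$components),
                 energy = unname(x$components))
}

#' One-row summary of an energy report
#'
#' @inheritParams tidy.qmmm_energy
#' @return Tibble: `total` (kJ/mol), `embedding`, `formulation`, `scheme`
#'   (NA when not applicable), `backend`, `n_components`.
#' @export
glance.qmmm_energy <- function(x, ...) {
  tibble::tibble(
    total = x$total,
    embedding = x$variant$embedding,
    formulation = x$variant$formulation,
    scheme = x$variant$scheme %||% NA_character_,
    backend = x$variant$backend %||% NA_character_,
    n_components = length(x$components)
  )
}

#' Tidy a point-charge model
#'
#' @param x A `qmmm_point_charges` from [apply_scheme()].
#' @param ... Unused.
#' @return The underlying tibble with the scheme recorded in a column.
#' @export
tidy.qmmm_point_charges <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$scheme <- attr(x, "scheme")
  out
}

#' @rdname tidy.qmmm_point_charges
#' @export
glance.qmmm_point_charges <- function(x, ...) {
  out <- model_summary(x)
  out$scheme <- attr(x, "scheme")
  out
}

#' Plot an energy report as a component bar chart
#'
#' @param object A `qmmm_energy`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qmmm_energy <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$energy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      y = "energy (kJ/mol)", x = NULL,
      title = sprintf("%s %s: total %.3f kJ/mol", object$variant$embedding,
                      object$variant$formulation, object$total)) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot a point-charge model projected on the x-y plane
#'
#' Sites colored by charge, shaped by origin (atom, midpoint, shift pair).
#'
#' @param object A `qmmm_point_charges`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qmmm_point_charges <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$charge,
                                   shape = .data$origin)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_gradient2(low = "firebrick", mid = "grey85",
                                   high = "navy", midpoint = 0) +
    ggplot2::labs(title = sprintf("point-charge model (%s)",
                                  attr(object, "scheme")),
                  x = "x (Å)", y = "y (Å)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
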