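#' Mother-offspring FID scatter
#'
#' Offspring mean subadult FID against rearing-mother mean adult FID, with
#' an ordinary least-squares line; cross-fostered offspring are highlighted.
#'
#' @param object Output of [fid_mother_offspring_means()] (or an
#'   observation table, which is converted first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fid_means <- function(object, ...) {
  plot_mother_offspring_fid(object)
}

#' @rdname autoplot.fid_means
#' @param table Observation table or precomputed means tibble.
#' @export
plot_mother_offspring_fid <- function(table) {
  d <- if (all(c("offspring_fid", "rearing_mother_fid") %in% names(table))) {
    table
  } else {
    fid_mother_offspring_means(table)
  }
  d <- dplyr::filter(d, !is.na(.data$rearing_mother_fid))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rearing_mother_fid,
                                  y = .data$offspring_fid)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$adopted)) +
    ggplot2::labs(x = "mother mean FID (m)", y = "offspring mean FID (m)",
                  shape = "cross-fostered") +
    ggplot2::theme_minimal()
}

#' Posterior densities of repeatability ratios
#'
#' @param object A `variance_decomposition` from [decompose_variance()].
#' @param ... Unused.
#' @return A ggplot object showing the posterior density of each ratio with
#'   its posterior mode marked.
#' @export
autoplot.variance_decomposition <- function(object, ...) {
  draws <- attr(object, "draws")
  d <- tidyr::pivot_longer(tibble::as_tibble(draws), cols = dplyr::everything(),
                           names_to = "quantity", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(data = as.data.frame(object[, c("quantity", "posterior_mode")]),
                        ggplot2::aes(xintercept = .data$posterior_mode),
                        linetype = 2) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "proportion of variance", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Posterior trace plot for selected parameters
#'
#' @param fit An `mt_fit`.
#' @param parameters Character vector of parameter names (default: all
#'   (co)variance parameters).
#' @return A ggplot object.
#' @export
plot_traces <- function(fit, parameters = NULL) {
  d <- tidy(fit)
  parameters <- parameters %||%
    grep("^(G\\.|R\\.)", unique(d$parameter_name), value = TRUE)
  d <- dplyr::filter(d, .data$parameter_name %in% parameters)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter_name, scales = "free_y") +
    ggplot2::theme_minimal()
}
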