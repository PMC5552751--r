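# ggplot2 visualization for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a free-energy profile
#'
#' @param object an `egress_fes`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot egress_fes
#' @export
autoplot.egress_fes <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$grid, y = .data$F)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "collective variable", y = "F [kcal/mol]")
  if (!is.null(object$standard_error))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$F - .data$std_error,
                   ymax = .data$F + .data$std_error), alpha = 0.3)
  p
}

#' Plot metadynamics diagnostics
#'
#' Two standard views: the CV trajectory (`which = "colvar"`) or the
#' Gaussian-height convergence trace (`which = "heights"`).
#'
#' @param object an `egress_metad`.
#' @param which `"colvar"` or `"heights"`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot egress_metad
#' @export
autoplot.egress_metad <- function(object, which = c("colvar", "heights"), ...) {
  which <- match.arg(which)
  if (which == "colvar") {
    ggplot2::ggplot(object$colvar, ggplot2::aes(x = .data$time, y = .data$value)) +
      ggplot2::geom_line(linewidth = 0.2) +
      ggplot2::labs(x = "time [ps]", y = object$cv)
  } else {
    ggplot2::ggplot(object$bias$kernels,
                    ggplot2::aes(x = .data$time, y = .data$height)) +
      ggplot2::geom_point(size = 0.4) +
      ggplot2::labs(x = "time [ps]", y = "Gaussian height [kcal/mol]")
  }
}

#' Plot a conformational-state embedding
#'
#' 2-D MDS embedding colored by cluster; noise in grey, medoids marked.
#'
#' @param object an `egress_states`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot egress_states
#' @export
autoplot.egress_states <- function(object, ...) {
  df <- tidy(object)
  df$state <- factor(ifelse(df$cluster < 0, "noise", paste0("state ", df$cluster)))
  med <- df[df$frame %in% object$medoids$medoid, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   color = .data$state)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = med, shape = 4, size = 3, stroke = 1.5,
                        color = "black") +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", color = NULL)
}
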