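# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a free-energy profile
#'
#' @param x an `egress_fes`.
#' @param ... unused.
#' @return Tibble with columns `grid`, `F` and, when available, `std_error`.
#' @method tidy egress_fes
#' @export
tidy.egress_fes <- function(x, ...) {
  out <- tibble::tibble(grid = x$grid, F = x$F)
  if (!is.null(x$standard_error)) out$std_error <- x$standard_error
  out
}

#' @rdname tidy.egress_fes
#' @method glance egress_fes
#' @export
glance.egress_fes <- function(x, ...) {
  tibble::tibble(n_grid = length(x$grid), barrier = max(x$F),
                 bias_factor = x$bias_factor %||% NA_real_,
                 reweighted = isTRUE(x$reweighted))
}

#' Tidy a metadynamics run
#'
#' `tidy()` returns the recorded CV time series; `glance()` a one-row
#' convergence summary (kernel count, residual height fraction when at least
#' two kernels were deposited).
#'
#' @param x an `egress_metad`.
#' @param ... unused.
#' @method tidy egress_metad
#' @export
tidy.egress_metad <- function(x, ...) x$colvar

#' @rdname tidy.egress_metad
#' @method glance egress_metad
#' @export
glance.egress_metad <- function(x, ...) {
  k <- x$bias$kernels
  res <- if (nrow(k) >= 2)
    convergence_report(x$bias, blocks = 2)$residual_height_fraction
  else NA_real_
  tibble::tibble(cv = x$cv, n_kernels = nrow(k), n_frames = nrow(x$colvar),
                 residual_height_fraction = res,
                 barrier = if (!is.null(x$fes)) max(x$fes$F) else NA_real_)
}

#' Tidy a conformational-state decomposition
#'
#' `tidy()` returns the per-frame embedding with cluster labels; `glance()`
#' cluster counts and parameters.
#'
#' @param x an `egress_states`.
#' @param ... unused.
#' @method tidy egress_states
#' @export
tidy.egress_states <- function(x, ...) x$embedding

#' @rdname tidy.egress_states
#' @method glance egress_states
#' @export
glance.egress_states <- function(x, ...) {
  tibble::tibble(n_frames = nrow(x$embedding),
                 n_clusters = sum(x$occupancy$cluster >= 0),
                 noise_fraction = sum(x$occupancy$occupancy[x$occupancy$cluster < 0]),
                 eps = x$eps, min_pts = x$min_pts)
}

#' Tidy a path
#'
#' One row per node with the per-segment MSD to the previous node.
#'
#' @param x an `egress_path`.
#' @param ... unused.
#' @method tidy egress_path
#' @export
tidy.egress_path <- function(x, ...) {
  tibble::tibble(node = seq_along(x$nodes),
                 time = vapply(x$nodes, function(n) n$time %||% NA_real_, numeric(1)),
                 msd_prev = c(NA_real_, x$neighbor_msd))
}

#' @rdname tidy.egress_path
#' @method glance egress_path
#' @export
glance.egress_path <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes), lambda = x$lambda,
                 mean_neighbor_msd = x$mean_neighbor_msd,
                 complete = isTRUE(x$complete))
}
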