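# Well-tempered metadynamics: Gaussian bias bookkeeping, adaptive widths,
# the z upper wall, the time-independent free-energy estimator
# F = -((T+dT)/dT) V, c(t) reweighting, and convergence diagnostics.

#' Create a bias state
#'
#' Holds the deposited Gaussians plus the tempering parameters. The default
#' deposition rate (initial height x frequency) is 0.48 kcal/mol every
#' 0.25 ps = 1.92 kcal/mol per ps.
#'
#' @param kernels tibble with columns `time`, `center`, `width`, `height`
#'   (may be empty).
#' @param temperature simulation temperature T, K.
#' @param delta_t tempering parameter dT, K (> 0); bias factor = (T + dT)/T.
#' @param h0 initial Gaussian height, kcal/mol.
#' @param deposit_interval deposition period, ps.
#' @param adaptive_tau trailing time window for the adaptive width, ps.
#' @return Object of class `egress_bias`.
#' @export
bias_state <- function(kernels = NULL, temperature = 300, delta_t = 3300,
                       h0 = 0.48, deposit_interval = 0.25, adaptive_tau = 0.25) {
  if (delta_t <= 0) stop("delta_t must be > 0", call. = FALSE)
  if (is.null(kernels))
    kernels <- tibble::tibble(time = numeric(), center = numeric(),
                              width = numeric(), height = numeric())
  kernels <- tibble::as_tibble(kernels)
  if (nrow(kernels) > 0) {
    if (any(kernels$width <= 0)) stop("kernel widths must be > 0", call. = FALSE)
    if (any(kernels$height < 0)) stop("kernel heights must be >= 0", call. = FALSE)
  }
  structure(list(kernels = kernels, temperature = temperature,
                 delta_t = delta_t, h0 = h0,
                 deposit_interval = deposit_interval,
                 adaptive_tau = adaptive_tau),
            class = "egress_bias")
}

#' @export
print.egress_bias <- function(x, ...) {
  cat(sprintf("<egress_bias> %d kernels, T = %g K, dT = %g K (bias factor %.3g)\n",
              nrow(x$kernels), x$temperature, x$delta_t,
              (x$temperature + x$delta_t) / x$temperature))
  invisible(x)
}

#' Bias potential V(s)
#'
#' Sum of the deposited Gaussians at the given CV value(s); 0 for an empty
#' kernel list.
#'
#' @param bias an `egress_bias`.
#' @param s CV value(s).
#' @return V in kcal/mol (vectorized over `s`).
#' @export
bias_potential <- function(bias, s) {
  k <- bias$kernels
  if (nrow(k) == 0) return(rep(0, length(s)))
  vapply(s, function(si)
    sum(k$height * exp(-(si - k$center)^2 / (2 * k$width^2))), numeric(1))
}

bias_force_1d <- function(bias, s) {
  k <- bias$kernels
  if (nrow(k) == 0) return(rep(0, length(s)))
  vapply(s, function(si) {
    e <- k$height * exp(-(si - k$center)^2 / (2 * k$width^2))
    sum(e * (si - k$center) / k$width^2)   # -dV/ds
  }, numeric(1))
}

#' Deposit a well-tempered Gaussian
#'
#' Appends a kernel whose height follows the tempering rule
#' `h = h0 * exp(-V(s) / (kB * dT))`, with V evaluated before the deposition.
#'
#' @param bias an `egress_bias`.
#' @param s CV value at which to deposit.
#' @param width_now kernel width (> 0), typically from [adaptive_width()].
#' @param time deposition time, ps.
#' @return The updated `egress_bias`.
#' @export
deposit_gaussian <- function(bias, s, width_now, time = NA_real_) {
  if (width_now <= 0) stop("width_now must be > 0", call. = FALSE)
  h <- bias$h0 * exp(-bias_potential(bias, s) / (.kB * bias$delta_t))
  bias$kernels <- dplyr::bind_rows(bias$kernels,
    tibble::tibble(time = time, center = s, width = width_now, height = h))
  bias
}

#' Adaptive Gaussian width from the trailing CV history
#'
#' Width = standard deviation of the CV over the trailing window of length
#' `tau`, floored at `floor` to avoid spike kernels.
#'
#' @param cv_history tibble/data frame with columns `time` (ps) and `value`.
#' @param tau trailing window length, ps.
#' @param floor minimum width (CV units).
#' @return Width in CV units.
#' @export
adaptive_width <- function(cv_history, tau, floor = 0.01) {
  t <- cv_history$time; v <- cv_history$value
  if (diff(range(t)) < tau)
    stop("CV history does not span the adaptive window tau", call. = FALSE)
  win <- v[t > max(t) - tau]
  if (length(win) < 2)
    stop("adaptive window shorter than the sampling interval", call. = FALSE)
  max(stats::sd(win), floor)
}

#' One-sided harmonic wall on the path deviation z
#'
#' Zero below the limit; `0.5 * kappa * (z - limit)^2` above. The force is
#' continuous (C1) at the limit.
#'
#' @param z deviation value(s), A^2.
#' @param limit wall position, A^2 (default 6).
#' @param kappa wall stiffness, kcal/mol/A^4.
#' @return List with `energy` (kcal/mol) and `force` (-dE/dz, kcal/mol/A^2).
#' @export
z_wall_force <- function(z, limit = 6, kappa = 100) {
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  over <- pmax(z - limit, 0)
  list(energy = 0.5 * kappa * over^2, force = -kappa * over)
}

#' Time-independent free-energy estimator
#'
#' `F(s) = -((T + dT)/dT) * V(s)` on the grid, shifted so `min(F) = 0`.
#'
#' @param bias an `egress_bias` with at least one kernel.
#' @param grid strictly increasing CV grid.
#' @return Object of class `egress_fes`: list with `grid`, `F`,
#'   `standard_error` (NULL until [convergence_report()]), `reweighted`.
#' @export
free_energy_estimate <- function(bias, grid) {
  if (nrow(bias$kernels) == 0) stop("empty bias", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing", call. = FALSE)
  fac <- (bias$temperature + bias$delta_t) / bias$delta_t
  F <- -fac * bias_potential(bias, grid)
  F <- F - min(F)
  structure(list(grid = grid, F = F, standard_error = NULL, reweighted = FALSE,
                 bias_factor = (bias$temperature + bias$delta_t) / bias$temperature),
            class = "egress_fes")
}

#' @export
print.egress_fes <- function(x, ...) {
  cat(sprintf("<egress_fes> %d grid points, range F = [0, %.3g] kcal/mol%s\n",
              length(x$grid), max(x$F),
              if (isTRUE(x$reweighted)) " (reweighted)" else ""))
  invisible(x)
}

#' Interpolated free-energy value
#'
#' @param fes an `egress_fes`.
#' @param at CV value(s).
#' @return F at the requested point(s), kcal/mol.
#' @export
fes_value <- function(fes, at) {
  stats::approx(fes$grid, fes$F, xout = at, rule = 2)$y
}

# log of trapezoid integral of exp(a) on a uniform grid (log-sum-exp)
logtrapz <- function(a, dx) {
  w <- rep(1, length(a)); w[1] <- 0.5; w[length(a)] <- 0.5
  m <- max(a)
  m + log(sum(w * exp(a - m))) + log(dx)
}

#' Reweighting constant c(t)
#'
#' \deqn{c(t) = \frac{1}{\beta}\ln
#'   \frac{\int d\xi\, e^{-\beta F(\xi)}}{\int d\xi\, e^{-\beta[F(\xi)+V(\xi,t)]}}}
#' evaluated by trapezoid quadrature on the grid with log-sum-exp
#' stabilization. `F` defaults to the time-independent estimate from the full
#' bias; `V(.,t)` sums kernels deposited up to time `t`.
#'
#' @param bias an `egress_bias`.
#' @param grid strictly increasing CV grid (nonempty).
#' @param t time, ps.
#' @param F optional free-energy values on `grid` overriding the default.
#' @return c(t), kcal/mol.
#' @export
reweight_constant <- function(bias, grid, t, F = NULL) {
  if (length(grid) < 2) stop("grid must contain at least 2 points", call. = FALSE)
  if (is.null(F)) F <- free_energy_estimate(bias, grid)$F
  bt <- bias
  bt$kernels <- bias$kernels[!is.na(bias$kernels$time) & bias$kernels$time <= t, , drop = FALSE]
  Vt <- bias_potential(bt, grid)
  beta <- 1 / (.kB * bias$temperature)
  dx <- grid[2] - grid[1]
  (logtrapz(-beta * F, dx) - logtrapz(-beta * (F + Vt), dx)) / beta
}

# c(t) evaluated at every deposition time (incremental over kernels)
reweight_ct_series <- function(bias, grid, F = NULL) {
  k <- bias$kernels
  if (nrow(k) == 0)
    return(tibble::tibble(time = numeric(), c = numeric()))
  if (is.null(F)) F <- free_energy_estimate(bias, grid)$F
  beta <- 1 / (.kB * bias$temperature)
  dx <- grid[2] - grid[1]
  l0 <- logtrapz(-beta * F, dx)
  V <- rep(0, length(grid))
  cs <- numeric(nrow(k))
  for (j in seq_len(nrow(k))) {
    V <- V + k$height[j] * exp(-(grid - k$center[j])^2 / (2 * k$width[j]^2))
    cs[j] <- (l0 - logtrapz(-beta * (F + V), dx)) / beta
  }
  tibble::tibble(time = k$time, c = cs)
}

#' Reweighted distribution of an observable
#'
#' Each frame is weighted by `exp(beta * (V(s(t), t) - c(t)))` — the
#' time-independent estimator weights — and a normalized histogram of the
#' observable is returned. With an empty bias the weights are uniform and the
#' histogram equals the raw histogram.
#'
#' @param colvar tibble with columns `time`, `value` (the observable), `s`
#'   (the biased CV), and optionally `bias` (instantaneous V(s(t), t);
#'   computed from the kernel list when absent).
#' @param bias an `egress_bias`.
#' @param breaks histogram break points or count (passed to [hist()]).
#' @param grid CV grid for the quadratures (defaults to the kernel range).
#' @return Tibble with columns `mid` and `density` (integrating to 1), with
#'   the per-frame weights in `attr(, "weights")`.
#' @export
reweighted_histogram <- function(colvar, bias, breaks = 50, grid = NULL) {
  n <- nrow(colvar)
  k <- bias$kernels
  if (nrow(k) == 0) {
    w <- rep(1 / n, n)
  } else {
    if (is.null(grid)) {
      rng <- range(k$center) + c(-3, 3) * max(k$width)
      grid <- seq(rng[1], rng[2], length.out = 400)
    }
    vt <- colvar$bias %||% vapply(seq_len(n), function(i) {
      bt <- bias
      bt$kernels <- k[!is.na(k$time) & k$time <= colvar$time[i], , drop = FALSE]
      bias_potential(bt, colvar$s[i])
    }, numeric(1))
    cts <- reweight_ct_series(bias, grid)
    ct <- stats::approx(c(0, cts$time), c(0, cts$c), xout = colvar$time,
                        method = "constant", rule = 2)$y
    beta <- 1 / (.kB * bias$temperature)
    lw <- beta * (vt - ct)
    lw <- lw - max(lw)
    w <- exp(lw); w <- w / sum(w)
  }
  h <- graphics::hist(colvar$value, breaks = breaks, plot = FALSE)
  bin <- findInterval(colvar$value, h$breaks, rightmost.closed = TRUE)
  dens <- vapply(seq_along(h$mids), function(b) sum(w[bin == b]), numeric(1))
  dens <- dens / diff(h$breaks)
  out <- tibble::tibble(mid = h$mids, density = dens)
  attr(out, "weights") <- w
  out
}

#' Convergence diagnostics of a metadynamics run
#'
#' Reports the Gaussian-height trace, the residual height fraction (mean
#' height of the final 5% of kernels over the initial height — the standard
#' convergence signature, below 0.01 for a converged well-tempered run), and
#' per-grid-point standard errors across block-wise free-energy estimates
#' taken at evenly spaced times over the second half of the run.
#'
#' @param bias an `egress_bias` with >= 2 kernels.
#' @param blocks number of blocks (>= 2).
#' @param grid CV grid (defaults to the kernel range).
#' @return List with `height_trace` (tibble `time`, `height`),
#'   `residual_height_fraction`, `block_se` (kcal/mol per grid point),
#'   `mean_block_se`, and `grid`.
#' @export
convergence_report <- function(bias, blocks = 4, grid = NULL) {
  k <- bias$kernels
  if (nrow(k) < 2) stop("need at least 2 deposited kernels", call. = FALSE)
  if (blocks < 2) stop("blocks must be >= 2", call. = FALSE)
  if (is.null(grid)) {
    rng <- range(k$center) + c(-2, 2) * stats::median(k$width)
    grid <- seq(rng[1], rng[2], length.out = 200)
  }
  n <- nrow(k)
  tail_idx <- seq(from = max(1L, ceiling(0.95 * n)), to = n)
  res_frac <- mean(k$height[tail_idx]) / bias$h0

  t_end <- max(k$time)
  t_half <- t_end / 2
  t_marks <- seq(t_half, t_end, length.out = blocks)
  prof <- sapply(t_marks, function(tm) {
    bt <- bias
    bt$kernels <- k[k$time <= tm, , drop = FALSE]
    free_energy_estimate(bt, grid)$F
  })
  block_se <- apply(prof, 1, stats::sd) / sqrt(blocks)
  list(height_trace = tibble::tibble(time = k$time, height = k$height),
       residual_height_fraction = res_frac,
       block_se = block_se, mean_block_se = mean(block_se), grid = grid)
}

# ---- drivers ----------------------------------------------------------------

#' Well-tempered metadynamics on the analytic double well
#'
#' Runs Langevin dynamics with on-the-fly well-tempered metadynamics on the
#' particle position (compiled inner loop; bias accumulated on a grid). With
#' `h0 = 0` this is a plain unbiased Langevin run, useful for Boltzmann
#' sampling checks.
#'
#' @param system an analytic 1D `egress_system` from [make_double_well()].
#' @param n_steps number of MD steps.
#' @param dt time step, ps.
#' @param friction Langevin friction, 1/ps.
#' @param temperature temperature, K.
#' @param delta_t tempering dT, K.
#' @param h0 initial Gaussian height, kcal/mol (0.48 every 0.25 ps =
#'   1.92 kcal/mol/ps deposition rate).
#' @param deposit_interval deposition period, ps.
#' @param adaptive_tau adaptive-width window, ps (set `width` to bypass).
#' @param width fixed Gaussian width, A; `NULL` uses the adaptive rule.
#' @param width_floor minimum width, A.
#' @param grid_n number of bias-grid points.
#' @param sample_stride record the CV every this many steps.
#' @param seed RNG seed (initial velocity + thermostat noise).
#' @param x0 starting position (defaults to the left minimum).
#' @return Object of class `egress_metad` with elements `bias`
#'   (`egress_bias`), `colvar` (tibble `time`, `value`, `s`, `bias`), `fes`
#'   (`egress_fes`), and `grid`.
#' @export
run_metad_1d <- function(system, n_steps, dt = 0.002, friction = 5,
                         temperature = 300, delta_t = 3300, h0 = 0.48,
                         deposit_interval = 0.25, adaptive_tau = 0.25,
                         width = NULL, width_floor = 0.05, grid_n = 801,
                         sample_stride = 100, seed = 1, x0 = NULL) {
  stopifnot(system$potential_kind == "analytic1D")
  p <- system$analytic_params
  m <- system$atoms$mass[1]
  set.seed(as.integer(seed))
  kT <- .kB * temperature * .F2A
  v0 <- stats::rnorm(1, sd = sqrt(kT / m))
  x0 <- x0 %||% (-p$spacing)
  gmin <- -2.2 * p$spacing; gmax <- 2.2 * p$spacing
  res <- cpp_metad_1d(x0, v0, m, dt, friction, temperature, as.numeric(n_steps),
                      p$barrier, p$spacing,
                      h0, max(1L, as.integer(round(deposit_interval / dt))),
                      delta_t,
                      as.integer(round(adaptive_tau / dt)), width_floor,
                      if (is.null(width)) -1 else width,
                      gmin, gmax, as.integer(grid_n),
                      as.integer(sample_stride))
  bias <- bias_state(tibble::as_tibble(res$kernels), temperature, delta_t,
                     h0, deposit_interval, adaptive_tau)
  colvar <- tibble::as_tibble(res$samples)
  colvar <- tibble::tibble(time = colvar$time, value = colvar$x,
                           s = colvar$x, v = colvar$v, bias = colvar$bias)
  grid <- seq(gmin, gmax, length.out = grid_n)
  fes <- if (nrow(bias$kernels) > 0) free_energy_estimate(bias, grid) else NULL
  structure(list(bias = bias, colvar = colvar, fes = fes, grid = grid,
                 cv = "x", system = system,
                 params = list(n_steps = n_steps, dt = dt, friction = friction,
                               temperature = temperature, delta_t = delta_t,
                               h0 = h0, deposit_interval = deposit_interval,
                               seed = seed)),
            class = "egress_metad")
}

#' @export
print.egress_metad <- function(x, ...) {
  cat(sprintf("<egress_metad> CV = %s, %d kernels, %d recorded frames\n",
              x$cv, nrow(x$bias$kernels), nrow(x$colvar)))
  invisible(x)
}

#' Path-CV well-tempered metadynamics on a cage system
#'
#' Biases the order parameter sigma = (s - 1)/(N - 1) along a reference
#' egress path; the deviation z is confined by a one-sided harmonic wall
#' (z < `z_limit`), mirroring standard path-variable practice. Bias forces
#' reach the atoms through the chain rule with the analytic path-variable
#' gradients.
#'
#' @param system a cage `egress_system`.
#' @param state0 starting `egress_state`.
#' @param path an `egress_path`.
#' @param n_steps number of MD steps.
#' @param h0,delta_t,deposit_interval,adaptive_tau as in [run_metad_1d()];
#'   widths are in sigma units (floor 0.01).
#' @param z_limit,z_kappa wall position (A^2) and stiffness (kcal/mol/A^4).
#' @param width fixed width in sigma units; `NULL` = adaptive.
#' @param width_floor minimum width, sigma units.
#' @param sample_stride record the CVs every this many steps.
#' @param grid_n FES grid points on [0, 1].
#' @param store_frames_stride store a full-system conformation every this
#'   many steps (0 = off), for conformational-state analysis.
#' @return Object of class `egress_metad` with `colvar` columns `time`,
#'   `value` (= sigma), `s`, `sigma`, `z`, `bias`, plus `state` (final) and
#'   `frames` (list of stored conformations, possibly empty).
#' @export
run_metad_pcv <- function(system, state0, path, n_steps,
                          h0 = 0.48, delta_t = 3300, deposit_interval = 0.25,
                          adaptive_tau = 0.25, z_limit = 6, z_kappa = 100,
                          width = NULL, width_floor = 0.01,
                          sample_stride = 10, grid_n = 501,
                          store_frames_stride = 0) {
  N <- length(path$nodes)
  di_atoms <- path$displacement_set
  env <- new.env()
  env$kern <- list()
  env$sig_hist <- numeric(0)
  env$t_hist <- numeric(0)
  env$cur <- NULL

  kernels_tbl <- function() {
    if (length(env$kern) == 0)
      tibble::tibble(time = numeric(), center = numeric(),
                     width = numeric(), height = numeric())
    else dplyr::bind_rows(env$kern)
  }
  vbias <- function(sig) {
    kt <- kernels_tbl()
    if (nrow(kt) == 0) return(list(v = 0, dv = 0))
    e <- kt$height * exp(-(sig - kt$center)^2 / (2 * kt$width^2))
    list(v = sum(e), dv = -sum(e * (sig - kt$center) / kt$width^2))  # dV/dsigma
  }
  bias_force <- function(sys, x, st) {
    r <- pcv_eval(conformation(x), path, gradients = TRUE)
    env$cur <- r
    F <- matrix(0, nrow(x), 3)
    vb <- vbias(r$sigma)
    dsig <- r$ds_dx / (N - 1)
    F[di_atoms, ] <- F[di_atoms, ] - vb$dv * dsig
    wall <- z_wall_force(r$z, z_limit, z_kappa)
    F[di_atoms, ] <- F[di_atoms, ] + wall$force * r$dz_dx
    F
  }

  dt <- state0$dt
  dep_stride <- max(1L, as.integer(round(deposit_interval / dt)))
  tau_steps <- max(2L, as.integer(round(adaptive_tau / dt)))
  state <- state0
  cv_rows <- list()
  frames <- list()
  for (s in seq_len(n_steps)) {
    state <- langevin_step(system, state, 1L, extra_force = bias_force)
    r <- env$cur
    env$sig_hist <- c(env$sig_hist, r$sigma)
    if (length(env$sig_hist) > tau_steps)
      env$sig_hist <- env$sig_hist[(length(env$sig_hist) - tau_steps):length(env$sig_hist)]
    if (s %% dep_stride == 0) {
      w <- if (!is.null(width)) width else max(stats::sd(env$sig_hist), width_floor)
      if (!is.finite(w)) w <- width_floor
      vh <- vbias(r$sigma)$v
      h <- h0 * exp(-vh / (.kB * delta_t))
      env$kern[[length(env$kern) + 1L]] <-
        tibble::tibble(time = state$time, center = r$sigma, width = w, height = h)
    }
    if (s %% sample_stride == 0) {
      cv_rows[[length(cv_rows) + 1L]] <-
        tibble::tibble(time = state$time, value = r$sigma, s = r$s,
                       sigma = r$sigma, z = r$z, bias = vbias(r$sigma)$v)
    }
    if (store_frames_stride > 0 && s %% store_frames_stride == 0) {
      frames[[length(frames) + 1L]] <- conformation(state$coords, time = state$time)
    }
  }
  bias <- bias_state(kernels_tbl(), state0$temperature, delta_t, h0,
                     deposit_interval, adaptive_tau)
  colvar <- if (length(cv_rows)) dplyr::bind_rows(cv_rows) else
    tibble::tibble(time = numeric(), value = numeric(), s = numeric(),
                   sigma = numeric(), z = numeric(), bias = numeric())
  grid <- seq(0, 1, length.out = grid_n)
  fes <- if (nrow(bias$kernels) > 0) free_energy_estimate(bias, grid) else NULL
  structure(list(bias = bias, colvar = colvar, fes = fes, grid = grid,
                 cv = "sigma", state = state, path = path, frames = frames,
                 params = list(n_steps = n_steps, h0 = h0, delta_t = delta_t,
                               z_limit = z_limit, z_kappa = z_kappa)),
            class = "egress_metad")
}
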