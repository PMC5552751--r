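# Toy particle-dynamics engine: fixture systems (analytic double well, particle
# cage + rigid ligand), pairwise energies, restraints, Langevin (BAOAB) dynamics.

#' Build an atom table
#'
#' Atoms carry the per-atom parameters used by the pairwise force field and by
#' the effective interaction functional: Lennard-Jones epsilon/sigma, partial
#' charge, and the partial volume / solvation coefficient entering the
#' desolvation-like Gaussian term.
#'
#' @param role character vector, each one of `"ligand"`, `"protein"`, `"anchor"`.
#' @param mass atomic masses, amu (> 0).
#' @param charge partial charges, elementary charge units.
#' @param lj_epsilon Lennard-Jones well depth, kcal/mol.
#' @param lj_sigma Lennard-Jones diameter, Angstrom (> 0).
#' @param partial_volume partial atomic volume, A^3 (default 1).
#' @param solvation_coefficient solvation coefficient, kcal/mol/A^3 (default 0).
#' @return A tibble with one row per atom and a 0-based contiguous `id` column.
#' @export
make_atoms <- function(role, mass, charge = 0, lj_epsilon = 0.2, lj_sigma = 3.4,
                       partial_volume = 1, solvation_coefficient = 0) {
  n <- length(role)
  stopifnot(n >= 1)
  if (!all(role %in% c("ligand", "protein", "anchor")))
    stop("atom role must be one of 'ligand', 'protein', 'anchor'", call. = FALSE)
  at <- tibble::tibble(
    id = seq_len(n) - 1L,
    role = role,
    mass = rep_len(as.numeric(mass), n),
    charge = rep_len(as.numeric(charge), n),
    lj_epsilon = rep_len(as.numeric(lj_epsilon), n),
    lj_sigma = rep_len(as.numeric(lj_sigma), n),
    partial_volume = rep_len(as.numeric(partial_volume), n),
    solvation_coefficient = rep_len(as.numeric(solvation_coefficient), n)
  )
  if (any(at$mass <= 0)) stop("atom mass must be > 0", call. = FALSE)
  if (any(at$lj_sigma <= 0)) stop("lj_sigma must be > 0", call. = FALSE)
  at
}

#' Create a conformation (one system snapshot)
#'
#' @param coords numeric matrix, one row per atom (3 columns for particle
#'   systems, 1 or 2 for analytic benchmark potentials).
#' @param time simulation time, ps.
#' @param label free-text label.
#' @return An object of class `egress_conformation`.
#' @export
conformation <- function(coords, time = 0, label = "") {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("conformation coordinates must be finite", call. = FALSE)
  structure(list(coords = coords, time = time, label = label),
            class = "egress_conformation")
}

#' @export
print.egress_conformation <- function(x, ...) {
  cat(sprintf("<egress_conformation> %d atoms, t = %g ps%s\n",
              nrow(x$coords), x$time,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

as_conformation <- function(x, n_atoms = NULL) {
  if (inherits(x, "egress_conformation")) return(x)
  conformation(x)
}

new_system <- function(atoms, potential_kind, analytic_params = list(),
                       restraints = list(), dielectric = 1, coords0 = NULL,
                       cage = NULL) {
  if (!potential_kind %in% c("pairwise3D", "analytic1D", "analytic2D"))
    stop("unknown potential kind: ", potential_kind, call. = FALSE)
  if (anyDuplicated(atoms$id) || !identical(atoms$id, seq_len(nrow(atoms)) - 1L))
    stop("atom ids must be unique and contiguous from 0", call. = FALSE)
  lig <- which(atoms$role == "ligand")
  if (potential_kind == "pairwise3D" && length(lig) == 0)
    stop("pairwise3D system needs at least one ligand atom", call. = FALSE)
  for (r in restraints) {
    if (!r$kind %in% c("harmonicPosition", "distanceUpperWall", "cvUpperWall"))
      stop("unknown restraint kind: ", r$kind, call. = FALSE)
    if (r$spring_constant < 0) stop("restraint spring constant must be >= 0", call. = FALSE)
    if (r$kind != "cvUpperWall" && !all(r$targets %in% atoms$id))
      stop("restraint references unknown atom ids", call. = FALSE)
  }
  if (!is.null(coords0)) coords0 <- unname(as.matrix(coords0))
  sys <- structure(list(
    atoms = atoms, potential_kind = potential_kind,
    analytic_params = analytic_params, restraints = restraints,
    dielectric = dielectric, coords0 = coords0, cage = cage
  ), class = "egress_system")
  if (potential_kind == "pairwise3D") sys$body <- rigid_body_frame(sys)
  sys
}

#' @export
print.egress_system <- function(x, ...) {
  cat(sprintf("<egress_system> %s, %d atoms (%d ligand), %d restraints\n",
              x$potential_kind, nrow(x$atoms),
              sum(x$atoms$role == "ligand"), length(x$restraints)))
  invisible(x)
}

ligand_rows <- function(system) which(system$atoms$role == "ligand")
env_rows <- function(system) which(system$atoms$role %in% c("protein", "anchor"))

# principal-axis body frame of the rigid ligand
rigid_body_frame <- function(system) {
  li <- ligand_rows(system)
  m <- system$atoms$mass[li]
  xyz <- system$coords0[li, , drop = FALSE]
  com <- colSums(xyz * m) / sum(m)
  c0 <- sweep(xyz, 2, com)
  if (length(li) == 1L) {
    return(list(ref = matrix(0, 1, 3), masses = m, mass_total = sum(m),
                inertia = c(0, 0, 0), axes = diag(3), rotational = FALSE))
  }
  It <- matrix(0, 3, 3)
  for (i in seq_along(li)) {
    r <- c0[i, ]
    It <- It + m[i] * (sum(r^2) * diag(3) - tcrossprod(r))
  }
  eig <- eigen(It, symmetric = TRUE)
  V <- eig$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  ref <- c0 %*% V                      # coordinates in the principal frame
  rotational <- all(eig$values > 1e-8)
  list(ref = ref, masses = m, mass_total = sum(m),
       inertia = pmax(eig$values, 1e-8), axes = V, rotational = rotational)
}

#' Analytic 1D double-well benchmark system
#'
#' Builds a single-particle system with potential
#' \eqn{U(x) = b\,((x/a)^2 - 1)^2} (barrier `b` at x = 0, minima at x = ±`a`),
#' the standard benchmark for metadynamics convergence checks.
#'
#' @param barrier barrier height at x = 0, kcal/mol (> 0).
#' @param spacing half-distance between the minima, Angstrom (> 0).
#' @param mass particle mass, amu.
#' @return An `egress_system` with `potential_kind = "analytic1D"`.
#' @examples
#' sys <- make_double_well(4, 1)
#' potential_energy(sys, conformation(matrix(0)))$total  # == 4
#' @export
make_double_well <- function(barrier, spacing, mass = 1) {
  if (!is.numeric(barrier) || barrier <= 0) stop("barrier must be > 0", call. = FALSE)
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  atoms <- make_atoms("ligand", mass = mass, lj_epsilon = 0, lj_sigma = 1)
  new_system(atoms, "analytic1D",
             analytic_params = list(kind = "double_well", barrier = barrier, spacing = spacing),
             coords0 = matrix(-spacing, 1, 1))
}

#' Particle cage enclosing a rigid ligand
#'
#' The desk-scale stand-in for a protein matrix with buried binding site:
#' cage atoms are placed quasi-uniformly on a sphere (Fibonacci lattice) with
#' `n_tunnels` angular gaps cut out (the tunnel mouths), each gap wider than
#' the ligand diameter; a rigid five-atom ligand sits at an off-center
#' "active site"; cage atoms are harmonically restrained to their lattice
#' sites, and a one-sided distance wall on the ligand center of mass prevents
#' escape to infinity. A single fixed anchor atom at the cage center plays the
#' role of the metal center from which the wall distance is measured.
#'
#' @param n_cage number of cage atoms (>= 12).
#' @param cage_radius sphere radius, Angstrom.
#' @param n_tunnels number of angular gaps, 1..6.
#' @param seed integer seed; the construction is deterministic given the seed.
#' @param tunnel_halfwidth angular half-width of each gap, degrees.
#' @param restraint_k cage-site harmonic spring constant, kcal/mol/A^2
#'   (config default 10; the value is a package choice, not taken from any
#'   reference system).
#' @param wall_factor the COM distance wall is placed at `wall_factor * cage_radius`.
#' @return An `egress_system` with `potential_kind = "pairwise3D"`.
#' @export
make_cage_ligand <- function(n_cage, cage_radius, n_tunnels, seed,
                             tunnel_halfwidth = 25, restraint_k = 10,
                             wall_factor = 1.4) {
  if (n_cage < 12) stop("n_cage must be >= 12", call. = FALSE)
  if (n_tunnels < 1 || n_tunnels > 6) stop("n_tunnels must be in 1..6", call. = FALSE)
  lj_sigma_cage <- 3.4
  if (cage_radius <= 2 * lj_sigma_cage)
    stop("cage_radius must exceed twice the largest lj_sigma", call. = FALSE)
  set.seed(as.integer(seed))
  hw <- tunnel_halfwidth * pi / 180

  # tunnel axes: sequential rejection sampling with minimum angular separation
  axes <- matrix(0, 0, 3)
  tries <- 0L
  while (nrow(axes) < n_tunnels) {
    tries <- tries + 1L
    if (tries > 2000L)
      stop("infeasible tunnel geometry: cannot place non-overlapping tunnels", call. = FALSE)
    u <- random_unit_vector()
    ok <- TRUE
    if (nrow(axes) > 0) {
      ang <- acos(pmin(1, pmax(-1, axes %*% u)))
      ok <- all(ang > 2 * hw + 0.15)
    }
    if (ok) axes <- rbind(axes, c(u))
  }

  # Fibonacci lattice, oversampled so that n_cage atoms survive the gap cuts
  n_grid <- n_cage
  repeat {
    pts <- fibonacci_sphere(n_grid)
    keep <- rep(TRUE, nrow(pts))
    for (k in seq_len(n_tunnels)) {
      ang <- acos(pmin(1, pmax(-1, pts %*% axes[k, ])))
      keep <- keep & (ang > hw)
    }
    if (sum(keep) >= n_cage) break
    n_grid <- ceiling(n_grid * 1.2) + 1L
    if (n_grid > 50 * n_cage)
      stop("infeasible tunnel geometry: gaps remove too much of the cage", call. = FALSE)
  }
  kept <- pts[keep, , drop = FALSE]
  # trim to n_cage by repeatedly removing a point from the locally densest
  # spot, so the only sparse region of the shell is the engineered gap
  while (nrow(kept) > n_cage) {
    cosm <- tcrossprod(kept)
    diag(cosm) <- -1
    nnbr <- apply(cosm, 1, max)          # cos of nearest-neighbor angle
    kept <- kept[-which.max(nnbr)[1], , drop = FALSE]
  }
  sites <- cage_radius * kept

  # rigid ligand: central atom + tetrahedral shell ("camphor-like" compact body)
  b <- 1.5
  lig_ref <- rbind(c(0, 0, 0),
                   b / sqrt(3) * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)))
  lig_diam <- 2 * max(sqrt(rowSums(lig_ref^2)))
  chord <- 2 * cage_radius * sin(hw)
  if (chord <= lig_diam)
    stop("infeasible tunnel geometry: gap narrower than the ligand diameter", call. = FALSE)

  # the "active site" sits off-center, adjacent to (but not aligned with)
  # the first egress route, mirroring a buried site from which exit tunnels
  # emanate: tilted 50 degrees off the first tunnel axis about a random
  # perpendicular direction
  u1 <- axes[1, ]
  perp <- cross3(u1, random_unit_vector())
  while (sqrt(sum(perp^2)) < 1e-6) perp <- cross3(u1, random_unit_vector())
  perp <- perp / sqrt(sum(perp^2))
  tilt <- 50 * pi / 180
  dir0 <- cos(tilt) * u1 + sin(tilt) * perp
  lig_com0 <- 0.3 * cage_radius * dir0
  lig_xyz <- sweep(lig_ref, 2, lig_com0, "+")

  n_l <- nrow(lig_ref)
  atoms <- make_atoms(
    role = c(rep("ligand", n_l), rep("protein", n_cage), "anchor"),
    mass = c(rep(30, n_l), rep(40, n_cage), 56),
    charge = 0,
    lj_epsilon = c(rep(0.15, n_l), rep(0.2, n_cage), 0.2),
    lj_sigma = c(rep(3.4, n_l), rep(3.4, n_cage), 2.0),
    partial_volume = c(rep(1, n_l), rep(1, n_cage), 1),
    solvation_coefficient = c(rep(0, n_l), rep(1, n_cage), 1)
  )
  coords0 <- rbind(lig_xyz, sites, c(0, 0, 0))
  lig_ids <- 0:(n_l - 1L)
  cage_ids <- n_l:(n_l + n_cage - 1L)
  restraints <- list(
    list(kind = "harmonicPosition", targets = cage_ids,
         reference = sites, spring_constant = restraint_k),
    list(kind = "distanceUpperWall", targets = lig_ids,
         reference = wall_factor * cage_radius, spring_constant = 10,
         center = c(0, 0, 0))
  )
  sys <- new_system(atoms, "pairwise3D", restraints = restraints,
                    coords0 = coords0,
                    cage = list(center = c(0, 0, 0), radius = cage_radius,
                                tunnel_axes = axes, tunnel_halfwidth = tunnel_halfwidth))
  sys
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# ---- energies and forces ----------------------------------------------------

.r_min_clamp <- 0.1  # Angstrom; pair distances below this are clamped

analytic_potential <- function(system, x) {
  p <- system$analytic_params
  u <- x[1] / p$spacing
  list(energy = p$barrier * (u^2 - 1)^2,
       force = -4 * p$barrier * x[1] * (u^2 - 1) / p$spacing^2)
}

#' Potential energy decomposition of a conformation
#'
#' Lennard-Jones 12-6 plus Coulomb (configurable dielectric) over
#' ligand-environment pairs, and restraint energies (harmonic position
#' restraints, one-sided distance upper walls). Pair distances are clamped at
#' 0.1 A so overlapping coordinates give a large finite energy with a warning,
#' never NaN. CV-space walls (`cvUpperWall`) act only during biased dynamics
#' and contribute 0 here.
#'
#' @param system an `egress_system`.
#' @param conf an `egress_conformation` (or bare coordinate matrix) with one
#'   row per atom.
#' @return A list with components `vdw`, `coulomb`, `restraint`, `total`
#'   (kcal/mol); `total` is the sum of the parts.
#' @export
potential_energy <- function(system, conf) {
  conf <- as_conformation(conf)
  x <- conf$coords
  if (nrow(x) != nrow(system$atoms))
    stop("conformation has ", nrow(x), " atoms, system has ", nrow(system$atoms), call. = FALSE)
  if (system$potential_kind %in% c("analytic1D", "analytic2D")) {
    e <- analytic_potential(system, x)$energy
    return(list(vdw = 0, coulomb = 0, restraint = 0, total = e))
  }
  ff <- pair_terms(system, x)
  er <- restraint_energy(system, x)$energy
  list(vdw = ff$vdw, coulomb = ff$coulomb, restraint = er,
       total = ff$vdw + ff$coulomb + er)
}

pair_terms <- function(system, x, forces = FALSE) {
  li <- ligand_rows(system); ei <- env_rows(system)
  at <- system$atoms
  n <- nrow(x)
  F <- if (forces) matrix(0, n, 3) else NULL
  vdw <- 0; coul <- 0
  warned <- FALSE
  for (i in li) {
    dx <- sweep(x[ei, , drop = FALSE], 2, x[i, ], "-")   # env - lig
    r2 <- rowSums(dx^2)
    r <- sqrt(r2)
    clamped <- r < .r_min_clamp
    if (any(clamped) && !warned) {
      warning("atom overlap: pair distance clamped at ", .r_min_clamp, " A")
      warned <- TRUE
    }
    # deterministic separation direction for exact overlap
    if (any(r == 0)) dx[r == 0, ] <- matrix(c(.r_min_clamp, 0, 0),
                                            sum(r == 0), 3, byrow = TRUE)
    r[clamped] <- .r_min_clamp
    sig <- (at$lj_sigma[i] + at$lj_sigma[ei]) / 2
    eps <- sqrt(at$lj_epsilon[i] * at$lj_epsilon[ei])
    sr6 <- (sig / r)^6
    vdw <- vdw + sum(4 * eps * (sr6^2 - sr6))
    qq <- 332.0636 * at$charge[i] * at$charge[ei] / system$dielectric
    coul <- coul + sum(qq / r)
    if (forces) {
      # dU/dr for LJ + Coulomb; force on ligand atom i along -(env-lig)/r * dU/dr
      dudr <- 4 * eps * (-12 * sr6^2 + 6 * sr6) / r - qq / r2
      fi <- dx * (dudr / r)        # force on atom i
      F[i, ] <- F[i, ] + colSums(fi)
      F[ei, ] <- F[ei, ] - fi
    }
  }
  list(vdw = vdw, coulomb = coul, forces = F)
}

restraint_energy <- function(system, x, forces = FALSE) {
  n <- nrow(x)
  F <- if (forces) matrix(0, n, 3) else NULL
  e <- 0
  for (r in system$restraints) {
    if (r$kind == "harmonicPosition") {
      idx <- r$targets + 1L
      d <- x[idx, , drop = FALSE] - r$reference
      e <- e + 0.5 * r$spring_constant * sum(d^2)
      if (forces) F[idx, ] <- F[idx, ] - r$spring_constant * d
    } else if (r$kind == "distanceUpperWall") {
      idx <- r$targets + 1L
      m <- system$atoms$mass[idx]
      com <- colSums(x[idx, , drop = FALSE] * m) / sum(m)
      dv <- com - (r$center %||% c(0, 0, 0))
      d <- sqrt(sum(dv^2))
      if (d > r$reference) {
        e <- e + 0.5 * r$spring_constant * (d - r$reference)^2
        if (forces && d > 0) {
          fcom <- -r$spring_constant * (d - r$reference) * dv / d
          F[idx, ] <- F[idx, ] + outer(m / sum(m), fcom)
        }
      }
    }
    # cvUpperWall handled by the metadynamics driver
  }
  list(energy = e, forces = F)
}

# total forces (kcal/mol/A) and potential energy for dynamics
system_forces <- function(system, x) {
  if (system$potential_kind %in% c("analytic1D", "analytic2D")) {
    a <- analytic_potential(system, x)
    return(list(forces = matrix(a$force, 1, ncol(x)), energy = a$energy))
  }
  pf <- pair_terms(system, x, forces = TRUE)
  rf <- restraint_energy(system, x, forces = TRUE)
  list(forces = pf$forces + rf$forces, energy = pf$vdw + pf$coulomb + rf$energy)
}

# ---- thermostate and BAOAB integration -------------------------------------

#' Initialize a thermodynamic state for Langevin dynamics
#'
#' Velocities are drawn from the Maxwell-Boltzmann distribution at the target
#' temperature (deterministically, given `seed`); the rigid ligand receives a
#' center-of-mass velocity and a body-frame angular velocity.
#'
#' @param system an `egress_system`.
#' @param temperature target temperature, K.
#' @param friction Langevin friction, 1/ps.
#' @param dt time step, ps.
#' @param seed integer RNG seed stored in the state; all subsequent dynamics
#'   are deterministic given this seed.
#' @param coords optional starting coordinates (defaults to the system's
#'   construction coordinates).
#' @return An object of class `egress_state`.
#' @export
thermo_state <- function(system, temperature = 300, friction = 10, dt = 0.002,
                         seed = 1, coords = NULL) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  x <- coords %||% system$coords0
  x <- as.matrix(x)
  set.seed(as.integer(seed))
  kT <- .kB * temperature * .F2A           # amu A^2/ps^2
  st <- list(coords = x, temperature = temperature, friction = friction,
             dt = dt, rng_seed = as.integer(seed), step_count = 0L, time = 0)
  if (system$potential_kind %in% c("analytic1D", "analytic2D")) {
    m <- system$atoms$mass[1]
    st$vel <- matrix(stats::rnorm(ncol(x), sd = sqrt(kT / m)), 1, ncol(x))
  } else {
    at <- system$atoms
    n <- nrow(x)
    st$vel <- matrix(0, n, 3)
    free <- which(at$role == "protein")
    st$vel[free, ] <- stats::rnorm(3 * length(free)) * sqrt(kT / at$mass[free])
    bd <- system$body
    st$lig_vcom <- stats::rnorm(3, sd = sqrt(kT / bd$mass_total))
    st$quat <- ligand_pose(system, x)$quat
    st$omega <- if (bd$rotational) stats::rnorm(3) * sqrt(kT / bd$inertia) else c(0, 0, 0)
    st <- sync_ligand_coords(system, st)
  }
  structure(st, class = "egress_state")
}

#' @export
print.egress_state <- function(x, ...) {
  cat(sprintf("<egress_state> t = %g ps (%d steps), T_target = %g K\n",
              x$time, x$step_count, x$temperature))
  invisible(x)
}

sync_ligand_coords <- function(system, state) {
  bd <- system$body
  li <- ligand_rows(system)
  com <- colSums(state$coords[li, , drop = FALSE] * bd$masses) / bd$mass_total
  R <- quat_to_mat(state$quat)
  state$coords[li, ] <- sweep(bd$ref %*% t(R), 2, com, "+")
  # atom velocities = v_com + omega x r (world frame), for reporting
  w_world <- R %*% state$omega
  rw <- bd$ref %*% t(R)
  state$vel[li, ] <- matrix(state$lig_vcom, length(li), 3, byrow = TRUE) +
    t(vapply(seq_along(li), function(i) cross3(w_world, rw[i, ]), numeric(3)))
  state
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Advance Langevin dynamics
#'
#' BAOAB discretization of Langevin dynamics in the package unit system; the
#' rigid ligand moves as a unit (center-of-mass translation plus Euler
#' rotation about its principal axes). Deterministic given the state's RNG
#' seed and step count. With zero friction the scheme reduces to velocity
#' Verlet.
#'
#' @param system an `egress_system`.
#' @param state an `egress_state`.
#' @param n_steps number of steps (>= 1).
#' @param extra_force optional function `(system, coords, state) -> n x 3
#'   matrix` of additional forces (kcal/mol/A), used by biased dynamics.
#' @return The advanced `egress_state` with `step_count` incremented.
#' @export
langevin_step <- function(system, state, n_steps, extra_force = NULL) {
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  set.seed((state$rng_seed + state$step_count) %% .Machine$integer.max)
  if (system$potential_kind %in% c("analytic1D", "analytic2D")) {
    langevin_analytic(system, state, n_steps, extra_force)
  } else {
    langevin_cage(system, state, n_steps, extra_force)
  }
}

langevin_analytic <- function(system, state, n_steps, extra_force = NULL) {
  m <- system$atoms$mass[1]
  dt <- state$dt
  kT <- .kB * state$temperature * .F2A
  c1 <- exp(-state$friction * dt)
  c2 <- sqrt((1 - c1^2) * kT / m)
  x <- state$coords; v <- state$vel
  f <- total_force(system, x, state, extra_force)
  for (s in seq_len(n_steps)) {
    v <- v + 0.5 * dt * f * .F2A / m
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * matrix(stats::rnorm(length(v)), nrow(v))
    x <- x + 0.5 * dt * v
    f <- total_force(system, x, state, extra_force)
    if (!all(is.finite(f)))
      stop("non-finite force on atom 0 at step ", state$step_count + s, call. = FALSE)
    v <- v + 0.5 * dt * f * .F2A / m
  }
  state$coords <- x; state$vel <- v
  state$step_count <- state$step_count + as.integer(n_steps)
  state$time <- state$time + n_steps * dt
  state
}

total_force <- function(system, x, state, extra_force) {
  f <- system_forces(system, x)$forces
  if (!is.null(extra_force)) f <- f + extra_force(system, x, state)
  f
}

langevin_cage <- function(system, state, n_steps, extra_force = NULL) {
  at <- system$atoms
  bd <- system$body
  li <- ligand_rows(system)
  free <- which(at$role == "protein")
  dt <- state$dt
  kT <- .kB * state$temperature * .F2A
  c1 <- exp(-state$friction * dt)
  c2f <- sqrt((1 - c1^2) * kT / at$mass[free])
  c2t <- sqrt((1 - c1^2) * kT / bd$mass_total)
  c2r <- sqrt((1 - c1^2) * kT / bd$inertia)

  x <- state$coords
  v <- state$vel
  vcom <- state$lig_vcom
  q <- state$quat
  w <- state$omega   # body frame

  eval_forces <- function(x) {
    f <- total_force(system, x, state, extra_force)
    if (!all(is.finite(f))) {
      bad <- which(!apply(f, 1, function(r) all(is.finite(r))))[1]
      stop("non-finite force on atom ", bad - 1L, call. = FALSE)
    }
    R <- quat_to_mat(q)
    fl <- f[li, , drop = FALSE]
    fcom <- colSums(fl)
    rw <- sweep(x[li, , drop = FALSE], 2, ligand_com(system, x))
    tau_w <- colSums(t(vapply(seq_along(li),
                              function(i) cross3(rw[i, ], fl[i, ]), numeric(3))))
    list(ffree = f[free, , drop = FALSE], fcom = fcom, tau_body = t(R) %*% tau_w)
  }

  half_kick <- function(fr) {
    v[free, ] <<- v[free, ] + 0.5 * dt * fr$ffree * .F2A / at$mass[free]
    vcom <<- vcom + 0.5 * dt * fr$fcom * .F2A / bd$mass_total
    if (bd$rotational) {
      wd <- (as.numeric(fr$tau_body) * .F2A - cross3(w, bd$inertia * w)) / bd$inertia
      w <<- w + 0.5 * dt * wd
    }
  }
  drift <- function() {
    x[free, ] <<- x[free, ] + 0.5 * dt * v[free, , drop = FALSE]
    com <- ligand_com(system, x) + 0.5 * dt * vcom
    if (bd$rotational) q <<- quat_mult(q, quat_exp(0.5 * dt * w))
    R <- quat_to_mat(q)
    x[li, ] <<- sweep(bd$ref %*% t(R), 2, com, "+")
  }

  fr <- eval_forces(x)
  for (s in seq_len(n_steps)) {
    half_kick(fr)
    drift()
    v[free, ] <- c1 * v[free, , drop = FALSE] +
      c2f * matrix(stats::rnorm(3 * length(free)), length(free), 3)
    vcom <- c1 * vcom + c2t * stats::rnorm(3)
    if (bd$rotational) w <- c1 * w + c2r * stats::rnorm(3)
    drift()
    fr <- eval_forces(x)
    half_kick(fr)
  }
  state$coords <- x
  state$vel <- v
  state$lig_vcom <- vcom
  state$quat <- q / sqrt(sum(q^2))
  state$omega <- w
  state <- sync_ligand_coords(system, state)
  state$step_count <- state$step_count + as.integer(n_steps)
  state$time <- state$time + n_steps * dt
  state
}

ligand_com <- function(system, x) {
  li <- ligand_rows(system)
  m <- system$atoms$mass[li]
  colSums(x[li, , drop = FALSE] * m) / sum(m)
}

#' Kinetic energy and instantaneous temperature of a state
#'
#' @param system an `egress_system`.
#' @param state an `egress_state`.
#' @return List with `kinetic` (kcal/mol), `ndof`, and `temperature` (K).
#' @export
kinetic_energy <- function(system, state) {
  if (system$potential_kind %in% c("analytic1D", "analytic2D")) {
    m <- system$atoms$mass[1]
    ke <- 0.5 * m * sum(state$vel^2) / .F2A
    ndof <- length(state$vel)
  } else {
    at <- system$atoms
    free <- which(at$role == "protein")
    bd <- system$body
    ke <- 0.5 * sum(at$mass[free] * rowSums(state$vel[free, , drop = FALSE]^2)) / .F2A
    ke <- ke + 0.5 * bd$mass_total * sum(state$lig_vcom^2) / .F2A
    ndof <- 3 * length(free) + 3
    if (bd$rotational) {
      ke <- ke + 0.5 * sum(bd$inertia * state$omega^2) / .F2A
      ndof <- ndof + 3
    }
  }
  list(kinetic = ke, ndof = ndof, temperature = 2 * ke / (ndof * .kB))
}

# ---- quaternion helpers -----------------------------------------------------

quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

mat_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_exp <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(c(1, 0, 0, 0))
  c(cos(th / 2), sin(th / 2) * v / th)
}

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}
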