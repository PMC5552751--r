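# Memetic reaction-coordinate search: candidate ligand poses sampled in a
# local sphere, scored by the effective interaction functional Lambda
# (desolvation-like Gaussian term + optional vdW/electrostatics), best pose
# used as the target of a biasing force over m MD steps; the visited
# conformations assemble the egress path S(1..N).

#' Parameters of the effective-interaction functional and its minimization
#'
#' @param w Gaussian width of the desolvation term, Angstrom (default 3.5,
#'   the solvation-shell scale).
#' @param include_gamma include the vdW + electrostatic ligand-environment
#'   energy term in Lambda.
#' @param candidate_count number of candidate poses per search step (>= 2).
#' @param sphere_radius radius of the local sampling sphere, Angstrom.
#' @param local_refine_steps sweeps of derivative-free local descent applied
#'   to the best candidate.
#' @param rng_seed integer seed controlling candidate sampling.
#' @return List of class `lambda_params`.
#' @export
lambda_params <- function(w = 3.5, include_gamma = TRUE, candidate_count = 16,
                          sphere_radius = 2, local_refine_steps = 10,
                          rng_seed = 1) {
  if (w <= 0) stop("w must be > 0", call. = FALSE)
  if (sphere_radius <= 0) stop("sphere_radius must be > 0", call. = FALSE)
  if (candidate_count < 2) stop("candidate_count must be >= 2", call. = FALSE)
  structure(list(w = w, include_gamma = include_gamma,
                 candidate_count = as.integer(candidate_count),
                 sphere_radius = sphere_radius,
                 local_refine_steps = as.integer(local_refine_steps),
                 rng_seed = as.integer(rng_seed)),
            class = "lambda_params")
}

#' Path-search configuration
#'
#' @param segment_steps m, the number of MD steps per biased pulling segment.
#' @param bias_force_magnitude constant biasing force on the ligand center of
#'   mass, kcal/mol/A.
#' @param termination_distance ligand COM distance from the cage center at
#'   which the search stops, Angstrom; defaults to 1.3 x cage radius.
#' @param max_nodes upper bound on the number of path nodes.
#' @param orient_torque strength of the weak orienting torque toward the
#'   target pose, kcal/mol.
#' @return List of class `path_search_config`.
#' @export
path_search_config <- function(segment_steps = 100, bias_force_magnitude = 20,
                               termination_distance = NULL, max_nodes = 60,
                               orient_torque = 0.5) {
  if (segment_steps < 1) stop("segment_steps must be >= 1", call. = FALSE)
  if (!is.null(termination_distance) && termination_distance <= 0)
    stop("termination_distance must be > 0", call. = FALSE)
  structure(list(segment_steps = as.integer(segment_steps),
                 bias_force_magnitude = bias_force_magnitude,
                 termination_distance = termination_distance,
                 max_nodes = as.integer(max_nodes),
                 orient_torque = orient_torque),
            class = "path_search_config")
}

#' Effective ligand-environment interaction functional Lambda
#'
#' \deqn{\Lambda = \sum_{i,j} h_{ij}\, e^{-r_{ij}^2 / 2w^2} + \gamma,\qquad
#'       h_{ij} = s_i v_j + s_j v_i,}
#' where i runs over ligand atoms, j over environment atoms, s and v are the
#' per-atom partial volume and solvation coefficient, and gamma (optional) is
#' the vdW + electrostatic ligand-environment energy. Minimizing Lambda over
#' ligand poses picks the next target pose of the egress search.
#'
#' @param system an `egress_system` (pairwise3D).
#' @param conf a conformation consistent with the system.
#' @param params a [lambda_params()] list.
#' @return Lambda in kcal/mol.
#' @export
lambda_energy <- function(system, conf, params = lambda_params()) {
  conf <- as_conformation(conf)
  x <- conf$coords
  at <- system$atoms
  if (any(is.na(at$partial_volume)) || any(is.na(at$solvation_coefficient)))
    stop("atoms are missing partial_volume or solvation_coefficient", call. = FALSE)
  li <- ligand_rows(system); ei <- env_rows(system)
  lam <- 0
  for (i in li) {
    dx <- sweep(x[ei, , drop = FALSE], 2, x[i, ], "-")
    r2 <- rowSums(dx^2)
    h <- at$partial_volume[i] * at$solvation_coefficient[ei] +
      at$partial_volume[ei] * at$solvation_coefficient[i]
    lam <- lam + sum(h * exp(-r2 / (2 * params$w^2)))
  }
  if (isTRUE(params$include_gamma)) {
    pe <- suppressWarnings(pair_terms(system, x))
    lam <- lam + pe$vdw + pe$coulomb
  }
  lam
}

# ---- rigid-body poses -------------------------------------------------------

#' Extract the rigid-body pose of the ligand from coordinates
#'
#' @param system an `egress_system`.
#' @param coords full coordinate matrix (or conformation).
#' @return List with `com` (length 3) and `quat` (unit quaternion).
#' @export
ligand_pose <- function(system, coords) {
  x <- if (inherits(coords, "egress_conformation")) coords$coords else as.matrix(coords)
  bd <- system$body
  li <- ligand_rows(system)
  com <- colSums(x[li, , drop = FALSE] * bd$masses) / bd$mass_total
  if (nrow(bd$ref) < 3) return(list(com = com, quat = c(1, 0, 0, 0)))
  c0 <- sweep(x[li, , drop = FALSE], 2, com)
  H <- crossprod(bd$ref, c0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(com = com, quat = mat_to_quat(R))
}

# place the rigid ligand at a pose within base coordinates
pose_to_coords <- function(system, base_coords, pose) {
  x <- as.matrix(base_coords)
  li <- ligand_rows(system)
  R <- quat_to_mat(pose$quat)
  x[li, ] <- sweep(system$body$ref %*% t(R), 2, pose$com, "+")
  x
}

#' Sample candidate ligand poses in a local sphere
#'
#' Candidate 0 is the previous pose itself; the remaining poses have centers
#' of mass drawn uniformly from the sphere of radius `sphere_radius` about
#' the previous center and orientations perturbed by a random rotation of at
#' most 15 degrees. Deterministic given the seed.
#'
#' @param prev_pose a pose as returned by [ligand_pose()].
#' @param params a [lambda_params()] list.
#' @param seed optional seed override (defaults to `params$rng_seed`).
#' @return List of poses of length `candidate_count`.
#' @export
propose_candidates <- function(prev_pose, params, seed = NULL) {
  set.seed(as.integer(seed %||% params$rng_seed))
  n <- params$candidate_count
  out <- vector("list", n)
  out[[1]] <- prev_pose
  for (k in seq_len(n - 1L)) {
    u <- random_unit_vector()
    r <- params$sphere_radius * stats::runif(1)^(1 / 3)  # uniform in volume
    ax <- random_unit_vector()
    ang <- stats::runif(1, 0, 15 * pi / 180)
    out[[k + 1L]] <- list(com = prev_pose$com + r * u,
                          quat = quat_mult(quat_from_axis_angle(ax, ang), prev_pose$quat))
  }
  out
}

#' Minimize Lambda over candidate poses with local refinement
#'
#' Evaluates Lambda for every candidate, then applies derivative-free
#' coordinate-wise trust-region descent on the six rigid-body coordinates
#' (three translations, three incremental rotations) starting from the best
#' candidate. The refined Lambda never exceeds the best raw candidate value.
#'
#' @param system an `egress_system`.
#' @param candidates list of poses (see [propose_candidates()]).
#' @param params a [lambda_params()] list.
#' @param base_conf coordinates supplying the environment atoms (defaults to
#'   the system's construction coordinates).
#' @param center center of the sampling sphere constraining the refinement
#'   (defaults to the first candidate's COM); refined poses stay within
#'   `sphere_radius` of it, keeping the search local as in the
#'   propose-and-pull scheme.
#' @return List with `pose`, `lambda`, and `clashed` (TRUE when every
#'   candidate had a clamped-overlap energy).
#' @export
memetic_minimize <- function(system, candidates, params = lambda_params(),
                             base_conf = NULL, center = NULL) {
  if (length(candidates) == 0) stop("no candidate poses", call. = FALSE)
  base <- if (is.null(base_conf)) system$coords0
          else if (inherits(base_conf, "egress_conformation")) base_conf$coords
          else as.matrix(base_conf)
  eval_pose <- function(p) {
    x <- pose_to_coords(system, base, p)
    suppressWarnings(lambda_energy(system, x, params))
  }
  vals <- vapply(candidates, eval_pose, numeric(1))
  clash_thresh <- 1e4
  clashed <- all(vals > clash_thresh)
  if (clashed) warning("all candidate poses clash; returning the least-bad pose")
  best <- which.min(vals)
  pose <- candidates[[best]]
  fbest <- vals[best]

  center <- center %||% candidates[[1]]$com
  # trial moves leaving the sampling sphere are projected back onto it, so
  # the descent can slide along the boundary instead of pinning there
  clip_to_sphere <- function(p) {
    d <- p$com - center
    r <- sqrt(sum(d^2))
    if (r > params$sphere_radius) p$com <- center + d * (params$sphere_radius / r)
    p
  }
  step_t <- 0.25 * params$sphere_radius   # A
  step_r <- 0.05                          # rad
  for (it in seq_len(params$local_refine_steps)) {
    improved <- FALSE
    for (dim in 1:3) for (sgn in c(-1, 1)) {
      p2 <- pose
      p2$com[dim] <- p2$com[dim] + sgn * step_t
      p2 <- clip_to_sphere(p2)
      f2 <- eval_pose(p2)
      if (f2 < fbest) { pose <- p2; fbest <- f2; improved <- TRUE }
    }
    for (dim in 1:3) for (sgn in c(-1, 1)) {
      ax <- c(dim == 1, dim == 2, dim == 3)
      p2 <- pose
      p2$quat <- quat_mult(quat_from_axis_angle(ax, sgn * step_r), p2$quat)
      f2 <- eval_pose(p2)
      if (f2 < fbest) { pose <- p2; fbest <- f2; improved <- TRUE }
    }
    if (!improved) { step_t <- step_t / 2; step_r <- step_r / 2 }
    if (step_t < 1e-4) break
  }
  list(pose = pose, lambda = fbest, clashed = clashed)
}

#' Biased pulling segment toward a target pose
#'
#' Runs `segment_steps` Langevin steps with an added constant-magnitude force
#' on the ligand center of mass directed (re-evaluated every step) from the
#' current COM toward the target COM, plus a weak torque toward the target
#' orientation. When the COM coincides with the target the bias direction is
#' defined as the zero vector.
#'
#' @param system an `egress_system`.
#' @param state an `egress_state`.
#' @param target_pose target pose (see [ligand_pose()]).
#' @param cfg a [path_search_config()].
#' @return The advanced `egress_state`.
#' @export
biased_segment <- function(system, state, target_pose, cfg) {
  li <- ligand_rows(system)
  bd <- system$body
  mag <- cfg$bias_force_magnitude
  kt <- cfg$orient_torque
  bias_fun <- function(sys, x, st) {
    F <- matrix(0, nrow(x), 3)
    com <- ligand_com(sys, x)
    dv <- target_pose$com - com
    dn <- sqrt(sum(dv^2))
    if (mag > 0 && dn > 1e-10) {
      fcom <- mag * dv / dn
      F[li, ] <- F[li, ] + outer(bd$masses / bd$mass_total, fcom)
    }
    if (kt > 0 && bd$rotational) {
      cur <- ligand_pose(sys, x)
      dq <- quat_mult(target_pose$quat, c(cur$quat[1], -cur$quat[2:4]))
      ang <- 2 * acos(pmin(1, abs(dq[1])))
      if (ang > 1e-8) {
        axis <- dq[2:4] * sign(dq[1])
        axis <- axis / sqrt(sum(axis^2))
        tau <- kt * ang * axis            # world-frame torque, kcal/mol
        rw <- sweep(x[li, , drop = FALSE], 2, com)
        denom <- sum(rowSums(rw^2))
        if (denom > 1e-8) {
          # per-atom forces realizing a torque approximately equal to tau
          ft <- t(vapply(seq_along(li), function(i) cross3(tau, rw[i, ]), numeric(3)))
          F[li, ] <- F[li, ] + ft / denom
        }
      }
    }
    F
  }
  langevin_step(system, state, cfg$segment_steps,
                extra_force = if (mag > 0 || kt > 0) bias_fun else NULL)
}

#' Construct a path object from conformations
#'
#' @param nodes ordered list of conformations S(1..N); node 1 is the bound
#'   state.
#' @param alignment_set,displacement_set 1-based atom indices; must be
#'   nonempty and disjoint.
#' @param lambda optional path-variable lambda, A^-2; when `NULL` the 2.3 /
#'   <MSD> rule of [choose_lambda()] is applied.
#' @param complete logical flag; `FALSE` marks a search stopped at the node
#'   budget before reaching the egress distance.
#' @return Object of class `egress_path`.
#' @export
new_path <- function(nodes, alignment_set, displacement_set, lambda = NULL,
                     complete = TRUE) {
  if (length(nodes) < 2) stop("a path needs at least 2 nodes", call. = FALSE)
  if (length(alignment_set) == 0 || length(displacement_set) == 0 ||
      length(intersect(alignment_set, displacement_set)) > 0)
    stop("alignment and displacement sets must be nonempty and disjoint", call. = FALSE)
  p <- structure(list(nodes = nodes, alignment_set = alignment_set,
                      displacement_set = displacement_set,
                      lambda = lambda, lambda_override = !is.null(lambda),
                      complete = complete),
                 class = "egress_path")
  msds <- vapply(seq_len(length(nodes) - 1L), function(k)
    msd_displacement(nodes[[k + 1L]], nodes[[k]], alignment_set, displacement_set),
    numeric(1))
  p$neighbor_msd <- msds
  p$mean_neighbor_msd <- mean(msds)
  if (is.null(lambda)) p$lambda <- choose_lambda(p)
  p
}

#' @export
print.egress_path <- function(x, ...) {
  cat(sprintf("<egress_path> %d nodes, lambda = %.4g A^-2, <MSD> = %.3g A^2%s\n",
              length(x$nodes), x$lambda, x$mean_neighbor_msd,
              if (isTRUE(x$complete)) "" else " [incomplete]"))
  invisible(x)
}

#' Search a ligand egress path by memetic sampling
#'
#' Iterates propose-minimize-pull: candidate poses are sampled around the
#' current ligand pose, the pose minimizing Lambda is chosen as the target,
#' the ligand is pulled toward it for `segment_steps` Langevin steps, and the
#' resulting full-system snapshot is appended as the next path node. The
#' search stops when the ligand COM reaches `termination_distance` from the
#' cage center (egress) or at `max_nodes` (the path is then flagged
#' incomplete).
#'
#' @param system a cage `egress_system` from [make_cage_ligand()].
#' @param state0 an equilibrated `egress_state` (caller's responsibility).
#' @param lp a [lambda_params()] list.
#' @param cfg a [path_search_config()].
#' @return An `egress_path`; alignment set = cage atoms, displacement set =
#'   ligand atoms.
#' @export
build_path <- function(system, state0, lp = lambda_params(),
                       cfg = path_search_config()) {
  center <- system$cage$center %||% c(0, 0, 0)
  term <- cfg$termination_distance %||% (1.3 * system$cage$radius)
  state <- state0
  nodes <- list(conformation(state$coords, time = state$time, label = "bound state"))
  complete <- FALSE
  for (k in seq_len(cfg$max_nodes - 1L)) {
    prev <- ligand_pose(system, state$coords)
    cand <- propose_candidates(prev, lp, seed = lp$rng_seed + 7919L * k)
    best <- memetic_minimize(system, cand, lp, base_conf = state$coords)
    state <- biased_segment(system, state, best$pose, cfg)
    nodes[[k + 1L]] <- conformation(state$coords, time = state$time,
                                    label = sprintf("S(%d)", k + 1L))
    d <- sqrt(sum((ligand_com(system, state$coords) - center)^2))
    if (d >= term) { complete <- TRUE; break }
  }
  if (!complete) warning("node budget reached before egress; returning partial path")
  ai <- which(system$atoms$role == "protein")
  di <- ligand_rows(system)
  new_path(nodes, alignment_set = ai, displacement_set = di, complete = complete)
}

#' Resample a path to near-equidistant nodes
#'
#' Nodes are re-sampled by linear interpolation at equal arc length in
#' displacement-set coordinate space (all nodes first brought into the frame
#' of node 1 via the alignment set); endpoints are preserved exactly.
#'
#' @param path an `egress_path`.
#' @param target_n desired number of nodes (>= 2).
#' @return A new `egress_path` with `target_n` nodes.
#' @export
reparameterize_path <- function(path, target_n) {
  if (target_n < 2) stop("target_n must be >= 2", call. = FALSE)
  N <- length(path$nodes)
  ref <- node_coords(path$nodes[[1]])
  aligned <- vector("list", N)
  aligned[[1]] <- ref
  for (k in 2:N)
    aligned[[k]] <- kabsch_align(node_coords(path$nodes[[k]]), ref,
                                 path$alignment_set)$coords
  di <- path$displacement_set
  Y <- t(vapply(aligned, function(a) as.numeric(a[di, , drop = FALSE]),
                numeric(3 * length(di))))
  seg <- sqrt(rowSums((Y[-1, , drop = FALSE] - Y[-N, , drop = FALSE])^2))
  L <- c(0, cumsum(seg))
  if (L[N] <= 1e-10) stop("degenerate path: zero total length", call. = FALSE)
  targets <- L[N] * (seq_len(target_n) - 1) / (target_n - 1)
  nodes <- vector("list", target_n)
  nodes[[1]] <- path$nodes[[1]]
  nodes[[target_n]] <- path$nodes[[N]]
  if (target_n > 2) {
    for (j in 2:(target_n - 1L)) {
      i <- max(which(L <= targets[j] + 1e-12))
      i <- min(i, N - 1L)
      tfrac <- if (seg[i] > 0) (targets[j] - L[i]) / seg[i] else 0
      xi <- (1 - tfrac) * aligned[[i]] + tfrac * aligned[[i + 1L]]
      nodes[[j]] <- conformation(xi, time = NA_real_,
                                 label = sprintf("interp %.3f", targets[j] / L[N]))
    }
  }
  new_path(nodes, path$alignment_set, path$displacement_set,
           lambda = if (isTRUE(path$lambda_override)) path$lambda else NULL,
           complete = path$complete)
}
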