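# Shared fixtures and independent oracles used across the test files.

kB <- 0.0019872041

# ---- cached expensive runs (computed once per test session) ----------------

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

# converged well-tempered run on the 4 kcal/mol double well at the standard
# tempering parameters (T = 300 K, dT = 3300 K, 0.48 kcal/mol every 0.25 ps)
dw_metad_run <- function(seed) {
  cached(paste0("dw_metad_", seed), {
    sys <- make_double_well(4, 1)
    run_metad_1d(sys, n_steps = 5e6, seed = seed)
  })
}

# the cage configuration used for the egress-path studies: dense shell so the
# engineered gap is the only soft spot, stiff site restraints
study_cage <- function(seed, n_tunnels = 1) {
  make_cage_ligand(150, 10, n_tunnels, seed = seed, tunnel_halfwidth = 30,
                   restraint_k = 50)
}

study_lambda_params <- function(seed) lambda_params(w = 6, rng_seed = seed)

study_path_config <- function(max_nodes = 60) {
  path_search_config(bias_force_magnitude = 5, segment_steps = 200,
                     max_nodes = max_nodes)
}

search_egress_path <- function(seed, max_nodes = 60) {
  cached(paste0("egress_", seed, "_", max_nodes), {
    sys <- study_cage(100 + seed)
    st <- thermo_state(sys, 300, friction = 10, dt = 0.002, seed = seed)
    st <- langevin_step(sys, st, 200)
    p <- suppressWarnings(build_path(sys, st, study_lambda_params(seed),
                                     study_path_config(max_nodes)))
    list(system = sys, path = p)
  })
}

# angle (degrees) between the final ligand COM and the first tunnel axis
egress_exit_angle <- function(res) {
  fin <- res$path$nodes[[length(res$path$nodes)]]$coords
  li <- which(res$system$atoms$role == "ligand")
  com <- colMeans(fin[li, ])
  u <- res$system$cage$tunnel_axes[1, ]
  acos(sum(com * u) / sqrt(sum(com^2))) * 180 / pi
}

# ---- independent oracles ----------------------------------------------------

# Boltzmann density of U(x) = barrier*((x/a)^2-1)^2 on histogram bins, by
# fine-grid quadrature
boltzmann_bin_density <- function(breaks, barrier, spacing = 1, temp = 300) {
  U <- function(x) barrier * ((x / spacing)^2 - 1)^2
  beta <- 1 / (kB * temp)
  fine <- seq(min(breaks), max(breaks), length.out = 8001)
  h <- fine[2] - fine[1]
  p <- exp(-beta * U(fine))
  Z <- sum(p) * h
  vapply(seq_len(length(breaks) - 1), function(b) {
    m <- fine >= breaks[b] & fine < breaks[b + 1]
    sum(p[m]) * h / Z / (breaks[b + 1] - breaks[b])
  }, numeric(1))
}

# DBSCAN oracle built a different way: core points from neighborhood counts,
# clusters = connected components of the core-core eps-graph (igraph), border
# points attached to the first core neighbor in point order.
dbscan_oracle <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  core <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= min_pts, logical(1))
  labels <- rep(-1L, n)
  ci <- which(core)
  if (length(ci) > 0) {
    adj <- d[ci, ci, drop = FALSE] <= eps
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    # renumber components by order of first appearance (matches queue DBSCAN)
    first <- order(vapply(seq_len(max(comp)), function(c2) min(which(comp == c2)),
                          numeric(1)))
    remap <- integer(max(comp)); remap[first] <- seq_along(first) - 1L
    labels[ci] <- remap[comp]
    for (i in which(!core)) {
      nb <- ci[d[i, ci] <= eps]
      if (length(nb) > 0) labels[i] <- labels[nb[1]]
    }
  }
  labels
}

# exhaustive grid search over ligand COM positions within the sampling
# sphere: 0.05 A grid, then a 0.005 A refinement pass around the coarse
# argmin so discretization error is below the comparison tolerance
grid_search_lambda <- function(sys, lp, quat, radius) {
  eval_at <- function(p) {
    x <- egresslab:::pose_to_coords(sys, sys$coords0, list(com = p, quat = quat))
    suppressWarnings(lambda_energy(sys, x, lp))
  }
  sweep_box <- function(center, half, step) {
    gr <- seq(-half, half, by = step)
    best <- Inf; argmin <- center
    for (dx in gr) for (dy in gr) for (dz in gr) {
      p <- center + c(dx, dy, dz)
      if (sum(p^2) > radius^2) next
      v <- eval_at(p)
      if (v < best) { best <- v; argmin <- p }
    }
    list(value = best, com = argmin)
  }
  coarse <- sweep_box(c(0, 0, 0), radius, 0.05)
  fine <- sweep_box(coarse$com, 0.06, 0.005)
  min(coarse$value, fine$value)
}

# two-step RMSD oracle: explicit optimal transform, then root mean square
rmsd_oracle <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  H <- crossprod(A, B)
  sv <- svd(H)
  R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  sqrt(mean(rowSums((A %*% t(R) - B)^2)))
}

# path whose nodes give prescribed displacement-set MSDs {0, 4, 16} from the
# first node when the conformation sits on node 1 (alignment atoms fixed)
worked_example_path <- function(lambda = 0.18) {
  ref <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  mknode <- function(d) conformation(rbind(ref, c(d, 0, 0)))
  new_path(list(mknode(0), mknode(2), mknode(4)),
           alignment_set = 1:4, displacement_set = 5, lambda = lambda)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# planted two-family (open/closed) conformer mixture from the cage fixture
planted_mixture <- function(n_closed = 42, n_open = 18, noise_sd = 0.3,
                            seed = 11) {
  sys <- make_cage_ligand(60, 10, 1, seed = 7)
  sites <- sys$coords0
  prot <- which(sys$atoms$role == "protein")
  u <- sys$cage$tunnel_axes[1, ]
  ring <- prot[acos(pmax(pmin(as.numeric(sites[prot, ] %*% u) / 10, 1), -1)) <
                 45 * pi / 180]
  open_coords <- sites
  open_coords[ring, ] <- open_coords[ring, ] +
    3 * matrix(u, length(ring), 3, byrow = TRUE)
  set.seed(seed)
  mk <- function(base, n, lab) lapply(seq_len(n), function(i)
    conformation(base + matrix(stats::rnorm(length(base), sd = noise_sd),
                               nrow(base)), label = lab))
  list(confs = c(mk(sites, n_closed, "closed"), mk(open_coords, n_open, "open")),
       subset = prot, n_closed = n_closed, n_open = n_open,
       family = rep(c("closed", "open"), c(n_closed, n_open)))
}
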