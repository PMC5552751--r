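# Memetic egress-path search: the interaction functional, candidate
# sampling, local minimization, biased pulling, path assembly.

two_atom_system <- function() {
  atoms <- make_atoms(c("ligand", "protein"), mass = c(30, 40),
                      partial_volume = c(1, 2),
                      solvation_coefficient = c(0.5, 1))
  egresslab:::new_system(atoms, "pairwise3D",
                         coords0 = rbind(c(0, 0, 0), c(3, 0, 0)))
}

test_that("the interaction functional matches its closed form", {
  sys <- two_atom_system()
  lp <- lambda_params(w = 1, include_gamma = FALSE)
  at_r <- function(r) conformation(rbind(c(0, 0, 0), c(r, 0, 0)))
  # h = s_lig * v_prot + s_prot * v_lig = 1*1 + 2*0.5 = 2
  expect_equal(lambda_energy(sys, at_r(0), lp), 2)
  expect_equal(lambda_energy(sys, at_r(1), lp), 2 * exp(-0.5), tolerance = 1e-12)
  # desolvation term vanishes at large separation; gamma remains
  lpg <- lambda_params(w = 1, include_gamma = TRUE)
  far <- at_r(500)
  gamma_only <- potential_energy(sys, far)
  expect_equal(lambda_energy(sys, far, lpg),
               gamma_only$vdw + gamma_only$coulomb, tolerance = 1e-10)
})

test_that("the functional vanishes when solvation coefficients are zero", {
  sys <- study_cage(5)
  sys$atoms$solvation_coefficient[] <- 0
  lp <- lambda_params(include_gamma = FALSE)
  set.seed(2)
  for (i in 1:5) {
    x <- sys$coords0 + matrix(rnorm(length(sys$coords0), sd = 0.5),
                              nrow(sys$coords0))
    expect_identical(lambda_energy(sys, conformation(x), lp), 0)
  }
})

test_that("candidate proposals are local, deterministic, and fill the sphere", {
  pose <- list(com = c(1, 2, 3), quat = c(1, 0, 0, 0))
  lp <- lambda_params(sphere_radius = 2, candidate_count = 8, rng_seed = 9)
  cand <- propose_candidates(pose, lp)
  expect_length(cand, 8)
  expect_identical(cand[[1]], pose)
  disp <- vapply(cand, function(p) sqrt(sum((p$com - pose$com)^2)), numeric(1))
  expect_true(all(disp <= 2 + 1e-12))
  expect_identical(propose_candidates(pose, lp), cand)

  lp2 <- lambda_params(sphere_radius = 2, candidate_count = 3000, rng_seed = 1)
  disp2 <- vapply(propose_candidates(pose, lp2),
                  function(p) sqrt(sum((p$com - pose$com)^2)), numeric(1))
  expect_gt(max(disp2), 2 * 0.99)   # the empirical maximum approaches rho
})

test_that("minimization equals exhaustive grid search on a 2-atom instance", {
  sys <- two_atom_system()
  lp <- lambda_params(w = 1.5, include_gamma = TRUE, candidate_count = 12,
                      sphere_radius = 1.5, local_refine_steps = 25, rng_seed = 3)
  pose0 <- ligand_pose(sys, sys$coords0)
  cand <- propose_candidates(pose0, lp, seed = 9)
  mm <- memetic_minimize(sys, cand, lp)
  raw_best <- min(vapply(cand, function(p) {
    x <- egresslab:::pose_to_coords(sys, sys$coords0, p)
    suppressWarnings(lambda_energy(sys, x, lp))
  }, numeric(1)))
  expect_lte(mm$lambda, raw_best)
  grid_best <- grid_search_lambda(sys, lp, pose0$quat, 1.5)
  expect_lt(abs(mm$lambda - grid_best), 1e-3)
})

test_that("a single candidate with no refinement is returned unchanged", {
  sys <- two_atom_system()
  lp <- lambda_params(local_refine_steps = 0)
  pose <- list(com = c(0.3, 0, 0), quat = c(1, 0, 0, 0))
  mm <- memetic_minimize(sys, list(pose), lp)
  expect_identical(mm$pose, pose)
  expect_false(mm$clashed)
})

test_that("zero bias force reproduces the unbiased trajectory", {
  sys <- study_cage(3)
  st <- thermo_state(sys, 300, friction = 10, dt = 0.002, seed = 4)
  target <- ligand_pose(sys, sys$coords0)
  cfg <- path_search_config(segment_steps = 40, bias_force_magnitude = 0,
                            orient_torque = 0)
  a <- biased_segment(sys, st, target, cfg)
  b <- langevin_step(sys, st, 40)
  expect_equal(a$coords, b$coords, tolerance = 1e-12)
})

test_that("a strong pull moves the ligand along the target direction", {
  # ligand alone in a huge cage: effectively no obstacles
  sys <- make_cage_ligand(30, 30, 1, seed = 2, tunnel_halfwidth = 25)
  st <- thermo_state(sys, 300, friction = 10, dt = 0.002, seed = 8)
  com0 <- egresslab:::ligand_com(sys, st$coords)
  dir <- c(0, 0, 1)
  target <- list(com = com0 + 6 * dir, quat = st$quat)
  cfg <- path_search_config(segment_steps = 400, bias_force_magnitude = 30)
  st2 <- biased_segment(sys, st, target, cfg)
  move <- egresslab:::ligand_com(sys, st2$coords) - com0
  cosang <- sum(move * dir) / sqrt(sum(move^2))
  expect_gt(cosang, 0.9)
})

test_that("path search starts from the bound state and always progresses", {
  res <- search_egress_path(1, max_nodes = 8)
  p <- res$path
  expect_gte(length(p$nodes), 2)
  # node 1 is the starting snapshot
  expect_equal(p$nodes[[1]]$label, "bound state")
  expect_true(all(p$neighbor_msd > 0))
})

test_that("the full search is reproducible from its seeds", {
  a <- search_egress_path(2, max_nodes = 5)
  b <- search_egress_path(2, max_nodes = 5)
  expect_identical(lapply(a$path$nodes, function(n) n$coords),
                   lapply(b$path$nodes, function(n) n$coords))
})

test_that("egress paths exit through the engineered tunnel", {
  res <- search_egress_path(1)
  p <- res$path
  expect_true(p$complete)
  fin <- p$nodes[[length(p$nodes)]]$coords
  li <- which(res$system$atoms$role == "ligand")
  com <- colMeans(fin[li, ])
  u <- res$system$cage$tunnel_axes[1, ]
  ang <- acos(sum(com * u) / sqrt(sum(com^2))) * 180 / pi
  expect_lt(ang, 30)
})

test_that("reparameterization equalizes spacing and preserves endpoints", {
  # collinear ligand positions at arc fractions 0, 0.9, 1.0
  ref <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  mknode <- function(d) conformation(rbind(ref, c(d, 0, 0)))
  p <- new_path(list(mknode(0), mknode(9), mknode(10)),
                alignment_set = 1:4, displacement_set = 5)
  q <- reparameterize_path(p, 3)
  expect_identical(q$nodes[[1]]$coords, p$nodes[[1]]$coords)
  expect_identical(q$nodes[[3]]$coords, p$nodes[[3]]$coords)
  expect_equal(q$nodes[[2]]$coords[5, 1], 5, tolerance = 1e-9)
  expect_lt(diff(range(q$neighbor_msd)) / mean(q$neighbor_msd), 0.1)

  # an already-equidistant path is unchanged
  pe <- new_path(list(mknode(0), mknode(5), mknode(10)),
                 alignment_set = 1:4, displacement_set = 5)
  qe <- reparameterize_path(pe, 3)
  for (k in 1:3)
    expect_equal(qe$nodes[[k]]$coords, pe$nodes[[k]]$coords, tolerance = 1e-9)
})

test_that("degenerate and invalid paths are rejected", {
  ref <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  n0 <- conformation(rbind(ref, c(1, 0, 0)))
  expect_error(new_path(list(n0), 1:4, 5), "at least 2")
  expect_error(new_path(list(n0, n0), 1:4, integer(0)), "disjoint|nonempty")
  expect_error(new_path(list(n0, n0), 1:5, 5), "disjoint|nonempty")
  p0 <- suppressWarnings(new_path(list(n0, n0), 1:4, 5, lambda = 1))
  expect_error(reparameterize_path(p0, 3), "degenerate|zero")
})
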