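# Toy engine: fixture construction, energies, restraints, Langevin dynamics.

test_that("double-well potential has the prescribed closed form", {
  sys <- make_double_well(4, 1)
  expect_equal(potential_energy(sys, conformation(matrix(0)))$total, 4)
  expect_equal(potential_energy(sys, conformation(matrix(1)))$total, 0)
  expect_equal(potential_energy(sys, conformation(matrix(-1)))$total, 0)
  expect_equal(potential_energy(sys, conformation(matrix(0.5)))$total, 2.25)
  sys2 <- make_double_well(2.5, 1.7)
  expect_equal(potential_energy(sys2, conformation(matrix(0)))$total, 2.5)
  expect_lt(abs(potential_energy(sys2, conformation(matrix(1.7)))$total), 1e-12)
})

test_that("non-positive double-well parameters are rejected", {
  expect_error(make_double_well(0, 1), "barrier")
  expect_error(make_double_well(4, -1), "spacing")
})

test_that("Lennard-Jones minimum and restraint energies match closed forms", {
  atoms <- make_atoms(c("ligand", "protein"), mass = 10, charge = 0,
                      lj_epsilon = 0.3, lj_sigma = 3)
  r <- 2^(1 / 6) * 3
  sys <- egresslab:::new_system(atoms, "pairwise3D",
                               coords0 = rbind(c(0, 0, 0), c(r, 0, 0)))
  pe <- potential_energy(sys, conformation(sys$coords0))
  expect_equal(pe$vdw, -0.3, tolerance = 1e-12)
  expect_equal(pe$total, pe$vdw + pe$coulomb + pe$restraint)

  # harmonic position restraint: 1 A displacement at k = 10 -> 5 kcal/mol
  rs <- list(list(kind = "harmonicPosition", targets = 1L,
                  reference = matrix(c(r, 0, 0), 1), spring_constant = 10))
  sys2 <- egresslab:::new_system(atoms, "pairwise3D", restraints = rs,
                                 coords0 = sys$coords0)
  moved <- sys2$coords0; moved[2, 3] <- 1
  expect_equal(potential_energy(sys2, conformation(moved))$restraint, 5)
})

test_that("distance upper wall is one-sided: zero below the reference", {
  atoms <- make_atoms(c("ligand", "protein"), mass = c(10, 10))
  # wall at 26 A on the ligand COM, ligand placed at 25 A -> no contribution
  rs <- list(list(kind = "distanceUpperWall", targets = 0L, reference = 26,
                  spring_constant = 10, center = c(0, 0, 0)))
  sys <- egresslab:::new_system(atoms, "pairwise3D", restraints = rs,
                               coords0 = rbind(c(25, 0, 0), c(100, 0, 0)))
  expect_identical(potential_energy(sys, conformation(sys$coords0))$restraint, 0)
  over <- sys$coords0; over[1, 1] <- 28
  expect_equal(potential_energy(sys, conformation(over))$restraint,
               0.5 * 10 * 4)
})

test_that("overlapping coordinates give a large finite energy with a warning", {
  atoms <- make_atoms(c("ligand", "protein"), mass = 10)
  sys <- egresslab:::new_system(atoms, "pairwise3D",
                               coords0 = rbind(c(0, 0, 0), c(5, 0, 0)))
  x <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_warning(pe <- potential_energy(sys, conformation(x)), "overlap")
  expect_true(is.finite(pe$total))
  expect_gt(pe$total, 1e3)
})

test_that("cage construction is deterministic and geometrically sound", {
  s1 <- make_cage_ligand(60, 10, 3, seed = 7)
  s2 <- make_cage_ligand(60, 10, 3, seed = 7)
  expect_identical(s1, s2)
  s3 <- make_cage_ligand(60, 10, 3, seed = 8)
  expect_false(identical(s1$coords0, s3$coords0))

  li <- which(s1$atoms$role == "ligand")
  com <- colMeans(s1$coords0[li, ])
  expect_lt(sqrt(sum(com^2)), 10 / 2)

  # three disjoint angular gaps, each wider than the ligand diameter
  axes <- s1$cage$tunnel_axes
  expect_identical(nrow(axes), 3L)
  hw <- s1$cage$tunnel_halfwidth * pi / 180
  for (i in 1:2) for (j in (i + 1):3) {
    sep <- acos(max(-1, min(1, sum(axes[i, ] * axes[j, ]))))
    expect_gt(sep, 2 * hw)
  }
  sites <- s1$coords0[s1$atoms$role == "protein", ]
  lig_xyz <- s1$coords0[li, ]
  lig_diam <- max(dist(lig_xyz))
  for (k in 1:3) {
    ang <- acos(pmax(pmin(as.numeric((sites / 10) %*% axes[k, ]), 1), -1))
    expect_gt(min(ang), hw)                     # gap is empty
    chord <- 2 * 10 * sin(hw)
    expect_gt(chord, lig_diam)                  # and wide enough
  }
})

test_that("infeasible tunnel geometry is rejected", {
  expect_error(make_cage_ligand(60, 10, 6, seed = 1, tunnel_halfwidth = 40),
               "infeasible|non-overlapping")
  expect_error(make_cage_ligand(60, 8, 1, seed = 1, tunnel_halfwidth = 8),
               "gap narrower|infeasible")
})

test_that("the engineered tunnel is the sparsest region of the study cage", {
  sys <- study_cage(101)
  sites <- sys$coords0[sys$atoms$role == "protein", ]
  u <- sys$cage$tunnel_axes[1, ]
  set.seed(1)
  dirs <- matrix(rnorm(3000), 1000, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  minang <- apply(acos(pmax(pmin(tcrossprod(dirs, sites / 10), 1), -1)), 1, min)
  angax <- acos(pmax(pmin(dirs %*% matrix(u), 1), -1))
  # holes away from the tunnel are narrower than the tunnel itself
  expect_lt(max(minang[angax > 40 * pi / 180]), max(minang[angax < 10 * pi / 180]))
})

test_that("free flight: zero force and zero friction gives ballistic motion", {
  atoms <- make_atoms("ligand", mass = 10)
  sys <- egresslab:::new_system(atoms, "pairwise3D",
                               coords0 = matrix(c(0, 0, 0), 1))
  st <- thermo_state(sys, 300, friction = 0, dt = 0.001, seed = 1)
  st$lig_vcom <- c(1, 0, 0)
  st <- egresslab:::sync_ligand_coords(sys, st)
  x0 <- st$coords[1, ]
  st2 <- langevin_step(sys, st, 1000)
  expect_equal(st2$coords[1, ] - x0, c(1, 0, 0), tolerance = 1e-9)
  expect_identical(st2$step_count, 1000L)
})

test_that("trajectories are reproducible from the state seed", {
  sys <- make_cage_ligand(30, 9, 1, seed = 3)
  st <- thermo_state(sys, 300, friction = 5, dt = 0.002, seed = 42)
  a <- langevin_step(sys, st, 50)
  b <- langevin_step(sys, st, 50)
  expect_identical(a$coords, b$coords)
  expect_identical(a$vel, b$vel)
})

test_that("microcanonical limit conserves energy on the double well", {
  sys <- make_double_well(4, 1)
  st <- thermo_state(sys, 300, friction = 0, dt = 2e-4, seed = 7)
  etot <- function(s) potential_energy(sys, conformation(s$coords))$total +
    kinetic_energy(sys, s)$kinetic
  e0 <- etot(st)
  drift <- 0
  s <- st
  for (i in 1:20) {
    s <- langevin_step(sys, s, 500)
    drift <- max(drift, abs(etot(s) - e0))
  }
  # < 1e-3 of the mean thermal energy (~kB T per oscillator)
  expect_lt(drift, 1e-3 * kB * 300)
})

test_that("thermostat reproduces the target temperature (equipartition)", {
  sys <- make_double_well(4, 1)
  run <- run_metad_1d(sys, n_steps = 1e6, h0 = 0, seed = 5, sample_stride = 10)
  ke <- 0.5 * sys$atoms$mass[1] * run$colvar$v^2 / 418.4
  se <- sd(ke) / sqrt(length(ke) / 50)    # generous autocorrelation allowance
  expect_lt(abs(mean(ke) - kB * 300 / 2), max(2 * se, 0.05 * kB * 300 / 2))
})

test_that("unbiased sampling reproduces the Boltzmann density", {
  sys <- make_double_well(1, 1)
  run <- run_metad_1d(sys, n_steps = 2e6, h0 = 0, seed = 6, sample_stride = 10)
  br <- seq(-2, 2, length.out = 41)
  x <- run$colvar$value[abs(run$colvar$value) < 2]
  hc <- hist(x, breaks = br, plot = FALSE)
  dens_a <- boltzmann_bin_density(br, barrier = 1)
  l1 <- sum(abs(hc$density - dens_a)) * diff(br)[1]
  expect_lt(l1, 0.05)
})

test_that("atom table and state validation reject bad input", {
  expect_error(make_atoms("solvent", 1), "role")
  expect_error(make_atoms("ligand", mass = -1), "mass")
  sys <- make_double_well(4, 1)
  expect_error(thermo_state(sys, temperature = -10), "temperature")
  expect_error(langevin_step(sys, thermo_state(sys), 0), "n_steps")
})
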