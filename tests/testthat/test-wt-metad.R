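# Well-tempered metadynamics: bias bookkeeping, tempering rule, estimator,
# c(t) reweighting, convergence diagnostics.

test_that("the bias potential is the sum of the deposited Gaussians", {
  b <- bias_state()
  expect_identical(bias_potential(b, 0.3), 0)
  b1 <- bias_state(tibble::tibble(time = 0, center = 0, width = 1, height = 2))
  expect_equal(bias_potential(b1, 0), 2)
  expect_equal(bias_potential(b1, 1), 2 * exp(-0.5), tolerance = 1e-12)
  b2 <- deposit_gaussian(b1, 1, 0.5, time = 1)
  expect_identical(nrow(b2$kernels), 2L)
  expect_equal(bias_potential(b2, 1),
               2 * exp(-0.5) + b2$kernels$height[2], tolerance = 1e-12)
})

test_that("deposition follows the well-tempered height rule", {
  b <- bias_state(h0 = 0.48, delta_t = 3300)
  b <- deposit_gaussian(b, 0, 0.1, time = 0.25)
  expect_equal(b$kernels$height[1], 0.48)           # V = 0 at first deposition
  # place the CV where V equals kB * dT -> height h0 / e
  kBdT <- kB * 3300
  b2 <- bias_state(tibble::tibble(time = 0, center = 0, width = 100,
                                  height = kBdT),
                   h0 = 0.48, delta_t = 3300)
  b2 <- deposit_gaussian(b2, 0, 0.1, time = 0.25)
  expect_equal(b2$kernels$height[2], 0.48 / exp(1), tolerance = 1e-6)
  expect_error(deposit_gaussian(b, 0, 0), "width")
})

test_that("default deposition settings give the 1.92 kcal/mol per ps rate", {
  b <- bias_state()
  expect_equal(b$h0 / b$deposit_interval, 1.92)
})

test_that("Gaussian heights decay along a converging double-well run", {
  run <- dw_metad_run(1)
  h <- run$bias$kernels$height
  n <- length(h)
  thirds <- split(h, cut(seq_len(n), 3, labels = FALSE))
  m <- vapply(thirds, mean, numeric(1))
  expect_true(all(diff(m) < 0))          # block means non-increasing
  expect_lt(m[3], 0.05 * run$bias$h0)
})

test_that("adaptive width tracks the trailing CV fluctuation", {
  hist_alt <- tibble::tibble(time = seq(0, 1, by = 0.01),
                             value = rep(c(-0.7, 0.7), length.out = 101))
  w <- adaptive_width(hist_alt, tau = 0.5, floor = 0.01)
  expect_equal(w, sd(rep(c(-0.7, 0.7), length.out = 50)), tolerance = 0.05)
  hist_const <- tibble::tibble(time = seq(0, 1, by = 0.01), value = 1)
  expect_identical(adaptive_width(hist_const, tau = 0.5, floor = 0.02), 0.02)
  expect_error(adaptive_width(hist_const, tau = 2), "span")
  short <- tibble::tibble(time = c(0, 1), value = c(0, 1))
  expect_error(adaptive_width(short, tau = 0.5), "sampling interval")
})

test_that("the z wall is one-sided and C1-continuous", {
  expect_identical(z_wall_force(5.9, 6, 100)$energy, 0)
  expect_identical(z_wall_force(5.9, 6, 100)$force, 0)
  expect_equal(z_wall_force(7, 6, 100)$energy, 50)
  expect_equal(z_wall_force(7, 6, 100)$force, -100)
  eps <- 1e-9
  expect_lt(abs(z_wall_force(6 + eps, 6, 100)$energy), 1e-12)
  expect_lt(abs(z_wall_force(6 + eps, 6, 100)$force), 1e-6)
  expect_error(z_wall_force(1, 6, 0), "kappa")
})

test_that("the free-energy estimator applies the tempering prefactor", {
  # T = 300, dT = 3300: a bias depth of 1.1 maps to a free-energy depth 1.2
  g <- seq(-3, 3, length.out = 401)    # wide enough that the kernel tail ~ 0
  b <- bias_state(tibble::tibble(time = 0, center = 0, width = 0.3, height = 1.1),
                  temperature = 300, delta_t = 3300)
  f <- free_energy_estimate(b, g)
  expect_equal(min(f$F), 0)
  expect_equal(max(f$F), 1.1 * (300 + 3300) / 3300, tolerance = 1e-9)
  expect_equal(max(f$F), 1.2, tolerance = 1e-9)

  # zero bias -> flat zero profile
  b0 <- bias_state(tibble::tibble(time = 0, center = 0, width = 1, height = 0))
  expect_true(all(free_energy_estimate(b0, g)$F == 0))

  # doubling all heights doubles free-energy differences
  b2 <- b; b2$kernels$height <- 2 * b$kernels$height
  f2 <- free_energy_estimate(b2, g)
  expect_equal(f2$F, 2 * f$F, tolerance = 1e-9)

  expect_error(free_energy_estimate(bias_state(), g), "empty")
  expect_error(free_energy_estimate(b, rev(g)), "increasing")
})

test_that("the reweighting constant obeys its exact identities", {
  g <- seq(-1, 1, length.out = 101)
  b0 <- bias_state(tibble::tibble(time = 0.1, center = 0, width = 1, height = 0))
  expect_equal(reweight_constant(b0, g, t = 1), 0, tolerance = 1e-12)

  # uniform bias V0 -> c = V0 exactly, for any F
  b1 <- bias_state(tibble::tibble(time = 0.1, center = 0, width = 1e6,
                                  height = 3.7))
  F <- 4 * ((g)^2 - 1)^2
  expect_equal(reweight_constant(b1, g, t = 1, F = F), 3.7, tolerance = 1e-9)

  # grid-refinement oracle for a nontrivial bias
  b2 <- bias_state(tibble::tibble(time = c(0.1, 0.2), center = c(-0.5, 0.4),
                                  width = c(0.2, 0.3), height = c(1, 2)))
  c_coarse <- reweight_constant(b2, seq(-1.5, 1.5, length.out = 301), t = 1, F = NULL)
  c_fine <- reweight_constant(b2, seq(-1.5, 1.5, length.out = 6001), t = 1, F = NULL)
  expect_lt(abs(c_coarse - c_fine), 1e-4)
  expect_error(reweight_constant(b2, numeric(0), 1), "grid")
})

test_that("reweighted histograms reduce to raw histograms without bias", {
  set.seed(5)
  cv <- tibble::tibble(time = seq_len(500) * 0.1, value = rnorm(500),
                       s = rnorm(500))
  h <- reweighted_histogram(cv, bias_state(), breaks = seq(-4, 4, by = 0.5))
  w <- attr(h, "weights")
  expect_true(all(w > 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  raw <- hist(cv$value, breaks = seq(-4, 4, by = 0.5), plot = FALSE)
  expect_equal(h$density, raw$density, tolerance = 1e-12)
  expect_equal(sum(h$density * 0.5), 1, tolerance = 1e-12)
})

test_that("convergence report flags unconverged and converged biases", {
  flat <- bias_state(tibble::tibble(time = c(1, 2, 3, 4),
                                    center = 0, width = 1, height = 0.48))
  cr <- convergence_report(flat, blocks = 2)
  expect_equal(cr$residual_height_fraction, 1)
  expect_error(convergence_report(bias_state(), 2), "kernels")
  expect_error(convergence_report(flat, blocks = 1), "blocks")

  run <- dw_metad_run(1)
  crr <- convergence_report(run$bias, blocks = 4,
                            grid = seq(-1.5, 1.5, length.out = 201))
  expect_lt(crr$residual_height_fraction, 0.01)
  expect_lt(crr$mean_block_se, 0.2)
  expect_identical(nrow(crr$height_trace), nrow(run$bias$kernels))
})

test_that("estimator-based and reweighted profiles agree on the double well", {
  run <- dw_metad_run(1)
  g <- seq(-1.5, 1.5, length.out = 61)
  fes <- free_energy_estimate(run$bias, g)
  cv <- run$colvar[abs(run$colvar$value) <= 1.5, ]
  hw <- reweighted_histogram(cv, run$bias, breaks = seq(-1.5, 1.5, length.out = 62))
  Frew <- -kB * 300 * log(pmax(hw$density, 1e-12))
  Frew <- Frew - min(Frew)
  Fest <- fes_value(fes, hw$mid) - min(fes_value(fes, hw$mid))
  # compare over the thermally relevant region (within ~4 kcal/mol)
  keep <- Fest < 4
  cr <- convergence_report(run$bias, blocks = 4, grid = hw$mid)
  tol <- max(2 * mean(cr$block_se), 0.3)
  expect_lt(max(abs(Frew[keep] - Fest[keep])), tol + 0.2)
})
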