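test_that("the stochastic integrator is reproducible and respects D = 0", {
  p <- bgct_params(T42 = 2, T53 = 0)
  eq <- find_equilibria(p, n_starts = 400)
  x <- as.numeric(eq[eq$stability == "stable", paste0("x", 1:7)][1, ])
  ## same seed -> bit-identical trajectories
  a <- langevin_simulate(p, x + 0.1, 200, noise_spec(D = 1e-6, seed = 99))
  b <- langevin_simulate(p, x + 0.1, 200, noise_spec(D = 1e-6, seed = 99))
  expect_identical(a, b)
  ## D = 0 from a stable equilibrium stays put
  z <- langevin_simulate(p, x, 500, noise_spec(D = 0, seed = 1))
  expect_lt(max(abs(as.matrix(z[, -1]) -
                      matrix(x, nrow(z), 7, byrow = TRUE))), 1e-6)
  ## D = 0 matches the adaptive integrator to the order of the step
  x0 <- x + 0.5
  ze <- langevin_simulate(p, x0, 50, noise_spec(D = 0, dt = 0.002))
  za <- integrate_bgct(p, x0, 50)
  expect_lt(max(abs(as.numeric(ze[nrow(ze), -1]) -
                      as.numeric(za[nrow(za), -1]))), 1e-3)
})

test_that("stationary variance matches the Ornstein-Uhlenbeck closed form", {
  ## with all couplings off each coordinate is an independent OU process
  ## dx = -(x - RI)/(RC) dt + sqrt(2D) dW with stationary variance D*R*C
  p0 <- decoupled_params()
  D <- 1e-4
  x0 <- 1.67 * c(0.1, 0.05, 1.2, 4.4, 2.8, 2, 1.2)
  tr <- langevin_simulate(p0, x0, 30000, noise_spec(D = D, seed = 5),
                          record_dt = 0.5, burn_in = 2000)
  v <- apply(as.matrix(tr[, -1]), 2, var)
  expect_equal(mean(v), D * 1.67 * 3.6, tolerance = 0.05)
})

test_that("a uniform occupancy gives a flat potential with no strict minima", {
  pss <- matrix(0, 20, 20)
  pss[5:15, 5:15] <- 1
  ls <- potential_landscape(fake_landscape(pss))
  k <- sum(pss > 0)
  expect_equal(max(ls$U, na.rm = TRUE), log(k), tolerance = 1e-12)
  expect_equal(min(ls$U, na.rm = TRUE), log(k), tolerance = 1e-12)
  expect_equal(nrow(ls$minima), 0)
})

test_that("a two-Gaussian occupancy yields two minima at the centres", {
  n <- 60
  cx <- seq(0.5 / n, 1 - 0.5 / n, length.out = n)
  g <- function(m1, m2, s) outer(cx, cx, function(a, b)
    exp(-((a - m1)^2 + (b - m2)^2) / (2 * s^2)))
  ## centres chosen off the bin-corner symmetry so the minima are strict
  pss <- g(0.312, 0.296, 0.05) + 0.7 * g(0.753, 0.704, 0.05)
  ls <- potential_landscape(fake_landscape(pss))
  expect_equal(nrow(ls$minima), 2)
  ## deeper minimum first, at the heavier component's centre
  expect_equal(ls$minima$x1, c(0.312, 0.753), tolerance = 0.02)
  expect_equal(ls$minima$x2, c(0.296, 0.704), tolerance = 0.02)
  expect_false(ls$ring_detected)
})

test_that("an annular occupancy is recognised as a closed ring", {
  n <- 60
  cx <- seq(0.5 / n, 1 - 0.5 / n, length.out = n)
  r <- outer(cx, cx, function(a, b) sqrt((a - 0.5)^2 + (b - 0.5)^2))
  ring <- exp(-((r - 0.3) / 0.03)^2)
  ring[ring < 1e-6] <- 0   # empirical histograms have exact zeros
  ls <- potential_landscape(fake_landscape(ring))
  expect_true(ls$ring_detected)
})

test_that("a bistable landscape has two minima on the stable equilibria", {
  p <- bgct_params(T42 = 2, T53 = 0)
  eq <- find_equilibria(p, n_starts = 600)
  st <- eq[eq$stability == "stable", c("x1", "x2")]
  ls <- estimate_pss(p, noise_spec(D = 1e-6, seed = 21), ensemble = 60,
                     grid_n = 60)
  ls <- potential_landscape(ls)
  expect_equal(nrow(ls$minima), 2)
  bw1 <- diff(ls$x1_edges[1:2])
  bw2 <- diff(ls$x2_edges[1:2])
  for (i in 1:2) {
    d <- sqrt(((ls$minima$x1 - st$x1[i]) / bw1)^2 +
                ((ls$minima$x2 - st$x2[i]) / bw2)^2)
    expect_lt(min(d), sqrt(2) + 1e-9)   # within one bin diagonal
  }
  ## doubling the ensemble moves the minima by less than one bin
  ls2 <- potential_landscape(
    estimate_pss(p, noise_spec(D = 1e-6, seed = 21), ensemble = 120,
                 grid_n = 60))
  expect_equal(nrow(ls2$minima), 2)
  for (i in 1:2) {
    d <- sqrt(((ls2$minima$x1 - ls$minima$x1[i]) / bw1)^2 +
                ((ls2$minima$x2 - ls$minima$x2[i]) / bw2)^2)
    expect_lt(min(d), sqrt(2) + 1e-9)
  }
})

test_that("an oscillatory regime produces a closed low-potential ring", {
  p <- bgct_params(T42 = 5, T53 = 4)
  ls <- potential_landscape(
    estimate_pss(p, noise_spec(D = 1e-6, seed = 22), ensemble = 60,
                 grid_n = 60))
  expect_true(ls$ring_detected)
})

test_that("endpoint sampling supports the same bistable census", {
  p <- bgct_params(T42 = 2, T53 = 0)
  ls <- potential_landscape(
    estimate_pss(p, noise_spec(D = 1e-6, seed = 23), ensemble = 80,
                 grid_n = 40, sample_mode = "endpoint"))
  expect_equal(nrow(ls$minima), 2)
})
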