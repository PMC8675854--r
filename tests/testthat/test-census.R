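test_that("a constant trajectory is classified as an equilibrium", {
  p <- bgct_params(T42 = 1, T53 = 1)
  eq <- find_equilibria(p, n_starts = 400)
  x <- as.numeric(eq[1, paste0("x", 1:7)])
  tr <- integrate_bgct(p, x, 500)
  ## trajectory started on the attractor stays on it
  expect_lt(max(abs(as.matrix(tr[, -1]) -
                      matrix(x, nrow(tr), 7, byrow = TRUE))), 1e-6)
  det <- detect_attractor(tr, p)
  expect_s3_class(det, "bgct_equilibrium")
  expect_equal(det$state, x, tolerance = 1e-6)
  expect_equal(det$stability, "stable")
})

test_that("an injected sinusoid is measured at its true period", {
  t <- seq(0, 2000, by = 0.1)
  df <- data.frame(time = t, x1 = 1 + 0.5 * sin(2 * pi * t / 40))
  for (i in 2:7) df[[paste0("x", i)]] <- 0.5
  class(df) <- c("bgct_trajectory", "data.frame")
  det <- detect_attractor(df, bgct_params())
  expect_s3_class(det, "bgct_cycle")
  expect_equal(det$period, 40, tolerance = 1e-4)
  expect_equal(det$frequency, 25, tolerance = 1e-4)
  expect_equal(det$frequency * det$period, 1000, tolerance = 1e-9)
  expect_equal(unname(det$envelope["max", 1]), 1.5, tolerance = 1e-3)
  expect_equal(unname(det$envelope["min", 1]), 0.5, tolerance = 1e-3)
})

test_that("oscillation frequency converts period and flags the beta band", {
  f50 <- oscillation_frequency(fake_cycle(50))
  expect_equal(f50$frequency_hz, 20)
  expect_true(f50$beta_band)
  f200 <- oscillation_frequency(fake_cycle(200))
  expect_equal(f200$frequency_hz, 5)
  expect_false(f200$beta_band)
})

test_that("decoupled model censuses as a single steady state", {
  cs <- attractor_census(decoupled_params(), n_box = 16, n_starts = 300)
  expect_equal(cs$regime_tag, "1SS+0LC")
  expect_true(cs$exhaustive)
  ## approach to the fixed point is mono-exponential at the leak rate
  p0 <- decoupled_params()
  tr <- integrate_bgct(p0, rep(0, 7), 60)
  xstar <- 1.67 * 0.1
  dev <- abs(tr$x1 - xstar)
  rate <- -coef(lm(log(dev) ~ tr$time))[2]
  expect_equal(unname(rate), 1 / (3.6 * 1.67), tolerance = 1e-3)
})

test_that("bistable direct-pathway window holds two steady states", {
  cs <- attractor_census(bgct_params(T42 = 2, T53 = 0), n_starts = 800)
  expect_equal(cs$regime_tag, "2SS+0LC")
})

test_that("the oscillatory window at T53 = 4 carries a beta-band cycle", {
  p <- bgct_params(T42 = 5, T53 = 4)
  cs <- attractor_census(p, n_starts = 800)
  expect_equal(cs$regime_tag, "0SS+1LC")
  cc <- cs$cycles[[1]]
  expect_gt(cc$envelope["max", 1] - cc$envelope["min", 1], 1e-3)
  fr <- oscillation_frequency(cc)
  expect_gte(fr$frequency_hz, 13)
  expect_lte(fr$frequency_hz, 30)
})

test_that("two coexisting limit cycles are found and not merged", {
  cs <- attractor_census(bgct_params(T42 = 6.8, T53 = 6), n_starts = 800)
  expect_equal(length(cs$cycles), 2)
  periods <- vapply(cs$cycles, function(cc) cc$period, numeric(1))
  means <- vapply(cs$cycles, function(cc) cc$mean_state[1], numeric(1))
  expect_true(abs(diff(periods)) / max(periods) > 0.02 ||
                abs(diff(means)) > 0.05)
})

test_that("the census is idempotent under a denser initial-condition grid", {
  pts <- list(c(1, 1), c(2, 0), c(6, 6), c(6.8, 6))
  for (pt in pts) {
    p <- bgct_params(T42 = pt[1], T53 = pt[2])
    a <- attractor_census(p, n_box = 32, n_starts = 600)
    b <- attractor_census(p, n_box = 64, n_starts = 600)
    expect_equal(a$regime_tag, b$regime_tag,
                 info = paste("T42 =", pt[1], "T53 =", pt[2]))
  }
})

test_that("census JSON export round-trips the regime tag", {
  cs <- attractor_census(bgct_params(T42 = 5, T53 = 4),
                         ic_strategy = "targeted", n_starts = 600)
  f <- tempfile(fileext = ".json")
  write_census_json(cs, f)
  got <- jsonlite::read_json(f)
  expect_equal(got$regime_tag, cs$regime_tag)
  expect_equal(length(got$cycles), length(cs$cycles))
})
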