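test_that("Hill response matches hand values, is monotone and saturates", {
  expect_identical(hill_response(0, 2, 2), 0)
  expect_equal(hill_response(2, 2, 2), 0.5)
  expect_equal(hill_response(1, 2, 2), 0.2)   # 1/(4+1)
  ## monotone increasing on x >= 0 and saturating towards 1
  xs <- seq(0, 50, by = 0.1)
  expect_true(all(diff(hill_response(xs, 2, 2)) > 0))
  expect_lt(abs(hill_response(1e6, 2, 2) - 1), 1e-10)
  expect_true(all(hill_response(xs, 2, 2) >= 0 &
                    hill_response(xs, 2, 2) < 1))
  expect_error(hill_response(NaN, 2, 2), "finite")
  expect_error(hill_response(1, -1, 2), "positive")
  expect_error(hill_response(1, 2, 0.5), "integer")
})

test_that("default parameters reproduce the published typical values", {
  p <- unclass(bgct_params())
  expect_equal(unname(p[paste0("C", 1:7)]), rep(3.60, 7))
  expect_equal(unname(p[paste0("R", 1:7)]), rep(1.67, 7))
  expect_equal(unname(p[c("T16", "T21", "T26", "T31", "T36")]),
               c(2, 1.4, 1.4, 1.4, 1.4))
  expect_equal(unname(p[c("T45", "T47", "T57", "T64", "T71", "T75")]),
               c(3, 2, 1, 3.2, 1.8, 1.8))
  expect_equal(unname(p[paste0("I", 1:7)]),
               c(0.1, 0.05, 1.2, 4.4, 2.8, 2, 1.2))
  expect_equal(unname(p[c("s", "n", "Dinput")]), c(2, 2, 0.6))
})

test_that("parameter validation rejects bad values and flags the range", {
  expect_error(bgct_params(T99 = 1), "unknown parameter")
  expect_error(bgct_params(n = 0), "integer")
  expect_error(bgct_params(C1 = -1), "positive")
  expect_warning(bgct_params(T42 = 8), "outside the explored range")
  expect_silent(bgct_params(T42 = 6.5))
})

test_that("parameter files round-trip through flat YAML", {
  p <- bgct_params(T42 = 5.25, T53 = 3.75, I1 = 0.2)
  f <- tempfile(fileext = ".yml")
  write_params(p, f)
  q <- read_params(f)
  expect_equal(unclass(q), unclass(p))
  ## unknown keys are rejected
  writeLines("Tbad: 1", f)
  expect_error(read_params(f), "unknown parameter")
  ## the shipped typical-values file reproduces the defaults
  shipped <- system.file("extdata", "typical_params.yml",
                         package = "bgctdyn")
  expect_equal(unclass(read_params(shipped)), unclass(bgct_params()))
})

test_that("drift matches an independent transcription of the equations", {
  p <- bgct_params()
  ## zero state: first component is I1/C1
  f0 <- bgct_drift(rep(0, 7), p)
  expect_equal(f0[1], 0.1 / 3.6, tolerance = 1e-15)
  ## pinned-state regression against the plain-R transcription
  pinned <- list(
    rep(0, 7),
    c(0.5, 1, 1.5, 2, 2.5, 3, 3.5),
    rep(2, 7),
    c(0.2235, 1.4135, 2.0518, 6.1041, 4.6253, 1.1525, 3.3391),
    c(1.5, 3, 4, -2, 5, 0.5, 2)
  )
  for (x in pinned)
    expect_equal(bgct_drift(x, p), oracle_drift(x, p), tolerance = 1e-12)
  ## the dopamine level enters the two striatal equations with opposite sign
  pD <- bgct_params(Dinput = 1)
  d <- bgct_drift(rep(0, 7), pD) - bgct_drift(rep(0, 7), bgct_params(Dinput = 0))
  expect_equal(d[2], 1 / 3.6, tolerance = 1e-14)
  expect_equal(d[3], -1 / 3.6, tolerance = 1e-14)
  expect_equal(d[c(1, 4:7)], rep(0, 5))
})

test_that("decoupled model is linear decay to R_i * I_i", {
  p0 <- decoupled_params()
  x <- c(1, 2, 3, 4, 5, 6, 7)
  v <- unclass(p0)
  expected <- (v[paste0("I", 1:7)] - x / v[paste0("R", 1:7)]) /
    v[paste0("C", 1:7)]
  expect_equal(bgct_drift(x, p0), unname(expected), tolerance = 1e-14)
})

test_that("Jacobian agrees with central finite differences at random states", {
  set.seed(42)
  p <- bgct_params(T42 = 4, T53 = 5)
  for (k in 1:100) {
    x <- runif(7, -1, 8)
    J <- bgct_jacobian(x, p)
    Jfd <- oracle_fd_jacobian(x, p)
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
})

test_that("Jacobian diagonal carries the leak terms; decoupled case is diagonal", {
  p <- bgct_params(T42 = 3, T53 = 2)
  J <- bgct_jacobian(c(0.3, 1, 2, 5, 4, 1, 3), p)
  expect_equal(unname(diag(J)), rep(-1 / (3.6 * 1.67), 7), tolerance = 1e-14)
  J0 <- bgct_jacobian(runif(7), decoupled_params())
  expect_equal(unname(J0), diag(rep(-1 / (3.6 * 1.67), 7)), tolerance = 1e-14)
})
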