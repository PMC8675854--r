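test_that("decoupled system has exactly one stable equilibrium at R_i * I_i", {
  p0 <- decoupled_params()
  eq <- find_equilibria(p0, n_starts = 300)
  expect_equal(nrow(eq), 1)
  expect_equal(as.numeric(eq[1, paste0("x", 1:7)]),
               1.67 * c(0.1, 0.05, 1.2, 4.4, 2.8, 2, 1.2),
               tolerance = 1e-8)
  expect_equal(eq$stability, "stable")
  ## all eigenvalues real and equal to the leak rate
  expect_equal(as.numeric(eq[1, paste0("re_lambda", 1:7)]),
               rep(-1 / (3.6 * 1.67), 7), tolerance = 1e-10)
  expect_equal(as.numeric(eq[1, paste0("im_lambda", 1:7)]), rep(0, 7))
})

test_that("multistart enumeration agrees with the scalar-reduction oracle", {
  set.seed(7)
  draws <- cbind(T42 = runif(8, 0, 7), T53 = runif(8, 0, 7))
  for (k in seq_len(nrow(draws))) {
    p <- bgct_params(T42 = draws[k, 1], T53 = draws[k, 2])
    eq <- find_equilibria(p, n_starts = 800)
    or <- oracle_equilibria(p)
    or <- or[order(or[, 1]), , drop = FALSE]
    expect_equal(nrow(eq), nrow(or), info = paste("draw", k))
    expect_equal(as.matrix(eq[, paste0("x", 1:7)]), or,
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_true(all(eq$residual < 1e-9))
  }
})

test_that("equilibrium list saturates when the number of starts is doubled", {
  set.seed(11)
  draws <- cbind(T42 = runif(20, 0, 7), T53 = runif(20, 0, 7))
  for (k in seq_len(nrow(draws))) {
    p <- bgct_params(T42 = draws[k, 1], T53 = draws[k, 2])
    a <- find_equilibria(p, n_starts = 800)
    b <- find_equilibria(p, n_starts = 1600)
    expect_equal(nrow(a), nrow(b), info = paste("draw", k))
    expect_equal(as.matrix(a[, paste0("x", 1:7)]),
                 as.matrix(b[, paste0("x", 1:7)]), tolerance = 1e-7)
  }
})

test_that("repeated calls with identical arguments are identical", {
  p <- bgct_params(T42 = 2, T53 = 0)
  a <- find_equilibria(p, n_starts = 500)
  b <- find_equilibria(p, n_starts = 500)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("indirect-pathway slice at T53 = 3 is monostable for any T42", {
  for (t42 in c(0, 1.5, 3, 4.5, 6, 7)) {
    eq <- find_equilibria(bgct_params(T42 = t42, T53 = 3), n_starts = 600)
    expect_equal(nrow(eq), 1, info = paste("T42 =", t42))
    expect_equal(eq$stability, "stable")
  }
})

test_that("tristable window at T53 = 6 holds 3 stable and 2 unstable states", {
  eq <- find_equilibria(bgct_params(T42 = 4.5, T53 = 6))
  expect_equal(sum(eq$stability == "stable"), 3)
  expect_equal(sum(eq$stability == "unstable"), 2)
})

test_that("stable equilibria attract nearby initial conditions", {
  set.seed(3)
  for (pt in list(c(2, 0), c(4.5, 6), c(1, 1))) {
    p <- bgct_params(T42 = pt[1], T53 = pt[2])
    eq <- find_equilibria(p, n_starts = 800)
    st <- eq[eq$stability == "stable", , drop = FALSE]
    for (i in seq_len(nrow(st))) {
      x <- as.numeric(st[i, paste0("x", 1:7)])
      tr <- integrate_bgct(p, x + runif(7, -0.01, 0.01), 2000)
      xe <- as.numeric(tr[nrow(tr), paste0("x", 1:7)])
      expect_lt(sqrt(sum((xe - x)^2)), 1e-4)
    }
  }
})

test_that("the middle branch between folds is a repelling saddle", {
  p <- bgct_params(T42 = 1.6, T53 = 4)   # inside the Z-shaped window
  eq <- find_equilibria(p, n_starts = 800)
  expect_equal(nrow(eq), 3)
  mid <- eq[2, ]
  expect_equal(mid$stability, "unstable")
  expect_gt(mid$re_lambda1, 0)
  expect_equal(mid$im_lambda1, 0)   # a real positive eigenvalue
  ## perturbing off the saddle diverges from it
  x <- as.numeric(mid[paste0("x", 1:7)])
  tr <- integrate_bgct(p, x + 1e-3, 1500)
  xe <- as.numeric(tr[nrow(tr), paste0("x", 1:7)])
  expect_gt(sqrt(sum((xe - x)^2)), 0.1)
})

test_that("equilibrium CSV export carries the documented columns", {
  eq <- find_equilibria(bgct_params(T42 = 2, T53 = 0), n_starts = 400)
  f <- tempfile(fileext = ".csv")
  write_equilibria_csv(eq, f)
  got <- utils::read.csv(f, comment.char = "#")
  expect_equal(names(got),
               c(paste0("x", 1:7), paste0("re_lambda", 1:7),
                 paste0("im_lambda", 1:7), "stability", "residual"))
  expect_equal(nrow(got), nrow(eq))
})
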