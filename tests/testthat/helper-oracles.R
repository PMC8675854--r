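# Independent oracles used across the suite.  Everything here is written
# against the printed model equations directly, without calling the
# package's compiled core, so the two code paths can check each other.

oracle_hill <- function(x, s, n) x^n / (s^n + x^n)

# plain-R transcription of the seven equations
oracle_drift <- function(x, p) {
  v <- unclass(p)
  H <- function(z) oracle_hill(z, v["s"], v["n"])
  unname(c(
    (v["I1"] - x[1]/v["R1"] + v["T16"]*H(x[6]))                            / v["C1"],
    (v["I2"] - x[2]/v["R2"] + v["T21"]*H(x[1]) + v["T26"]*H(x[6]) +
       v["Dinput"])                                                        / v["C2"],
    (v["I3"] - x[3]/v["R3"] + v["T31"]*H(x[1]) + v["T36"]*H(x[6]) -
       v["Dinput"])                                                        / v["C3"],
    (v["I4"] - x[4]/v["R4"] + v["T47"]*H(x[7]) - v["T42"]*H(x[2]) -
       v["T45"]*H(x[5]))                                                   / v["C4"],
    (v["I5"] - x[5]/v["R5"] + v["T57"]*H(x[7]) - v["T53"]*H(x[3]))         / v["C5"],
    (v["I6"] - x[6]/v["R6"] - v["T64"]*H(x[4]))                            / v["C6"],
    (v["I7"] - x[7]/v["R7"] + v["T71"]*H(x[1]) - v["T75"]*H(x[5]))         / v["C7"]
  ))
}

# central finite differences of the drift
oracle_fd_jacobian <- function(x, p, h = 1e-6) {
  J <- matrix(0, 7, 7)
  for (j in 1:7) {
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (oracle_drift(xp, p) - oracle_drift(xm, p)) / (2 * h)
  }
  J
}

# Complete enumeration of equilibria by scalar reduction.  At a fixed
# thalamic activity x6 the loop resolves sequentially: x6 -> x1 -> x2, x3.
# The GPe/STN pair reduces to the scalar fixed point
#   phi(x5) = x5 - a - b*H(c - d*H(x5)) = 0,
# with a = R5(I5 - T53*H(x3)), b = R5*T57, c = R7(I7 + T71*H(x1)),
# d = R7*T75.  Since |H'| <= 4/(3*sqrt(3)*s) (~0.162 for s=2, n=2) and
# b*d*max(H')^2 < 1 at the default weights, phi is strictly increasing and
# the inner root is unique — bisection is rigorous.  Then x7 and x4 follow
# and the closure residual lives in x6 alone; all equilibria are roots of
# that continuous scalar residual on a bracketing interval, found by dense
# sign scanning + uniroot.  Independent of the package's Newton multistart.
oracle_equilibria <- function(p, n_scan = 4000) {
  v <- unclass(p)
  H <- function(z) oracle_hill(z, v["s"], v["n"])
  state_given_x6 <- function(x6) {
    x1 <- v["R1"] * (v["I1"] + v["T16"] * H(x6))
    x2 <- v["R2"] * (v["I2"] + v["T21"]*H(x1) + v["T26"]*H(x6) + v["Dinput"])
    x3 <- v["R3"] * (v["I3"] + v["T31"]*H(x1) + v["T36"]*H(x6) - v["Dinput"])
    a <- v["R5"] * (v["I5"] - v["T53"] * H(x3))
    b <- v["R5"] * v["T57"]
    cc <- v["R7"] * (v["I7"] + v["T71"] * H(x1))
    d <- v["R7"] * v["T75"]
    phi <- function(x5) x5 - a - b * H(cc - d * H(x5))
    lo <- a - 0.5; hi <- a + b + 0.5   # phi(lo) < 0 < phi(hi)
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (phi(mid) < 0) lo <- mid else hi <- mid
    }
    x5 <- (lo + hi) / 2
    x7 <- cc - d * H(x5)
    x4 <- v["R4"] * (v["I4"] + v["T47"]*H(x7) - v["T42"]*H(x2) -
                       v["T45"]*H(x5))
    c(x1, x2, x3, x4, x5, x7)
  }
  resid <- function(x6) {
    st <- state_given_x6(x6)
    v["R6"] * (v["I6"] - v["T64"] * H(st[4])) - x6
  }
  lo <- v["R6"] * (v["I6"] - v["T64"]) - 0.5
  hi <- v["R6"] * v["I6"] + 0.5
  xs <- seq(lo, hi, length.out = n_scan)
  rs <- vapply(xs, resid, numeric(1))
  roots <- c()
  for (k in seq_len(n_scan - 1)) {
    if (is.finite(rs[k]) && is.finite(rs[k + 1]) &&
        rs[k] * rs[k + 1] < 0) {
      r <- stats::uniroot(resid, c(xs[k], xs[k + 1]), tol = 1e-13)$root
      roots <- c(roots, r)
    }
  }
  t(vapply(roots, function(x6) {
    st <- state_given_x6(x6)
    c(st[1:4], st[5], x6, st[6])
  }, numeric(7)))
}

# minimal constructed cycle object for arithmetic-only checks
fake_cycle <- function(period) {
  structure(list(period = period, frequency = 1000 / period,
                 beta_band = 1000 / period >= 13 && 1000 / period <= 30,
                 envelope = rbind(min = rep(0, 7), max = rep(1, 7)),
                 mean_state = rep(0.5, 7),
                 sample_orbit = NULL),
            class = "bgct_cycle")
}

# constructed landscape container for potential-only checks
fake_landscape <- function(pss, x1_edges = NULL, x2_edges = NULL) {
  n <- nrow(pss)
  structure(list(pss = pss / sum(pss),
                 x1_edges = x1_edges %||% seq(0, 1, length.out = n + 1),
                 x2_edges = x2_edges %||% seq(0, 1, length.out = ncol(pss) + 1),
                 n_samples = 1e6, sample_mode = "occupancy",
                 noise = noise_spec(), ensemble = 1,
                 params = bgct_params()),
            class = "bgct_landscape")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

decoupled_params <- function() {
  bgct_params(T16 = 0, T21 = 0, T26 = 0, T31 = 0, T36 = 0, T42 = 0,
              T45 = 0, T47 = 0, T53 = 0, T57 = 0, T64 = 0, T71 = 0,
              T75 = 0, Dinput = 0)
}
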