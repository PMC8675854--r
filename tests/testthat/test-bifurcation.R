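test_that("codim-1 scans reproduce the fold/Hopf structure of each slice", {
  ## slice T53 = 0: two folds bounding a bistable window, one Hopf beyond
  bd0 <- trace_branch(bgct_params(T53 = 0), "T42", envelope = FALSE)
  expect_equal(nrow(bd0$folds), 2)
  expect_equal(nrow(bd0$hopfs), 1)
  expect_gt(bd0$hopfs$param[1], max(bd0$folds$param))
  mid <- mean(bd0$folds$param)
  eq <- find_equilibria(bgct_params(T42 = mid, T53 = 0), n_starts = 600)
  expect_equal(sum(eq$stability == "stable"), 2)

  ## slice T53 = 3: no bifurcation at all
  bd3 <- trace_branch(bgct_params(T53 = 3), "T42", envelope = FALSE)
  expect_equal(nrow(bd3$folds), 0)
  expect_equal(nrow(bd3$hopfs), 0)

  ## slice T53 = 4: two supercritical Hopf points with a cycle between
  bd4 <- trace_branch(bgct_params(T53 = 4), "T42", envelope = FALSE)
  expect_equal(nrow(bd4$hopfs), 2)
  expect_true(all(bd4$hopfs$omega > 0))
  hm <- mean(bd4$hopfs$param)
  cs <- attractor_census(bgct_params(T42 = hm, T53 = 4),
                         ic_strategy = "targeted", n_starts = 600)
  expect_equal(length(cs$cycles), 1)
})

test_that("stability changes along a branch only at detected bifurcations", {
  bd <- trace_branch(bgct_params(T53 = 0), "T42", envelope = FALSE)
  crit <- sort(c(bd$folds$param, bd$hopfs$param))
  for (df in bd$branches) {
    flips <- which(df$stability[-1] != df$stability[-nrow(df)])
    for (i in flips) {
      pm <- (df$param[i] + df$param[i + 1]) / 2
      ## every stability flip sits within one continuation step of a
      ## detected fold or Hopf point
      expect_lt(min(abs(crit - pm)), 0.15)
    }
  }
})

test_that("cycle envelopes open at the Hopf points and stay inside them", {
  bd <- trace_branch(bgct_params(T53 = 4), "T42", range = c(3.5, 6.5),
                     envelope = TRUE, n_env = 25)
  env <- bd$envelope
  expect_gt(nrow(env), 5)
  expect_true(all(env$x1_max > env$x1_min))
  h <- sort(bd$hopfs$param)
  expect_true(all(env$param > h[1] - 0.2 & env$param < h[2] + 0.2))
})

test_that("the GPi-input plane shows four distinct stable dynamics", {
  ## with the striatal weights at an oscillation-prone operating point,
  ## varying the GPe->GPi and STN->GPi weights reproduces the four
  ## regime types of that plane: 1SS, 2SS, a lone cycle, and SS+cycle
  m <- region_map(bgct_params(T42 = 5, T53 = 4), "T45", "T47",
                  resolution = 21)
  expect_equal(length(unique(m$faces$tag)), 4)
  expect_setequal(unique(m$faces$tag),
                  c("1SS+0LC", "2SS+0LC", "0SS+1LC", "1SS+1LC"))
})

test_that("traced fold curves are confirmed by codim-1 scans through them", {
  cv <- trace_codim2_curves(bgct_params(), "T42", "T53",
                            window = c(1, 3.5, 0, 3.2), n_slices = 3,
                            n_starts = 400)
  fold <- NULL
  for (c1 in cv$curves) if (c1$type == "fold") { fold <- c1; break }
  expect_false(is.null(fold))
  idx <- round(seq(2, length(fold$p1) - 1, length.out = 3))
  for (i in idx) {
    a <- fold$p1[i]; b <- fold$p2[i]
    if (b < 0.05 || b > 3.1) next
    bd <- trace_branch(bgct_params(T53 = b), "T42",
                       range = c(max(0, a - 0.4), a + 0.4),
                       envelope = FALSE, n_starts = 400)
    expect_gt(nrow(bd$folds), 0)
    expect_lt(min(abs(bd$folds$param - a)), 1e-3)
  }
  ## each cusp lies on a fold curve
  if (!is.null(cv$cusps) && nrow(cv$cusps)) {
    for (k in seq_len(nrow(cv$cusps))) {
      d <- min(sqrt((fold$p1 - cv$cusps[k, 1])^2 +
                      (fold$p2 - cv$cusps[k, 2])^2))
      expect_lt(d, 0.05)
    }
  }
  ## fold pairing across the cusp: two folds just below, none just above
  expect_gte(nrow(cv$cusps), 1)
  cusp <- cv$cusps[which.max(cv$cusps[, 2]), ]
  below <- trace_branch(bgct_params(T53 = cusp[2] - 0.3), "T42",
                        range = c(max(0, cusp[1] - 1), cusp[1] + 1),
                        envelope = FALSE, n_starts = 400)
  above <- trace_branch(bgct_params(T53 = cusp[2] + 0.3), "T42",
                        range = c(max(0, cusp[1] - 1), cusp[1] + 1),
                        envelope = FALSE, n_starts = 400)
  expect_equal(nrow(below$folds), 2)
  expect_equal(nrow(above$folds), 0)
})

test_that("crossing a Hopf curve flips the sign of the leading pair", {
  cv <- trace_codim2_curves(bgct_params(), "T42", "T53",
                            window = c(5.5, 7, 0, 1.2), n_slices = 3,
                            n_starts = 400)
  hopf <- NULL
  for (c1 in cv$curves) if (c1$type == "hopf") { hopf <- c1; break }
  expect_false(is.null(hopf))
  i <- which.min(abs(hopf$p2 - 0.5))
  a <- hopf$p1[i]; b <- hopf$p2[i]
  sgn <- function(t42) {
    p <- bgct_params(T42 = t42, T53 = b)
    eq <- find_equilibria(p, n_starts = 500)
    ## the branch the Hopf sits on is the one nearest the curve state
    j <- which.min(abs(eq$x1 - hopf$x[i, 1]))
    cl <- classify_stability(as.numeric(eq[j, paste0("x", 1:7)]), p)
    Re(cl$leading_complex)
  }
  expect_lt(sgn(a - 0.15) * sgn(a + 0.15), 0)
})

test_that("no oscillatory regime exists at weak direct and indirect coupling", {
  for (t42 in c(0, 1, 2)) for (t53 in c(0, 1, 2)) {
    cs <- attractor_census(bgct_params(T42 = t42, T53 = t53),
                           ic_strategy = "targeted", n_starts = 400)
    expect_equal(length(cs$cycles), 0,
                 info = paste("T42 =", t42, "T53 =", t53))
  }
})

test_that("branch CSV/JSON export writes branches, folds and Hopf points", {
  bd <- trace_branch(bgct_params(T53 = 0), "T42", envelope = FALSE,
                     n_starts = 400)
  fc <- tempfile(fileext = ".csv")
  fj <- tempfile(fileext = ".json")
  write_branch_csv(bd, fc, fj)
  got <- utils::read.csv(fc, comment.char = "#")
  expect_true(all(c("branch", "param", "x1", "stability") %in% names(got)))
  side <- jsonlite::read_json(fj)   # data.frames serialize row-wise
  expect_equal(length(side$folds), 2)
  expect_equal(length(side$hopfs), 1)
  expect_true("omega" %in% names(side$hopfs[[1]]))
})
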