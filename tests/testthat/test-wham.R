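test_that("a single unbiased window gives uniform weights", {
  u <- matrix(0, 100, 1)
  fit <- binless_wham(u, 100)
  expect_equal(fit$weights, rep(1 / 100, 100), tolerance = 1e-12)
  expect_equal(fit$f, 0)
})

test_that("two windows with identical biases have equal free energies", {
  set.seed(1)
  x <- rnorm(400)
  u <- cbind(0.5 * x^2, 0.5 * x^2)
  fit <- binless_wham(u, c(200, 200))
  expect_equal(fit$f[1], 0)
  expect_lt(abs(fit$f[2]), 1e-6)
})

test_that("shifting all bias energies by a constant leaves weights unchanged", {
  set.seed(2)
  x <- c(rnorm(300, -1), rnorm(300, 1))
  u <- cbind(0.5 * 3 * (x + 1)^2, 0.5 * 3 * (x - 1)^2)
  f1 <- binless_wham(u, c(300, 300))
  f2 <- binless_wham(u + 7.3, c(300, 300))
  expect_equal(f1$weights, f2$weights, tolerance = 1e-9)
})

test_that("the self-consistent and likelihood solvers agree", {
  set.seed(3)
  x <- c(rnorm(200, -1, 0.7), rnorm(200, 1, 0.7))
  u <- cbind(0.5 * 2 * (x + 1)^2, 0.5 * 2 * (x - 1)^2)
  a <- binless_wham(u, c(200, 200), method = "mle")
  b <- binless_wham(u, c(200, 200), method = "self-consistent")
  expect_equal(a$f, b$f, tolerance = 1e-5)
})

test_that("the 2-window Gaussian case matches the closed-form free-energy gap", {
  # flat potential, harmonic biases k1 and k2 at the same center:
  # f2 - f1 = (kT/2) log(k2/k1); deterministic quantile sampling makes
  # the estimator error O(1/n^2)
  kT <- 1; k1 <- 2; k2 <- 8; n <- 4000
  qs <- qnorm((seq_len(n) - 0.5) / n)
  x <- c(qs * sqrt(kT / k1), qs * sqrt(kT / k2))
  u <- cbind(0.5 * k1 * x^2, 0.5 * k2 * x^2)
  fit <- binless_wham(u, c(n, n), kT = kT)
  expect_true(fit$converged)
  expect_lt(abs(fit$f[2] - 0.5 * kT * log(k2 / k1)), 1e-3)
})

test_that("umbrella sampling on a harmonic potential reconstructs its PMF", {
  pot <- potential_single_well(center = 0, stiffness = 1.5)
  us <- umbrella_1d(pot, centers = seq(-2.5, 2.5, length.out = 21),
                    k_bias = 10, n_keep = 8000, seed = 10)
  fit <- binless_wham(us$u, us$n)
  expect_true(fit$converged)
  err <- pmf_vs_reference(us$x, fit$weights, pot, -2, 2)
  expect_lt(max(abs(err)), 0.2)
})

test_that("umbrella sampling on a double well reconstructs its PMF", {
  pot <- potential_double_well(height = 3, width = 1)
  us <- umbrella_1d(pot, centers = seq(-1.5, 1.5, length.out = 21),
                    k_bias = 25, n_keep = 8000, seed = 20)
  fit <- binless_wham(us$u, us$n)
  expect_true(fit$converged)
  err <- pmf_vs_reference(us$x, fit$weights, pot, -1.3, 1.3)
  expect_lt(max(abs(err)), 0.2)
})

test_that("a symmetric double well has equal minima in the estimated PMF", {
  pot <- potential_double_well(height = 3, width = 1)
  us <- umbrella_1d(pot, centers = seq(-1.5, 1.5, length.out = 21),
                    k_bias = 25, seed = 30)
  fit <- binless_wham(us$u, us$n)
  grid <- seq(-1.4, 1.4, length.out = 29)
  bin <- findInterval(us$x, grid, rightmost.closed = TRUE)
  occ <- vapply(1:28, function(b) sum(fit$weights[bin == b]), numeric(1))
  pmf <- -log(occ)
  left <- min(pmf[1:14]); right <- min(pmf[15:28])
  expect_lt(abs(left - right), 0.15)
})

test_that("flat ensembles give a flat PMF with zero barrier", {
  # windows restrained with zero force constant on a flat region sample
  # identically; every window's occupancy is equal up to noise
  set.seed(5)
  nodes <- matrix(seq(0, 1, length.out = 5), ncol = 1)
  samples <- lapply(1:5, function(i) {
    matrix(runif(400, nodes[i] - 0.1, nodes[i] + 0.1), ncol = 1)
  })
  sr <- list(ensembles = samples,
             sampling_path = unbindkit:::new_string_path(nodes,
                                                         force_constant = 0))
  prof <- pmf_and_barrier(sr, kT = 1, subgroups = 4)
  expect_lt(prof$barrier, 0.1)
})

test_that("the pocket pipeline's PMF barrier matches the analytic barrier", {
  fx <- make_fixtures(1)$pocket
  cvs <- list(cv_coordinate(1), cv_coordinate(2))
  mep <- pocket_mep(lo = -0.05, hi = 4.4)
  path0 <- seed_string(mep, n_windows = 30, coords = mep)
  sr <- run_string(fx$potential, cvs, path0, steps_per_window = 1200,
                   max_iterations = 2, kT = fx$kT, seed = 8)
  prof <- pmf_and_barrier(sr, kT = fx$kT)
  # barrier within combined sampling + restraint-broadening tolerance
  expect_lt(abs(prof$barrier - fx$mep_barrier), 0.2 * fx$mep_barrier + 0.6)
  # the TS window sits near the known barrier position
  ts_x <- sr$sampling_path$nodes[prof$ts_window, 1]
  expect_lt(abs(ts_x - fx$barrier_x), 0.8)
  expect_true(all(prof$profile$se >= 0, na.rm = TRUE))
  expect_equal(min(prof$profile$dG[seq_len(prof$ts_window)]), 0)
})

test_that("TS candidates are the highest-energy windows around the peak", {
  mk <- function(dg) tibble::tibble(window = seq_along(dg), dG = dg)
  # single sharp peak at window 40 of 100
  dg <- -abs(seq_len(100) - 40) * 0.1 + 4
  expect_equal(pick_ts_candidates(mk(dg), 5), 38:42)
  # flat profile: lowest-index block (documented tie rule)
  expect_equal(pick_ts_candidates(mk(rep(1, 50)), 5), 1:5)
  # two equal peaks: the bound-side (earlier) peak is chosen
  dg2 <- rep(0, 60); dg2[20] <- 3; dg2[45] <- 3
  expect_true(all(pick_ts_candidates(mk(dg2), 5) <= 25))
  # exhaustive-scan oracle: block containing the argmax with maximal sum
  set.seed(6)
  dg3 <- cumsum(rnorm(30))
  got <- pick_ts_candidates(mk(dg3), 4)
  peak <- which.max(dg3)
  starts <- max(1, peak - 3):min(peak, 27)
  sums <- vapply(starts, function(s) sum(dg3[s:(s + 3)]), numeric(1))
  expect_equal(got, seq(starts[which.max(sums)], length.out = 4))
  expect_error(pick_ts_candidates(mk(rep(1, 3)), 5), "exceeds")
})

test_that("the overlap diagnostic exposes disconnected windows", {
  set.seed(7)
  x <- c(rnorm(100, -20, 0.1), rnorm(100, 20, 0.1))
  u <- cbind(0.5 * 50 * (x + 20)^2, 0.5 * 50 * (x - 20)^2)
  fit <- suppressWarnings(binless_wham(u, c(100, 100), max_iter = 200))
  expect_lt(fit$overlap[1, 2], 1e-6)
  # a well-overlapped pair shows substantial shared weight
  y <- c(rnorm(100, -0.3), rnorm(100, 0.3))
  u2 <- cbind(0.5 * (y + 0.3)^2, 0.5 * (y - 0.3)^2)
  fit2 <- binless_wham(u2, c(100, 100))
  expect_gt(fit2$overlap[1, 2], 0.1)
})
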