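# Shared toy systems and slow-object caches for the test suite.

# Small benchmark for unit tests: same construction as the full 1-DW
# system, scaled down for speed.
tiny_benchmark_config <- function(...) {
  benchmark_config(n_coordinates = 9, n_features = 40, n_correlated = 5,
                   n_train_traj = 40, n_valid_traj = 10, n_steps = 120,
                   window = c(30, 60), ...)
}

tiny_mlp <- function(...) mlp_config(hidden_units = 20, max_epochs = 100, ...)
tiny_gbdt <- function(...) gbdt_config(n_estimators = 60, ...)

# Umbrella sampling on a 1D potential via the engine; returns pooled
# samples, bias-energy matrix and counts ready for binless_wham().
umbrella_1d <- function(potential, centers, k_bias = 15, n_keep = 2000,
                        n_burn = 500, kT = 1, step_size = 0.005, seed = 1) {
  samps <- lapply(seq_along(centers), function(i) {
    b <- bias_harmonic(cv_coordinate(1), centers[i], k = k_bias)
    tr <- simulate_langevin(potential, n_steps = n_burn + n_keep,
                            x0 = centers[i], step_size = step_size,
                            kT = kT, bias = b, seed = seed + i)
    tr$frames[1, (n_burn + 1):(n_burn + n_keep), 1]
  })
  x <- unlist(samps)
  u <- vapply(centers, function(c0) 0.5 * k_bias * (x - c0)^2,
              numeric(length(x)))
  list(x = x, u = u, n = rep(n_keep, length(centers)))
}

# Binless-weights PMF on a grid, compared against the bin-integrated
# Boltzmann reference (the correct oracle for a histogram estimate).
pmf_vs_reference <- function(x, weights, potential, lo, hi, n_bins = 40,
                             kT = 1) {
  grid <- seq(lo, hi, length.out = n_bins + 1)
  bin <- findInterval(x, grid, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin <= n_bins
  occ <- vapply(seq_len(n_bins), function(b) sum(weights[inside][bin[inside] == b]),
                numeric(1))
  stopifnot(all(occ > 0))
  pmf <- -kT * log(occ)
  ref <- vapply(seq_len(n_bins), function(b) {
    xs <- seq(grid[b], grid[b + 1], length.out = 51)
    v <- pot_energy(potential, matrix(xs, ncol = 1))
    -kT * log(mean(exp(-v / kT)))
  }, numeric(1))
  err <- (pmf - ref)
  err - mean(err)   # profiles are defined up to an additive constant
}

# The pocket fixture's minimum-energy path (the x axis), as a CV-space
# curve from inside the bound basin to past the barrier.
pocket_mep <- function(lo = -0.2, hi = 5, n = 200) {
  cbind(seq(lo, hi, length.out = n), 0)
}

# Cache for expensive acceptance-grade objects shared between tests.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# The full 1-DW benchmark report at acceptance scale (10 replicas).
acceptance_report <- function() {
  cached("acceptance_report", run_mltsa_benchmark(benchmark_config(),
                                                  n_replicas = 10, seed = 1))
}
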