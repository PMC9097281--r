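# A small labelled feature ensemble where one feature tracks the label
# exactly and the rest are noise.
make_separable <- function(n_traj = 40, n_steps = 80, n_feat = 6, seed = 1) {
  set.seed(seed)
  labels <- factor(rep(c("IN", "OUT"), length.out = n_traj),
                   levels = c("IN", "OUT"))
  frames <- array(rnorm(n_traj * n_steps * n_feat),
                  dim = c(n_traj, n_steps, n_feat))
  frames[, , 1] <- rep(ifelse(labels == "OUT", 2, -2), n_steps) +
    0.05 * frames[, , 1]
  structure(list(frames = frames, step_size = 1, labels = labels,
                 provenance = list()), class = "trj_ensemble")
}

test_that("dataset construction splits frames and holds out whole trajectories", {
  feats <- make_separable()
  ds <- mltsa_dataset(feats, window = c(10, 29), train_frac = 0.7,
                      validation_ids = 31:40, seed = 2)
  nw <- 20; n_train_traj <- 30
  expect_equal(nrow(ds$X_train) + nrow(ds$X_test), n_train_traj * nw)
  expect_equal(nrow(ds$X_train), floor(0.7 * n_train_traj * nw))
  expect_length(ds$validation, 10)
  # no validation frame leaks into the training pool: trajectory 31..40
  # feature-1 values are +-2-ish constants distinct per label; check by
  # fingerprinting exact rows
  val_rows <- do.call(rbind, ds$validation)
  pool <- rbind(ds$X_train, ds$X_test)
  key <- function(m) apply(round(m, 10), 1, paste, collapse = ",")
  expect_length(intersect(key(val_rows), key(pool)), 0)
})

test_that("removing held-out trajectories changes no training input", {
  feats <- make_separable()
  ds_all <- mltsa_dataset(feats, window = c(10, 29),
                          validation_ids = 31:40, seed = 2)
  feats30 <- feats
  feats30$frames <- feats$frames[1:30, , , drop = FALSE]
  feats30$labels <- feats$labels[1:30]
  ds_sub <- mltsa_dataset(feats30, window = c(10, 29), seed = 2)
  expect_identical(ds_all$X_train, ds_sub$X_train)
  expect_identical(ds_all$y_train, ds_sub$y_train)
})

test_that("a perfectly separating feature yields near-perfect accuracy", {
  feats <- make_separable()
  ds <- mltsa_dataset(feats, window = c(10, 29), validation_ids = 31:40,
                      seed = 3)
  for (config in list(tiny_mlp(), tiny_gbdt())) {
    fit <- fit_mltsa(ds, config, seed = 3)
    expect_gt(glance(fit)$test, 0.98)
    expect_gt(glance(fit)$validation, 0.95)
  }
})

test_that("permuted labels give chance-level accuracy (permutation null)", {
  feats <- make_separable(n_traj = 60, seed = 4)
  set.seed(5)
  feats$labels <- sample(feats$labels)   # break the feature-label link
  # re-randomise feature 1 so no signal remains at all
  feats$frames[, , 1] <- rnorm(length(feats$frames[, , 1]))
  ds <- mltsa_dataset(feats, window = c(10, 29), validation_ids = 51:60,
                      seed = 5)
  fit <- fit_mltsa(ds, tiny_gbdt(), validation = "frame", seed = 5)
  maj <- max(mean(ds$y_test), 1 - mean(ds$y_test))
  expect_lt(abs(glance(fit)$validation - maj), 0.25)
})

test_that("single-class training data are rejected", {
  feats <- make_separable()
  feats$labels <- factor(rep("IN", 40), levels = c("IN", "OUT"))
  ds <- mltsa_dataset(feats, window = c(10, 29), seed = 1)
  expect_error(fit_mltsa(ds, tiny_mlp()), "single class")
})

test_that("global-mean swap of a constant feature drops exactly zero", {
  feats <- make_separable()
  feats$frames[, , 3] <- 1.7
  ds <- mltsa_dataset(feats, window = c(10, 29), seed = 6)
  fit <- fit_mltsa(ds, tiny_mlp(), seed = 6)
  dr <- global_mean_drop(fit, ds)
  expect_identical(dr$drop[3], 0)
})

test_that("the sole informative feature loses everything under the swap", {
  feats <- make_separable(n_traj = 60, seed = 7)
  ds <- mltsa_dataset(feats, window = c(10, 29), seed = 7)
  for (config in list(tiny_mlp(), tiny_gbdt())) {
    fit <- fit_mltsa(ds, config, seed = 7)
    dr <- global_mean_drop(fit, ds)
    baseline <- attr(dr, "baseline")
    maj <- max(mean(c(ds$y_train, ds$y_test)),
               1 - mean(c(ds$y_train, ds$y_test)))
    # drop ~ baseline - majority fraction (degenerate-dataset oracle)
    expect_lt(abs(dr$drop[1] - (baseline - maj)), 0.12)
    expect_lt(max(abs(dr$drop[-1])), 0.05)
  }
})

test_that("GBDT importances are normalised and concentrate on the signal", {
  feats <- make_separable(n_traj = 60, seed = 8)
  ds <- mltsa_dataset(feats, window = c(10, 29), seed = 8)
  fit <- fit_mltsa(ds, tiny_gbdt(), seed = 8)
  fi <- gbdt_importances(fit)
  expect_equal(sum(fi$importance), 1, tolerance = 1e-9)
  expect_gt(fi$importance[1], 0.9)
  expect_error(gbdt_importances(fit_mltsa(ds, tiny_mlp(), seed = 8)))
})

test_that("the accuracy sweep finds late windows easier than early ones", {
  cfg <- tiny_benchmark_config()
  bench <- generate_benchmark(cfg, seed = 9)
  sweep <- accuracy_sweep(bench$features,
                          windows = list(c(0, 5), c(30, 60), c(100, 119)),
                          config = tiny_gbdt(),
                          validation_ids = bench$validation_ids, seed = 9)
  expect_equal(nrow(sweep), 3)
  # the final window is determined by construction; step-0 carries
  # essentially no information beyond the (memorisable) noise offsets
  expect_gt(sweep$validation[3], sweep$validation[1] - 0.05)
  expect_gt(sweep$validation[3], 0.9)
})

test_that("downhill runs from a barrier top commit to both basins", {
  pot <- potential_double_well(height = 6, width = 1)
  runs <- generate_downhill(pot, starts = matrix(c(0, -1), ncol = 1),
                            n_runs = 40, n_steps = 400, kT = 1, seed = 10)
  lab_top <- label_outcome(runs[[1]], crest = 0)$labels
  expect_gt(mean(lab_top == "IN"), 0.1)
  expect_lt(mean(lab_top == "IN"), 0.9)
  # deep in the bound basin: (statistically) all IN
  lab_deep <- label_outcome(runs[[2]], crest = 0)$labels
  expect_gt(mean(lab_deep == "IN"), 0.9)
  # fixed seeds reproduce the outcome vector
  runs2 <- generate_downhill(pot, starts = matrix(c(0, -1), ncol = 1),
                             n_runs = 40, n_steps = 400, kT = 1, seed = 10)
  expect_identical(label_outcome(runs2[[1]], crest = 0)$labels, lab_top)
})

test_that("TS selection picks the committor closest to one half", {
  tb <- tibble::tibble(in_fraction = c(0.9, 0.7, 0.55, 0.2))
  expect_equal(select_ts(tb), 3)
  # exact tie resolved toward the higher free-energy candidate
  tb2 <- tibble::tibble(in_fraction = c(0.4, 0.6), pmf = c(1, 2))
  expect_equal(select_ts(tb2), 2)
  expect_equal(select_ts(tibble::tibble(in_fraction = 0.8)), 1)
})

test_that("two-distance labelling agrees with the basin rule on the pocket", {
  fx <- make_fixtures(1)$pocket
  runs <- generate_downhill(fx$potential,
                            starts = matrix(c(fx$barrier_x, 0), ncol = 2),
                            n_runs = 60, n_steps = 500, step_size = 0.005,
                            kT = fx$kT, seed = 11)[[1]]
  # trivial checks: bound distances -> IN, far distances -> OUT
  d_in <- matrix(2, 3, 50); d_out_m <- matrix(7, 3, 50)
  expect_true(all(label_downhill(d_in, d_in, c(3.5, 3.5)) == "IN"))
  expect_true(all(label_downhill(d_out_m, d_out_m, c(3.5, 3.5)) == "OUT"))
  # pocket ensemble: labels from two anchor distances match basin labels
  basin <- label_outcome(runs, decisive_dimension = 1,
                         crest = fx$barrier_x)$labels
  n <- dim(runs$frames)[2]
  dist_to <- function(anchor) {
    sqrt((runs$frames[, , 1] - anchor[1])^2 +
           (runs$frames[, , 2] - anchor[2])^2)
  }
  d1 <- dist_to(fx$anchors[1, ]); d2 <- dist_to(fx$anchors[2, ])
  lab <- label_downhill(d1, d2, bound_thresholds = c(3.5, 3.5),
                        unbound_threshold = 6, final_window = 25)
  resolved <- !is.na(lab)
  expect_gt(mean(resolved), 0.7)
  agree <- mean(lab[resolved] == basin[resolved])
  expect_gt(agree, 0.9)
})

test_that("training is deterministic under a fixed seed", {
  feats <- make_separable()
  ds <- mltsa_dataset(feats, window = c(10, 29), seed = 12)
  f1 <- fit_mltsa(ds, tiny_mlp(), seed = 12)
  f2 <- fit_mltsa(ds, tiny_mlp(), seed = 12)
  expect_identical(f1$accuracy, f2$accuracy)
  expect_identical(f1$model$W1, f2$model$W1)
})

test_that("an independent single-hidden-layer backend corroborates the MLP", {
  skip_if_not_installed("nnet")
  feats <- make_separable(n_traj = 40, seed = 13)
  ds <- mltsa_dataset(feats, window = c(10, 29), seed = 13)
  fit <- fit_mltsa(ds, tiny_mlp(), seed = 13)
  nn <- nnet::nnet(ds$X_train, ds$y_train, size = 10, decay = 1e-4,
                   entropy = TRUE, maxit = 200, trace = FALSE)
  acc_nnet <- mean((predict(nn, ds$X_test) > 0.5) == ds$y_test)
  expect_lt(abs(glance(fit)$test - acc_nnet), 0.05)
})
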