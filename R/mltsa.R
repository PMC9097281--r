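#' Build a downhill-trajectory learning dataset
#'
#' Takes a labelled feature ensemble (e.g. from [apply_mixing()] or from
#' downhill runs), restricts it to an early-time frame window, holds out
#' whole validation trajectories, and splits the remaining window frames
#' --- concatenated across trajectories and randomly shuffled --- into
#' training (0.7) and test (0.3) sets. Validation trajectories never
#' contribute frames to training or test.
#'
#' @param features a `trj_ensemble` of features with labels attached, or a
#'   plain `n_traj x n_steps x n_features` array plus `labels`.
#' @param labels factor of `IN`/`OUT` per trajectory (taken from the
#'   ensemble when omitted).
#' @param window integer pair: first and last time step used (steps are
#'   0-based, so `c(30, 60)` selects frames 31..61).
#' @param train_frac fraction of the shuffled window frames used for
#'   training (the rest is the test set).
#' @param validation_ids trajectory indices held out for per-trajectory
#'   validation; default none.
#' @param seed shuffle seed.
#' @return A `downhill_dataset`: list with `X_train`, `y_train`,
#'   `X_test`, `y_test` (matrices / 0-1 vectors with 1 = OUT),
#'   `validation` (list of per-trajectory frame matrices), `validation_y`,
#'   `window`, `n_features`, bookkeeping ids.
#' @export
mltsa_dataset <- function(features, labels = NULL, window = c(30, 60),
                          train_frac = 0.7, validation_ids = integer(),
                          seed = 1) {
  frames <- if (inherits(features, "trj_ensemble")) features$frames else features
  if (is.null(labels) && inherits(features, "trj_ensemble")) {
    labels <- features$labels
  }
  d <- dim(frames)
  stopifnot(!is.null(labels), length(labels) == d[1],
            window[1] >= 0, window[2] >= window[1], window[2] < d[2],
            train_frac > 0, train_frac < 1)
  labels <- factor(labels, levels = c("IN", "OUT"))
  if (!all(levels(droplevels(labels)) %in% c("IN", "OUT"))) {
    stop("labels must be IN/OUT", call. = FALSE)
  }
  validation_ids <- sort(unique(as.integer(validation_ids)))
  train_traj <- setdiff(seq_len(d[1]), validation_ids)
  win <- seq.int(window[1] + 1L, window[2] + 1L)   # steps are 0-based
  nw <- length(win)
  # concatenate window frames of the training trajectories
  flat <- matrix(aperm(frames[train_traj, win, , drop = FALSE], c(2, 1, 3)),
                 nrow = length(train_traj) * nw, ncol = d[3])
  y_flat <- rep(as.integer(labels[train_traj]) - 1L, each = nw)
  set.seed(seed)
  perm <- sample.int(nrow(flat))
  flat <- flat[perm, , drop = FALSE]
  y_flat <- y_flat[perm]
  n_train <- floor(train_frac * nrow(flat))
  validation <- lapply(validation_ids, function(i) {
    matrix(frames[i, win, ], nrow = nw, ncol = d[3])
  })
  structure(
    list(X_train = flat[seq_len(n_train), , drop = FALSE],
         y_train = y_flat[seq_len(n_train)],
         X_test = flat[-seq_len(n_train), , drop = FALSE],
         y_test = y_flat[-seq_len(n_train)],
         validation = validation,
         validation_y = as.integer(labels[validation_ids]) - 1L,
         window = window, n_features = d[3],
         train_trajectories = train_traj, validation_ids = validation_ids,
         seed = seed),
    class = "downhill_dataset"
  )
}

#' @export
print.downhill_dataset <- function(x, ...) {
  cat("<downhill_dataset> ", nrow(x$X_train), " train / ", nrow(x$X_test),
      " test frames x ", x$n_features, " features; ",
      length(x$validation), " held-out validation trajectories\n", sep = "")
  invisible(x)
}

#' Classifier configurations for MLTSA
#'
#' `mlp_config()`: single hidden layer of 100 rectified-linear units,
#' logistic output, adaptive-moment (Adam) minibatch optimisation at
#' learning rate 0.001, at most 500 epochs, stopping after 10 consecutive
#' epochs improving the loss by less than 1e-4. `gbdt_config()`: gradient
#' boosted trees, 500 weak learners of depth 3, learning rate 0.1,
#' logistic loss, minimum 2 samples to split / 1 per leaf, validation
#' fraction 0.1 held out during boosting.
#'
#' @param hidden_units,learning_rate,max_epochs,tol,patience,batch_size,l2
#'   MLP hyperparameters.
#' @param standardize center/scale inputs with training-set statistics
#'   before optimisation (off by default: inputs are fed raw, as in the
#'   reference architecture).
#' @return A config list tagged with its backend.
#' @export
mlp_config <- function(hidden_units = 100, learning_rate = 0.001,
                       max_epochs = 500, tol = 1e-4, patience = 10,
                       batch_size = 200, l2 = 1e-4, standardize = FALSE) {
  stopifnot(hidden_units > 0, learning_rate > 0, max_epochs > 0, tol > 0)
  structure(list(backend = "mlp", hidden_units = hidden_units,
                 learning_rate = learning_rate, max_epochs = max_epochs,
                 tol = tol, patience = patience, batch_size = batch_size,
                 l2 = l2, standardize = standardize),
            class = "mltsa_config")
}

#' @rdname mlp_config
#' @param n_estimators,max_depth,min_split,min_leaf,validation_fraction
#'   GBDT hyperparameters (`learning_rate` is shared).
#' @export
gbdt_config <- function(n_estimators = 500, learning_rate = 0.1,
                        max_depth = 3, min_split = 2, min_leaf = 1,
                        validation_fraction = 0.1) {
  stopifnot(n_estimators > 0, learning_rate > 0, max_depth >= 1)
  structure(list(backend = "gbdt", n_estimators = n_estimators,
                 learning_rate = learning_rate, max_depth = max_depth,
                 min_split = min_split, min_leaf = min_leaf,
                 validation_fraction = validation_fraction),
            class = "mltsa_config")
}

#' Train a classifier on a downhill dataset and score it
#'
#' Fits the configured backend on the training frames and reports
#' frame-level train and test accuracy plus validation accuracy on the
#' held-out trajectories. Validation is per-trajectory by default: a
#' trajectory is scored correct when the majority vote over its window
#' frames matches its label (`validation = "frame"` scores every frame).
#'
#' @param dataset a [mltsa_dataset()].
#' @param config [mlp_config()] or [gbdt_config()].
#' @param validation `"trajectory"` (majority vote) or `"frame"`.
#' @param seed training seed (weight init / minibatch order / boosting).
#' @return An `mltsa_fit`: list with `model`, `config`, `accuracy`
#'   (tibble `set`, `accuracy`), and prediction closures.
#' @export
fit_mltsa <- function(dataset, config = mlp_config(),
                      validation = c("trajectory", "frame"), seed = 1) {
  validation <- match.arg(validation)
  if (length(unique(dataset$y_train)) < 2) {
    stop("training data contain a single class", call. = FALSE)
  }
  if (config$backend == "mlp") {
    model <- mlp_train(dataset$X_train, dataset$y_train,
                       hidden_units = config$hidden_units,
                       learning_rate = config$learning_rate,
                       max_epochs = config$max_epochs, tol = config$tol,
                       patience = config$patience,
                       batch_size = config$batch_size, l2 = config$l2,
                       standardize = isTRUE(config$standardize),
                       seed = seed)
    predict_fn <- function(X) mlp_predict(model, X)
  } else {
    n <- nrow(dataset$X_train)
    set.seed(seed)
    hold <- sample.int(n, max(1, floor(config$validation_fraction * n)))
    dtrain <- xgboost::xgb.DMatrix(dataset$X_train[-hold, , drop = FALSE],
                                   label = dataset$y_train[-hold])
    dwatch <- xgboost::xgb.DMatrix(dataset$X_train[hold, , drop = FALSE],
                                   label = dataset$y_train[hold])
    model <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    eta = config$learning_rate,
                    max_depth = config$max_depth,
                    min_child_weight = config$min_leaf,
                    lambda = 0, alpha = 0, subsample = 1,
                    colsample_bytree = 1, nthread = 1),
      data = dtrain, nrounds = config$n_estimators,
      evals = list(validation = dwatch), verbose = 0)
    predict_fn <- function(X) {
      as.integer(stats::predict(model, xgboost::xgb.DMatrix(X)) > 0.5)
    }
  }
  acc <- function(X, y) mean(predict_fn(X) == y)
  val_acc <- if (length(dataset$validation) == 0) NA_real_ else {
    if (validation == "trajectory") {
      votes <- vapply(dataset$validation,
                      function(m) mean(predict_fn(m)) > 0.5, logical(1))
      mean(as.integer(votes) == dataset$validation_y)
    } else {
      preds <- unlist(lapply(dataset$validation, predict_fn))
      truth <- rep(dataset$validation_y,
                   vapply(dataset$validation, nrow, integer(1)))
      mean(preds == truth)
    }
  }
  structure(
    list(model = model, config = config, predict = predict_fn,
         n_features = dataset$n_features,
         accuracy = tibble::tibble(
           set = c("train", "test", "validation"),
           accuracy = c(acc(dataset$X_train, dataset$y_train),
                        acc(dataset$X_test, dataset$y_test),
                        val_acc)),
         dataset_window = dataset$window, seed = seed),
    class = "mltsa_fit"
  )
}

#' @export
print.mltsa_fit <- function(x, ...) {
  cat("<mltsa_fit> backend:", x$config$backend, "\n")
  print(x$accuracy)
  invisible(x)
}

#' @param x an `mltsa_fit`.
#' @param ... unused.
#' @return `tidy()`: the accuracy tibble; `glance()`: one row with
#'   `backend`, `train`, `test`, `validation`.
#' @rdname fit_mltsa
#' @method tidy mltsa_fit
#' @export
tidy.mltsa_fit <- function(x, ...) x$accuracy

#' @rdname fit_mltsa
#' @method glance mltsa_fit
#' @export
glance.mltsa_fit <- function(x, ...) {
  a <- x$accuracy$accuracy
  tibble::tibble(backend = x$config$backend, train = a[1], test = a[2],
                 validation = a[3])
}

#' Accuracy as a function of the training window
#'
#' Trains one classifier per window and tabulates the accuracies; used to
#' find the early-time regime where the outcome is accurately predictable
#' but not trivially separable.
#'
#' @param features labelled feature ensemble (see [mltsa_dataset()]).
#' @param windows list of `c(start, end)` step pairs.
#' @param config classifier configuration.
#' @param validation_ids,seed passed to [mltsa_dataset()] / [fit_mltsa()].
#' @return A tibble `window_start`, `window_end`, `train`, `test`,
#'   `validation`.
#' @export
accuracy_sweep <- function(features, windows, config = mlp_config(),
                           validation_ids = integer(), seed = 1) {
  purrr::map_dfr(windows, function(w) {
    ds <- mltsa_dataset(features, window = w,
                        validation_ids = validation_ids, seed = seed)
    fit <- fit_mltsa(ds, config, seed = seed)
    dplyr::bind_cols(tibble::tibble(window_start = w[1], window_end = w[2]),
                     glance(fit)[, c("train", "test", "validation")])
  })
}

#' Global-mean swap: per-feature accuracy drop
#'
#' The MLTSA feature attribution: each feature in turn is replaced,
#' everywhere, by its global mean over the training frames (cancelling its
#' variance while leaving every other feature untouched); the model
#' re-predicts and the drop is baseline accuracy minus swapped accuracy.
#' Evaluated on all frames used in training and testing by default (the
#' larger pool gives the finest drop resolution).
#'
#' @param fit an `mltsa_fit`.
#' @param dataset the [mltsa_dataset()] it was trained on.
#' @param on `"all"` (train + test pool), `"test"` or `"train"` frames.
#' @return A tibble `feature`, `drop`, with the baseline accuracy as
#'   attribute `baseline`.
#' @export
global_mean_drop <- function(fit, dataset, on = c("all", "test", "train")) {
  on <- match.arg(on)
  X <- switch(on, all = rbind(dataset$X_train, dataset$X_test),
              test = dataset$X_test, train = dataset$X_train)
  y <- switch(on, all = c(dataset$y_train, dataset$y_test),
              test = dataset$y_test, train = dataset$y_train)
  gm <- colMeans(dataset$X_train)
  baseline <- mean(fit$predict(X) == y)
  drops <- vapply(seq_len(ncol(X)), function(j) {
    Xs <- X
    Xs[, j] <- gm[j]
    baseline - mean(fit$predict(Xs) == y)
  }, numeric(1))
  out <- tibble::tibble(feature = seq_len(ncol(X)), drop = drops)
  attr(out, "baseline") <- baseline
  out
}

#' GBDT feature importances
#'
#' Split-gain importances of a fitted gradient-boosted-tree backend,
#' normalised to sum to 1; features never used by a split score 0.
#'
#' @param fit an `mltsa_fit` with the GBDT backend.
#' @return A tibble `feature`, `importance`.
#' @export
gbdt_importances <- function(fit) {
  stopifnot(fit$config$backend == "gbdt")
  imp <- xgboost::xgb.importance(model = fit$model)
  n <- fit$n_features
  out <- numeric(n)
  idx <- as.integer(sub("^f", "", imp$Feature)) + 1L
  out[idx] <- imp$Gain
  tibble::tibble(feature = seq_len(n), importance = out / sum(out))
}

#' Launch unbiased downhill trajectories from TS candidates
#'
#' For each candidate starting coordinate, runs `n_runs` independent
#' unbiased trajectories with distinct seeds.
#'
#' @param potential the `unbind_potential`.
#' @param starts matrix of candidate starting coordinates
#'   (`n_candidates x dimension`).
#' @param n_runs trajectories per candidate (default 50).
#' @param n_steps frames per trajectory.
#' @param step_size,friction,kT engine settings.
#' @param seed base seed; candidate `i` uses `seed + i`.
#' @return A list of `trj_ensemble`, one per candidate.
#' @export
generate_downhill <- function(potential, starts, n_runs = 50, n_steps = 500,
                              step_size = 0.01, friction = 1, kT = 1,
                              seed = 1) {
  starts <- as_coord_matrix(starts, potential$dimension)
  lapply(seq_len(nrow(starts)), function(i) {
    simulate_langevin(potential, n_steps = n_steps, n_traj = n_runs,
                      x0 = matrix(starts[i, ], n_runs, ncol(starts),
                                  byrow = TRUE),
                      step_size = step_size, friction = friction, kT = kT,
                      seed = seed + i)
  })
}

#' Choose the transition-state candidate closest to a 1:1 committor
#'
#' Picks the candidate whose IN fraction is closest to 0.5; exact ties go
#' to the candidate with the higher free energy.
#'
#' @param candidates tibble with `in_fraction` and (optionally) `pmf`
#'   columns, one row per candidate.
#' @return The chosen row index.
#' @export
select_ts <- function(candidates) {
  stopifnot(nrow(candidates) >= 1, "in_fraction" %in% names(candidates))
  dev <- abs(candidates$in_fraction - 0.5)
  best <- which(dev == min(dev))
  if (length(best) > 1 && "pmf" %in% names(candidates)) {
    best <- best[which.max(candidates$pmf[best])]
  }
  best[1]
}

#' Label downhill trajectories from two monitored key distances
#'
#' A trajectory is `IN` when both monitored distances' means over the
#' final window are below their bound thresholds, `OUT` when either
#' exceeds the unbound threshold, and `NA` (unresolved, to be excluded)
#' otherwise.
#'
#' @param d1,d2 matrices (`n_traj x n_steps`) of the two key distances.
#' @param bound_thresholds length-2 numeric: bound cutoffs for d1 and d2
#'   (Å).
#' @param unbound_threshold single unbound cutoff (default 6 Å).
#' @param final_window how many final frames to average (default 10).
#' @return Factor `IN`/`OUT` with `NA` for unresolved trajectories.
#' @export
label_downhill <- function(d1, d2, bound_thresholds,
                           unbound_threshold = 6, final_window = 10) {
  stopifnot(all(dim(d1) == dim(d2)), length(bound_thresholds) == 2)
  idx <- seq.int(ncol(d1) - final_window + 1L, ncol(d1))
  m1 <- rowMeans(d1[, idx, drop = FALSE])
  m2 <- rowMeans(d2[, idx, drop = FALSE])
  lab <- rep(NA_character_, nrow(d1))
  lab[m1 > unbound_threshold | m2 > unbound_threshold] <- "OUT"
  lab[m1 < bound_thresholds[1] & m2 < bound_thresholds[2]] <- "IN"
  if (all(is.na(lab))) stop("all trajectories unresolved", call. = FALSE)
  factor(lab, levels = c("IN", "OUT"))
}
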