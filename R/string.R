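#' Finite-temperature string over collective-variable space
#'
#' A string is an ordered set of nodes (restraint centers) in CV space,
#' equidistant in arc length, together with the arc parameter of each node
#' in \[0, 1\]. Strings are seeded from an unbinding trajectory's CV
#' series, refined against per-window sampled means with a high-order
#' polynomial refit, and reparametrised to equal arc spacing after every
#' refit.
#'
#' @name string_path
NULL

new_string_path <- function(nodes, force_constant = 20, iteration = 0L,
                            node_coords = NULL) {
  n <- nrow(nodes)
  structure(
    list(nodes = nodes, arc_parameter = seq(0, 1, length.out = n),
         force_constant = force_constant, iteration = as.integer(iteration),
         node_coords = node_coords),
    class = "string_path"
  )
}

#' @export
print.string_path <- function(x, ...) {
  cat("<string_path> ", nrow(x$nodes), " windows x ", ncol(x$nodes),
      " CVs (iteration ", x$iteration, ")\n", sep = "")
  invisible(x)
}

#' @param x a `string_path`.
#' @param ... unused.
#' @return A tibble `window`, `arc`, one column per CV.
#' @rdname string_path
#' @method tidy string_path
#' @export
tidy.string_path <- function(x, ...) {
  nodes <- x$nodes
  colnames(nodes) <- paste0("cv", seq_len(ncol(nodes)))
  dplyr::bind_cols(
    tibble::tibble(window = seq_len(nrow(nodes)), arc = x$arc_parameter),
    tibble::as_tibble(nodes)
  )
}

# Fit per-CV polynomials in a parameter s and re-place n_out nodes
# equidistantly in arc length along the fitted curve.
fit_and_reparametrize <- function(points, s, order, n_out, dense = 2001L) {
  n_cv <- ncol(points)
  order <- min(order, length(s) - 1L)
  grid <- seq(min(s), max(s), length.out = dense)
  fitted <- matrix(0, dense, n_cv)
  for (j in seq_len(n_cv)) {
    if (stats::sd(points[, j]) < 1e-12) {
      fitted[, j] <- mean(points[, j])
    } else {
      fit <- stats::lm(y ~ stats::poly(s, order, raw = FALSE),
                       data = list(y = points[, j], s = s))
      fitted[, j] <- stats::predict(fit, newdata = list(s = grid))
    }
  }
  seg <- sqrt(rowSums((fitted[-1, , drop = FALSE] -
                         fitted[-dense, , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  total <- arc[dense]
  if (total < 1e-10) stop("degenerate (constant) CV series", call. = FALSE)
  targets <- seq(0, total, length.out = n_out)
  idx <- findInterval(targets, arc, all.inside = TRUE)
  # linear interpolation between dense grid points
  a0 <- arc[idx]; a1 <- arc[idx + 1L]
  w <- ifelse(a1 > a0, (targets - a0) / (a1 - a0), 0)
  nodes <- fitted[idx, , drop = FALSE] * (1 - w) +
    fitted[idx + 1L, , drop = FALSE] * w
  list(nodes = nodes, grid_idx = idx, fitted = fitted)
}

#' Seed a string from an unbinding CV series
#'
#' Fits a smooth curve (per-CV polynomial in normalised time) through the
#' CV series of an unbinding trajectory and places `n_windows` nodes
#' equidistantly in arc length along it. When `coords` (the trajectory's
#' coordinates, one row per CV-series frame) are supplied, each node also
#' records the coordinates of the nearest frame in CV space, used to start
#' the window samplers.
#'
#' @param cv_series matrix (frames x n_cvs) of CV values spanning
#'   bound to unbound.
#' @param n_windows number of string windows (default 100).
#' @param order polynomial order of the seeding fit.
#' @param coords optional coordinate matrix aligned with `cv_series` rows.
#' @param force_constant per-CV restraint force constant
#'   (kcal mol^-1 Å^-2).
#' @return A `string_path`.
#' @export
seed_string <- function(cv_series, n_windows = 100, order = 8,
                        coords = NULL, force_constant = 20) {
  cv_series <- as.matrix(cv_series)
  stopifnot(n_windows >= 2, nrow(cv_series) >= 2)
  s <- seq(0, 1, length.out = nrow(cv_series))
  fit <- fit_and_reparametrize(cv_series, s, order, n_windows)
  node_coords <- NULL
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == nrow(cv_series))
    nearest <- vapply(seq_len(n_windows), function(i) {
      which.min(colSums((t(cv_series) - fit$nodes[i, ])^2))
    }, integer(1))
    node_coords <- coords[nearest, , drop = FALSE]
  }
  new_string_path(fit$nodes, force_constant = force_constant,
                  node_coords = node_coords)
}

#' Polynomial refit of a string to sampled window means
#'
#' Fits an order-`order` polynomial per CV (in the current arc parameter)
#' to the per-window sampled mean CV values, then re-places the nodes
#' equidistantly in arc length along the refitted curve.
#'
#' @param path the current `string_path`.
#' @param window_means matrix (n_windows x n_cvs) of sampled mean CV
#'   values, one per window.
#' @param order polynomial order (default 8); must be < n_windows.
#' @return The refitted `string_path` (iteration incremented).
#' @export
refit_string <- function(path, window_means, order = 8) {
  window_means <- as.matrix(window_means)
  n <- nrow(path$nodes)
  stopifnot(nrow(window_means) == n,
            ncol(window_means) == ncol(path$nodes))
  if (order >= n) stop("polynomial order must be below n_windows",
                       call. = FALSE)
  fit <- fit_and_reparametrize(window_means, path$arc_parameter, order, n)
  out <- new_string_path(fit$nodes, force_constant = path$force_constant,
                         iteration = path$iteration + 1L,
                         node_coords = path$node_coords)
  out
}

#' String convergence check
#'
#' Converged when, for every CV, the maximal node displacement between
#' subsequent iterations is below `rel_tol` (default 7%) of that CV's
#' range along the path, or below `abs_tol` (default 0.3 Å) absolutely.
#'
#' @param prev,curr `string_path`s of identical shape.
#' @param rel_tol relative threshold (fraction of the CV's path range).
#' @param abs_tol absolute threshold (Å).
#' @return A list: `converged` (logical) and `changes`, a tibble with
#'   `cv`, `max_change`, `range`, `converged`.
#' @export
check_convergence <- function(prev, curr, rel_tol = 0.07, abs_tol = 0.3) {
  stopifnot(all(dim(prev$nodes) == dim(curr$nodes)))
  delta <- abs(curr$nodes - prev$nodes)
  max_change <- apply(delta, 2, max)
  rng <- apply(prev$nodes, 2, function(v) diff(range(v)))
  ok <- max_change < rel_tol * rng | max_change < abs_tol
  list(converged = all(ok),
       changes = tibble::tibble(cv = seq_along(max_change),
                                max_change = max_change, range = rng,
                                converged = ok))
}

#' Sample the string windows and iterate the refinement
#'
#' For each window, runs restrained Langevin sampling with per-CV harmonic
#' restraints at the node centers (force constant `path$force_constant`),
#' collects the CV values of every frame, refits the string to the window
#' means and reparametrises, until [check_convergence()] passes or
#' `max_iterations` is reached. Sampling starts from each node's recorded
#' coordinates (warm-started across iterations).
#'
#' @param potential the `unbind_potential` sampled.
#' @param cvs list of `unbind_cv` defining the string space.
#' @param path initial `string_path` with `node_coords` set.
#' @param steps_per_window engine frames sampled per window per iteration.
#' @param equilibration frames discarded from the start of each window.
#' @param max_iterations string iterations.
#' @param min_iterations iterations to run before the convergence check
#'   may stop the refinement; with stiff restraints the per-iteration
#'   node displacement can sit below the absolute threshold while the
#'   path is still drifting toward the minimum free-energy path, so
#'   probing the true fixed point requires forcing further iterations.
#' @param step_size,friction,kT engine settings.
#' @param order refit polynomial order.
#' @param rel_tol,abs_tol convergence thresholds ([check_convergence()]).
#' @param seed integer seed.
#' @return A list of class `string_run`: `path` (final), `paths` (per
#'   iteration), `converged`, `history` (tibble of per-iteration max
#'   changes), and `ensembles` (final iteration: per-window CV samples,
#'   a list of matrices), `node_coords`.
#' @export
run_string <- function(potential, cvs, path, steps_per_window = 800,
                       equilibration = floor(steps_per_window / 4),
                       max_iterations = 10, min_iterations = 1,
                       step_size = 0.005, friction = 1,
                       kT = 0.5925, order = 8, rel_tol = 0.07,
                       abs_tol = 0.3, seed = 1) {
  stopifnot(!is.null(path$node_coords))
  n_win <- nrow(path$nodes)
  paths <- list(path)
  history <- list()
  converged <- FALSE
  ensembles <- NULL
  for (it in seq_len(max_iterations)) {
    samples <- vector("list", n_win)
    means <- matrix(0, n_win, ncol(path$nodes))
    for (w in seq_len(n_win)) {
      bias <- bias_harmonic(cvs, center = path$nodes[w, ],
                            k = path$force_constant, schedule = "fixed")
      run <- simulate_langevin(potential, n_steps = steps_per_window,
                               n_traj = 1, x0 = path$node_coords[w, ],
                               step_size = step_size, friction = friction,
                               kT = kT, bias = bias,
                               seed = seed + 1000L * it + w)
      coords <- matrix(run$frames[1, , ], ncol = potential$dimension)
      cvvals <- vapply(cvs, function(cv) cv$value(coords),
                       numeric(nrow(coords)))
      keep <- seq.int(equilibration + 1L, steps_per_window)
      samples[[w]] <- cvvals[keep, , drop = FALSE]
      means[w, ] <- colMeans(samples[[w]])
      path$node_coords[w, ] <- coords[steps_per_window, ]
    }
    new_path <- refit_string(path, means, order = order)
    conv <- check_convergence(path, new_path, rel_tol, abs_tol)
    history[[it]] <- dplyr::mutate(conv$changes, iteration = it)
    paths <- c(paths, list(new_path))
    ensembles <- samples
    path <- new_path
    if (conv$converged && it >= min_iterations) { converged <- TRUE; break }
  }
  structure(
    list(path = path, paths = paths, converged = converged,
         history = dplyr::bind_rows(history), ensembles = ensembles,
         sampling_path = paths[[length(paths) - 1L]],
         node_coords = path$node_coords),
    class = "string_run"
  )
}

#' @export
print.string_run <- function(x, ...) {
  cat("<string_run> ", length(x$paths) - 1L, " iterations; converged: ",
      x$converged, "\n", sep = "")
  invisible(x)
}
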