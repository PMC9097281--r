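#' Overdamped Langevin dynamics on an analytic potential
#'
#' Integrates the overdamped (Brownian) equation of motion by the
#' Euler--Maruyama scheme
#' \deqn{x_{t+1} = x_t - \frac{\Delta t}{\gamma}\,\nabla(V + U_{bias})(x_t)
#'       + \sqrt{2\,k_BT\,\Delta t/\gamma}\;\xi_t,}
#' with \eqn{\xi_t} i.i.d. standard normal. All trajectories of the
#' ensemble are advanced together, so the cost is `n_steps` vectorised
#' gradient evaluations. The returned frames include the initial condition
#' as frame 1, so `n_steps` frames span time steps 0 to `n_steps - 1`.
#'
#' @param potential an `unbind_potential`.
#' @param n_steps number of recorded frames (>= 1).
#' @param n_traj number of independent trajectories.
#' @param x0 initial coordinates: a vector of length `dimension` (shared by
#'   all trajectories) or an `n_traj x dimension` matrix.
#' @param step_size integration time step (dimensionless time units).
#' @param friction friction coefficient \eqn{\gamma} (sets mobility
#'   \eqn{\Delta t/\gamma}); a scalar, or a vector of per-coordinate
#'   frictions (different degrees of freedom may have different
#'   mobilities).
#' @param kT thermal energy, in the potential's energy units. `kT = 0`
#'   gives deterministic gradient descent.
#' @param bias optional [bias_harmonic()] term; its ramp schedule fraction
#'   advances linearly from 0 at the first step to 1 at the last.
#' @param seed integer seed; identical seeds give bit-identical ensembles.
#' @param guard divergence guard: an error is raised if any |coordinate|
#'   exceeds this (signals a step size too large for the stiffness).
#' @return A `trj_ensemble`: list with `frames`
#'   (`n_traj x n_steps x dimension` array), `step_size`, `labels`
#'   (NULL until [label_outcome()]), and `provenance`.
#' @examples
#' dw <- potential_double_well(height = 8)
#' trj <- simulate_langevin(dw, n_steps = 100, n_traj = 4, x0 = 0, kT = 1, seed = 1)
#' dim(trj$frames)
#' @export
simulate_langevin <- function(potential, n_steps, n_traj = 1, x0,
                     step_size = 0.01, friction = 1, kT = 1,
                     bias = NULL, seed = NULL, guard = 1e3) {
  stopifnot(n_steps >= 1, n_traj >= 1, step_size > 0, all(friction > 0),
            kT >= 0)
  d <- potential$dimension
  stopifnot(length(friction) %in% c(1L, d))
  friction <- rep_len(friction, d)
  x <- if (is.matrix(x0)) {
    stopifnot(nrow(x0) == n_traj, ncol(x0) == d)
    x0
  } else {
    stopifnot(length(x0) == d)
    matrix(x0, n_traj, d, byrow = TRUE)
  }
  if (!is.null(seed)) set.seed(seed)
  frames <- array(NA_real_, dim = c(n_traj, n_steps, d))
  frames[, 1, ] <- x
  mob <- matrix(step_size / friction, n_traj, d, byrow = TRUE)
  noise_sd <- matrix(sqrt(2 * kT * step_size / friction), n_traj, d,
                     byrow = TRUE)
  for (t in seq_len(n_steps - 1L)) {
    g <- potential$gradient(x)
    if (!is.null(bias)) {
      frac <- if (n_steps > 2L) (t - 1) / (n_steps - 2L) else 1
      g <- g + bias_gradient(bias, x, frac)
    }
    x <- x - mob * g
    if (kT > 0) {
      x <- x + matrix(stats::rnorm(n_traj * d), n_traj, d) * noise_sd
    }
    if (any(abs(x) > guard)) {
      stop("trajectory diverged (|x| > ", guard,
           "): step_size too large for the potential stiffness", call. = FALSE)
    }
    frames[, t + 1L, ] <- x
  }
  structure(
    list(frames = frames, step_size = step_size, labels = NULL,
         provenance = list(potential_kind = potential$kind,
                           biased = !is.null(bias), seed = seed,
                           friction = friction, kT = kT)),
    class = "trj_ensemble"
  )
}

#' @export
print.trj_ensemble <- function(x, ...) {
  d <- dim(x$frames)
  cat("<trj_ensemble> ", d[1], " trajectories x ", d[2], " frames x ",
      d[3], " dims", if (!is.null(x$labels)) " (labelled)", "\n", sep = "")
  invisible(x)
}

#' Label trajectories IN/OUT by the final basin of the decisive coordinate
#'
#' A trajectory is labelled `IN` when the decisive coordinate's final-frame
#' value is on the bound side of the crest separating the two basins, `OUT`
#' otherwise. A final frame exactly at the crest is assigned `IN`
#' (deterministic tie rule for a measure-zero event).
#'
#' @param traj a `trj_ensemble`.
#' @param decisive_dimension which coordinate decides the outcome.
#' @param crest basin boundary (barrier-top position).
#' @param bound_side `"lower"` if the bound basin is below the crest.
#' @return The ensemble with a `labels` factor (`IN`/`OUT`) attached.
#' @export
label_outcome <- function(traj, decisive_dimension = 1, crest = 0,
                          bound_side = c("lower", "upper")) {
  bound_side <- match.arg(bound_side)
  d <- dim(traj$frames)
  stopifnot(decisive_dimension >= 1, decisive_dimension <= d[3])
  final <- traj$frames[, d[2], decisive_dimension]
  is_in <- if (bound_side == "lower") final <= crest else final >= crest
  traj$labels <- factor(ifelse(is_in, "IN", "OUT"), levels = c("IN", "OUT"))
  traj
}

#' Tidy a trajectory ensemble into a long tibble
#'
#' @param x a `trj_ensemble`.
#' @param ... unused.
#' @return A tibble with columns `trajectory`, `frame`, `dim`, `value`,
#'   and `label` when labels are present.
#' @method tidy trj_ensemble
#' @export
tidy.trj_ensemble <- function(x, ...) {
  d <- dim(x$frames)
  out <- tibble::tibble(
    trajectory = rep(seq_len(d[1]), times = d[2] * d[3]),
    frame = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    dim = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(x$frames)
  )
  if (!is.null(x$labels)) out$label <- x$labels[out$trajectory]
  out
}

#' Per-frame distances from an ensemble to fixed anchors
#'
#' The toy analog of a protein--ligand heavy-atom distance table: one row
#' per frame, one column per anchor, units of the coordinate space (Å).
#' Only single-trajectory ensembles are accepted.
#'
#' @param traj a `trj_ensemble` with one trajectory.
#' @param anchors matrix of anchor positions (`n_anchors x dimension`),
#'   with rownames used as pair ids.
#' @return A tibble, frames in rows, one column per anchor id.
#' @export
anchor_distances <- function(traj, anchors) {
  stopifnot(dim(traj$frames)[1] == 1L)
  coords <- traj$frames[1, , , drop = TRUE]
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1)
  ids <- rownames(anchors)
  if (is.null(ids)) ids <- paste0("a", seq_len(nrow(anchors)))
  cols <- lapply(seq_len(nrow(anchors)), function(i) {
    sqrt(rowSums((coords - matrix(anchors[i, ], nrow(coords), ncol(coords),
                                  byrow = TRUE))^2))
  })
  names(cols) <- ids
  tibble::as_tibble(cols)
}

#' Write / read a trajectory ensemble as delimited text
#'
#' One file per trajectory (`traj_<i>.tsv`), tab-separated with a header
#' naming the dimensions, plus a JSON sidecar with step size, labels and
#' provenance.
#'
#' @param traj a `trj_ensemble`.
#' @param dir output directory (created if needed).
#' @return `write_trajectories()` the directory, invisibly;
#'   `read_trajectories()` a `trj_ensemble`.
#' @export
write_trajectories <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(traj$frames)
  for (i in seq_len(d[1])) {
    m <- matrix(traj$frames[i, , ], nrow = d[2], ncol = d[3])
    colnames(m) <- paste0("dim", seq_len(d[3]))
    utils::write.table(m, file.path(dir, sprintf("traj_%04d.tsv", i)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  meta <- list(n_trajectories = d[1], n_steps = d[2], dimension = d[3],
               step_size = traj$step_size,
               labels = if (is.null(traj$labels)) NULL else
                 as.character(traj$labels),
               provenance = traj$provenance)
  jsonlite::write_json(meta, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^traj_\\d+\\.tsv$",
                           full.names = TRUE))
  stopifnot(length(files) == meta$n_trajectories)
  frames <- array(NA_real_,
                  dim = c(meta$n_trajectories, meta$n_steps, meta$dimension))
  for (i in seq_along(files)) {
    frames[i, , ] <- as.matrix(utils::read.delim(files[i]))
  }
  structure(
    list(frames = frames, step_size = meta$step_size,
         labels = if (is.null(meta$labels)) NULL else
           factor(meta$labels, levels = c("IN", "OUT")),
         provenance = meta$provenance),
    class = "trj_ensemble"
  )
}
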