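#' Parameters of the iterative unbinding protocol
#'
#' Defaults follow the protocol's standard settings: contacts are included
#' below `d_in` = 3.5 Å, removed once their windowed mean exceeds
#' `d_out` = 6 Å or their windowed variance exceeds `d_var` = 1 Å², the
#' per-distance bias increment `d_tar` is 1 Å, and the harmonic force
#' constant `k` is 20 kcal mol^-1 Å^-2. A contact must sit below `d_in`
#' for strictly more than `persistence_fraction` (default one half) of the
#' evaluated frames to count as stable. Iteration and evaluation-window
#' lengths are in engine frames; the evaluation window defaults to the
#' last half of an iteration.
#'
#' @param d_in inclusion cutoff (Å).
#' @param d_out removal cutoff on the windowed mean (Å).
#' @param d_var removal cutoff on the windowed variance (Å²); with
#'   `var_mode = "sd"` interpreted as a standard-deviation cutoff in Å.
#' @param d_tar per-distance bias increment (Å).
#' @param k bias force constant (kcal mol^-1 Å^-2).
#' @param persistence_fraction fraction of frames a candidate must spend
#'   below `d_in` (strict inequality) to become active.
#' @param iteration_length frames simulated per iteration.
#' @param evaluation_window frames (from the end of an iteration) used for
#'   the add/remove rules.
#' @param var_mode `"variance"` (threshold in Å²) or `"sd"` (Å).
#' @param removal_mode `"mean"` (windowed mean beyond `d_out`) or `"any"`
#'   (any windowed frame beyond `d_out`).
#' @param max_iterations non-termination guard.
#' @return A list of class `protocol_params`.
#' @export
protocol_params <- function(d_in = 3.5, d_out = 6, d_var = 1, d_tar = 1,
                            k = 20, persistence_fraction = 0.5,
                            iteration_length = 10000,
                            evaluation_window = iteration_length / 2,
                            var_mode = c("variance", "sd"),
                            removal_mode = c("mean", "any"),
                            max_iterations = 50) {
  var_mode <- match.arg(var_mode)
  removal_mode <- match.arg(removal_mode)
  stopifnot(d_in > 0, d_in < d_out, d_tar >= 0, k >= 0,
            persistence_fraction > 0, persistence_fraction <= 1,
            iteration_length >= 2, evaluation_window >= 2,
            evaluation_window <= iteration_length)
  structure(list(d_in = d_in, d_out = d_out, d_var = d_var, d_tar = d_tar,
                 k = k, persistence_fraction = persistence_fraction,
                 iteration_length = as.integer(iteration_length),
                 evaluation_window = as.integer(evaluation_window),
                 var_mode = var_mode, removal_mode = removal_mode,
                 max_iterations = as.integer(max_iterations)),
            class = "protocol_params")
}

contact_tbl <- function(ids) {
  tibble::tibble(id = as.character(ids),
                 status = character(length(ids)),
                 added_iteration = NA_integer_,
                 removed_iteration = NA_integer_)
}

#' Detect the initial contact set from an unbiased exploration
#'
#' A pair is an active contact when its distance is below `d_in` for
#' strictly more than `persistence_fraction` of the provided frames;
#' everything else stays a candidate.
#'
#' @param distances per-frame distance table (tibble/data.frame, frames in
#'   rows, one column per pair id, Å).
#' @param params a [protocol_params()].
#' @return A `contact_set` tibble: `id`, `status`
#'   (`active`/`candidate`), `added_iteration`, `removed_iteration`.
#' @export
detect_initial_contacts <- function(distances, params = protocol_params()) {
  if (nrow(distances) == 0 || ncol(distances) == 0) {
    stop("empty distance table", call. = FALSE)
  }
  frac <- unname(vapply(distances, function(d) mean(d < params$d_in),
                        numeric(1)))
  out <- contact_tbl(names(distances))
  out$status <- ifelse(frac > params$persistence_fraction,
                       "active", "candidate")
  out$added_iteration <- ifelse(out$status == "active", 0L, NA_integer_)
  class(out) <- c("contact_set", class(out))
  out
}

#' Bias target for the next unbinding iteration
#'
#' \eqn{D = D_0 + M\,d_{tar}}: the main-CV target grows by the increment
#' `d_tar` per active distance, and is approached progressively (linear
#' ramp) over the iteration.
#'
#' @param D0 CV value at the start of the iteration (Å).
#' @param M number of active distances in the main CV.
#' @param params a [protocol_params()].
#' @return Target CV value `D` (Å).
#' @export
bias_target <- function(D0, M, params = protocol_params()) {
  stopifnot(M >= 1)
  D0 + M * params$d_tar
}

#' Re-evaluate contacts after an iteration
#'
#' Over the evaluation window: candidates below `d_in` for strictly more
#' than `persistence_fraction` of frames become active; active contacts
#' whose windowed mean exceeds `d_out` (or, in `"any"` mode, that exceed
#' `d_out` in any frame) or whose windowed variance exceeds `d_var` are
#' removed. Removed contacts stay removed.
#'
#' @param window distance table for the evaluation window (frames x pairs).
#' @param contacts a `contact_set`.
#' @param params a [protocol_params()].
#' @param iteration iteration index recorded in the history.
#' @return The updated `contact_set`.
#' @export
update_contacts <- function(window, contacts, params = protocol_params(),
                            iteration = 1L) {
  stopifnot(all(contacts$id %in% names(window)))
  for (i in seq_len(nrow(contacts))) {
    d <- window[[contacts$id[i]]]
    st <- contacts$status[i]
    if (st == "candidate") {
      if (mean(d < params$d_in) > params$persistence_fraction) {
        contacts$status[i] <- "active"
        contacts$added_iteration[i] <- as.integer(iteration)
      }
    } else if (st == "active") {
      disp <- if (params$var_mode == "variance") stats::var(d) else stats::sd(d)
      far <- if (params$removal_mode == "mean") mean(d) > params$d_out
             else any(d > params$d_out)
      if (far || disp > params$d_var) {
        contacts$status[i] <- "removed"
        contacts$removed_iteration[i] <- as.integer(iteration)
      }
    }
  }
  contacts
}

#' Merge equivalent anchor groups into center-of-mass pseudo-sites
#'
#' Anchors related by a rotational degree of freedom (e.g. the two oxygens
#' of a carboxylate) are replaced by a single pseudo-site at their
#' unweighted center of mass; distances are then computed to the
#' representative. Groups must be disjoint; singletons leave their anchor
#' unchanged.
#'
#' @param groups named list; each element a character vector of anchor ids.
#' @param anchors anchor position matrix with rownames as ids.
#' @return Reduced anchor matrix (group representatives replace members).
#' @export
merge_equivalent <- function(groups, anchors) {
  ids <- rownames(anchors)
  stopifnot(!is.null(ids))
  members <- unlist(groups)
  if (anyDuplicated(members)) stop("overlapping groups", call. = FALSE)
  stopifnot(all(members %in% ids))
  keep <- anchors[setdiff(ids, members), , drop = FALSE]
  reps <- do.call(rbind, lapply(groups, function(g) {
    colMeans(anchors[g, , drop = FALSE])
  }))
  rownames(reps) <- names(groups)
  rbind(keep, reps)
}

#' Run the iterative unbinding protocol on a toy pocket
#'
#' Implements the full loop: an unbiased exploration detects the initial
#' contacts; each iteration then biases the sum of the active anchor
#' distances harmonically toward \eqn{D = D_0 + M d_{tar}} (linear ramp
#' over the iteration), re-evaluates contacts over the evaluation window,
#' and re-targets. The protocol terminates when no active contact remains
#' (the particle has left the pocket) or at `max_iterations`.
#'
#' @param potential a 2D (or any-dimensional) `unbind_potential`.
#' @param anchors anchor position matrix (rownames = pair ids).
#' @param x0 initial particle position.
#' @param params a [protocol_params()].
#' @param step_size,friction,kT engine settings ([simulate_langevin()]).
#' @param seed integer seed; the full iteration history is reproducible.
#' @return A list of class `unbinding_run`:
#' \describe{
#'   \item{trajectory}{`trj_ensemble` concatenated over all iterations.}
#'   \item{contacts}{final `contact_set` with add/remove history.}
#'   \item{log}{tibble, one row per iteration: `iteration`, `M`, `D0`,
#'     `D`, `added`, `removed`, `cv_end`.}
#'   \item{cv_series}{tibble `frame`, `cv` (active-sum CV over the full
#'     run, frozen membership per iteration).}
#'   \item{distances}{tibble of all anchor distances over the full run.}
#'   \item{terminated}{TRUE if the active set emptied before the guard.}
#' }
#' @export
run_unbinding <- function(potential, anchors, x0,
                          params = protocol_params(),
                          step_size = 0.005, friction = 1, kT = 0.5925,
                          seed = 1) {
  ids <- rownames(anchors)
  if (is.null(ids)) {
    ids <- paste0("a", seq_len(nrow(anchors)))
    rownames(anchors) <- ids
  }
  cvs <- lapply(seq_len(nrow(anchors)),
                function(i) cv_distance(anchors[i, ], label = ids[i]))
  names(cvs) <- ids

  explore <- simulate_langevin(potential, n_steps = params$iteration_length,
                               n_traj = 1, x0 = x0, step_size = step_size,
                               friction = friction, kT = kT, seed = seed)
  dists <- anchor_distances(explore, anchors)
  contacts <- detect_initial_contacts(dists, params)
  all_frames <- list(explore$frames)
  all_dists <- list(dists)
  cv_series <- list()
  log_rows <- list()

  x_cur <- explore$frames[1, params$iteration_length, ]
  iter <- 0L
  terminated <- !any(contacts$status == "active")
  while (!terminated && iter < params$max_iterations) {
    iter <- iter + 1L
    active <- contacts$id[contacts$status == "active"]
    M <- length(active)
    main_cv <- cv_sum(cvs[active], label = "main")
    D0 <- main_cv$value(matrix(x_cur, nrow = 1))
    D <- bias_target(D0, M, params)
    bias <- bias_harmonic(main_cv, center = D, k = params$k,
                          schedule = "ramp", from = D0)
    run <- simulate_langevin(potential, n_steps = params$iteration_length,
                             n_traj = 1, x0 = x_cur, step_size = step_size,
                             friction = friction, kT = kT, bias = bias,
                             seed = seed + iter)
    d_iter <- anchor_distances(run, anchors)
    window <- d_iter[seq.int(params$iteration_length -
                               params$evaluation_window + 1L,
                             params$iteration_length), , drop = FALSE]
    before <- contacts$status
    contacts <- update_contacts(window, contacts, params, iteration = iter)
    added <- contacts$id[before != "active" & contacts$status == "active"]
    removed <- contacts$id[before == "active" & contacts$status == "removed"]
    coords_iter <- matrix(run$frames[1, , ], ncol = potential$dimension)
    cv_vals <- main_cv$value(coords_iter)
    all_frames <- c(all_frames, list(run$frames))
    all_dists <- c(all_dists, list(d_iter))
    cv_series <- c(cv_series, list(cv_vals))
    log_rows[[iter]] <- tibble::tibble(
      iteration = iter, M = M, D0 = as.numeric(D0), D = as.numeric(D),
      added = paste(added, collapse = ","),
      removed = paste(removed, collapse = ","),
      cv_end = cv_vals[length(cv_vals)]
    )
    x_cur <- run$frames[1, params$iteration_length, ]
    terminated <- !any(contacts$status == "active")
  }

  frames <- array(NA_real_, dim = c(1, length(all_frames) *
                                      params$iteration_length,
                                    potential$dimension))
  for (i in seq_along(all_frames)) {
    idx <- (i - 1L) * params$iteration_length + seq_len(params$iteration_length)
    frames[1, idx, ] <- all_frames[[i]]
  }
  traj <- structure(
    list(frames = frames, step_size = step_size, labels = NULL,
         provenance = list(potential_kind = potential$kind,
                           protocol = "unbinding", seed = seed)),
    class = "trj_ensemble"
  )
  structure(
    list(trajectory = traj, contacts = contacts,
         log = if (length(log_rows)) dplyr::bind_rows(log_rows) else
           tibble::tibble(iteration = integer(), M = integer(),
                          D0 = numeric(), D = numeric(), added = character(),
                          removed = character(), cv_end = numeric()),
         cv_series = tibble::tibble(
           frame = seq_len(sum(lengths(cv_series))),
           cv = unlist(cv_series, use.names = FALSE)),
         distances = dplyr::bind_rows(all_dists),
         terminated = terminated),
    class = "unbinding_run"
  )
}

#' @export
print.unbinding_run <- function(x, ...) {
  cat("<unbinding_run> ", nrow(x$log), " iterations; terminated: ",
      x$terminated, "; active contacts left: ",
      sum(x$contacts$status == "active"), "\n", sep = "")
  invisible(x)
}

#' Write an unbinding iteration log and CV series
#'
#' The iteration log (added/removed ids, `D0`, `D`, `M` per iteration)
#' goes to JSON; the main-CV series to a TSV.
#'
#' @param run an `unbinding_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_unbinding <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(iterations = run$log, terminated = run$terminated,
         contacts = run$contacts),
    file.path(dir, "iterations.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA)
  utils::write.table(run$cv_series, file.path(dir, "cv_series.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
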