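#' Analytical MLTSA benchmark systems
#'
#' `benchmark_config()` describes the analytical benchmark: trajectories
#' of Langevin dynamics over `n_coordinates` independent 1D potentials ---
#' `n_dw` quartic double wells (one of them the decisive coordinate that
#' defines the IN/OUT outcome, the rest noise) and harmonic single wells
#' of two mobility classes (soft/fast and stiff/slow) with randomised
#' distance-like centers for the remaining coordinates ---
#' observed through `n_features` L1-normalised linear feature
#' combinations, `n_correlated` of which carry the decisive coordinate.
#' Every trajectory starts at the decisive crest, so outcomes are near
#' 50/50 and the early-time window is informative but not trivially
#' separable. The standard systems are the 1-DW set (180 features, 11
#' correlated) and the 5-DW set (15 correlated features).
#'
#' @param n_dw number of double-well coordinates (first is decisive).
#' @param n_coordinates latent coordinates (default 25).
#' @param n_features observable features (default 180).
#' @param n_correlated features carrying the decisive coordinate.
#' @param n_train_traj trajectories for training/test (default 180).
#' @param n_valid_traj additional unseen validation trajectories (50).
#' @param n_steps time steps per trajectory (default 500).
#' @param barrier decisive double-well barrier height (kT units).
#' @param noise_barrier barrier of the noise double wells (kT units).
#' @param well_width double-well half-separation.
#' @param soft_stiffness,soft_friction parameters of the soft noise
#'   wells: large-amplitude (\eqn{\sqrt{kT/k}}), fast-relaxing
#'   (\eqn{\tau = \gamma/k}) coordinates that give the observable
#'   features genuinely noisy views of the decisive coordinate.
#' @param stiff_stiffness,stiff_friction parameters of the stiff noise
#'   wells: small-amplitude, slowly relaxing coordinates (quasi-static
#'   over the training window, like a persisting contact geometry).
#' @param sw_center_range single-well centers are drawn uniformly from
#'   this interval (distance-like offsets, Å-scale).
#' @param alpha_range decisive mixing-coefficient range
#'   ([make_mixing()]).
#' @param step_size,friction,kT Langevin settings (dimensionless units);
#'   `friction` applies to the decisive coordinate.
#' @param noise_friction friction of the non-decisive coordinates (their
#'   relaxation time is `noise_friction / stiffness`).
#' @param window early-time training window (steps, 0-based).
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_dw = 1, n_coordinates = 25, n_features = 180,
                             n_correlated = 11, n_train_traj = 180,
                             n_valid_traj = 50, n_steps = 500,
                             barrier = 7, noise_barrier = 2,
                             well_width = 2,
                             soft_stiffness = 0.15, soft_friction = 0.02,
                             stiff_stiffness = 40, stiff_friction = 12,
                             sw_center_range = c(2, 8),
                             alpha_range = c(0.35, 0.8),
                             step_size = 0.01, friction = 1, kT = 1,
                             window = c(30, 60)) {
  stopifnot(n_dw >= 1, n_dw <= n_coordinates, n_correlated <= n_features)
  structure(as.list(environment()), class = "benchmark_config")
}

#' Standard benchmark fixtures
#'
#' The shipped toy systems: the 1-DW analytical set (25 coordinates, 180
#' features, 11 correlated), the harder 5-DW set (15 correlated
#' features), and the 2D pocket with its minimum-energy path along the x
#' axis and an analytically known barrier (computed by a dense scan of
#' the potential along the MEP).
#'
#' @param seed seed recorded in the fixtures.
#' @return Named list: `one_dw`, `five_dw` (`benchmark_config`s) and
#'   `pocket` (list with `potential`, `anchors`, `x0`, `mep_barrier`,
#'   `barrier_x`, `kT`).
#' @export
make_fixtures <- function(seed = 1) {
  pocket <- potential_pocket2d()
  xs <- seq(-1, 6, length.out = 4001)
  vx <- pot_energy(pocket, cbind(xs, 0))
  barrier_x <- xs[which.max(vx)]
  mep_barrier <- max(vx) - min(vx[xs < barrier_x])
  anchors <- rbind(p1 = c(1.5, 0),
                   p2 = c(-0.75, 1.3),
                   p3 = c(-0.75, -1.3))
  list(
    one_dw = benchmark_config(n_dw = 1, n_correlated = 11),
    five_dw = benchmark_config(n_dw = 5, n_correlated = 15),
    pocket = list(potential = pocket, anchors = anchors, x0 = c(0, 0),
                  mep_barrier = mep_barrier, barrier_x = barrier_x,
                  kT = 0.5925, seed = seed)
  )
}

#' Generate one realisation of the analytical benchmark
#'
#' Draws the latent potentials and mixing matrix, simulates the training
#' and validation trajectory ensembles from the decisive crest, labels
#' them by the decisive coordinate's final basin, and mixes them into
#' observable features.
#'
#' @param config a [benchmark_config()].
#' @param seed integer seed for the whole realisation.
#' @return A list: `features` (labelled `trj_ensemble`, training +
#'   validation trajectories stacked), `validation_ids`, `mixing`,
#'   `potential`, `labels`.
#' @export
generate_benchmark <- function(config, seed = 1) {
  set.seed(seed)
  pots <- vector("list", config$n_coordinates)
  pots[[1]] <- potential_double_well(height = config$barrier * config$kT,
                                     width = config$well_width)
  if (config$n_dw > 1) {
    for (j in seq.int(2, config$n_dw)) {
      pots[[j]] <- potential_double_well(
        height = config$noise_barrier * config$kT,
        width = config$well_width,
        center = stats::runif(1, -0.5, 0.5))
    }
  }
  sw_idx <- seq.int(config$n_dw + 1, config$n_coordinates)
  soft <- sw_idx[seq_along(sw_idx) %% 2L == 1L]   # alternate soft/stiff
  for (j in sw_idx) {
    pots[[j]] <- potential_single_well(
      center = stats::runif(1, config$sw_center_range[1],
                            config$sw_center_range[2]),
      stiffness = if (j %in% soft) config$soft_stiffness else
        config$stiff_stiffness)
  }
  pot <- potential_set(pots)
  # start: decisive coordinate at its crest; noise coordinates at their
  # equilibrium positions, so early frames carry no spurious transient
  x0 <- vapply(pots, function(p) p$parameters$center, numeric(1))
  n_total <- config$n_train_traj + config$n_valid_traj
  gamma <- rep(config$friction, config$n_coordinates)
  gamma[sw_idx] <- ifelse(sw_idx %in% soft, config$soft_friction,
                          config$stiff_friction)
  traj <- simulate_langevin(pot, n_steps = config$n_steps,
                            n_traj = n_total, x0 = x0,
                            step_size = config$step_size,
                            friction = gamma, kT = config$kT,
                            seed = seed + 1L)
  traj <- label_outcome(traj, decisive_dimension = 1,
                        crest = pots[[1]]$parameters$center)
  mixing <- make_mixing(config$n_features, config$n_coordinates,
                        config$n_correlated,
                        alpha_range = config$alpha_range,
                        decisive_column = 1,
                        correlated_noise_pool = soft,
                        seed = seed + 2L)
  features <- apply_mixing(mixing, traj)
  list(features = features,
       validation_ids = seq.int(config$n_train_traj + 1L, n_total),
       mixing = mixing, potential = pot, labels = traj$labels)
}

#' Run the full MLTSA benchmark over replicas
#'
#' For each replica: generate an independent benchmark realisation, build
#' the windowed dataset (0.7/0.3 frame split, validation trajectories
#' held out), train the MLP and the GBDT, compute the MLP global-mean
#' accuracy drops and the GBDT feature importances, and record everything
#' against the known mixing.
#'
#' @param config a [benchmark_config()].
#' @param n_replicas number of independent replicas (default 10).
#' @param seed base seed; replica `r` uses `seed + 1000 * r`.
#' @param mlp,gbdt classifier configurations.
#' @param drop_on frames used for the accuracy-drop evaluation
#'   ([global_mean_drop()]).
#' @return An `mltsa_report`: list with `accuracy` (tibble: replica,
#'   backend, train/test/validation), `drops` (tibble: replica, feature,
#'   drop, alpha, correlated), `importances` (same for GBDT FI), and
#'   `config`.
#' @export
run_mltsa_benchmark <- function(config = benchmark_config(),
                                n_replicas = 10, seed = 1,
                                mlp = mlp_config(), gbdt = gbdt_config(),
                                drop_on = "all") {
  acc <- list(); drops <- list(); imps <- list()
  for (r in seq_len(n_replicas)) {
    rs <- seed + 1000L * r
    bench <- generate_benchmark(config, seed = rs)
    ds <- mltsa_dataset(bench$features, window = config$window,
                        validation_ids = bench$validation_ids, seed = rs)
    fit_nn <- fit_mltsa(ds, mlp, seed = rs)
    fit_tr <- fit_mltsa(ds, gbdt, seed = rs)
    acc[[r]] <- dplyr::bind_rows(
      dplyr::mutate(glance(fit_nn), replica = r),
      dplyr::mutate(glance(fit_tr), replica = r))
    mix_tbl <- tidy(bench$mixing)
    drops[[r]] <- dplyr::mutate(
      dplyr::left_join(global_mean_drop(fit_nn, ds, on = drop_on),
                       mix_tbl, by = "feature"),
      replica = r)
    imps[[r]] <- dplyr::mutate(
      dplyr::left_join(gbdt_importances(fit_tr), mix_tbl, by = "feature"),
      replica = r)
  }
  structure(
    list(accuracy = dplyr::bind_rows(acc),
         drops = dplyr::bind_rows(drops),
         importances = dplyr::bind_rows(imps),
         config = config, n_replicas = n_replicas, seed = seed),
    class = "mltsa_report"
  )
}

#' @export
print.mltsa_report <- function(x, ...) {
  cat("<mltsa_report> ", x$n_replicas, " replicas\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Summaries of a benchmark report
#'
#' `glance()` gives mean accuracies per backend and set (as fractions);
#' `tidy()` returns per-feature replica-averaged drops and importances.
#'
#' @param x an `mltsa_report`.
#' @param ... unused.
#' @method glance mltsa_report
#' @export
glance.mltsa_report <- function(x, ...) {
  long <- tidyr::pivot_longer(x$accuracy, c("train", "test", "validation"),
                              names_to = "set", values_to = "accuracy")
  out <- dplyr::summarise(dplyr::group_by(long, .data$backend, .data$set),
                          accuracy = mean(.data$accuracy), .groups = "drop")
  tidyr::pivot_wider(out, names_from = "set", values_from = "accuracy")
}

#' @rdname glance.mltsa_report
#' @method tidy mltsa_report
#' @export
tidy.mltsa_report <- function(x, ...) {
  d <- dplyr::summarise(
    dplyr::group_by(x$drops, .data$feature, .data$alpha, .data$correlated),
    mean_drop = mean(.data$drop), .groups = "drop")
  i <- dplyr::summarise(dplyr::group_by(x$importances, .data$feature),
                        mean_importance = mean(.data$importance),
                        .groups = "drop")
  dplyr::left_join(d, i, by = "feature")
}

#' Literature reference values for the CDK2 systems
#'
#' Experimental dissociation kinetics of the two CDK2 inhibitor systems
#' used as real-world context for this toolkit, with the activation free
#' energies implied by the Eyring--Polanyi equation at 298 K, and the
#' all-atom simulation barriers and classifier accuracies reported in the
#' source study. The simulation-derived values require all-atom MD
#' trajectories and are **not** reproducible by this package's analytic
#' toys; they are carried only as reference points
#' (`source = "reference"`).
#'
#' @return A tibble with `system`, `ligand`, `quantity`, `value`,
#'   `units`, `source` (`"experiment"` or `"reference"`).
#' @export
cdk2_reference <- function() {
  tibble::tribble(
    ~system, ~ligand, ~quantity, ~value, ~units, ~source,
    "3sw4", "18K", "k_off", 0.0823, "s^-1", "experiment",
    "4fkw", "62K", "k_off", 0.00261, "s^-1", "experiment",
    "3sw4", "18K", "dG_exp", 18.93, "kcal/mol", "experiment",
    "4fkw", "62K", "dG_exp", 20.97, "kcal/mol", "experiment",
    "3sw4", "18K", "dG_calc", 16.29, "kcal/mol", "reference",
    "4fkw", "62K", "dG_calc", 20.27, "kcal/mol", "reference",
    "3sw4", "18K", "mlp_accuracy", 80.11, "%", "reference",
    "4fkw", "62K", "mlp_accuracy", 93.83, "%", "reference"
  )
}
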