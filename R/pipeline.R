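#' Read and validate a pipeline run configuration
#'
#' Run configurations are plain JSON with optional sections `stages`
#' (character vector, a prefix of `unbind`, `string`, `wham`, `downhill`,
#' `mltsa`), `seed`, `pocket` (toy pocket settings: anchor positions,
#' `x0`, engine constants), `protocol` (fields of [protocol_params()]),
#' `string` (`n_windows`, `steps_per_window`, `max_iterations`),
#' `benchmark` (fields of [benchmark_config()]) and `mltsa`
#' (`n_replicas`). Unknown fields are reported with their paths.
#'
#' @param path JSON file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("stages", "seed", "pocket", "protocol", "string", "benchmark",
             "mltsa", "out")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  all_stages <- c("unbind", "string", "wham", "downhill", "mltsa")
  cfg$stages <- if (is.null(cfg$stages)) all_stages else
    match.arg(cfg$stages, all_stages, several.ok = TRUE)
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

default_run_config <- function(seed = 1) {
  structure(list(stages = c("unbind", "string", "wham", "downhill", "mltsa"),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Execute the end-to-end toy pipeline
#'
#' Runs the requested stage prefix on the toy pocket fixture and the
#' analytical benchmark: `unbind` (iterative contact protocol),
#' `string` (path refinement seeded from the unbinding CV series),
#' `wham` (PMF and barrier), `downhill` (trajectories from the TS
#' candidates plus committor-based TS selection) and `mltsa`
#' (benchmark replicas with both classifiers). Writes delimited-text and
#' JSON artifacts plus a `manifest.json` recording the package version,
#' seeds and stage outputs into `out_dir`.
#'
#' @param config a `run_config` (see [read_run_config()]); `NULL` for
#'   defaults.
#' @param out_dir output directory.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("unbindkit_run")) {
  if (is.null(config)) config <- default_run_config()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  fixtures <- make_fixtures(seed)
  pocket <- fixtures$pocket
  stages <- config$stages
  results <- list()
  manifest <- list(package = "unbindkit",
                   version = as.character(utils::packageVersion("unbindkit")),
                   seed = seed, stages = stages, outputs = list())

  if ("unbind" %in% stages) {
    pp_args <- config$protocol
    pp <- if (is.null(pp_args)) {
      protocol_params(iteration_length = 3000, max_iterations = 20)
    } else {
      do.call(protocol_params, pp_args)
    }
    unb <- run_unbinding(pocket$potential, pocket$anchors, pocket$x0,
                         params = pp, kT = pocket$kT, seed = seed)
    write_unbinding(unb, file.path(out_dir, "unbind"))
    results$unbind <- unb
    manifest$outputs$unbind <- "unbind/iterations.json"
  }

  if ("string" %in% stages && !is.null(results$unbind)) {
    scfg <- config$string
    n_windows <- scfg$n_windows %||% 30
    steps_per_window <- scfg$steps_per_window %||% 600
    max_iterations <- scfg$max_iterations %||% 6
    cvs <- list(cv_coordinate(1), cv_coordinate(2))
    traj <- results$unbind$trajectory
    coords <- matrix(traj$frames[1, , ], ncol = 2)
    keep <- coords[, 1] < 6 & abs(coords[, 2]) < 4
    path0 <- seed_string(coords[keep, , drop = FALSE], n_windows = n_windows,
                         coords = coords[keep, , drop = FALSE])
    srun <- run_string(pocket$potential, cvs, path0,
                       steps_per_window = steps_per_window,
                       max_iterations = max_iterations, kT = pocket$kT,
                       seed = seed)
    utils::write.table(tidy(srun$path), file.path(out_dir, "string_nodes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$string <- srun
    manifest$outputs$string <- "string_nodes.tsv"
  }

  if ("wham" %in% stages && !is.null(results$string)) {
    pmf <- pmf_and_barrier(results$string, kT = pocket$kT)
    write_pmf(pmf, file.path(out_dir, "pmf.tsv"))
    results$pmf <- pmf
    manifest$outputs$wham <- "pmf.tsv"
  }

  if ("downhill" %in% stages && !is.null(results$pmf)) {
    cand <- pick_ts_candidates(results$pmf, n = 5)
    starts <- results$string$node_coords[cand, , drop = FALSE]
    runs <- generate_downhill(pocket$potential, starts, n_runs = 20,
                              n_steps = 400, step_size = 0.005,
                              kT = pocket$kT, seed = seed)
    frac <- vapply(runs, function(r) {
      lab <- label_outcome(r, decisive_dimension = 1,
                           crest = pocket$barrier_x)$labels
      mean(lab == "IN")
    }, numeric(1))
    cand_tbl <- tibble::tibble(window = cand, in_fraction = frac,
                               pmf = results$pmf$profile$dG[cand])
    chosen <- select_ts(cand_tbl)
    utils::write.table(cand_tbl, file.path(out_dir, "ts_candidates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$downhill <- list(candidates = cand_tbl, chosen = chosen,
                             runs = runs)
    manifest$outputs$downhill <- "ts_candidates.tsv"
  }

  if ("mltsa" %in% stages) {
    bcfg_args <- config$benchmark
    bcfg <- if (is.null(bcfg_args)) benchmark_config() else
      do.call(benchmark_config, bcfg_args)
    n_replicas <- config$mltsa$n_replicas %||% 3
    report <- run_mltsa_benchmark(bcfg, n_replicas = n_replicas, seed = seed)
    utils::write.table(report$accuracy,
                       file.path(out_dir, "mltsa_accuracy.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(tidy(report), file.path(out_dir, "mltsa_features.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    results$mltsa <- report
    manifest$outputs$mltsa <- c("mltsa_accuracy.tsv", "mltsa_features.tsv")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
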