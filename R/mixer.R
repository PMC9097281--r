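#' Linear mixing of latent coordinates into observable features
#'
#' The analytical MLTSA benchmark observes the latent 1D coordinates only
#' through linear combinations, emulating how real collective variables mix
#' many degrees of freedom. `make_mixing()` draws a mixing matrix in which
#' exactly `n_correlated` features carry the decisive double-well
#' coordinate with a mixing coefficient alpha drawn from `alpha_range`
#' (reported as a percentage of the feature's total weight); every row is
#' L1-normalised so its coefficients sum to 1 (100%). All other rows mix
#' only noise coordinates and carry a zero decisive coefficient.
#'
#' @param n_features number of observable features (rows).
#' @param n_coordinates number of latent coordinates (columns).
#' @param n_correlated how many features carry the decisive coordinate.
#' @param alpha_range interval (fractions of L1 weight, e.g. `c(0.2, 1)`)
#'   from which decisive coefficients are drawn.
#' @param alpha_mode `"tiered"` (default) gives three features evenly
#'   spaced alphas in the top fifth of `alpha_range` and spreads the rest
#'   evenly over the lower three fifths (assigned to features in random
#'   order) --- a top trio of strongly correlated features over a tail of
#'   weak ones; `"ladder"` spaces all alphas evenly over `alpha_range`;
#'   `"uniform"` draws them independently.
#' @param decisive_column index of the decisive latent coordinate.
#' @param n_mix how many noise coordinates each row mixes.
#' @param correlated_noise_pool optional subset of noise-coordinate
#'   indices from which the correlated rows draw their noise share (so
#'   that the correlated features' noise has a homogeneous scale and
#'   their signal-to-noise ratio is ordered by alpha); uncorrelated rows
#'   always draw from all noise coordinates.
#' @param noise_weights `"equal"` (default) gives each chosen noise
#'   coordinate the same share of the remaining L1 weight, so a feature's
#'   noise amplitude decreases monotonically with its alpha;
#'   `"random"` draws the shares uniformly before normalisation.
#' @param seed integer seed for the draw.
#' @return A `mixing_matrix`: list with `coefficients`
#'   (`n_features x n_coordinates`), `decisive_column`, `correlated`
#'   (logical per feature), `alpha` (decisive fraction per feature), `seed`.
#' @examples
#' mx <- make_mixing(180, 25, 11, seed = 1)
#' sum(mx$correlated)
#' @export
make_mixing <- function(n_features, n_coordinates, n_correlated,
                        alpha_range = c(0.2, 1), decisive_column = 1,
                        n_mix = 3, noise_weights = c("equal", "random"),
                        alpha_mode = c("tiered", "ladder", "uniform"),
                        correlated_noise_pool = NULL,
                        seed = NULL) {
  noise_weights <- match.arg(noise_weights)
  alpha_mode <- match.arg(alpha_mode)
  stopifnot(n_correlated <= n_features, n_correlated >= 0,
            decisive_column >= 1, decisive_column <= n_coordinates,
            length(alpha_range) == 2, diff(alpha_range) >= 0,
            alpha_range[1] > 0 || n_correlated == 0,
            alpha_range[2] <= 1)
  if (!is.null(seed)) set.seed(seed)
  noise_cols <- setdiff(seq_len(n_coordinates), decisive_column)
  stopifnot(length(noise_cols) >= 1, n_mix <= length(noise_cols))
  if (!is.null(correlated_noise_pool)) {
    stopifnot(all(correlated_noise_pool %in% noise_cols),
              length(correlated_noise_pool) >= n_mix)
  }
  coef <- matrix(0, n_features, n_coordinates)
  correlated_rows <- if (n_correlated > 0) {
    sort(sample(seq_len(n_features), n_correlated))
  } else integer()
  alpha <- numeric(n_features)
  ladder <- if (n_correlated == 0) numeric() else if (alpha_mode == "tiered") {
    lo <- alpha_range[1]; hi <- alpha_range[2]
    n_top <- min(3L, n_correlated)
    top <- seq(hi - 0.2 * (hi - lo), hi, length.out = max(n_top, 2))[seq_len(n_top)]
    low <- if (n_correlated > n_top) {
      seq(lo, lo + 0.6 * (hi - lo), length.out = n_correlated - n_top)
    } else numeric()
    sample(c(top, low))
  } else {
    sample(seq(alpha_range[1], alpha_range[2],
               length.out = max(n_correlated, 2))[seq_len(n_correlated)])
  }
  k_cor <- 0L
  for (i in seq_len(n_features)) {
    is_cor <- i %in% correlated_rows
    a <- if (!is_cor) 0 else if (alpha_mode != "uniform") {
      k_cor <- k_cor + 1L
      ladder[k_cor]
    } else {
      stats::runif(1, alpha_range[1], alpha_range[2])
    }
    # noise part: uniform draws on randomly chosen columns, scaled to 1 - a
    cols <- if (is_cor && !is.null(correlated_noise_pool)) {
      sample(correlated_noise_pool, n_mix)
    } else {
      sample(noise_cols, n_mix)
    }
    w <- if (noise_weights == "equal") rep(1, n_mix) else stats::runif(n_mix)
    if (a < 1) {
      coef[i, cols] <- (1 - a) * w / sum(w)
    }
    if (is_cor) coef[i, decisive_column] <- a
    alpha[i] <- a
  }
  structure(
    list(coefficients = coef, decisive_column = as.integer(decisive_column),
         correlated = seq_len(n_features) %in% correlated_rows,
         alpha = alpha, seed = seed),
    class = "mixing_matrix"
  )
}

#' @export
print.mixing_matrix <- function(x, ...) {
  cat("<mixing_matrix> ", nrow(x$coefficients), " features x ",
      ncol(x$coefficients), " coordinates; ", sum(x$correlated),
      " correlated with column ", x$decisive_column, "\n", sep = "")
  invisible(x)
}

#' Per-feature mixing summary
#'
#' @param x a `mixing_matrix`.
#' @param ... unused.
#' @return A tibble with `feature`, `alpha` (decisive L1 fraction),
#'   `correlated`.
#' @method tidy mixing_matrix
#' @export
tidy.mixing_matrix <- function(x, ...) {
  tibble::tibble(feature = seq_len(nrow(x$coefficients)),
                 alpha = x$alpha, correlated = x$correlated)
}

#' Project a latent-coordinate ensemble onto observable features
#'
#' Applies `features = frames %*% t(coefficients)` frame by frame; linear
#' and deterministic.
#'
#' @param mix a `mixing_matrix`.
#' @param traj a `trj_ensemble` whose dimension equals the mixing matrix's
#'   number of latent coordinates.
#' @return A `trj_ensemble` of features (`n_traj x n_steps x n_features`),
#'   inheriting labels and provenance.
#' @export
apply_mixing <- function(mix, traj) {
  d <- dim(traj$frames)
  nc <- ncol(mix$coefficients)
  if (d[3] != nc) {
    stop("ensemble dimension (", d[3], ") does not match mixing matrix (",
         nc, " coordinates)", call. = FALSE)
  }
  flat <- matrix(aperm(traj$frames, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  feat <- flat %*% t(mix$coefficients)
  frames <- aperm(array(feat, dim = c(d[2], d[1], nrow(mix$coefficients))),
                  c(2, 1, 3))
  structure(
    list(frames = frames, step_size = traj$step_size, labels = traj$labels,
         provenance = c(traj$provenance, list(mixed = TRUE))),
    class = "trj_ensemble"
  )
}

#' Round-trip a mixing matrix through delimited text
#'
#' Coefficients as a TSV (features in rows) plus a JSON sidecar holding
#' the decisive column, correlated flags, alphas and seed.
#'
#' @param mix a `mixing_matrix`.
#' @param path basename; writes `<path>.tsv` and `<path>.json`.
#' @return `write_mixing()` the basename invisibly; `read_mixing()` a
#'   `mixing_matrix`.
#' @export
write_mixing <- function(mix, path) {
  m <- mix$coefficients
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  utils::write.table(m, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(decisive_column = mix$decisive_column,
         correlated = mix$correlated, alpha = mix$alpha, seed = mix$seed),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_mixing
#' @export
read_mixing <- function(path) {
  coef <- as.matrix(utils::read.delim(paste0(path, ".tsv")))
  dimnames(coef) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(coefficients = coef,
         decisive_column = as.integer(meta$decisive_column),
         correlated = meta$correlated, alpha = meta$alpha,
         seed = meta$seed),
    class = "mixing_matrix"
  )
}
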