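#' Analytic model potentials
#'
#' Constructors for the analytic potentials the simulation engine runs on:
#' 1D harmonic single wells, 1D quartic double wells, a 2D binding-pocket
#' surface, products of independent 1D potentials, and composites with an
#' additive bias. Energies are in the same units as `kT` passed to
#' [simulate()] (dimensionless "thermal" units by default; kcal/mol for the
#' pocket toys).
#'
#' @details
#' * `potential_single_well(center, stiffness)`:
#'   \eqn{V(x) = (\kappa/2)(x-c)^2}.
#' * `potential_double_well(height, width, center)`: quartic
#'   \eqn{V(x) = h\,((\,(x-c)/w)^2 - 1)^2} with minima at \eqn{c \pm w} and a
#'   barrier of height `h` at the crest \eqn{x = c}, which is also the basin
#'   boundary.
#' * `potential_pocket2d()`: a bounded "bound" basin (attractive Gaussian
#'   well at the origin) separated by a Gaussian barrier ridge at
#'   `barrier_pos` along x from an unbound region that is unbounded in +x;
#'   a transverse harmonic term `ky/2 * y^2` keeps the minimum-energy path
#'   on the x axis, so the MEP and barrier are known.
#'
#' @param center well center (single well / double well crest position).
#' @param stiffness harmonic force constant.
#' @param height double-well barrier height (energy units).
#' @param width half-distance between the two minima.
#' @param depth,sigma depth and width of the pocket's bound well.
#' @param barrier_height,barrier_pos,barrier_width Gaussian barrier ridge
#'   parameters along x.
#' @param ky transverse harmonic stiffness.
#' @return An object of class `unbind_potential` with `energy(x)` and
#'   `gradient(x)` operating on an `n x dimension` matrix.
#' @examples
#' dw <- potential_double_well(height = 8)
#' pot_energy(dw, matrix(c(-1, 0, 1), ncol = 1))
#' @name potentials
NULL

new_potential <- function(kind, dimension, energy, gradient, parameters,
                          basin_boundaries = numeric(), minima = NULL) {
  structure(
    list(kind = kind, dimension = dimension, energy = energy,
         gradient = gradient, parameters = parameters,
         basin_boundaries = basin_boundaries, minima = minima),
    class = "unbind_potential"
  )
}

#' @rdname potentials
#' @export
potential_single_well <- function(center = 0, stiffness = 1) {
  force(center); force(stiffness)
  new_potential(
    kind = "single_well", dimension = 1L,
    energy = function(x) 0.5 * stiffness * (x[, 1] - center)^2,
    gradient = function(x) cbind(stiffness * (x[, 1] - center)),
    parameters = list(center = center, stiffness = stiffness),
    minima = matrix(center, ncol = 1)
  )
}

#' @rdname potentials
#' @export
potential_double_well <- function(height = 8, width = 1, center = 0) {
  force(height); force(width); force(center)
  new_potential(
    kind = "double_well", dimension = 1L,
    energy = function(x) {
      u <- ((x[, 1] - center) / width)^2 - 1
      height * u^2
    },
    gradient = function(x) {
      s <- (x[, 1] - center) / width
      cbind(4 * height * s * (s^2 - 1) / width)
    },
    parameters = list(height = height, width = width, center = center),
    basin_boundaries = center,
    minima = matrix(c(center - width, center + width), ncol = 1)
  )
}

#' @rdname potentials
#' @export
potential_pocket2d <- function(depth = 6, sigma = 1.2,
                               barrier_height = 3, barrier_pos = 2.8,
                               barrier_width = 0.8, ky = 3) {
  force(depth); force(sigma); force(barrier_height)
  force(barrier_pos); force(barrier_width); force(ky)
  new_potential(
    kind = "pocket2d", dimension = 2L,
    energy = function(x) {
      r2 <- x[, 1]^2 + x[, 2]^2
      -depth * exp(-r2 / (2 * sigma^2)) +
        barrier_height * exp(-(x[, 1] - barrier_pos)^2 / (2 * barrier_width^2)) *
          exp(-x[, 2]^2 / (2 * sigma^2)) +
        0.5 * ky * x[, 2]^2
    },
    gradient = function(x) {
      r2 <- x[, 1]^2 + x[, 2]^2
      well <- -depth * exp(-r2 / (2 * sigma^2))
      gw_x <- -well * x[, 1] / sigma^2
      gw_y <- -well * x[, 2] / sigma^2
      bar <- barrier_height *
        exp(-(x[, 1] - barrier_pos)^2 / (2 * barrier_width^2)) *
        exp(-x[, 2]^2 / (2 * sigma^2))
      gb_x <- -bar * (x[, 1] - barrier_pos) / barrier_width^2
      gb_y <- -bar * x[, 2] / sigma^2
      cbind(gw_x + gb_x, gw_y + gb_y + ky * x[, 2])
    },
    parameters = list(depth = depth, sigma = sigma,
                      barrier_height = barrier_height,
                      barrier_pos = barrier_pos,
                      barrier_width = barrier_width, ky = ky),
    basin_boundaries = barrier_pos,
    minima = matrix(c(0, 0), ncol = 2)
  )
}

#' Product of independent one-dimensional potentials
#'
#' Stacks a list of 1D potentials into a single multi-dimensional potential
#' whose coordinates evolve independently; this is how the analytical MLTSA
#' benchmark's 25 latent coordinates are simulated in one ensemble.
#'
#' @param potentials list of one-dimensional `unbind_potential` objects.
#' @return An `unbind_potential` of dimension `length(potentials)`.
#' @export
potential_set <- function(potentials) {
  stopifnot(length(potentials) >= 1,
            all(vapply(potentials, function(p) p$dimension, 1L) == 1L))
  d <- length(potentials)
  new_potential(
    kind = "product", dimension = as.integer(d),
    energy = function(x) {
      e <- 0
      for (j in seq_len(d)) e <- e + potentials[[j]]$energy(x[, j, drop = FALSE])
      e
    },
    gradient = function(x) {
      g <- matrix(0, nrow(x), d)
      for (j in seq_len(d)) g[, j] <- potentials[[j]]$gradient(x[, j, drop = FALSE])
      g
    },
    parameters = list(components = potentials)
  )
}

#' Potential plus a frozen bias term
#'
#' Wraps a potential and a [bias_harmonic()] term (evaluated at a fixed
#' schedule fraction) into a plain potential, so that biased dynamics can be
#' cross-checked against unbiased dynamics on the composite surface.
#'
#' @param potential an `unbind_potential`.
#' @param bias a bias term from [bias_harmonic()].
#' @param at schedule fraction in \[0, 1\] at which the (possibly ramped)
#'   bias center is frozen.
#' @return An `unbind_potential` of the same dimension.
#' @export
potential_with_bias <- function(potential, bias, at = 1) {
  force(potential); force(bias); force(at)
  new_potential(
    kind = paste0(potential$kind, "+bias"), dimension = potential$dimension,
    energy = function(x) potential$energy(x) + bias_energy(bias, x, at),
    gradient = function(x) potential$gradient(x) + bias_gradient(bias, x, at),
    parameters = list(base = potential, bias = bias, at = at),
    basin_boundaries = potential$basin_boundaries,
    minima = potential$minima
  )
}

#' Evaluate potential energy / gradient
#'
#' @param potential an `unbind_potential`.
#' @param x numeric matrix (`n x dimension`) or vector of coordinates.
#' @return `pot_energy()` a numeric vector of length `n`; `pot_gradient()`
#'   an `n x dimension` matrix.
#' @export
pot_energy <- function(potential, x) {
  potential$energy(as_coord_matrix(x, potential$dimension))
}

#' @rdname pot_energy
#' @export
pot_gradient <- function(potential, x) {
  potential$gradient(as_coord_matrix(x, potential$dimension))
}

as_coord_matrix <- function(x, dimension) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == dimension)
    x
  } else {
    matrix(x, ncol = dimension,
           byrow = dimension > 1L && length(x) > dimension)
  }
}

#' @export
print.unbind_potential <- function(x, ...) {
  cat("<unbind_potential> kind:", x$kind, " dimension:", x$dimension, "\n")
  invisible(x)
}
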