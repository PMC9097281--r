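#' Collective-variable definitions
#'
#' A collective variable (CV) is a scalar function of the particle
#' coordinates with an analytic gradient; biases and string restraints act
#' on CVs. Two families cover the toolkit's needs:
#'
#' * `cv_coordinate(dim)` — the raw coordinate along dimension `dim`.
#' * `cv_distance(anchor)` — Euclidean distance from the particle to a
#'   fixed anchor point (the toy analog of a protein--ligand atom-pair
#'   distance, in Å).
#' * `cv_sum(cvs)` — sum of a list of CVs (the unbinding protocol's main
#'   CV, the sum of the active contact distances).
#'
#' @param dim integer coordinate index.
#' @param anchor numeric vector, the fixed anchor position.
#' @param cvs list of CV objects.
#' @param label optional identifier.
#' @return An object of class `unbind_cv` with `value(x)` and
#'   `gradient(x)` methods over an `n x dimension` coordinate matrix.
#' @name collective_variables
NULL

new_cv <- function(value, gradient, label) {
  structure(list(value = value, gradient = gradient, label = label),
            class = "unbind_cv")
}

#' @rdname collective_variables
#' @export
cv_coordinate <- function(dim, label = paste0("x", dim)) {
  force(dim)
  new_cv(
    value = function(x) x[, dim],
    gradient = function(x) {
      g <- matrix(0, nrow(x), ncol(x))
      g[, dim] <- 1
      g
    },
    label = label
  )
}

#' @rdname collective_variables
#' @export
cv_distance <- function(anchor, label = NULL) {
  anchor <- as.numeric(anchor)
  if (is.null(label)) {
    label <- paste0("d(", paste(signif(anchor, 4), collapse = ","), ")")
  }
  new_cv(
    value = function(x) {
      sqrt(rowSums((x - matrix(anchor, nrow(x), length(anchor),
                               byrow = TRUE))^2))
    },
    gradient = function(x) {
      diff <- x - matrix(anchor, nrow(x), length(anchor), byrow = TRUE)
      r <- sqrt(rowSums(diff^2))
      diff / pmax(r, 1e-12)
    },
    label = label
  )
}

#' @rdname collective_variables
#' @export
cv_sum <- function(cvs, label = "sum") {
  stopifnot(length(cvs) >= 1)
  new_cv(
    value = function(x) {
      v <- 0
      for (cv in cvs) v <- v + cv$value(x)
      v
    },
    gradient = function(x) {
      g <- 0
      for (cv in cvs) g <- g + cv$gradient(x)
      g
    },
    label = label
  )
}

#' @rdname collective_variables
#' @param cv an `unbind_cv`.
#' @param x coordinate matrix.
#' @export
cv_value <- function(cv, x) cv$value(x)

#' Harmonic bias on a collective variable
#'
#' Harmonic restraint \eqn{U(x) = (k/2)\,(CV(x) - D_t)^2} used both as the
#' unbinding protocol's moving bias and as the string windows' position
#' restraints. With `schedule = "ramp"` the center moves linearly from
#' `from` (\eqn{D_0}) to `center` (\eqn{D}) as the schedule fraction goes 0
#' to 1, reaching the target progressively over an iteration; with
#' `schedule = "fixed"` the center is constant. A zero force constant
#' recovers unbiased dynamics.
#'
#' @param cv an `unbind_cv` (or list of CVs, each restrained to the
#'   corresponding element of `center`).
#' @param center target CV value(s) \eqn{D} (Å).
#' @param k force constant (kcal mol\eqn{^{-1}} Å\eqn{^{-2}}); default 20.
#' @param schedule `"fixed"` or `"ramp"`.
#' @param from starting center(s) \eqn{D_0} for the ramp.
#' @return An object of class `unbind_bias`.
#' @export
bias_harmonic <- function(cv, center, k = 20, schedule = c("fixed", "ramp"),
                          from = NULL) {
  schedule <- match.arg(schedule)
  stopifnot(k >= 0)
  cvs <- if (inherits(cv, "unbind_cv")) list(cv) else cv
  stopifnot(length(center) == length(cvs))
  if (schedule == "ramp") {
    stopifnot(!is.null(from), length(from) == length(center))
  } else {
    from <- center
  }
  structure(list(cvs = cvs, center = as.numeric(center), k = k,
                 schedule = schedule, from = as.numeric(from)),
            class = "unbind_bias")
}

bias_center_at <- function(bias, frac) {
  bias$from + frac * (bias$center - bias$from)
}

#' Bias energy and gradient
#'
#' @param bias an `unbind_bias`.
#' @param x coordinate matrix.
#' @param frac schedule fraction in \[0, 1\].
#' @return energy vector / gradient matrix.
#' @export
bias_energy <- function(bias, x, frac = 1) {
  ctr <- bias_center_at(bias, frac)
  e <- 0
  for (i in seq_along(bias$cvs)) {
    e <- e + 0.5 * bias$k * (bias$cvs[[i]]$value(x) - ctr[i])^2
  }
  e
}

#' @rdname bias_energy
#' @export
bias_gradient <- function(bias, x, frac = 1) {
  ctr <- bias_center_at(bias, frac)
  g <- 0
  for (i in seq_along(bias$cvs)) {
    dv <- bias$cvs[[i]]$value(x) - ctr[i]
    g <- g + bias$k * dv * bias$cvs[[i]]$gradient(x)
  }
  g
}
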