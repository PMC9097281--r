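#' Binless WHAM: unbias restrained ensembles
#'
#' Solves the self-consistent binless WHAM (multistate reweighting)
#' equations for the window free energies \eqn{f_i},
#' \deqn{e^{-f_i/k_BT} = \sum_n \frac{e^{-u_i(x_n)/k_BT}}
#'   {\sum_j N_j\, e^{(f_j - u_j(x_n))/k_BT}},}
#' where \eqn{u_i(x_n)} is the bias energy of sample \eqn{n} evaluated
#' under window \eqn{i}'s restraint. The fixed point yields per-sample
#' unbiased weights \eqn{w_n \propto 1/\sum_j N_j e^{(f_j-u_j(x_n))/k_BT}}
#' (normalised to sum 1). The gauge is fixed at \eqn{f_1 = 0}. All
#' arithmetic is done in log space.
#'
#' @param bias_energies matrix (`n_samples x n_windows`): bias energy of
#'   every pooled sample under every window's restraint, in energy units.
#' @param n_per_window integer vector: samples contributed by each window
#'   (samples must be pooled window by window, in order).
#' @param kT thermal energy (same units as the bias energies).
#' @param tol convergence tolerance on max |change in f| between
#'   self-consistent sweeps (energy units).
#' @param max_iter self-consistent iteration cap.
#' @param method `"mle"` (default) first maximises the convex WHAM
#'   log-likelihood directly (L-BFGS-B), then polishes with
#'   self-consistent sweeps until `tol`; `"self-consistent"` iterates the
#'   fixed-point equations from zero.
#' @return A list of class `wham_fit`: `f` (window free energies, energy
#'   units, `f[1] = 0`), `weights` (per-sample, sum 1), `converged`,
#'   `n_iter`, `overlap` (window-overlap matrix: shared effective samples
#'   between the biased ensembles).
#' @export
binless_wham <- function(bias_energies, n_per_window, kT = 1,
                         tol = 1e-7, max_iter = 20000,
                         method = c("mle", "self-consistent")) {
  method <- match.arg(method)
  u <- as.matrix(bias_energies)
  N <- as.integer(n_per_window)
  stopifnot(sum(N) == nrow(u), ncol(u) == length(N), all(N > 0), kT > 0)
  W <- ncol(u)
  b <- u / kT                        # reduced bias energies
  logN <- log(N)
  rowlse <- function(m) {
    mx <- apply(m, 1, max)
    mx + log(rowSums(exp(m - mx)))
  }
  log_denom <- function(g) rowlse(sweep(-b, 2, logN + g, "+"))
  sc_sweep <- function(g) {
    ld <- log_denom(g)
    g_new <- vapply(seq_len(W), function(i) {
      v <- -b[, i] - ld
      mx <- max(v)
      -(mx + log(sum(exp(v - mx))))
    }, numeric(1))
    g_new - g_new[1]
  }
  g <- numeric(W)
  if (method == "mle" && W > 1) {
    # convex negative log-likelihood in the reduced free energies g[-1]
    nll <- function(g_free) {
      g_all <- c(0, g_free)
      sum(log_denom(g_all)) - sum(N * g_all)
    }
    grad <- function(g_free) {
      g_all <- c(0, g_free)
      ld <- log_denom(g_all)
      expected <- vapply(seq_len(W), function(j) {
        sum(exp(logN[j] + g_all[j] - b[, j] - ld))
      }, numeric(1))
      (expected - N)[-1]
    }
    opt <- stats::optim(numeric(W - 1), nll, grad, method = "L-BFGS-B",
                        control = list(maxit = 500, factr = 10))
    g <- c(0, opt$par)
  }
  delta <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g_new <- sc_sweep(g)
    delta <- max(abs(g_new - g)) * kT
    g <- g_new
    if (delta < tol) break
  }
  converged <- delta < tol
  ld <- log_denom(g)
  w <- exp(-ld)
  w <- w / sum(w)
  # overlap diagnostics: window i's biased weight of each pooled sample
  q <- exp(sweep(-b, 2, g, "+") - ld)            # exp(g_i - b_ni - ld_n)
  q <- sweep(q, 2, colSums(q), "/")
  overlap <- crossprod(q)
  overlap <- overlap / sqrt(outer(diag(overlap), diag(overlap)))
  if (!converged) {
    warning("binless WHAM did not converge (max |df| = ",
            signif(delta, 3), "); check window overlap diagnostics",
            call. = FALSE)
  }
  structure(list(f = g * kT, weights = w, converged = converged,
                 n_iter = it, overlap = overlap),
            class = "wham_fit")
}

#' @export
print.wham_fit <- function(x, ...) {
  cat("<wham_fit> ", length(x$f), " windows; converged: ", x$converged,
      " (", x$n_iter, " iterations)\n", sep = "")
  invisible(x)
}

#' @param x a `wham_fit`.
#' @param ... unused.
#' @return A tibble `window`, `f`.
#' @rdname binless_wham
#' @method tidy wham_fit
#' @export
tidy.wham_fit <- function(x, ...) {
  tibble::tibble(window = seq_along(x$f), f = x$f)
}

# Pool string-run window ensembles into WHAM inputs: bias energies of every
# sample under every window's restraint, computed in CV space.
pool_string_samples <- function(samples, nodes, force_constant) {
  X <- do.call(rbind, samples)
  N <- vapply(samples, nrow, integer(1))
  W <- nrow(nodes)
  u <- matrix(0, nrow(X), W)
  for (i in seq_len(W)) {
    u[, i] <- 0.5 * force_constant *
      rowSums(sweep(X, 2, nodes[i, ])^2)
  }
  list(cv = X, u = u, n_per_window = N)
}

#' Potential of mean force along the string from WHAM weights
#'
#' Pools the per-window CV samples of a [run_string()] result, unbiases
#' them with [binless_wham()], assigns every sample to its nearest string
#' node (arc-length coordinate), and reports the free-energy profile
#' \eqn{-k_BT \ln \sum_{n \in \mathrm{window}} w_n} along the normalised
#' string coordinate, zeroed at the bound-basin minimum (the minimum on
#' the bound side of the barrier top). The barrier is the profile maximum.
#' Standard errors come from splitting each window's samples into
#' `subgroups` contiguous subgroups and recomputing the profile per
#' subgroup (SE = sd / sqrt(subgroups)).
#'
#' @param string_run a `string_run` (or a list with `ensembles` and
#'   `sampling_path`).
#' @param kT thermal energy (energy units of the restraints).
#' @param subgroups number of contiguous data subdivisions for the error
#'   estimate (default 4).
#' @param tol,max_iter passed to [binless_wham()].
#' @return A `pmf_profile`: tibble-backed list with `profile` (tibble
#'   `window`, `arc`, `dG`, `se`), `barrier`, `ts_window`, `wham`.
#' @export
pmf_and_barrier <- function(string_run, kT = 0.5925, subgroups = 4,
                            tol = 1e-7, max_iter = 50000) {
  samples <- string_run$ensembles
  path <- string_run$sampling_path
  stopifnot(!is.null(samples), !is.null(path))
  pooled <- pool_string_samples(samples, path$nodes, path$force_constant)
  fit <- binless_wham(pooled$u, pooled$n_per_window, kT = kT,
                      tol = tol, max_iter = max_iter)
  # arc assignment: nearest string node in CV space
  d2 <- vapply(seq_len(nrow(path$nodes)), function(i) {
    rowSums(sweep(pooled$cv, 2, path$nodes[i, ])^2)
  }, numeric(nrow(pooled$cv)))
  assign_win <- max.col(-d2, ties.method = "first")
  W <- nrow(path$nodes)
  prof <- profile_from_weights(fit$weights, assign_win, W, kT)
  # subgroup error: contiguous 4-way split of each window's samples
  sub_profiles <- matrix(NA_real_, W, subgroups)
  grp_of <- unlist(lapply(pooled$n_per_window, function(n) {
    ceiling(seq_len(n) * subgroups / n)
  }))
  for (s in seq_len(subgroups)) {
    sel <- grp_of == s
    n_sub <- vapply(split(sel, rep(seq_len(W), pooled$n_per_window)),
                    sum, integer(1))
    if (any(n_sub == 0)) next
    fit_s <- binless_wham(pooled$u[sel, , drop = FALSE], n_sub, kT = kT,
                          tol = tol, max_iter = max_iter)
    sub_profiles[, s] <- profile_from_weights(fit_s$weights,
                                              assign_win[sel], W, kT)
  }
  se <- apply(sub_profiles, 1, stats::sd) / sqrt(subgroups)
  ts_window <- which.max(prof)
  profile <- tibble::tibble(window = seq_len(W),
                            arc = path$arc_parameter,
                            dG = prof, se = se)
  structure(list(profile = profile, barrier = max(prof),
                 ts_window = ts_window, wham = fit, kT = kT),
            class = "pmf_profile")
}

# -kT log weighted occupancy per window, zeroed at the bound-side minimum
profile_from_weights <- function(weights, assign_win, n_windows, kT) {
  occ <- vapply(seq_len(n_windows), function(i) sum(weights[assign_win == i]),
                numeric(1))
  occ <- pmax(occ, .Machine$double.xmin)
  dg <- -kT * log(occ)
  top <- which.max(dg)
  dg - min(dg[seq_len(top)])
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat("<pmf_profile> ", nrow(x$profile), " windows; barrier ",
      signif(x$barrier, 4), " (TS window ", x$ts_window, ")\n", sep = "")
  invisible(x)
}

#' @param x a `pmf_profile`.
#' @param ... unused.
#' @return `tidy()`: the profile tibble; `glance()`: one row with
#'   `barrier`, `ts_window`, `converged`.
#' @rdname pmf_and_barrier
#' @method tidy pmf_profile
#' @export
tidy.pmf_profile <- function(x, ...) x$profile

#' @rdname pmf_and_barrier
#' @method glance pmf_profile
#' @export
glance.pmf_profile <- function(x, ...) {
  tibble::tibble(barrier = x$barrier, ts_window = x$ts_window,
                 converged = x$wham$converged)
}

#' Transition-state candidate windows
#'
#' Returns the `n` highest-free-energy windows as a contiguous block
#' around the profile's global maximum: among all length-`n` contiguous
#' blocks containing the maximum, the one with the largest total free
#' energy, ties resolved toward the bound state (lower window index).
#'
#' @param profile a `pmf_profile` (or tibble with `window` and `dG`).
#' @param n number of candidate windows (default 5).
#' @return Integer vector of window indices.
#' @export
pick_ts_candidates <- function(profile, n = 5) {
  tb <- if (inherits(profile, "pmf_profile")) profile$profile else profile
  dg <- tb$dG
  W <- length(dg)
  if (n > W) stop("n exceeds the number of windows", call. = FALSE)
  peak <- which.max(dg)
  starts <- seq.int(max(1L, peak - n + 1L), min(peak, W - n + 1L))
  totals <- vapply(starts, function(s) sum(dg[s:(s + n - 1L)]), numeric(1))
  best <- starts[which.max(totals)]   # which.max: first (bound-side) tie
  seq.int(best, best + n - 1L)
}

#' Write a PMF profile as delimited text
#'
#' @param profile a `pmf_profile`.
#' @param path output TSV path (`arc`, `dG`, `se` columns).
#' @return `path`, invisibly.
#' @export
write_pmf <- function(profile, path) {
  utils::write.table(profile$profile, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
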