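# CODATA 2018 constants
.kB_J <- 1.380649e-23          # Boltzmann, J/K
.h_J <- 6.62607015e-34         # Planck, J s
.R_kcal <- 1.987204258640832e-3  # gas constant, kcal mol^-1 K^-1

#' Eyring--Polanyi conversion between rates and activation free energies
#'
#' The transition-state-theory relation
#' \deqn{k = \frac{k_B T}{h}\, e^{-\Delta G^\ddagger / k_B T}}
#' (transmission coefficient 1) links a dissociation rate constant
#' \eqn{k_{off}} to the unbinding activation free energy. With the
#' experimental CDK2 inhibitor rates, `barrier_from_rate(0.0823)` gives
#' 18.93 kcal/mol and `barrier_from_rate(0.00261)` gives 20.97 kcal/mol
#' at 298 K.
#'
#' @param k rate constant(s), s^-1.
#' @param temperature absolute temperature, K (default 298).
#' @return `barrier_from_rate()`: activation free energy in kcal/mol;
#'   `rate_from_barrier()`: rate constant in s^-1. Both vectorised,
#'   strictly decreasing in their first argument, and exact inverses.
#' @examples
#' barrier_from_rate(0.0823, 298)
#' rate_from_barrier(18.93, 298)
#' @export
barrier_from_rate <- function(k, temperature = 298) {
  stopifnot(all(k > 0), all(temperature > 0))
  prefactor <- .kB_J * temperature / .h_J
  .R_kcal * temperature * log(prefactor / k)
}

#' @rdname barrier_from_rate
#' @param barrier activation free energy, kcal/mol.
#' @export
rate_from_barrier <- function(barrier, temperature = 298) {
  stopifnot(all(temperature > 0))
  prefactor <- .kB_J * temperature / .h_J
  prefactor * exp(-barrier / (.R_kcal * temperature))
}
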