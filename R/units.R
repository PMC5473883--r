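# Speed of light in cm/ps; 1 cm^-1 of energy corresponds to an angular
# frequency of 2*pi*c ps^-1 once hbar is set to 1.
.c_cm_per_ps <- 2.99792458e-2

#' Convert wavenumbers to angular frequency
#'
#' Site energies, couplings and rates for molecular excitation-transfer
#' models are conventionally quoted in wavenumbers (cm\eqn{^{-1}}).  With
#' \eqn{\hbar = 1} and time measured in picoseconds, an energy of
#' 1 cm\eqn{^{-1}} corresponds to an angular frequency
#' \eqn{2\pi c \approx 0.18837} ps\eqn{^{-1}}.
#'
#' @param x numeric; value(s) in cm\eqn{^{-1}}.
#' @return Angular frequency in ps\eqn{^{-1}}.
#' @examples
#' cm1_to_angular(1)    # ~0.1884
#' cm1_to_angular(5.3)  # FMO sink rate in ps^-1
#' @export
cm1_to_angular <- function(x) {
  2 * pi * .c_cm_per_ps * x
}

#' Convert between sigma-z and projector dephasing-rate conventions
#'
#' The dephasing dissipators in this package use jump operators
#' \eqn{A_n = \sigma_z^{(n)}} in the prefactor-free Lindblad form
#' \eqn{\gamma(2A\rho A^\dagger - A^\dagger A\rho - \rho A^\dagger A)}.
#' Much of the exciton-transfer literature instead uses site projectors
#' \eqn{|e_n\rangle\langle e_n|} in the same form; for inter-site coherences
#' the two differ by a factor of 8 (a sigma-z rate \eqn{\gamma} dephases
#' site-site coherences at \eqn{8\gamma}, a projector rate \eqn{\gamma'} at
#' \eqn{\gamma'}).
#'
#' @param rate numeric rate(s).
#' @param from,to `"sigma_z"` or `"projector"`.
#' @return Converted rate(s).
#' @examples
#' dephasing_rate_convert(7.7, from = "sigma_z", to = "projector")
#' @export
dephasing_rate_convert <- function(rate, from = c("sigma_z", "projector"),
                                   to = c("projector", "sigma_z")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) {
    return(rate)
  }
  if (from == "sigma_z") rate * 8 else rate / 8
}
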