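# The two ready-made scenarios: a three-qubit dephasing chain and the
# seven-site FMO monomer with reaction-center sink and Haken-Strobl
# dephasing.

#' Three-qubit chain scenario
#'
#' Two qubits coherently coupled through a middle qubit,
#' \deqn{H = J_{12}(\sigma_+^1\sigma_-^2 + \sigma_-^1\sigma_+^2)
#'         + J_{23}(\sigma_+^2\sigma_-^3 + \sigma_-^2\sigma_+^3),}
#' with the middle qubit suffering phase damping at rate `gamma` (a
#' \eqn{\sigma_z^{(2)}} dissipator in the same prefactor-free convention as
#' the dephasing of the FMO model).  The initial state is
#' \eqn{|1\rangle\otimes|0\rangle\otimes|0\rangle} (qubit 1 excited), qubit
#' 1 is measured at time 0 with the Pauli X, Y, Z set, and the assemblage is
#' read out on `target`.  Couplings and rates are in units of \eqn{J}; time
#' is in units of \eqn{J^{-1}}.
#'
#' @param J12,J23 coupling strengths (default the symmetric chain
#'   \eqn{J_{12} = J_{23} = J = 1}).
#' @param gamma dephasing rate on qubit 2 (\eqn{\ge 0}).
#' @param target target qubit (default 3).
#' @return An [scenario()] of kind `"network"`.
#' @export
three_qubit_chain_scenario <- function(J12 = 1, J23 = 1, gamma = 0,
                                       target = 3) {
  stopifnot(gamma >= 0)
  sp <- state_space(3)
  hop <- function(i, j, J) {
    J * (site_operator(sp, "raise", i) %*% site_operator(sp, "lower", j))
  }
  H <- hop(1, 2, J12) + hop(2, 1, J12) + hop(2, 3, J23) + hop(3, 2, J23)
  diss <- if (gamma > 0) {
    list(list(rate = gamma, op = site_operator(sp, "sigma_z", 2),
              label = "dephasing_q2"))
  } else {
    list()
  }
  model <- lindblad_model(H, diss, sp)
  e1 <- basis_ket(sp, "e1")
  scenario(
    kind = "network",
    rho0 = e1 %*% t(Conj(e1)),
    measured_site = 1, target_site = target,
    assembly = pauli_measurement_set(),
    channel = channel_lindblad(model),
    space = sp,
    description = sprintf("three-qubit chain (gamma = %g J)", gamma)
  )
}

#' The seven-site FMO Hamiltonian
#'
#' Site energies (diagonal) and excitonic couplings (off-diagonal) of a
#' single Fenna-Matthews-Olson monomer, in cm\eqn{^{-1}}, relative to the
#' lowest site energy.  The recently discovered eighth site is omitted.
#'
#' @return Real symmetric 7x7 matrix.
#' @examples
#' fmo_site_hamiltonian()[1, 2]  # -104.1
#' @export
fmo_site_hamiltonian <- function() {
  H <- matrix(c(
     215,   -104.1,   5.1,  -4.3,   4.7, -15.1,  -7.8,
    -104.1,  220,    32.6,   7.1,   5.4,   8.3,   0.8,
       5.1,   32.6,   0,   -46.8,   1.0,  -8.1,   5.1,
      -4.3,    7.1, -46.8, 125,   -70.7, -14.7, -61.5,
       4.7,    5.4,   1.0, -70.7, 450,    89.7,  -2.5,
     -15.1,    8.3,  -8.1, -14.7,  89.7, 330,    32.7,
      -7.8,    0.8,   5.1, -61.5,  -2.5,  32.7, 280
  ), nrow = 7, byrow = TRUE)
  dimnames(H) <- list(paste0("site", 1:7), paste0("site", 1:7))
  H
}

#' Dephasing rate from temperature
#'
#' In the weak-coupling (Born-Markov, Ohmic) regime the pure-dephasing rate
#' is directly proportional to temperature; the proportionality constant is
#' anchored at the single calibration point \eqn{\gamma_{dp} = 7.7}
#' cm\eqn{^{-1}} at \eqn{T = 15} K.
#'
#' @param T_kelvin temperature in kelvin (\eqn{\ge 0}).
#' @return Dephasing rate in cm\eqn{^{-1}}.
#' @examples
#' gamma_dp_from_temperature(15)  # 7.7
#' @export
gamma_dp_from_temperature <- function(T_kelvin) {
  if (any(T_kelvin < 0)) {
    stop("temperature must be nonnegative", call. = FALSE)
  }
  (7.7 / 15) * T_kelvin
}

#' Lindblad model of the FMO monomer
#'
#' Nine-dimensional model (vacuum + 7 sites + reaction center).  The FMO
#' Hamiltonian occupies the single-excitation block; the vacuum and
#' reaction-center energies are set to 0 (the large ground-state offset is
#' dropped, inducing only a global inter-sector phase that provably leaves
#' both steering measures unchanged).  Dissipators: one sink
#' \eqn{\Gamma\,[2s\rho s^\dagger - s^\dagger s\rho - \rho s^\dagger s]}
#' with \eqn{s = \sigma_+^{(R)}\sigma_-^{(3)}} (irreversible transfer from
#' site 3 to the reaction center) and seven dephasers with jump operators
#' \eqn{A_n = \sigma_z^{(n)}} at rate `gamma_dp`.  Energies and rates are
#' entered in cm\eqn{^{-1}} and converted to angular frequencies in
#' ps\eqn{^{-1}}; time is in ps.
#'
#' @param gamma_dp dephasing rate in cm\eqn{^{-1}}.
#' @param sink_rate transfer rate \eqn{\Gamma} to the reaction center in
#'   cm\eqn{^{-1}}.
#' @param hamiltonian_cm1 7x7 site Hamiltonian (defaults to
#'   [fmo_site_hamiltonian()]).
#' @param convert_rates convert the rates with the same \eqn{2\pi c} factor
#'   as the energies (default `TRUE`; with this choice the printed rates
#'   reproduce the ~1 ps sink and ~100 fs dephasing timescales).
#' @return An [lindblad_model()] on `state_space(7, TRUE)`.
#' @export
fmo_model <- function(gamma_dp = 7.7, sink_rate = 5.3,
                      hamiltonian_cm1 = fmo_site_hamiltonian(),
                      convert_rates = TRUE) {
  sp <- state_space(7, include_reaction_center = TRUE)
  d <- sp$dimension
  H <- matrix(0i, d, d)
  H[2:8, 2:8] <- hamiltonian_cm1
  s <- site_operator(sp, "raise", "R") %*% site_operator(sp, "lower", 3)
  diss <- list(list(rate = sink_rate, op = s, label = "sink"))
  if (gamma_dp > 0) {
    for (n in 1:7) {
      diss[[length(diss) + 1L]] <-
        list(rate = gamma_dp, op = site_operator(sp, "sigma_z", n),
             label = paste0("dephasing_site", n))
    }
  }
  lindblad_model(H, diss, sp, units = "cm-1", convert_rates = convert_rates)
}

#' FMO steering scenario
#'
#' The excitation enters at site 6: the initial state is completely mixed
#' at site 6 with all other sites in the ground state,
#' \eqn{\rho_0 = (|\mathrm{vac}\rangle\langle\mathrm{vac}| +
#' |e_6\rangle\langle e_6|)/2}.  Site 6 is measured at time 0 with the
#' Pauli X, Y, Z set and the assemblage is read out at `target_site`.
#'
#' @param target_site any site 1-5 or 7 (not the measured site 6).
#' @param T_kelvin temperature, setting the dephasing rate through
#'   [gamma_dp_from_temperature()].
#' @param sink_rate reaction-center transfer rate in cm\eqn{^{-1}}.
#' @param ... passed to [fmo_model()].
#' @return An [scenario()] of kind `"network"`.
#' @export
fmo_scenario <- function(target_site, T_kelvin = 15, sink_rate = 5.3, ...) {
  if (identical(target_site, 6) || identical(target_site, 6L)) {
    stop("`target_site` must differ from the measured site 6", call. = FALSE)
  }
  model <- fmo_model(gamma_dp = gamma_dp_from_temperature(T_kelvin),
                     sink_rate = sink_rate, ...)
  sp <- model$space
  rho0 <- matrix(0i, sp$dimension, sp$dimension)
  rho0[1, 1] <- 0.5
  i6 <- site_index(sp, 6)
  rho0[i6, i6] <- 0.5
  scenario(
    kind = "network", rho0 = rho0,
    measured_site = 6, target_site = target_site,
    assembly = pauli_measurement_set(),
    channel = channel_lindblad(model),
    space = sp,
    description = sprintf("FMO site-6 -> site-%s (T = %g K)",
                          target_site, T_kelvin)
  )
}
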