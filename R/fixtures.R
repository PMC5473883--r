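# Synthetic fixtures: unsteerable assemblages built directly from the
# hidden-state model, Werner-state scenarios (the Einstein-Podolsky-Rosen
# reduction), and null-channel scenarios.

#' Seeded unsteerable assemblage
#'
#' Constructs \eqn{\sigma_{a|x} = \sum_\lambda p(\lambda) p(a|x,\lambda)
#' \sigma_\lambda} from randomly drawn weights \eqn{p(\lambda)},
#' deterministic response tables and random qubit states
#' \eqn{\sigma_\lambda}, so the result admits the hidden-state model by
#' construction (steering weight and robustness are both 0).  The seed
#' fully determines the output.
#'
#' @param seed integer seed.
#' @param m,o number of settings and outcomes.
#' @param n_lambda number of hidden states drawn (\eqn{\ge 1}).
#' @return An `sts_assemblage`.
#' @examples
#' asm <- unsteerable_fixture(1)
#' @export
unsteerable_fixture <- function(seed, m = 3, o = 2, n_lambda = 5) {
  stopifnot(n_lambda >= 1)
  withr::with_seed(as.integer(seed), {
    p <- stats::runif(n_lambda)
    p <- p / sum(p)
    responses <- matrix(sample.int(o, n_lambda * m, replace = TRUE),
                        n_lambda, m)
    states <- lapply(seq_len(n_lambda), function(i) random_qubit_state())
    members <- lapply(seq_len(m), function(x) {
      lapply(seq_len(o), function(a) {
        acc <- matrix(0i, 2, 2)
        for (lam in seq_len(n_lambda)) {
          if (responses[lam, x] == a) {
            acc <- acc + p[lam] * states[[lam]]
          }
        }
        acc
      })
    })
    new_assemblage(members, time = 0,
                   metadata = list(description =
                                     sprintf("unsteerable fixture (seed %d)",
                                             as.integer(seed))))
  })
}

# Random qubit density matrix: uniform Bloch direction, radius with
# volume-uniform law.
random_qubit_state <- function() {
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2)) * stats::runif(1)^(1 / 3)
  bloch_state(v)
}

# Qubit state (1 + r . sigma)/2 from a Bloch vector (|r| <= 1), basis (g, e)
# with sigma_z = diag(-1, +1).
bloch_state <- function(r) {
  sx <- matrix(c(0, 1, 1, 0), 2, 2) + 0i
  sy <- matrix(c(0i, -1i, 1i, 0i), 2, 2)
  sz <- diag(c(-1, 1)) + 0i
  (diag(2) + r[1] * sx + r[2] * sy + r[3] * sz) / 2
}

#' Werner-state scenario (the Einstein-Podolsky-Rosen reduction)
#'
#' Two qubits in the state \eqn{p\,|\Phi^+\rangle\langle\Phi^+| +
#' (1-p)\,\mathbb{1}/4}, identity channel, Pauli X, Y, Z measurements on
#' qubit A, target qubit B.  With these three mutually unbiased
#' measurements the assemblage is steerable exactly when
#' \eqn{p > 1/\sqrt{3} \approx 0.5774}, which makes the family a calibrated
#' steerable/unsteerable dial for tests.
#'
#' @param p mixing weight in \eqn{[0, 1]}.
#' @return An [scenario()] of kind `"qubit_pair"`.
#' @export
werner_scenario <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  phi <- complex(4)
  phi[1] <- phi[4] <- 1 / sqrt(2)     # (|gg> + |ee>)/sqrt(2)
  rho <- p * (phi %*% t(Conj(phi))) + (1 - p) * diag(4) / 4
  scenario(
    kind = "qubit_pair", rho0 = rho,
    measured_site = 1, target_site = 2,
    assembly = pauli_measurement_set(),
    channel = channel_identity(),
    description = sprintf("Werner state (p = %g)", p)
  )
}

#' Null-channel scenario
#'
#' The channel discards its input and installs a fixed target state
#' \eqn{\rho_B}: the model of a completely broken network link.  The
#' resulting assemblage is \eqn{\sigma_{a|x} = p(a|x)\,\rho_B} at every
#' time, which always admits a single-state hidden-state model, so both
#' steering measures vanish identically.
#'
#' @param rho_fixed 2x2 target state installed by the channel.
#' @param rho0 initial two-qubit state determining the outcome statistics
#'   (default the maximally entangled \eqn{|\Phi^+\rangle}).
#' @return An [scenario()] of kind `"qubit_pair"`.
#' @export
discard_channel_scenario <- function(rho_fixed,
                                     rho0 = NULL) {
  if (is.null(rho0)) {
    phi <- complex(4)
    phi[1] <- phi[4] <- 1 / sqrt(2)
    rho0 <- phi %*% t(Conj(phi))
  }
  scenario(
    kind = "qubit_pair", rho0 = rho0,
    measured_site = 1, target_site = 2,
    assembly = pauli_measurement_set(),
    channel = channel_discard(rho_fixed),
    description = "discard channel (broken link)"
  )
}
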