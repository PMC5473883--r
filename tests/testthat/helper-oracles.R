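# Independent oracles used across the test files.  Everything here is built
# from first principles (kronecker products on the full 2^n space, direct
# ODE integration, closed forms) without touching the package's restricted
# sector machinery, so agreement is a genuine cross-check.

# --- full tensor-space construction -----------------------------------------

# Single-qubit matrices, basis (g, e); sigma_z = |e><e| - |g><g|.
.q_sz <- diag(c(-1, 1)) + 0i
.q_raise <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE) + 0i  # |e><g|

# Operator acting as `op` on qubit `site` of an n-qubit register
# (qubit 1 is the leftmost kronecker factor).
full_site_op <- function(op, site, n) {
  out <- matrix(1 + 0i, 1, 1)
  for (k in seq_len(n)) {
    out <- out %x% (if (k == site) op else diag(2) + 0i)
  }
  out
}

# Index (1-based) of the full-space basis state with the given excited
# qubits (integer vector, possibly empty).
full_basis_index <- function(excited, n) {
  bits <- integer(n)
  bits[excited] <- 1L
  as.integer(1L + sum(bits * 2^(n - seq_len(n))))
}

# Embed a restricted-sector state (basis vac, e1..en) into the 2^n space.
embed_full <- function(rho_sector, n) {
  idx <- c(full_basis_index(integer(0), n),
           vapply(seq_len(n), function(k) full_basis_index(k, n),
                  integer(1)))
  out <- matrix(0i, 2^n, 2^n)
  out[idx, idx] <- rho_sector
  out
}

# Extract the restricted sector block from a full-space state.
project_sector <- function(rho_full, n) {
  idx <- c(full_basis_index(integer(0), n),
           vapply(seq_len(n), function(k) full_basis_index(k, n),
                  integer(1)))
  rho_full[idx, idx]
}

# Direct integration of the master equation on an arbitrary space, with the
# rhs written out locally (rate * (2 A rho A+ - A+A rho - rho A+A)).
full_evolve <- function(rho0, H, dissipators, times,
                        rtol = 1e-10, atol = 1e-12) {
  d <- nrow(rho0)
  rhs <- function(t, y, parms) {
    rho <- matrix(y, d, d)
    out <- -1i * (H %*% rho - rho %*% H)
    for (dd in dissipators) {
      A <- dd$op
      AdA <- Conj(t(A)) %*% A
      out <- out + dd$rate * (2 * A %*% rho %*% Conj(t(A)) -
                                AdA %*% rho - rho %*% AdA)
    }
    list(as.vector(out))
  }
  sol <- deSolve::zvode(y = as.vector(rho0 + 0i), times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol)
  lapply(seq_along(times), function(i) matrix(sol[i, -1], d, d))
}

# Partial trace of an n-qubit state onto qubit `site`.
full_partial_trace_to <- function(rho_full, site, n) {
  out <- matrix(0i, 2, 2)
  for (i in 0:(2^n - 1)) {
    for (j in 0:(2^n - 1)) {
      bi <- bitwAnd(i %/% 2^(n - site), 1L)
      bj <- bitwAnd(j %/% 2^(n - site), 1L)
      rest_i <- i - bi * 2^(n - site)
      rest_j <- j - bj * 2^(n - site)
      if (rest_i == rest_j) {
        out[bi + 1, bj + 1] <- out[bi + 1, bj + 1] + rho_full[i + 1, j + 1]
      }
    }
  }
  out
}

# --- closed forms ------------------------------------------------------------

# Werner-state assemblage under the Pauli set, by direct 4x4 algebra:
# sigma_{a|w} = tr_A[(F_{a|w} (x) 1) rho_W] = (1 + a p sigma_w^T)/4.
werner_assemblage_closed_form <- function(p) {
  paulis <- list(matrix(c(0, 1, 1, 0), 2, 2) + 0i,
                 matrix(c(0i, -1i, 1i, 0i), 2, 2),
                 diag(c(-1, 1)) + 0i)
  members <- lapply(paulis, function(s) {
    list((diag(2) + p * t(s)) / 4, (diag(2) - p * t(s)) / 4)
  })
  new_assemblage(members, time = 0)
}

# Uniformly random 2x2 unitary (Haar via QR of a Ginibre matrix).
random_unitary_2 <- function() {
  g <- matrix(complex(real = stats::rnorm(4), imaginary = stats::rnorm(4)),
              2, 2)
  qr_g <- qr(g)
  q <- qr.Q(qr_g)
  r <- qr.R(qr_g)
  q %*% diag(diag(r) / Mod(diag(r)))
}

expect_matrix_equal <- function(actual, expected, tol = 1e-8) {
  expect_lt(max(Mod(as.matrix(actual) - as.matrix(expected))), tol)
}
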