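test_that("the Pauli measurement set is a complete projective assembly", {
  pm <- pauli_measurement_set()
  expect_equal(pm$n_settings, 3)
  expect_equal(pm$n_outcomes, 2)
  # outcome + of Z is the excited-state projector
  expect_matrix_equal(pm$elements[["Z"]][[1]], diag(c(0, 1)))
  for (x in 1:3) {
    tot <- pm$elements[[x]][[1]] + pm$elements[[x]][[2]]
    expect_matrix_equal(tot, diag(2), 1e-12)
    for (a in 1:2) {
      F <- pm$elements[[x]][[a]]
      expect_matrix_equal(F %*% F, F, 1e-12)       # projector
      expect_equal(Re(sum(diag(F))), 1, tolerance = 1e-12)  # rank 1
    }
  }
})

test_that("post-measurement branches carry the outcome probabilities", {
  sp <- state_space(3)
  e1 <- basis_ket(sp, "e1")
  rho <- e1 %*% t(Conj(e1))
  br <- post_measurement_branches(rho, pauli_measurement_set(), 1, sp)
  # Z on the excited site: outcome + certain
  expect_equal(Re(sum(diag(br[[3]][[1]]))), 1, tolerance = 1e-12)
  expect_equal(Re(sum(diag(br[[3]][[2]]))), 0, tolerance = 1e-12)
  # X outcomes equiprobable and branches pure superpositions of vac and e1
  for (a in 1:2) {
    b <- br[[1]][[a]]
    expect_equal(Re(sum(diag(b))), 0.5, tolerance = 1e-12)
    expect_equal(Mod(b[2, 1]), 0.25, tolerance = 1e-12)
  }

  # maximally mixed at the measured site (the FMO initial condition):
  # X branches are the pure |+/-> superpositions of vac and the site state
  rho_mix <- 0.5 * basis_ket(sp, "vac") %*% t(Conj(basis_ket(sp, "vac"))) +
    0.5 * rho
  brm <- post_measurement_branches(rho_mix, pauli_measurement_set(), 1, sp)
  for (a in 1:2) {
    b <- brm[[1]][[a]]
    p <- Re(sum(diag(b)))
    expect_equal(p, 0.5, tolerance = 1e-12)
    cond <- b / p
    expect_equal(Re(sum(diag(cond %*% cond))), 1, tolerance = 1e-10)  # pure
  }

  # the trivial one-element assembly returns the state itself
  triv <- measurement_assembly(list(list(diag(2))))
  b1 <- post_measurement_branches(rho, triv, 1, sp)
  expect_matrix_equal(b1[[1]][[1]], rho, 1e-12)
})

test_that("reduction to a site qubit matches the full-space partial trace", {
  sp <- state_space(3)
  expect_matrix_equal(
    reduce_to_site_qubit(basis_ket(sp, "e3") %*% t(Conj(basis_ket(sp, "e3"))),
                         sp, 3),
    diag(c(0, 1)))
  expect_matrix_equal(
    reduce_to_site_qubit(basis_ket(sp, "e2") %*% t(Conj(basis_ket(sp, "e2"))),
                         sp, 3),
    diag(c(1, 0)))
  # coherent superposition of vacuum and e3 reduces to a pure |+> state,
  # verified against the explicit 2^3 partial trace
  psi <- (basis_ket(sp, "vac") + basis_ket(sp, "e3")) / sqrt(2)
  rho <- psi %*% t(Conj(psi))
  red <- reduce_to_site_qubit(rho, sp, 3)
  oracle <- full_partial_trace_to(embed_full(rho, 3), 3, 3)
  expect_matrix_equal(red, oracle, 1e-12)
  expect_matrix_equal(red, matrix(0.5, 2, 2))
  # and on a generic sector state
  set.seed(11)
  g <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  rho_g <- g %*% Conj(t(g))
  rho_g <- rho_g / Re(sum(diag(rho_g)))
  for (s in 1:3) {
    expect_matrix_equal(reduce_to_site_qubit(rho_g, sp, s),
                        full_partial_trace_to(embed_full(rho_g, 3), s, 3),
                        1e-12)
  }
})

test_that("the chain assemblage at t = 0 is classical on the ground state", {
  sc <- three_qubit_chain_scenario(gamma = 0.01)
  asm <- assemblage_at(sc, 0)
  probs <- assemblage_probabilities(asm)
  for (x in 1:3) {
    for (a in 1:2) {
      p <- probs[a, x]
      expect_matrix_equal(asm$members[[x]][[a]], p * diag(c(1, 0)), 1e-10)
    }
  }
  # qubit 1 is excited: Z is deterministic, X and Y unbiased
  expect_equal(probs[, 3], c(1, 0), tolerance = 1e-10)
  expect_equal(probs[, 1], c(0.5, 0.5), tolerance = 1e-10)
})

test_that("the identity-channel Werner scenario reproduces the closed-form steering ellipsoid", {
  for (p in c(0.3, 1)) {
    asm <- assemblage_at(werner_scenario(p), 0)
    ref <- werner_assemblage_closed_form(p)
    for (x in 1:3) {
      for (a in 1:2) {
        expect_matrix_equal(asm$members[[x]][[a]], ref$members[[x]][[a]],
                            1e-10)
      }
    }
    v <- validate_assemblage(asm)
    expect_true(v$non_signalling)
    expect_true(v$psd_ok)
    expect_true(v$traces_ok)
  }
})

test_that("the discard channel destroys all measurement dependence", {
  rb <- stsnet:::bloch_state(c(0.3, 0, 0.2))
  sc <- discard_channel_scenario(rb)
  for (t in c(0, 0.7, 3)) {
    asm <- assemblage_at(sc, t)
    probs <- assemblage_probabilities(asm)
    for (x in 1:3) {
      for (a in 1:2) {
        expect_matrix_equal(asm$members[[x]][[a]], probs[a, x] * rb, 1e-10)
      }
    }
    expect_true(validate_assemblage(asm)$non_signalling)
  }
})

test_that("spatio-temporal assemblages may signal across settings", {
  # measuring X vs Z on qubit 1 leaves different average states whose
  # difference propagates to qubit 3 under the chain dynamics
  sc <- three_qubit_chain_scenario(gamma = 0)
  asm <- assemblage_at(sc, 1)
  v <- validate_assemblage(asm)
  expect_false(v$non_signalling)
  expect_gt(v$max_signalling, 1e-3)
  # but probability is still conserved per setting
  expect_true(v$traces_ok)
})

test_that("per-setting trace sums equal one along scans", {
  sc <- fmo_scenario(5)
  asms <- assemblage_trajectory(sc, seq(0, 0.2, length.out = 5))
  for (asm in asms) {
    v <- validate_assemblage(asm)
    expect_true(all(abs(v$trace_sums - 1) <= 1e-8))
    expect_true(v$psd_ok)
  }
})

test_that("the temporal reduction reproduces the conditional-state construction", {
  # single system: measure it at time 0, evolve the same system, read it out
  sp <- state_space(1)
  gamma <- 0.25
  H <- 0.8 * site_operator(sp, "sigma_x", 1)
  mod <- lindblad_model(H, list(list(rate = gamma,
                                     op = site_operator(sp, "sigma_z", 1))),
                        sp)
  rho0 <- stsnet:::bloch_state(c(0.2, 0.1, 0.4))
  sc <- scenario("network", rho0, 1, 1, pauli_measurement_set(),
                 channel_lindblad(mod), sp, "temporal reduction")
  t <- 1.3
  asm <- assemblage_at(sc, t, rtol = 1e-12, atol = 1e-14)
  pm <- pauli_measurement_set()
  for (x in 1:3) {
    for (a in 1:2) {
      F <- pm$elements[[x]][[a]]
      p <- Re(sum(diag(F %*% rho0)))
      cond <- (F %*% rho0 %*% F) / p
      evolved <- evolve(cond, mod, c(0, t), rtol = 1e-12, atol = 1e-14)[[2]]
      expect_matrix_equal(asm$members[[x]][[a]], p * evolved, 1e-10)
    }
  }
})

test_that("assemblages are linear in the initial state", {
  sc <- three_qubit_chain_scenario(gamma = 0.2)
  sp <- sc$space
  v <- basis_ket(sp, "vac")
  e1 <- basis_ket(sp, "e1")
  rho_a <- e1 %*% t(Conj(e1))
  psi <- (v + e1) / sqrt(2)
  rho_b <- psi %*% t(Conj(psi))
  q <- 0.4
  mk <- function(rho) {
    s <- sc
    s$rho0 <- rho
    assemblage_at(s, 0.9)
  }
  asm_mix <- mk(q * rho_a + (1 - q) * rho_b)
  asm_a <- mk(rho_a)
  asm_b <- mk(rho_b)
  for (x in 1:3) {
    for (a in 1:2) {
      expect_matrix_equal(
        asm_mix$members[[x]][[a]],
        q * asm_a$members[[x]][[a]] + (1 - q) * asm_b$members[[x]][[a]],
        1e-8)
    }
  }
})

test_that("assemblage JSON round-trips to full precision and validates on read", {
  asm <- assemblage_at(three_qubit_chain_scenario(gamma = 0.01), 1.37)
  path <- withr::local_tempfile(fileext = ".json")
  write_assemblage(asm, path)
  back <- read_assemblage(path)
  expect_equal(back$n_settings, asm$n_settings)
  expect_equal(back$time, asm$time)
  for (x in 1:3) {
    for (a in 1:2) {
      expect_matrix_equal(back$members[[x]][[a]], asm$members[[x]][[a]],
                          1e-14)
    }
  }
  # a corrupted (negative) assemblage is rejected on load
  bad <- asm
  bad$members[[1]][[1]] <- diag(c(-0.2, 0.4)) + 0i
  path2 <- withr::local_tempfile(fileext = ".json")
  write_assemblage(bad, path2)
  expect_error(read_assemblage(path2), "violates invariants")
})
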