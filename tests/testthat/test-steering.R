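# Correctness of the three steering programs, cross-checked against
# independently coded dual formulations, closed forms and invariances.

test_that("hidden-state-model fixtures are unsteerable by all three programs", {
  for (seed in 1:12) {
    asm <- unsteerable_fixture(seed, n_lambda = sample(1:8, 1))
    expect_lt(sts_weight(asm)$value, 1e-6)
    expect_lt(sts_robustness(asm)$value, 1e-6)
    chk <- check_hidden_state_model(asm)
    expect_true(chk$feasible)
    # the feasibility certificate satisfies the member equalities
    strat <- enumerate_strategies(asm$n_settings, asm$n_outcomes)
    for (x in 1:asm$n_settings) {
      for (a in 1:asm$n_outcomes) {
        lams <- which(strat$d[a, x, ] == 1)
        acc <- Reduce(`+`, chk$certificate[lams])
        expect_matrix_equal(acc, asm$members[[x]][[a]], 5e-6)
      }
    }
  }
})

test_that("fixtures are deterministic in the seed and degenerate for one hidden state", {
  a1 <- unsteerable_fixture(42)
  a2 <- unsteerable_fixture(42)
  for (x in 1:3) {
    for (a in 1:2) {
      expect_identical(a1$members[[x]][[a]], a2$members[[x]][[a]])
    }
  }
  # a single hidden state: every nonzero member is proportional to it
  a3 <- unsteerable_fixture(7, n_lambda = 1)
  conds <- list()
  for (x in 1:3) {
    for (a in 1:2) {
      s <- a3$members[[x]][[a]]
      tr <- Re(sum(diag(s)))
      if (tr > 1e-12) conds[[length(conds) + 1]] <- s / tr
    }
  }
  for (k in seq_along(conds)) {
    expect_matrix_equal(conds[[k]], conds[[1]], 1e-10)
  }
})

test_that("the maximally entangled Werner state is maximally steerable", {
  asm <- assemblage_at(werner_scenario(1), 0)
  w <- sts_weight(asm)
  wd <- sts_weight_dual(asm)
  expect_equal(w$value, 1, tolerance = 1e-6)
  expect_equal(w$value, wd$value, tolerance = 1e-6)
  r <- sts_robustness(asm)
  rd <- sts_robustness_dual(asm)
  expect_equal(r$value, rd$value, tolerance = 1e-6)
  # closed form from the octant hidden-state construction: with the Pauli
  # set the optimal ensemble sits on the (+-1,+-1,+-1)/sqrt(3) directions,
  # giving robustness 2 - sqrt(3); the dual confirms tightness
  expect_equal(r$value, 2 - sqrt(3), tolerance = 1e-6)
  expect_false(check_hidden_state_model(asm)$feasible)
  # the optimal noise assemblage is itself a valid assemblage
  v <- validate_assemblage(r$noise_assemblage, tol = 1e-6)
  expect_true(v$psd_ok)
  expect_true(v$traces_ok)
})

test_that("Werner states below the three-measurement threshold are unsteerable", {
  asm <- assemblage_at(werner_scenario(0.5), 0)
  expect_lt(sts_weight(asm)$value, 1e-6)
  expect_lt(sts_robustness(asm)$value, 1e-6)
  expect_true(check_hidden_state_model(asm)$feasible)
})

test_that("primal and dual formulations agree on steerable assemblages", {
  cases <- list(
    assemblage_at(werner_scenario(0.8), 0),
    assemblage_at(werner_scenario(0.95), 0),
    assemblage_at(three_qubit_chain_scenario(gamma = 0.01), 2.2)
  )
  for (asm in cases) {
    w <- sts_weight(asm)
    r <- sts_robustness(asm)
    expect_gt(w$value, 1e-4)
    expect_gt(r$value, 1e-4)
    expect_equal(w$value, sts_weight_dual(asm)$value, tolerance = 1e-6)
    expect_equal(r$value, sts_robustness_dual(asm)$value, tolerance = 1e-6)
  }
})

test_that("both measures are monotone along the Werner family", {
  ps <- c(0, 0.2, 0.4, 0.6, 0.7, 0.8, 0.9, 1)
  ws <- rs <- numeric(length(ps))
  for (i in seq_along(ps)) {
    asm <- assemblage_at(werner_scenario(ps[i]), 0)
    ws[i] <- sts_weight(asm)$value
    rs[i] <- sts_robustness(asm)$value
  }
  expect_true(all(diff(ws) >= -1e-7))
  expect_true(all(diff(rs) >= -1e-7))
  expect_lt(ws[1], 1e-8)
  expect_lt(rs[1], 1e-8)
})

test_that("the measures are invariant under relabelings and a fixed target unitary", {
  asm <- assemblage_at(werner_scenario(0.85), 0)
  w0 <- sts_weight(asm)$value
  r0 <- sts_robustness(asm)$value

  # relabel settings
  perm <- asm
  perm$members <- asm$members[c(3, 1, 2)]
  expect_equal(sts_weight(perm)$value, w0, tolerance = 1e-6)
  expect_equal(sts_robustness(perm)$value, r0, tolerance = 1e-6)

  # relabel outcomes within one setting
  flip <- asm
  flip$members[[2]] <- flip$members[[2]][c(2, 1)]
  expect_equal(sts_weight(flip)$value, w0, tolerance = 1e-6)
  expect_equal(sts_robustness(flip)$value, r0, tolerance = 1e-6)

  # conjugate every member by one fixed unitary
  set.seed(5)
  U <- random_unitary_2()
  conj <- asm
  conj$members <- lapply(asm$members, function(st) {
    lapply(st, function(s) U %*% s %*% Conj(t(U)))
  })
  expect_equal(sts_weight(conj)$value, w0, tolerance = 1e-6)
  expect_equal(sts_robustness(conj)$value, r0, tolerance = 1e-6)
})

test_that("certificates satisfy their semidefinite constraints", {
  for (asm in list(assemblage_at(werner_scenario(0.9), 0),
                   unsteerable_fixture(3))) {
    w <- sts_weight(asm)
    r <- sts_robustness(asm)
    expect_gt(w$constraint_residual, -1e-7)
    expect_gt(r$constraint_residual, -1e-7)
    expect_true(all(vapply(w$certificate,
                           function(m) stsnet:::min_eigenvalue(m) > -1e-7,
                           logical(1))))
  }
})

test_that("any single-setting assemblage admits a hidden-state model", {
  # explicit construction: lambda = a, rho_lambda = sigma_{a|1}
  set.seed(9)
  g1 <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2)
  s1 <- g1 %*% Conj(t(g1))
  s1 <- 0.6 * s1 / Re(sum(diag(s1)))
  g2 <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2)
  s2 <- g2 %*% Conj(t(g2))
  s2 <- 0.4 * s2 / Re(sum(diag(s2)))
  asm <- new_assemblage(list(list(s1, s2)))
  expect_true(check_hidden_state_model(asm)$feasible)
  expect_lt(sts_weight(asm)$value, 1e-6)
})

test_that("signalling assemblages are steerable and fail the linear consistency stage", {
  asm <- assemblage_at(three_qubit_chain_scenario(gamma = 0), 1)
  chk <- check_hidden_state_model(asm)
  expect_false(chk$feasible)
  expect_equal(chk$status, "linearly_inconsistent")
  expect_gt(sts_weight(asm)$value, 1e-6)
  expect_gt(sts_robustness(asm)$value, 1e-6)
})

test_that("zero-probability outcomes are legal program inputs", {
  # the chain at t = 0 has an exactly zero member (outcome - of Z)
  asm <- assemblage_at(three_qubit_chain_scenario(gamma = 0.01), 0)
  expect_equal(Re(sum(diag(asm$members[[3]][[2]]))), 0, tolerance = 1e-14)
  expect_lt(sts_weight(asm)$value, 1e-6)
  expect_lt(sts_robustness(asm)$value, 1e-6)
  expect_true(check_hidden_state_model(asm)$feasible)
})

test_that("steering results expose tidy and glance summaries", {
  r <- sts_robustness(assemblage_at(werner_scenario(1), 0))
  g <- glance(r)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$measure, "robustness")
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8)   # one row per deterministic strategy
  expect_true(all(td$min_eigenvalue > -1e-7))
})
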