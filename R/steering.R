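# The three convex programs for spatio-temporal steering: hidden-state
# feasibility, steering weight, and steering robustness, plus independently
# formulated dual programs used as cross-checks.

# Members are symmetrized and eigenvalue-clipped before entering a program,
# to absorb integrator noise.
prep_members <- function(assemblage, clip_tol = 1e-10) {
  lapply(assemblage$members, function(setting) {
    lapply(setting, function(s) psd_clip(s, tol = clip_tol))
  })
}

new_steering_result <- function(measure, value, certificate, sol, extra = list()) {
  structure(
    c(list(measure = measure, value = value, certificate = certificate,
           solver_status = sol$status, iterations = sol$iterations,
           gap = sol$gap, primal_infeas = sol$primal_infeas,
           dual_infeas = sol$dual_infeas),
      extra),
    class = "sts_steering_result"
  )
}

#' @export
print.sts_steering_result <- function(x, ...) {
  cat("<sts_steering_result> ", x$measure, " = ", format(x$value),
      "  [", x$solver_status, ", ", x$iterations, " iterations]\n", sep = "")
  invisible(x)
}

#' @export
glance.sts_steering_result <- function(x, ...) {
  tibble::tibble(
    measure = x$measure, value = x$value, solver_status = x$solver_status,
    iterations = x$iterations, gap = x$gap,
    primal_infeas = x$primal_infeas, dual_infeas = x$dual_infeas
  )
}

#' @export
tidy.sts_steering_result <- function(x, ...) {
  if (is.null(x$certificate)) {
    return(tibble::tibble())
  }
  dplyr::bind_rows(lapply(seq_along(x$certificate), function(l) {
    r <- x$certificate[[l]]
    p <- Re(mat_trace(r))
    tibble::tibble(
      lambda = l, p_lambda = p,
      purity = if (p > 1e-12) Re(mat_trace((r / p) %*% (r / p))) else NA_real_,
      min_eigenvalue = min_eigenvalue(r)
    )
  }))
}

# Build blocks/constraints shared by the weight and robustness primals.
# sign = +1: slack block Y_ax = sigma - sum d rho (weight);
# sign = -1: slack block Y_ax = sum d rho - sigma (robustness).
#
# Exact presolve of zero members (outcomes of probability ~0): in the
# weight program a zero sigma_{a|x} forces every rho_lambda with
# d_lambda(a|x) = 1 to vanish, so those variables and the constraint are
# eliminated; in the robustness program the constraint is vacuous and is
# dropped.  This removes the cone-boundary degeneracy such members would
# otherwise inject into the interior-point iteration without changing the
# optimum.
primal_program <- function(members, strat, sign, zero_tol = 1e-11) {
  m <- strat$n_settings
  o <- strat$n_outcomes
  L <- strat$n
  B <- herm_basis_2()
  zero_ax <- matrix(FALSE, o, m)
  for (x in seq_len(m)) {
    for (a in seq_len(o)) {
      zero_ax[a, x] <- Re(mat_trace(members[[x]][[a]])) < zero_tol
    }
  }
  keep_lambda <- seq_len(L)
  if (sign > 0 && any(zero_ax)) {
    fixed <- unique(unlist(lapply(which(zero_ax), function(i) {
      a <- (i - 1L) %% o + 1L
      x <- (i - 1L) %/% o + 1L
      which(strat$d[a, x, ] == 1)
    })))
    keep_lambda <- setdiff(keep_lambda, fixed)
  }
  Ln <- length(keep_lambda)
  lam_block <- integer(L)
  lam_block[keep_lambda] <- seq_len(Ln)
  nz <- which(!zero_ax)                      # linear indices (a, x)
  yblock_of <- integer(o * m)
  yblock_of[nz] <- Ln + seq_along(nz)
  block_dims <- rep(2L, Ln + length(nz))
  constraints <- list()
  b <- numeric(0)
  for (x in seq_len(m)) {
    for (a in seq_len(o)) {
      if (zero_ax[a, x]) next
      lams <- intersect(which(strat$d[a, x, ] == 1), keep_lambda)
      yb <- yblock_of[(x - 1L) * o + a]
      for (k in seq_len(4)) {
        constraints[[length(constraints) + 1L]] <- list(
          blocks = c(yb, lam_block[lams]),
          mats = c(list(sign * B[[k]]), rep(list(B[[k]]), length(lams)))
        )
        b <- c(b, Re(mat_trace(B[[k]] %*% members[[x]][[a]])))
      }
    }
  }
  list(block_dims = block_dims, constraints = constraints, b = b,
       L = L, n_kept = Ln, keep_lambda = keep_lambda)
}

# Re-insert the eliminated (identically zero) certificate members.
expand_certificate <- function(Xblocks, prog) {
  cert <- rep(list(matrix(0i, 2, 2)), prog$L)
  cert[prog$keep_lambda] <- Xblocks[seq_len(prog$n_kept)]
  cert
}

#' Spatio-temporal steering weight
#'
#' The minimal steerable fraction in a convex split of the assemblage into
#' an unsteerable and an arbitrary part:
#' \deqn{\mathrm{STSW} = \min\Big(1 - \mathrm{tr}\sum_\lambda \rho_\lambda\Big)
#'   \quad \text{s.t.} \quad \sigma_{a|x} - \sum_\lambda p(a|x,\lambda)
#'   \rho_\lambda \ge 0, \quad \rho_\lambda \ge 0,}
#' a semidefinite program over the deterministic strategies \eqn{\lambda}.
#' The value is 0 exactly when the assemblage admits a hidden-state model.
#'
#' @param assemblage an `sts_assemblage`.
#' @param clip_tol pre-solve Hermitization/eigenvalue-clip tolerance.
#' @param tol solver tolerance.
#' @return An `sts_steering_result` with fields `value` (in \eqn{[0, 1]}),
#'   `certificate` (the optimal \eqn{\rho_\lambda}), `mu`
#'   (\eqn{\mathrm{tr}\sum_\lambda\rho_\lambda}), solver diagnostics, and
#'   `constraint_residual` (most negative eigenvalue across the reconstructed
#'   program constraints; near zero at optimality).
#' @export
sts_weight <- function(assemblage, clip_tol = 1e-10, tol = 1e-9) {
  members <- prep_members(assemblage, clip_tol)
  strat <- enumerate_strategies(assemblage$n_settings, assemblage$n_outcomes)
  prog <- primal_program(members, strat, sign = +1)
  C <- c(rep(list(-diag(2) + 0i), prog$n_kept),
         rep(list(matrix(0i, 2, 2)), length(prog$block_dims) - prog$n_kept))
  sol <- solve_sdp(C, prog$constraints, prog$b, prog$block_dims, tol = tol)
  check_solver(sol, "STS weight")
  cert <- expand_certificate(sol$X, prog)
  mu <- sum(vapply(cert, function(r) Re(mat_trace(r)), numeric(1)))
  value <- min(max(1 - mu, 0), 1)
  resid <- certificate_residual(members, strat, cert, sign = +1)
  new_steering_result("weight", value, cert, sol,
                      list(mu = mu, constraint_residual = resid))
}

#' Spatio-temporal steering robustness
#'
#' The minimal amount \eqn{\alpha} of noise assemblage that must be mixed
#' in to render the assemblage unsteerable:
#' \deqn{\mathrm{STSR} = \min\Big(\mathrm{tr}\sum_\lambda \rho_\lambda - 1\Big)
#'   \quad \text{s.t.} \quad \sum_\lambda p(a|x,\lambda)\rho_\lambda -
#'   \sigma_{a|x} \ge 0, \quad \rho_\lambda \ge 0.}
#' When the value \eqn{\alpha} is positive, the implied optimal noise
#' assemblage \eqn{\tau_{a|x} = (\sum_\lambda d_\lambda(a|x)\rho_\lambda -
#' \sigma_{a|x})/\alpha} is returned as well; the program optimizes over
#' \eqn{\tau} implicitly, so no extra decision variables are needed.
#'
#' @inheritParams sts_weight
#' @return An `sts_steering_result` with `value` (\eqn{\ge 0}),
#'   `certificate`, `noise_assemblage` (when the value is positive) and
#'   solver diagnostics.
#' @export
sts_robustness <- function(assemblage, clip_tol = 1e-10, tol = 1e-9) {
  members <- prep_members(assemblage, clip_tol)
  strat <- enumerate_strategies(assemblage$n_settings, assemblage$n_outcomes)
  prog <- primal_program(members, strat, sign = -1)
  C <- c(rep(list(diag(2) + 0i), prog$n_kept),
         rep(list(matrix(0i, 2, 2)), length(prog$block_dims) - prog$n_kept))
  sol <- solve_sdp(C, prog$constraints, prog$b, prog$block_dims, tol = tol)
  check_solver(sol, "STS robustness")
  cert <- expand_certificate(sol$X, prog)
  trsum <- sum(vapply(cert, function(r) Re(mat_trace(r)), numeric(1)))
  value <- max(trsum - 1, 0)
  resid <- certificate_residual(members, strat, cert, sign = -1)
  tau <- NULL
  if (value > 1e-9) {
    tau <- lapply(seq_len(assemblage$n_settings), function(x) {
      lapply(seq_len(assemblage$n_outcomes), function(a) {
        lams <- which(strat$d[a, x, ] == 1)
        acc <- Reduce(`+`, cert[lams])
        (acc - members[[x]][[a]]) / value
      })
    })
    tau <- new_assemblage(tau, time = assemblage$time,
                          metadata = list(description = "optimal noise"))
  }
  new_steering_result("robustness", value, cert, sol,
                      list(noise_assemblage = tau,
                           constraint_residual = resid))
}

# Most negative eigenvalue over all reconstructed semidefinite constraints
# of a primal certificate (>= -tol at a valid optimum).
certificate_residual <- function(members, strat, cert, sign) {
  worst <- 0
  for (x in seq_len(strat$n_settings)) {
    for (a in seq_len(strat$n_outcomes)) {
      lams <- which(strat$d[a, x, ] == 1)
      acc <- Reduce(`+`, cert[lams])
      slack <- sign * (members[[x]][[a]] - acc)
      worst <- min(worst, min_eigenvalue(slack))
    }
  }
  for (r in cert) {
    worst <- min(worst, min_eigenvalue(r))
  }
  worst
}

check_solver <- function(sol, what) {
  if (!sol$status %in% c("optimal", "inaccurate")) {
    stop(what, " solver did not converge (status ", sol$status,
         ", primal infeas ", format(sol$primal_infeas),
         ", dual infeas ", format(sol$dual_infeas), ")", call. = FALSE)
  }
  invisible(sol)
}

#' Hidden-state model feasibility
#'
#' Decides whether the assemblage admits the spatio-temporal hidden-state
#' decomposition \eqn{\sigma_{a|x} = \sum_\lambda p(a|x,\lambda)
#' \rho_\lambda} with \eqn{\rho_\lambda \ge 0}, i.e. whether it is
#' unsteerable.  Implemented in two stages, independent of the weight and
#' robustness programs: a least-squares consistency check of the linear
#' member equations (which already fails for signalling assemblages), then
#' a phase-I semidefinite program minimizing the uniform negativity
#' \eqn{t} such that \eqn{\rho_\lambda + t\,\mathbb{1} \ge 0}; the model is
#' feasible exactly when the optimum satisfies \eqn{t^\ast \le} `tol`.
#'
#' @param assemblage an `sts_assemblage`.
#' @param tol feasibility tolerance on the optimal negativity
#'   \eqn{t^\ast}; the default matches the package-wide convention that an
#'   assemblage counts as steerable when a measure exceeds `1e-6` (the
#'   phase-I optimum sits exactly on the cone boundary for unsteerable
#'   models built from pure hidden states, so a tighter cut would
#'   misclassify solver-accuracy-level positives).
#' @param clip_tol pre-solve Hermitization/eigenvalue-clip tolerance.
#' @return A list with `feasible` (flag), `certificate` (the
#'   \eqn{\rho_\lambda} when feasible), `t_star` (the optimal negativity),
#'   `lsq_residual` (linear-consistency residual) and `status`.
#' @export
check_hidden_state_model <- function(assemblage, tol = 1e-6,
                                     clip_tol = 1e-10) {
  members <- prep_members(assemblage, clip_tol)
  strat <- enumerate_strategies(assemblage$n_settings, assemblage$n_outcomes)
  m <- strat$n_settings
  o <- strat$n_outcomes
  L <- strat$n
  B <- herm_basis_2()

  # stage 1: linear consistency over Hermitian rho_lambda (4 real
  # coordinates each: s11, s22, re s12, im s12)
  coords <- function(s) c(Re(s[1, 1]), Re(s[2, 2]), Re(s[1, 2]), Im(s[1, 2]))
  nrow_sys <- 4 * m * o
  Amat <- matrix(0, nrow_sys, 4 * L)
  bvec <- numeric(nrow_sys)
  r <- 0L
  for (x in seq_len(m)) {
    for (a in seq_len(o)) {
      lams <- which(strat$d[a, x, ] == 1)
      cc <- coords(members[[x]][[a]])
      for (k in 1:4) {
        r <- r + 1L
        for (lam in lams) {
          Amat[r, 4 * (lam - 1) + k] <- 1
        }
        bvec[r] <- cc[k]
      }
    }
  }
  lsq_residual <- sqrt(sum(qr.resid(qr(Amat), bvec)^2))
  if (lsq_residual > 1e-6) {
    return(list(feasible = FALSE, certificate = NULL, t_star = Inf,
                lsq_residual = lsq_residual,
                status = "linearly_inconsistent"))
  }

  # stage 2: phase-I SDP.  Blocks: Q_lambda = rho_lambda + (u - 1) I >= 0
  # and the scalar u >= 0 (t = u - 1; t* > -1 always since
  # tr sum rho_lambda = 1).  Constraints: the member equalities rewritten
  # in terms of Q and u; objective min u.
  qr_keep <- qr(t(Amat))
  keep <- sort(qr_keep$pivot[seq_len(qr_keep$rank)])
  block_dims <- c(rep(2L, L), 1L)
  ublock <- L + 1L
  constraints <- list()
  b2 <- numeric(0)
  row_meta <- list()
  r <- 0L
  for (x in seq_len(m)) {
    for (a in seq_len(o)) {
      lams <- which(strat$d[a, x, ] == 1)
      c_ax <- length(lams)
      for (k in 1:4) {
        r <- r + 1L
        if (!(r %in% keep)) next
        tr_bk_id <- if (k <= 2) 1 else 0
        constraints[[length(constraints) + 1L]] <- list(
          blocks = c(lams, ublock),
          mats = c(rep(list(B[[k]]), c_ax),
                   list(matrix(-c_ax * tr_bk_id + 0i, 1, 1)))
        )
        b2 <- c(b2, Re(mat_trace(B[[k]] %*% members[[x]][[a]])) -
                  c_ax * tr_bk_id)
      }
    }
  }
  C <- c(rep(list(matrix(0i, 2, 2)), L), list(matrix(1 + 0i, 1, 1)))
  sol <- solve_sdp(C, constraints, b2, block_dims)
  check_solver(sol, "hidden-state feasibility")
  u <- Re(sol$X[[ublock]][1, 1])
  t_star <- u - 1
  feasible <- t_star <= tol
  cert <- NULL
  if (feasible) {
    cert <- lapply(sol$X[seq_len(L)], function(Q) {
      psd_clip(Q - t_star * diag(2), tol = 1)
    })
  }
  list(feasible = feasible, certificate = cert, t_star = t_star,
       lsq_residual = lsq_residual, status = sol$status)
}

# --- dual formulations (independent cross-checks) ----------------------------

#' Dual formulations of the steering measures
#'
#' Independently coded second formulations of the weight and robustness
#' programs, obtained by Lagrangian duality:
#' \deqn{\mathrm{STSW} = \max\Big(1 - \sum_{a,x}\mathrm{tr}(G_{a|x}
#'   \sigma_{a|x})\Big) \ \text{s.t.}\ \sum_{a,x} d_\lambda(a|x) G_{a|x}
#'   \ge \mathbb{1},\ G_{a|x} \ge 0,}
#' \deqn{\mathrm{STSR} = \max\Big(\sum_{a,x}\mathrm{tr}(G_{a|x}
#'   \sigma_{a|x}) - 1\Big) \ \text{s.t.}\ \sum_{a,x} d_\lambda(a|x) G_{a|x}
#'   \le \mathbb{1},\ G_{a|x} \ge 0.}
#' Strong duality holds for these programs, so the values agree with
#' [sts_weight()] / [sts_robustness()] up to solver tolerance; the package
#' test-suite uses this as a correctness oracle.
#'
#' @inheritParams sts_weight
#' @return An `sts_steering_result`; the certificate holds the optimal
#'   \eqn{G_{a|x}} (row-major in `x` then `a`).
#' @name steering_duals
NULL

dual_program <- function(assemblage, sense, clip_tol = 1e-10, tol = 1e-9) {
  members <- prep_members(assemblage, clip_tol)
  strat <- enumerate_strategies(assemblage$n_settings, assemblage$n_outcomes)
  m <- strat$n_settings
  o <- strat$n_outcomes
  L <- strat$n
  B <- herm_basis_2()
  # blocks: G_ax (m*o of them) then S_lambda slacks
  gblock <- function(a, x) (x - 1L) * o + a
  block_dims <- rep(2L, m * o + L)
  sign <- if (sense == "weight") -1 else +1   # S = sign*(I - sum d G) with
  # weight: S = sum d G - I >= 0 ; robustness: S = I - sum d G >= 0
  constraints <- list()
  b <- numeric(0)
  for (lam in seq_len(L)) {
    axs <- lapply(seq_len(m), function(x) gblock(strat$table[lam, x], x))
    for (k in 1:4) {
      tr_bk_id <- if (k <= 2) 1 else 0
      constraints[[length(constraints) + 1L]] <- list(
        blocks = c(m * o + lam, unlist(axs)),
        mats = c(list(sign * B[[k]]), rep(list(B[[k]]), m))
      )
      b <- c(b, tr_bk_id)
    }
  }
  csign <- if (sense == "weight") +1 else -1
  C <- c(lapply(seq_len(m * o), function(i) {
    x <- (i - 1L) %/% o + 1L
    a <- (i - 1L) %% o + 1L
    csign * members[[x]][[a]]
  }), rep(list(matrix(0i, 2, 2)), L))
  sol <- solve_sdp(C, constraints, b, block_dims, tol = tol)
  check_solver(sol, paste("dual", sense))
  G <- sol$X[seq_len(m * o)]
  value <- if (sense == "weight") {
    min(max(1 - sol$pobj, 0), 1)
  } else {
    max(-sol$pobj - 1, 0)
  }
  new_steering_result(paste0(sense, "_dual"), value, G, sol)
}

#' @rdname steering_duals
#' @export
sts_weight_dual <- function(assemblage, clip_tol = 1e-10, tol = 1e-9) {
  dual_program(assemblage, "weight", clip_tol, tol)
}

#' @rdname steering_duals
#' @export
sts_robustness_dual <- function(assemblage, clip_tol = 1e-10, tol = 1e-9) {
  dual_program(assemblage, "robustness", clip_tol, tol)
}
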