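# Primal-dual interior-point solver for small block-diagonal Hermitian
# semidefinite programs.
#
#   primal:  min  <C, X>   s.t.  <A_i, X> = b_i (i = 1..m),  X >= 0
#   dual:    max  b'y      s.t.  Z = C - sum_i y_i A_i >= 0
#
# X, Z and all data are block-diagonal with complex Hermitian blocks
# (<A, B> = Re tr(A B) for Hermitian arguments).  The steering programs
# produce blocks of size 1 or 2 and a few dozen constraints, so a dense
# infeasible-start path-following method with the HKM search direction and a
# Mehrotra predictor-corrector is ample.  Per block the Schur complement is
# accumulated via the identity tr(A_i X A_j Z^{-1}) =
# vec(A_i)^* (Z^{-T} (x) X) vec(A_j), with the constraint matrices kept
# flattened once per solve.

# Constraint representation: `constraints` is a list of length m; element i
# is list(blocks = integer vector, mats = list of matrices) giving the
# nonzero blocks of A_i.

solve_sdp <- function(C, constraints, b, block_dims,
                      tol = 1e-9, max_iter = 150) {
  nb <- length(block_dims)
  m <- length(b)
  ntot <- sum(block_dims)

  # flatten constraints per block: V[[bk]] is an m x dim^2 complex matrix
  # whose row i is vec(A_{i,bk}) (zero when constraint i does not touch bk)
  V <- lapply(seq_len(nb), function(bk) {
    matrix(0i, m, block_dims[bk]^2)
  })
  touching <- vector("list", nb)
  for (i in seq_len(m)) {
    ci <- constraints[[i]]
    for (k in seq_along(ci$blocks)) {
      bk <- ci$blocks[k]
      V[[bk]][i, ] <- as.vector(ci$mats[[k]])
      touching[[bk]] <- c(touching[[bk]], i)
    }
  }
  active <- which(vapply(touching, length, integer(1)) > 0 |
                    vapply(C, function(mm) any(Mod(mm) > 0), logical(1)))
  Vc <- lapply(V, Conj)

  newblocks <- function(val = 1) {
    lapply(block_dims, function(dd) diag(as.complex(val), dd))
  }
  X <- newblocks()
  Z <- newblocks()
  y <- numeric(m)

  inner <- function(P, Q) {
    sum(vapply(seq_len(nb), function(bk) {
      Re(sum(Conj(P[[bk]]) * Q[[bk]]))
    }, numeric(1)))
  }
  # A(X): vector of <A_i, X>
  applyA <- function(Xb) {
    out <- numeric(m)
    for (bk in seq_len(nb)) {
      if (length(touching[[bk]])) {
        out <- out + Re(Vc[[bk]] %*% as.vector(Xb[[bk]]))
      }
    }
    as.numeric(out)
  }
  # A*(y): list of blocks sum_i y_i A_{i,bk}
  applyAt <- function(y) {
    lapply(seq_len(nb), function(bk) {
      dd <- block_dims[bk]
      matrix(as.vector(t(y) %*% V[[bk]]), dd, dd)
    })
  }

  bnorm <- 1 + sqrt(sum(b^2))
  cnorm <- 1 + sqrt(sum(vapply(C, function(mm) sum(Mod(mm)^2), numeric(1))))

  # maximum step keeping block-diagonal PSD; X + alpha*dX >= 0
  max_step <- function(Xb, dXb) {
    alpha <- 1
    for (bk in seq_len(nb)) {
      dd <- block_dims[bk]
      if (dd == 1) {
        xv <- Re(Xb[[bk]][1, 1]); dv <- Re(dXb[[bk]][1, 1])
        if (dv < 0) alpha <- min(alpha, -xv / dv * 0.98)
      } else {
        e <- eigen(herm(Xb[[bk]]), symmetric = TRUE)
        isq <- e$vectors %*% (1 / sqrt(pmax(e$values, 1e-300)) *
                                dagger(e$vectors))
        w <- herm(isq %*% dXb[[bk]] %*% isq)
        lmin <- min(eigen(w, symmetric = TRUE, only.values = TRUE)$values)
        if (lmin < 0) alpha <- min(alpha, -1 / lmin * 0.98)
      }
    }
    alpha
  }

  # inverse through the eigendecomposition with clamped eigenvalues, so a
  # block grazing the cone boundary cannot abort the iteration
  safe_inv <- function(mm) {
    dd <- nrow(mm)
    if (dd == 1) {
      return(matrix(1 / max(Re(mm[1, 1]), 1e-300), 1, 1) + 0i)
    }
    e <- eigen(herm(mm), symmetric = TRUE)
    vals <- pmax(e$values, 1e-14 * max(abs(e$values), 1e-100))
    e$vectors %*% ((1 / vals) * dagger(e$vectors))
  }

  status <- "max_iterations"
  pobj <- dobj <- NA_real_
  mu <- inner(X, Z) / ntot
  best_metric <- Inf
  best <- NULL
  stall <- 0L

  for (iter in seq_len(max_iter)) {
    Zi <- lapply(Z, safe_inv)
    rp <- b - applyA(X)                       # primal residual (vector)
    Aty <- applyAt(y)
    rd <- lapply(seq_len(nb), function(bk) {  # dual residual (blocks)
      herm(C[[bk]] - Aty[[bk]] - Z[[bk]])
    })
    mu <- inner(X, Z) / ntot
    pobj <- inner(C, X)
    dobj <- sum(b * y)
    pinf <- sqrt(sum(rp^2)) / bnorm
    dinf <- sqrt(sum(vapply(rd, function(mm) sum(Mod(mm)^2),
                            numeric(1)))) / cnorm
    relgap <- abs(pobj - dobj) / (1 + abs(pobj) + abs(dobj))
    if (isTRUE(getOption("stsnet.sdp_verbose"))) {
      cat(sprintf("it=%3d pinf=%.2e dinf=%.2e gap=%.2e mu=%.2e\n",
                  iter, pinf, dinf, relgap, mu))
    }
    metric <- max(pinf, dinf, relgap)
    if (metric < best_metric) {
      best <- list(X = X, y = y, Z = Z, pobj = pobj, dobj = dobj,
                   pinf = pinf, dinf = dinf, relgap = relgap, mu = mu)
      stall <- if (metric < 0.98 * best_metric) 0L else stall
      best_metric <- metric
    } else {
      stall <- stall + 1L
    }
    if (pinf < tol && dinf < tol && relgap < tol) {
      status <- "optimal"
      break
    }
    # complementarity exhausted or no progress: the best iterate is as good
    # as this path will get
    if (mu < 1e-13 || stall >= 30L) {
      status <- "stalled"
      break
    }

    # Schur complement M_ij = Re tr(A_i X A_j Z^{-1}) over active blocks
    M <- matrix(0, m, m)
    for (bk in seq_len(nb)) {
      idx <- touching[[bk]]
      if (!length(idx)) next
      K <- t(Zi[[bk]]) %x% X[[bk]]
      Mb <- Re(Conj(V[[bk]][idx, , drop = FALSE]) %*% K %*%
                 t(V[[bk]][idx, , drop = FALSE]))
      M[idx, idx] <- M[idx, idx] + Mb
    }
    M <- (M + t(M)) / 2
    Mf <- tryCatch(chol(M + diag(1e-13 * max(diag(M), 1), m)),
                   error = function(e) NULL)
    if (is.null(Mf)) {
      Mf <- chol(M + diag(1e-9 * max(diag(M), 1), m))
    }

    solve_direction <- function(sig, corrX = NULL, corrZ = NULL) {
      # G = sig*mu*Z^{-1} - X - X rd Z^{-1} (- dXa dZa Z^{-1})
      G <- lapply(seq_len(nb), function(bk) {
        g <- sig * mu * Zi[[bk]] - X[[bk]] -
          X[[bk]] %*% rd[[bk]] %*% Zi[[bk]]
        if (!is.null(corrX)) {
          g <- g - corrX[[bk]] %*% corrZ[[bk]] %*% Zi[[bk]]
        }
        g
      })
      rhs <- rp - applyA(G)
      dy <- backsolve(Mf, forwardsolve(t(Mf), rhs))
      Atdy <- applyAt(dy)
      dZ <- lapply(seq_len(nb), function(bk) {
        herm(rd[[bk]] - Atdy[[bk]])
      })
      dX <- lapply(seq_len(nb), function(bk) {
        herm(G[[bk]] - X[[bk]] %*% (-Atdy[[bk]]) %*% Zi[[bk]])
      })
      list(dX = dX, dy = dy, dZ = dZ)
    }

    # predictor (affine) step
    aff <- solve_direction(0)
    ap <- max_step(X, aff$dX)
    ad <- max_step(Z, aff$dZ)
    Xa <- lapply(seq_len(nb), function(bk) X[[bk]] + ap * aff$dX[[bk]])
    Za <- lapply(seq_len(nb), function(bk) Z[[bk]] + ad * aff$dZ[[bk]])
    mua <- inner(Xa, Za) / ntot
    sig <- min(max((mua / mu)^3, 1e-6), 1)

    # corrector step
    dXa_s <- lapply(seq_len(nb), function(bk) ap * aff$dX[[bk]])
    dZa_s <- lapply(seq_len(nb), function(bk) ad * aff$dZ[[bk]])
    dir <- solve_direction(sig, corrX = dXa_s, corrZ = dZa_s)
    ap <- max_step(X, dir$dX)
    ad <- max_step(Z, dir$dZ)
    if (ap < 1e-10 && ad < 1e-10) {
      status <- "stalled"
      break
    }
    X <- lapply(seq_len(nb), function(bk) herm(X[[bk]] + ap * dir$dX[[bk]]))
    y <- y + ad * dir$dy
    Z <- lapply(seq_len(nb), function(bk) herm(Z[[bk]] + ad * dir$dZ[[bk]]))
  }

  if (!is.null(best) && best_metric <= max(pinf, dinf, relgap)) {
    X <- best$X; y <- best$y; Z <- best$Z
    pobj <- best$pobj; dobj <- best$dobj; mu <- best$mu
    pinf <- best$pinf; dinf <- best$dinf; relgap <- best$relgap
  }
  if (status != "optimal") {
    if (pinf < tol && dinf < tol && relgap < tol) {
      status <- "optimal"
    } else if (pinf < 1e-7 && dinf < 1e-7 && relgap < 1e-7) {
      # fully converged for practical purposes
      status <- "optimal"
    } else if (pinf < 1e-6 && dinf < 1e-6 && relgap < 5e-5) {
      # weakly feasible instances (rank-deficient members) cannot reach the
      # target accuracy; accept a looser but still tight solution
      status <- "inaccurate"
    }
  }
  list(X = X, y = y, Z = Z, pobj = pobj, dobj = dobj,
       gap = abs(pobj - dobj), mu = mu, iterations = iter,
       primal_infeas = pinf, dual_infeas = dinf, status = status)
}

# Hermitian 2x2 coordinate basis used to turn a Hermitian matrix equality
# into 4 real scalar equalities: tr(B_k S) picks out S11, S22, 2 Re S12,
# -2 Im S12.
herm_basis_2 <- function() {
  list(
    matrix(c(1, 0, 0, 0), 2, 2) + 0i,
    matrix(c(0, 0, 0, 1), 2, 2) + 0i,
    matrix(c(0, 1, 1, 0), 2, 2) + 0i,
    matrix(c(0i, 1i, -1i, 0i), 2, 2)
  )
}
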