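#' Lindblad model: Hamiltonian plus dissipators
#'
#' Defines the generator of a Markovian master equation in the
#' prefactor-free convention
#' \deqn{\dot\rho = -\frac{i}{\hbar}[H,\rho] +
#'   \sum_k \gamma_k (2 A_k \rho A_k^\dagger - A_k^\dagger A_k \rho
#'   - \rho A_k^\dagger A_k),}
#' with \eqn{\hbar = 1}.  Note the absence of the conventional factor 1/2 in
#' front of the dissipator: rates entered here are half the standard-form
#' (GKSL) rates, and sigma-z dephasing rates additionally differ from
#' site-projector rates by a factor of 8 (see [dephasing_rate_convert()]).
#'
#' @param hamiltonian Hermitian matrix on `space`.
#' @param dissipators list of `list(rate = , op = )` pairs; each `op` is a
#'   matrix on `space`, each `rate` a nonnegative scalar.
#' @param space the [state_space()] the operators act on.
#' @param units `"angular"` (energies/rates already angular frequencies in
#'   the chosen time unit) or `"cm-1"` (converted via [cm1_to_angular()]).
#' @param convert_rates when `units = "cm-1"`, also convert dissipator rates
#'   with the same \eqn{2\pi c} factor (default `TRUE`).
#' @return An object of class `sts_lindblad`.
#' @export
lindblad_model <- function(hamiltonian, dissipators = list(), space,
                           units = c("angular", "cm-1"),
                           convert_rates = TRUE) {
  units <- match.arg(units)
  stopifnot(inherits(space, "sts_space"))
  d <- space$dimension
  hamiltonian <- as.matrix(hamiltonian)
  if (!all(dim(hamiltonian) == c(d, d))) {
    stop("hamiltonian dimension does not match the state space",
         call. = FALSE)
  }
  if (!is_hermitian(hamiltonian, 1e-8)) {
    stop("hamiltonian must be Hermitian", call. = FALSE)
  }
  dissipators <- lapply(dissipators, function(dd) {
    if (is.null(dd$rate) || is.null(dd$op)) {
      stop("each dissipator needs `rate` and `op`", call. = FALSE)
    }
    if (dd$rate < 0) {
      stop("dissipator rates must be nonnegative", call. = FALSE)
    }
    op <- as.matrix(dd$op)
    if (!all(dim(op) == c(d, d))) {
      stop("dissipator operator dimension mismatch", call. = FALSE)
    }
    list(rate = as.numeric(dd$rate), op = op + 0i, label = dd$label)
  })
  if (units == "cm-1") {
    hamiltonian <- cm1_to_angular(hamiltonian)
    if (convert_rates) {
      dissipators <- lapply(dissipators, function(dd) {
        dd$rate <- cm1_to_angular(dd$rate)
        dd
      })
    }
  }
  structure(
    list(space = space, hamiltonian = hamiltonian + 0i,
         dissipators = dissipators),
    class = "sts_lindblad"
  )
}

#' @export
print.sts_lindblad <- function(x, ...) {
  cat("<sts_lindblad> on", x$space$dimension, "dimensional sector,",
      length(x$dissipators), "dissipator(s)\n")
  invisible(x)
}

#' Right-hand side of the master equation
#'
#' @param rho density matrix (may be subnormalized).
#' @param model an [lindblad_model()].
#' @return Matrix derivative \eqn{\dot\rho}.
#' @export
lindblad_rhs <- function(rho, model) {
  stopifnot(inherits(model, "sts_lindblad"))
  rho <- as.matrix(rho) + 0i
  d <- model$space$dimension
  if (!all(dim(rho) == c(d, d))) {
    stop("state dimension does not match the model's space", call. = FALSE)
  }
  H <- model$hamiltonian
  out <- -1i * (H %*% rho - rho %*% H)
  for (dd in model$dissipators) {
    A <- dd$op
    Ad <- dagger(A)
    AdA <- Ad %*% A
    out <- out + dd$rate *
      (2 * (A %*% rho %*% Ad) - AdA %*% rho - rho %*% AdA)
  }
  out
}

# Matrix representation of the generator acting on vec(rho) (column-major).
liouvillian <- function(model) {
  d <- model$space$dimension
  I <- diag(as.complex(1), d)
  H <- model$hamiltonian
  L <- -1i * (I %x% H - t(H) %x% I)
  for (dd in model$dissipators) {
    A <- dd$op
    Ad <- dagger(A)
    AdA <- Ad %*% A
    L <- L + dd$rate *
      (2 * (Conj(A) %x% A) - I %x% AdA - t(AdA) %x% I)
  }
  L
}

#' Propagate a state along the master equation
#'
#' Integrates the vectorized master equation with the adaptive complex ODE
#' solver `deSolve::zvode` at tight tolerances, returning the trajectory on
#' the requested time grid.  Works for subnormalized inputs (the generator
#' is linear).
#'
#' @param rho0 initial density matrix (possibly subnormalized).
#' @param model an [lindblad_model()].
#' @param times ordered time grid starting at 0.
#' @param rtol,atol integrator tolerances.
#' @param maxsteps maximum internal integrator steps between grid times.
#' @return List of density matrices, one per grid time, with the time grid
#'   attached as attribute `"times"`.
#' @examples
#' sp <- state_space(1)
#' mod <- lindblad_model(matrix(0, 2, 2), space = sp)
#' tr <- evolve(diag(c(0.5, 0.5)), mod, c(0, 1, 2))
#' @export
evolve <- function(rho0, model, times, rtol = 1e-10, atol = 1e-12,
                   maxsteps = 50000) {
  stopifnot(inherits(model, "sts_lindblad"))
  d <- model$space$dimension
  rho0 <- as.matrix(rho0) + 0i
  if (!all(dim(rho0) == c(d, d))) {
    stop("state dimension does not match the model's space", call. = FALSE)
  }
  if (length(times) < 1 || abs(times[1]) > 1e-14) {
    stop("`times` must start at 0", call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (length(times) == 1) {
    out <- list(rho0)
    attr(out, "times") <- times
    return(out)
  }
  L <- liouvillian(model)
  rhs <- function(t, y, parms) list(parms %*% y)
  sol <- deSolve::zvode(y = as.vector(rho0), times = times, func = rhs,
                        parms = L, rtol = rtol, atol = atol,
                        maxsteps = maxsteps)
  if (nrow(sol) < length(times)) {
    stop("integrator failed before reaching the final time (istate = ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  }
  traj <- lapply(seq_along(times), function(i) {
    matrix(sol[i, -1], d, d)
  })
  attr(traj, "times") <- times
  traj
}

# --- model JSON serialization ------------------------------------------------

#' Write / read a Lindblad model as JSON
#'
#' The interchange format stores the Hamiltonian in cm\eqn{^{-1}} together
#' with named dissipators:
#' `{n_sites, include_reaction_center, hamiltonian_cm1, dissipators:
#' [{rate_cm1, operator: {name, site}}]}`.  Complex Hamiltonians are stored
#' as `{re, im}` pairs.  Only dissipators built from named site operators
#' (`sigma_z`, `raise`, `lower`, or the sink `sink_from_3`) survive the
#' round trip.
#'
#' @param model an [lindblad_model()] (with fields still in cm\eqn{^{-1}};
#'   use `write_model_json` on the raw parameter set).
#' @param n_sites,include_reaction_center,hamiltonian_cm1,dissipators
#'   components of the serialized model.
#' @param path file path.
#' @return `read_model_json` returns a list with the deserialized fields;
#'   `model_from_json_spec` builds the `sts_lindblad`.
#' @name model_json
NULL

#' @rdname model_json
#' @export
write_model_json <- function(n_sites, include_reaction_center,
                             hamiltonian_cm1, dissipators, path) {
  H <- as.matrix(hamiltonian_cm1)
  obj <- list(
    n_sites = n_sites,
    include_reaction_center = include_reaction_center,
    hamiltonian_cm1 = complex_matrix_to_json(H),
    dissipators = lapply(dissipators, function(dd) {
      list(rate_cm1 = dd$rate_cm1, operator = dd$operator)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$hamiltonian_cm1 <- complex_matrix_from_json(obj$hamiltonian_cm1)
  obj
}

#' @rdname model_json
#' @export
model_from_json_spec <- function(path) {
  obj <- read_model_json(path)
  space <- state_space(obj$n_sites,
                       isTRUE(obj$include_reaction_center))
  d <- space$dimension
  Hfull <- matrix(0i, d, d)
  n <- obj$n_sites
  Hfull[1 + seq_len(n), 1 + seq_len(n)] <- obj$hamiltonian_cm1
  diss <- lapply(obj$dissipators, function(dd) {
    op <- dd$operator
    mat <- if (identical(op$name, "sink")) {
      site_operator(space, "raise", "R") %*%
        site_operator(space, "lower", op$site)
    } else {
      site_operator(space, op$name, op$site)
    }
    list(rate = dd$rate_cm1, op = mat, label = op$name)
  })
  lindblad_model(Hfull, diss, space, units = "cm-1")
}

# re/im pair encoding shared by the model and assemblage formats
complex_matrix_to_json <- function(m) {
  if (max(Mod(Im(m))) == 0) {
    return(apply(Re(m), 1, as.list, simplify = FALSE))
  }
  lapply(seq_len(nrow(m)), function(i) {
    lapply(seq_len(ncol(m)), function(j) {
      list(re = Re(m[i, j]), im = Im(m[i, j]))
    })
  })
}

complex_matrix_from_json <- function(rows) {
  n <- length(rows)
  m <- length(rows[[1]])
  out <- matrix(0i, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cell <- rows[[i]][[j]]
      out[i, j] <- if (is.list(cell)) {
        complex(real = cell$re, imaginary = cell$im %||% 0)
      } else {
        complex(real = cell)
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
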