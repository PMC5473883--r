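#' State space restricted to the vacuum-plus-single-excitation sector
#'
#' A network of `n_sites` two-level sites (optionally plus a reaction
#' center) conserving excitation number can be described, for at most one
#' excitation, on the span of the vacuum state and the states with exactly
#' one site excited.  The basis is ordered `("vac", "e1", ..., "eN")`, with
#' `"eR"` appended when a reaction center is present, so the dimension is
#' `n_sites + 1` (`+ 1` more with the reaction center).
#'
#' @param n_sites number of network sites (at least 1).
#' @param include_reaction_center add an absorbing reaction-center level?
#' @return An object of class `sts_space` with fields `n_sites`,
#'   `include_reaction_center`, `basis_labels` and `dimension`.
#' @examples
#' state_space(3)
#' state_space(7, include_reaction_center = TRUE)$dimension  # 9
#' @export
state_space <- function(n_sites, include_reaction_center = FALSE) {
  if (!is.numeric(n_sites) || length(n_sites) != 1 || is.na(n_sites) ||
      n_sites < 1 || n_sites != round(n_sites)) {
    stop("`n_sites` must be a positive integer", call. = FALSE)
  }
  n_sites <- as.integer(n_sites)
  labels <- c("vac", paste0("e", seq_len(n_sites)),
              if (include_reaction_center) "eR")
  structure(
    list(
      n_sites = n_sites,
      include_reaction_center = isTRUE(include_reaction_center),
      basis_labels = labels,
      dimension = length(labels)
    ),
    class = "sts_space"
  )
}

#' @export
print.sts_space <- function(x, ...) {
  cat("<sts_space> ", x$dimension, "-dimensional single-excitation sector\n",
      sep = "")
  cat("  basis:", paste(x$basis_labels, collapse = ", "), "\n")
  invisible(x)
}

# Matrix index (1-based) of the excited level of `site`; `site` is a site
# number or "R" for the reaction center.
site_index <- function(space, site) {
  stopifnot(inherits(space, "sts_space"))
  if (identical(site, "R") || identical(site, "eR")) {
    if (!space$include_reaction_center) {
      stop("space has no reaction center", call. = FALSE)
    }
    return(space$dimension)
  }
  if (!is.numeric(site) || length(site) != 1 || is.na(site) ||
      site < 1 || site > space$n_sites || site != round(site)) {
    stop("unknown site: ", site, call. = FALSE)
  }
  as.integer(site) + 1L
}

#' Basis ket of the restricted sector
#'
#' @param space an [state_space()] object.
#' @param label a basis label such as `"vac"`, `"e3"` or `"eR"`.
#' @return Complex column vector of length `space$dimension`.
#' @examples
#' basis_ket(state_space(3), "e1")
#' @export
basis_ket <- function(space, label) {
  idx <- match(label, space$basis_labels)
  if (is.na(idx)) {
    stop("unknown basis label: ", label, call. = FALSE)
  }
  v <- complex(space$dimension)
  v[idx] <- 1 + 0i
  v
}

#' Embed a single-site operator into the restricted sector
#'
#' Pauli and ladder operators of site `site`, written on the sector basis.
#' `raise` maps the vacuum to the excited state of the site, `lower` is its
#' adjoint, and `sigma_z` is \eqn{+1} on the site's excited state and
#' \eqn{-1} on every other basis state (in any such state the site is in its
#' ground state).  `sigma_x = raise + lower` and
#' `sigma_y = -i raise + i lower`.
#'
#' @param space an [state_space()] object.
#' @param op_name one of `"raise"`, `"lower"`, `"sigma_z"`, `"sigma_x"`,
#'   `"sigma_y"`, `"identity"`.
#' @param site a site number or `"R"` for the reaction center.
#' @return Complex `dimension x dimension` matrix.
#' @examples
#' site_operator(state_space(1), "sigma_z", 1)  # diag(-1, +1) over (vac, e1)
#' @export
site_operator <- function(space, op_name, site) {
  op_name <- match.arg(op_name,
                       c("raise", "lower", "sigma_z", "sigma_x", "sigma_y",
                         "identity"))
  d <- space$dimension
  if (op_name == "identity") {
    return(diag(as.complex(1), d))
  }
  idx <- site_index(space, site)
  raise <- matrix(0i, d, d)
  raise[idx, 1] <- 1 + 0i
  switch(op_name,
         raise = raise,
         lower = Conj(t(raise)),
         sigma_x = raise + Conj(t(raise)),
         sigma_y = -1i * raise + 1i * Conj(t(raise)),
         sigma_z = {
           m <- diag(as.complex(-1), d)
           m[idx, idx] <- 1 + 0i
           m
         })
}

# Compress a single-qubit operator acting on `site` (2x2, basis (g, e)) into
# the restricted sector: F_gg on every basis state with the site in g, F_ee
# on the excited level, and the off-diagonal elements connecting only the
# vacuum to the excited level (all other couplings leave the sector).
embed_qubit_operator <- function(space, op2, site) {
  stopifnot(is.matrix(op2), all(dim(op2) == c(2L, 2L)))
  d <- space$dimension
  idx <- site_index(space, site)
  m <- diag(as.complex(op2[1, 1]), d)
  m[idx, idx] <- op2[2, 2]
  m[idx, 1] <- op2[2, 1]
  m[1, idx] <- op2[1, 2]
  m
}

# --- small dense-matrix helpers used throughout ------------------------------

herm <- function(m) (m + Conj(t(m))) / 2

mat_trace <- function(m) sum(diag(m))

dagger <- function(m) Conj(t(m))

is_hermitian <- function(m, tol = 1e-8) {
  max(Mod(m - Conj(t(m)))) <= tol * max(1, max(Mod(m)))
}

min_eigenvalue <- function(m) {
  min(eigen(herm(m), symmetric = TRUE, only.values = TRUE)$values)
}

# Hermitian square root with eigenvalue clipping at zero; errors if an
# eigenvalue is more negative than -tol.
psd_sqrt <- function(m, tol = 1e-10) {
  e <- eigen(herm(m), symmetric = TRUE)
  if (min(e$values) < -tol) {
    stop("matrix is not positive semidefinite (min eigenvalue ",
         format(min(e$values)), ")", call. = FALSE)
  }
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * dagger(e$vectors))
}

# Project onto the PSD cone (used to absorb integrator noise before the SDPs).
psd_clip <- function(m, tol = 1e-10) {
  m <- herm(m)
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= 0) {
    return(m)
  }
  if (min(e$values) < -tol) {
    stop("matrix violates positivity beyond tolerance (min eigenvalue ",
         format(min(e$values)), ")", call. = FALSE)
  }
  e$vectors %*% (pmax(e$values, 0) * dagger(e$vectors))
}

# Validate a (possibly subnormalized) density operator.
check_density <- function(m, tol = 1e-8, trace_target = NULL) {
  if (!is_hermitian(m, tol)) {
    stop("density matrix is not Hermitian within tolerance", call. = FALSE)
  }
  if (min_eigenvalue(m) < -tol) {
    stop("density matrix is not positive semidefinite within tolerance",
         call. = FALSE)
  }
  if (!is.null(trace_target) &&
      abs(Re(mat_trace(m)) - trace_target) > tol) {
    stop("density matrix trace deviates from ", trace_target, call. = FALSE)
  }
  invisible(TRUE)
}
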