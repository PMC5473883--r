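#' Measurement assembly (a collection of POVMs)
#'
#' The POVMs \eqn{\{F_{a|x}\}} measured on the chosen node at time 0.  Each
#' element is a 2x2 positive-semidefinite matrix on the node's qubit space
#' (ordered basis `(g, e)`), and the elements of each setting sum to the
#' identity.
#'
#' @param elements nested list: `elements[[x]][[a]]` is the 2x2 POVM element
#'   for outcome `a` of setting `x`.
#' @param labels optional character vector of setting labels.
#' @param tol validation tolerance.
#' @return An object of class `sts_assembly` with fields `n_settings`,
#'   `n_outcomes`, `elements`, `labels`.
#' @export
measurement_assembly <- function(elements, labels = NULL, tol = 1e-10) {
  m <- length(elements)
  o <- length(elements[[1]])
  elements <- lapply(elements, function(setting) {
    lapply(setting, function(F) as.matrix(F) + 0i)
  })
  for (x in seq_len(m)) {
    if (length(elements[[x]]) != o) {
      stop("all settings must have the same number of outcomes",
           call. = FALSE)
    }
    tot <- matrix(0i, 2, 2)
    for (a in seq_len(o)) {
      F <- elements[[x]][[a]]
      if (!all(dim(F) == c(2L, 2L))) {
        stop("POVM elements must be 2x2", call. = FALSE)
      }
      if (!is_hermitian(F, tol) || min_eigenvalue(F) < -tol) {
        stop("POVM element (a = ", a, ", x = ", x,
             ") is not positive semidefinite", call. = FALSE)
      }
      tot <- tot + F
    }
    if (max(Mod(tot - diag(2))) > tol) {
      stop("POVM elements of setting ", x, " do not sum to the identity",
           call. = FALSE)
    }
  }
  if (is.null(labels)) {
    labels <- paste0("x", seq_len(m))
  }
  structure(
    list(n_settings = m, n_outcomes = o, elements = elements,
         labels = labels),
    class = "sts_assembly"
  )
}

#' @export
print.sts_assembly <- function(x, ...) {
  cat("<sts_assembly>", x$n_settings, "setting(s) x", x$n_outcomes,
      "outcome(s):", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' The Pauli X, Y, Z measurement set
#'
#' Three projective settings with elements
#' \eqn{F_{\pm|w} = (1 \pm \sigma_w)/2} for \eqn{w \in \{X, Y, Z\}},
#' outcomes ordered `(+, -)`.  Outcome `+` is the \eqn{+1} eigenvector of
#' the measured Pauli; the \eqn{\sigma_z} \eqn{+1} eigenstate is the excited
#' state, so \eqn{F_{+|Z} = |e\rangle\langle e|}.
#'
#' @return An [measurement_assembly()] with 3 settings and 2 outcomes.
#' @examples
#' pauli_measurement_set()$elements[["Z"]][[1]]  # |e><e|
#' @export
pauli_measurement_set <- function() {
  sx <- matrix(c(0, 1, 1, 0), 2, 2) + 0i
  sy <- matrix(c(0i, -1i, 1i, 0i), 2, 2)      # -i|e><g| + i|g><e|
  sz <- diag(c(-1, 1)) + 0i                   # +1 on the excited state
  I2 <- diag(2) + 0i
  els <- lapply(list(sx, sy, sz), function(s) {
    list((I2 + s) / 2, (I2 - s) / 2)
  })
  names(els) <- c("X", "Y", "Z")
  measurement_assembly(els, labels = c("X", "Y", "Z"))
}
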