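#' Enumerate deterministic response strategies
#'
#' The hidden-state programs sum over the extremal classical behaviours: the
#' deterministic strategies \eqn{\lambda}, each assigning one outcome to
#' every setting, \eqn{d_\lambda(a|x) \in \{0, 1\}} with
#' \eqn{\sum_a d_\lambda(a|x) = 1}.  There are \eqn{o^m} of them; convex
#' weights are absorbed into the \eqn{\rho_\lambda} decision variables, so
#' restricting to deterministic strategies is without loss of generality.
#'
#' @param n_settings,n_outcomes the scenario shape `m`, `o`.
#' @param cap refuse enumerations larger than this many strategies.
#' @return An object of class `sts_strategies`: `table` is an
#'   `o^m x m` integer matrix (row \eqn{\lambda}, column `x`, entry the
#'   chosen outcome), `d` the 0/1 array `d[a, x, lambda]`, ordered
#'   lexicographically in the outcome tuples.
#' @examples
#' enumerate_strategies(3, 2)$n  # 8
#' @export
enumerate_strategies <- function(n_settings, n_outcomes, cap = 4096) {
  m <- as.integer(n_settings)
  o <- as.integer(n_outcomes)
  if (m < 1 || o < 1) {
    stop("`n_settings` and `n_outcomes` must be at least 1", call. = FALSE)
  }
  n <- o^m
  if (n > cap) {
    stop("strategy enumeration would need ", n, " strategies (cap ", cap,
         "); reduce the number of settings or outcomes", call. = FALSE)
  }
  tab <- matrix(0L, n, m)
  for (x in seq_len(m)) {
    # setting 1 is the most significant digit: rows come out sorted
    tab[, x] <- ((seq_len(n) - 1L) %/% o^(m - x)) %% o + 1L
  }
  d <- array(0, dim = c(o, m, n))
  for (lam in seq_len(n)) {
    for (x in seq_len(m)) {
      d[tab[lam, x], x, lam] <- 1
    }
  }
  structure(list(n = n, n_settings = m, n_outcomes = o, table = tab, d = d),
            class = "sts_strategies")
}

#' @export
print.sts_strategies <- function(x, ...) {
  cat("<sts_strategies>", x$n, "deterministic strategies for",
      x$n_settings, "setting(s) x", x$n_outcomes, "outcome(s)\n")
  invisible(x)
}
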