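#' Spatio-temporal assemblages
#'
#' The central object: a table of subnormalized 2x2 target-qubit states
#' \eqn{\sigma_{a|x}(t)}, indexed by outcome `a` and setting `x`, with
#' \eqn{p(a|x) = \mathrm{tr}\,\sigma_{a|x}(t)}.
#'
#' @param members nested list: `members[[x]][[a]]` is a 2x2 matrix.
#' @param time the readout time the assemblage refers to.
#' @param metadata named list carried along (scenario description, target
#'   label, ...).
#' @return An object of class `sts_assemblage`.
#' @export
new_assemblage <- function(members, time = 0, metadata = list()) {
  m <- length(members)
  o <- length(members[[1]])
  members <- lapply(members, function(setting) {
    lapply(setting, function(s) as.matrix(s) + 0i)
  })
  structure(
    list(n_settings = m, n_outcomes = o, members = members, time = time,
         metadata = metadata),
    class = "sts_assemblage"
  )
}

#' @export
print.sts_assemblage <- function(x, ...) {
  cat("<sts_assemblage>", x$n_settings, "setting(s) x", x$n_outcomes,
      "outcome(s) at t =", format(x$time), "\n")
  p <- vapply(x$members, function(s) {
    vapply(s, function(mm) Re(mat_trace(mm)), numeric(1))
  }, numeric(x$n_outcomes))
  cat("  p(a|x):\n")
  print(round(t(p), 4))
  invisible(x)
}

#' Outcome probabilities of an assemblage
#'
#' @param assemblage an `sts_assemblage`.
#' @return `o x m` matrix of `p(a|x)`.
#' @export
assemblage_probabilities <- function(assemblage) {
  vapply(assemblage$members, function(s) {
    vapply(s, function(mm) Re(mat_trace(mm)), numeric(1))
  }, numeric(assemblage$n_outcomes))
}

#' Post-measurement branches of the initial state
#'
#' Applies \eqn{\rho_{a|x} = (\sqrt{F_{a|x}} \otimes 1)\,\rho_0\,
#' (\sqrt{F_{a|x}} \otimes 1)} for every element of the assembly, where the
#' square root is the Hermitian spectral square root (for projective
#' elements \eqn{\sqrt F = F}).  Branch traces are the outcome
#' probabilities \eqn{p(a|x)}.
#'
#' For a network scenario the measurement operator is compressed into the
#' single-excitation sector; this is exact whenever `rho0` has no excited
#' population outside the measured site or the element is diagonal in the
#' site basis (true for every scenario shipped with the package), and a
#' warning is raised otherwise.
#'
#' @param rho0 initial composite density matrix.
#' @param assembly an [measurement_assembly()].
#' @param measured_site measured node.
#' @param space the [state_space()] for network states, or `NULL` for a
#'   two-qubit state (measured qubit first).
#' @return Nested list `branches[[x]][[a]]` of subnormalized states.
#' @export
post_measurement_branches <- function(rho0, assembly, measured_site,
                                      space = NULL) {
  rho0 <- as.matrix(rho0) + 0i
  check_density(rho0, tol = 1e-8)
  lapply(seq_len(assembly$n_settings), function(x) {
    lapply(seq_len(assembly$n_outcomes), function(a) {
      F <- assembly$elements[[x]][[a]]
      sqF <- psd_sqrt(F)
      if (is.null(space)) {
        K <- sqF %x% diag(2)
        K %*% rho0 %*% K
      } else {
        warn_if_sector_leakage(rho0, F, measured_site, space)
        E <- embed_qubit_operator(space, sqF, measured_site)
        E %*% rho0 %*% E
      }
    })
  })
}

warn_if_sector_leakage <- function(rho0, F, measured_site, space) {
  if (Mod(F[1, 2]) < 1e-12) {
    return(invisible(FALSE))
  }
  idx <- site_index(space, measured_site)
  other <- setdiff(seq_len(space$dimension), c(1L, idx))
  if (length(other) && sum(Re(diag(rho0)[other])) > 1e-10) {
    warning("measurement element couples the vacuum to site ", measured_site,
            " while other sites carry excited population; the ",
            "single-excitation-sector compression is then approximate",
            call. = FALSE)
  }
  invisible(TRUE)
}

#' Reduce a network state to one site's qubit
#'
#' Partial trace over everything except `site`, evaluated on the restricted
#' sector: the excited population is \eqn{\langle e_s|\rho|e_s\rangle}, the
#' ground population is the remaining trace, and the only coherence
#' surviving the trace over the other subsystems is
#' \eqn{\langle e|\rho_B|g\rangle = \langle e_s|\rho|\mathrm{vac}\rangle}.
#'
#' @param rho density matrix on `space` (may be subnormalized).
#' @param space an [state_space()].
#' @param site the target site (number or `"R"`).
#' @return 2x2 matrix on the site's `(g, e)` basis.
#' @export
reduce_to_site_qubit <- function(rho, space, site) {
  idx <- site_index(space, site)
  rho <- as.matrix(rho)
  pe <- rho[idx, idx]
  pg <- mat_trace(rho) - pe
  coh <- rho[idx, 1]
  matrix(c(pg, coh, Conj(coh), pe), 2, 2)
}

# Partial trace of a two-qubit state over the first qubit.
reduce_qubit_pair <- function(rho) {
  rho[1:2, 1:2] + rho[3:4, 3:4]
}

# Reduce a full-space state from any scenario to the target qubit.
reduce_scenario_state <- function(scenario, rho) {
  if (scenario$kind == "network") {
    reduce_to_site_qubit(rho, scenario$space, scenario$target_site)
  } else {
    reduce_qubit_pair(rho)
  }
}

#' Assemblage of a scenario at one time
#'
#' Implements \eqn{\sigma_{a|x}(t) = \mathrm{tr}_A\{\Lambda_t[
#' (\sqrt{F_{a|x}} \otimes 1)\rho_0(\sqrt{F_{a|x}} \otimes 1)]\}}: each
#' post-measurement branch is evolved for a duration `t` under the
#' scenario's channel and then reduced to the target qubit.
#'
#' @param scenario an [scenario()].
#' @param t readout time (\eqn{\ge 0}).
#' @param ... passed to the integrator ([evolve()]).
#' @return An `sts_assemblage`.
#' @export
assemblage_at <- function(scenario, t, ...) {
  if (t < 0) {
    stop("`t` must be nonnegative", call. = FALSE)
  }
  times <- if (t == 0) 0 else c(0, t)
  asms <- assemblage_trajectory(scenario, times, ...)
  asms[[length(asms)]]
}

#' Assemblages of a scenario over a time grid
#'
#' Evolves every post-measurement branch once over the full grid (one
#' integrator call per branch) and assembles the reduced members at each
#' grid time.
#'
#' @param scenario an [scenario()].
#' @param times ordered grid starting at 0.
#' @param ... passed to the integrator.
#' @return List of `sts_assemblage`, one per grid time.
#' @export
assemblage_trajectory <- function(scenario, times, ...) {
  branches <- post_measurement_branches(
    scenario$rho0, scenario$assembly, scenario$measured_site, scenario$space
  )
  m <- scenario$assembly$n_settings
  o <- scenario$assembly$n_outcomes
  discard <- identical(scenario$channel$type, "discard")
  trajs <- lapply(branches, function(setting) {
    lapply(setting, function(br) {
      channel_trajectory(scenario$channel, br, times, ...)
    })
  })
  lapply(seq_along(times), function(i) {
    members <- lapply(seq_len(m), function(x) {
      lapply(seq_len(o), function(a) {
        st <- trajs[[x]][[a]][[i]]
        if (discard) st else reduce_scenario_state(scenario, st)
      })
    })
    new_assemblage(members, time = times[i],
                   metadata = list(description = scenario$description,
                                   target = scenario$target_site))
  })
}

#' Validate an assemblage
#'
#' Reports (without enforcing) positivity of every member, the per-setting
#' trace sums, and whether the assemblage is non-signalling across settings
#' (\eqn{\sum_a \sigma_{a|x}} equal for all `x` within `tol`).  Signalling
#' assemblages are legitimate inputs here: in the spatio-temporal setting
#' the measurement disturbance propagates through the channel, which is
#' precisely the effect being quantified.
#'
#' @param assemblage an `sts_assemblage`.
#' @param tol tolerance for all checks.
#' @return A list with a per-member tibble `report`, the per-setting
#'   `trace_sums`, `max_signalling` (largest deviation between the setting
#'   averages), and flags `psd_ok`, `traces_ok`, `non_signalling`.
#' @export
validate_assemblage <- function(assemblage, tol = 1e-8) {
  m <- assemblage$n_settings
  o <- assemblage$n_outcomes
  rows <- list()
  sums <- vector("list", m)
  trace_sums <- numeric(m)
  for (x in seq_len(m)) {
    tot <- matrix(0i, 2, 2)
    for (a in seq_len(o)) {
      s <- assemblage$members[[x]][[a]]
      tot <- tot + s
      rows[[length(rows) + 1L]] <- tibble::tibble(
        setting = x, outcome = a,
        probability = Re(mat_trace(s)),
        min_eigenvalue = min_eigenvalue(s),
        herm_defect = max(Mod(s - dagger(s)))
      )
    }
    sums[[x]] <- tot
    trace_sums[x] <- Re(mat_trace(tot))
  }
  report <- dplyr::bind_rows(rows)
  max_sig <- 0
  if (m > 1) {
    for (x in 2:m) {
      max_sig <- max(max_sig, max(Mod(sums[[x]] - sums[[1]])))
    }
  }
  list(
    report = report,
    trace_sums = trace_sums,
    max_signalling = max_sig,
    psd_ok = all(report$min_eigenvalue >= -tol) &&
      all(report$herm_defect <= tol),
    traces_ok = all(abs(trace_sums - 1) <= tol),
    non_signalling = max_sig <= tol
  )
}

# --- assemblage JSON interchange --------------------------------------------

#' Write / read an assemblage as JSON
#'
#' Format: `{n_settings, n_outcomes, time, members, metadata}` with
#' `members[[x]][[a]]` a 2x2 matrix of `{re, im}` pairs.  The reader
#' validates the assemblage invariants on load (member positivity and
#' per-setting trace sums) unless `validate = FALSE`.
#'
#' @param assemblage an `sts_assemblage`.
#' @param path file path.
#' @param validate check invariants on load?
#' @param tol validation tolerance.
#' @return `read_assemblage` returns the `sts_assemblage`.
#' @name assemblage_json
NULL

#' @rdname assemblage_json
#' @export
write_assemblage <- function(assemblage, path) {
  obj <- list(
    n_settings = assemblage$n_settings,
    n_outcomes = assemblage$n_outcomes,
    time = assemblage$time,
    members = lapply(assemblage$members, function(setting) {
      lapply(setting, function(s) {
        lapply(seq_len(2), function(i) {
          lapply(seq_len(2), function(j) {
            list(re = Re(s[i, j]), im = Im(s[i, j]))
          })
        })
      })
    }),
    metadata = assemblage$metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname assemblage_json
#' @export
read_assemblage <- function(path, validate = TRUE, tol = 1e-6) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  members <- lapply(obj$members, function(setting) {
    lapply(setting, complex_matrix_from_json)
  })
  asm <- new_assemblage(members, time = obj$time %||% 0,
                        metadata = obj$metadata %||% list())
  if (asm$n_settings != obj$n_settings || asm$n_outcomes != obj$n_outcomes) {
    stop("assemblage member table does not match the declared shape",
         call. = FALSE)
  }
  if (validate) {
    v <- validate_assemblage(asm, tol = tol)
    if (!v$psd_ok || !v$traces_ok) {
      stop("assemblage read from ", path, " violates invariants ",
           "(psd_ok = ", v$psd_ok, ", traces_ok = ", v$traces_ok, ")",
           call. = FALSE)
    }
  }
  asm
}
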