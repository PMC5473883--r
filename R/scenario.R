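#' Steering scenarios
#'
#' A scenario bundles everything needed to produce a spatio-temporal
#' assemblage: the initial composite state `rho0`, the node measured at time
#' 0, the target node read out at time `t`, the measurement assembly, and
#' the channel that evolves the post-measurement state.  Two kinds are
#' supported:
#'
#' * `"network"`: `rho0` lives on the single-excitation sector of a site
#'   network ([state_space()]) and the channel is a Lindblad model (or the
#'   identity) on that sector;
#' * `"qubit_pair"`: `rho0` is a plain two-qubit state (measured qubit
#'   first), used for the Einstein-Podolsky-Rosen reduction and null-channel
#'   fixtures.
#'
#' The measured and target node may coincide (the temporal reduction: one
#' system measured at time 0 and read out later).
#'
#' @param kind `"network"` or `"qubit_pair"`.
#' @param rho0 initial density matrix (normalized).
#' @param measured_site,target_site site numbers (network) or qubit indices
#'   1/2 (qubit pair).
#' @param assembly an [measurement_assembly()].
#' @param channel a channel object, see [channel_lindblad()].
#' @param space the [state_space()] (network kind only).
#' @param description free-text label carried into results.
#' @return An object of class `sts_scenario`.
#' @export
scenario <- function(kind = c("network", "qubit_pair"), rho0, measured_site,
                     target_site, assembly, channel, space = NULL,
                     description = "") {
  kind <- match.arg(kind)
  rho0 <- as.matrix(rho0) + 0i
  check_density(rho0, tol = 1e-8, trace_target = 1)
  if (kind == "network") {
    stopifnot(inherits(space, "sts_space"))
    site_index(space, measured_site)
    site_index(space, target_site)
  } else {
    stopifnot(all(dim(rho0) == c(4L, 4L)))
    stopifnot(measured_site %in% 1:2, target_site %in% 1:2)
  }
  stopifnot(inherits(assembly, "sts_assembly"))
  structure(
    list(kind = kind, rho0 = rho0, measured_site = measured_site,
         target_site = target_site, assembly = assembly, channel = channel,
         space = space, description = description),
    class = "sts_scenario"
  )
}

#' @export
print.sts_scenario <- function(x, ...) {
  cat("<sts_scenario> [", x$kind, "] ", x$description, "\n", sep = "")
  cat("  measure node", x$measured_site, "at t = 0,",
      "target node", x$target_site, "\n")
  invisible(x)
}

# --- channels ----------------------------------------------------------------

#' Channels connecting measurement time to readout time
#'
#' `channel_lindblad()` wraps an [lindblad_model()]; `channel_identity()`
#' leaves states untouched (the Einstein-Podolsky-Rosen reduction);
#' `channel_discard()` throws the input away and installs a fixed target
#' qubit state (a null model for a completely broken network link).
#'
#' @param model an [lindblad_model()].
#' @param rho_fixed a 2x2 density matrix.
#' @return A channel object of class `sts_channel`.
#' @name channels
NULL

#' @rdname channels
#' @export
channel_lindblad <- function(model) {
  stopifnot(inherits(model, "sts_lindblad"))
  structure(list(type = "lindblad", model = model), class = "sts_channel")
}

#' @rdname channels
#' @export
channel_identity <- function() {
  structure(list(type = "identity"), class = "sts_channel")
}

#' @rdname channels
#' @export
channel_discard <- function(rho_fixed) {
  rho_fixed <- as.matrix(rho_fixed) + 0i
  check_density(rho_fixed, tol = 1e-8, trace_target = 1)
  structure(list(type = "discard", rho_fixed = rho_fixed),
            class = "sts_channel")
}

# Propagate a (possibly subnormalized) state over a time grid; returns a
# list of matrices aligned with `times`.  For the discard channel the output
# already lives on the target qubit (trace times the fixed state).
channel_trajectory <- function(channel, rho, times, ...) {
  switch(channel$type,
         identity = rep(list(rho), length(times)),
         lindblad = evolve(rho, channel$model, times, ...),
         discard = {
           p <- Re(mat_trace(rho))
           rep(list(p * channel$rho_fixed), length(times))
         },
         stop("unknown channel type: ", channel$type, call. = FALSE))
}
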