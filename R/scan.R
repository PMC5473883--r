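#' Scan a steering measure over a time grid
#'
#' Builds the assemblage of the scenario at every grid time (each branch is
#' propagated once over the whole grid) and solves one semidefinite program
#' per time point.  Individual solver failures are recorded in the `status`
#' column and the scan continues.
#'
#' @param scenario an [scenario()].
#' @param measure `"weight"` or `"robustness"`.
#' @param times ordered time grid starting at 0 (units of the scenario's
#'   model: \eqn{J^{-1}} for the chain, ps for the FMO complex).
#' @param ... passed to the integrator.
#' @return A tibble of class `sts_scan` with columns `time`, `value`,
#'   `measure`, `scenario`, `status`, `iterations`, `residual` (certificate
#'   constraint residual).
#' @examples
#' \donttest{
#' sc <- scan_steering(werner_scenario(1), "weight", c(0, 1))
#' }
#' @export
scan_steering <- function(scenario, measure = c("weight", "robustness"),
                          times, ...) {
  measure <- match.arg(measure)
  asms <- assemblage_trajectory(scenario, times, ...)
  fn <- if (measure == "weight") sts_weight else sts_robustness
  rows <- lapply(seq_along(times), function(i) {
    res <- tryCatch(fn(asms[[i]]), error = function(e) e)
    if (inherits(res, "error")) {
      tibble::tibble(time = times[i], value = NA_real_, measure = measure,
                     scenario = scenario$description,
                     status = paste("error:", conditionMessage(res)),
                     iterations = NA_integer_, residual = NA_real_)
    } else {
      tibble::tibble(time = times[i], value = res$value, measure = measure,
                     scenario = scenario$description,
                     status = res$solver_status,
                     iterations = res$iterations,
                     residual = res$constraint_residual)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sts_scan", class(out))
  out
}

#' Write / read a steering scan as CSV
#'
#' The canonical scan output: a plain CSV preceded by a single `#`-prefixed
#' version header line.  Identical scenario, grid and solver settings
#' reproduce the file byte-for-byte apart from that header.
#'
#' @param scan an `sts_scan` tibble.
#' @param path file path.
#' @return `read_scan_csv` returns the tibble.
#' @name scan_csv
NULL

#' @rdname scan_csv
#' @export
write_scan_csv <- function(scan, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# stsnet scan v",
                    as.character(utils::packageVersion("stsnet"))), con)
  utils::write.csv(as.data.frame(scan), con, row.names = FALSE)
  invisible(path)
}

#' @rdname scan_csv
#' @export
read_scan_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  class(out) <- c("sts_scan", class(out))
  out
}

#' Plot a steering scan
#'
#' @param object an `sts_scan`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sts_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$value,
                               colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time", y = unique(object$measure),
      title = "Spatio-temporal steering scan"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.sts_scan <- function(x, ...) {
  print(autoplot(x, ...))
}

#' @importFrom rlang .data
NULL
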