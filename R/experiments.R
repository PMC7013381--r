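#' Declarative experiment designs
#'
#' Encodes the in-silico analogue of the bench competition experiments:
#' which host population is inoculated, with which phage mix, under which
#' parameters and schedule.
#'
#' Host types: `"sensitive"` starts from wild-type sensitive cells only
#' (`W(0) = N0`); `"crispr_ko"` is the isogenic CRISPR-knockout control
#' (sensitive cells with resistance acquisition forced to `A = 0`); `"bim"`
#' is a bacteriophage-insensitive mutant population (`R(0) = N0`, `W(0) = 0`)
#' whose resistance level is set by a `rho` preset: 1 targeting spacer maps
#' to `rho = 0.5`, 2 spacers to `rho = 0.9` (package conventions; only the
#' 1-spacer value is a reference value of the model).
#'
#' @param host_type `"sensitive"`, `"crispr_ko"` or `"bim"`.
#' @param v1,v2 initial densities of Acr-positive and Acr-negative phage;
#'   either may be 0 for a clonal infection, both 0 for a no-phage control.
#' @param params an [acr_params()] object (host presets may override `A` or
#'   `rho` as described above).
#' @param N0 initial total host density.
#' @param spacers for `host_type = "bim"`, 1 or 2 targeting spacers.
#' @param t_end,sample_times,transfers schedule, as in [acr_simulate()].
#' @return Object of class `acr_design`.
#' @examples
#' d <- acr_design("sensitive", v1 = 100, v2 = 100)
#' tr <- run_design(d)
#' final_phage_ratio(tr)
#' @export
acr_design <- function(host_type = c("sensitive", "crispr_ko", "bim"),
                       v1 = 100, v2 = 100, params = acr_params(),
                       N0 = 1e3, spacers = 1, t_end = 30,
                       sample_times = NULL, transfers = NULL) {
  host_type <- match.arg(host_type)
  if (v1 < 0 || v2 < 0) stop("phage inocula must be >= 0", call. = FALSE)
  if (N0 <= 0) stop("N0 must be > 0", call. = FALSE)
  p <- params
  if (host_type == "crispr_ko") p <- acr_params_modify(p, A = 0)
  if (host_type == "bim") {
    if (!spacers %in% c(1, 2))
      stop("spacers must be 1 or 2", call. = FALSE)
    p <- acr_params_modify(p, rho = c(`1` = 0.5, `2` = 0.9)[[as.character(spacers)]])
  }
  init <- switch(host_type,
                 sensitive = ,
                 crispr_ko = acr_state(W = N0, V1 = v1, V2 = v2),
                 bim = acr_state(R = N0, V1 = v1, V2 = v2))
  structure(list(host_type = host_type, initial = init, params = p,
                 t_end = t_end, sample_times = sample_times,
                 transfers = transfers),
            class = "acr_design")
}

# Replace fields of an acr_params object, re-validating.
#' @keywords internal
acr_params_modify <- function(p, ...) {
  repl <- list(...)
  p[names(repl)] <- repl
  do.call(acr_params, unclass(p))
}

#' @export
print.acr_design <- function(x, ...) {
  cat(sprintf("Experiment design: %s host, V1(0)=%g, V2(0)=%g, t_end=%g\n",
              x$host_type, x$initial[["V1"]], x$initial[["V2"]], x$t_end))
  invisible(x)
}

#' Run an experiment design
#'
#' Deterministically simulates a design; identical designs yield identical
#' trajectories.
#'
#' @param design an [acr_design()] object.
#' @param ... further arguments passed to [acr_simulate()] (e.g. tolerances).
#' @return An `acr_trajectory`.
#' @export
run_design <- function(design, ...) {
  stopifnot(inherits(design, "acr_design"))
  acr_simulate(design$initial, design$params, t_end = design$t_end,
               sample_times = design$sample_times,
               transfers = design$transfers, ...)
}

#' Sweep the Acr lysis probability phi
#'
#' Re-runs a mixed-infection design across a grid of `phi` values, all else
#' fixed, and records the final Acr-positive:Acr-negative phage ratio, the
#' extinction flags and the time-integrated immunosuppressed density
#' \eqn{\int S\,dt} (trapezoidal rule on the sampled trajectory) at each
#' grid point. Increasing `phi` means fewer failed infections of resistant
#' cells, hence fewer immunosuppressed cells that Acr-negative phage could
#' exploit: the ratio grows with `phi`.
#'
#' @param base a mixed-infection [acr_design()] on sensitive hosts.
#' @param phi_grid strictly increasing values in `[0, 1]`; default 11 points
#'   on `[0.05, 0.95]`.
#' @param ... passed to [acr_simulate()].
#' @return Object of class `acr_sweep`: data frame with columns
#'   `grid_value`, `ratio`, `log_ratio`, `v1_extinct`, `v2_extinct`,
#'   `integral_S` (full-horizon \eqn{\int S\,dt}) and `peak_S`
#'   (\eqn{\max_t S}, the accumulation reached during the infection wave);
#'   attribute `vary = "phi"`.
#' @export
sweep_phi <- function(base, phi_grid = seq(0.05, 0.95, length.out = 11), ...) {
  check_sweep_grid(phi_grid)
  if (any(phi_grid < 0 | phi_grid > 1))
    stop("phi_grid values must lie in [0, 1]", call. = FALSE)
  run_sweep(base, phi_grid, "phi",
            function(p, v) acr_params_modify(p, phi = v), ...)
}

#' Sweep the immunosuppression duration 1/gamma
#'
#' As [sweep_phi()], but varying the mean immunosuppression duration
#' `gamma_inv = 1/gamma`. Longer immunosuppression lets immunosuppressed
#' cells accumulate, which Acr-negative phage exploit: the final ratio
#' shrinks as `gamma_inv` grows.
#'
#' @param base a mixed-infection [acr_design()] on sensitive hosts.
#' @param gamma_inv_grid strictly increasing positive durations; default 11
#'   log-spaced points on `[0.1, 10]`.
#' @param ... passed to [acr_simulate()].
#' @return An `acr_sweep` with attribute `vary = "gamma_inv"`.
#' @export
sweep_gamma_inv <- function(base,
                            gamma_inv_grid = exp(seq(log(0.1), log(10),
                                                     length.out = 11)),
                            ...) {
  check_sweep_grid(gamma_inv_grid)
  if (any(gamma_inv_grid <= 0))
    stop("gamma_inv_grid values must be > 0", call. = FALSE)
  run_sweep(base, gamma_inv_grid, "gamma_inv",
            function(p, v) acr_params_modify(p, gamma = 1 / v), ...)
}

#' @keywords internal
check_sweep_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 1L || any(!is.finite(grid)) ||
      (length(grid) > 1L && any(diff(grid) <= 0)))
    stop("sweep grid must be strictly increasing and finite", call. = FALSE)
}

#' @keywords internal
run_sweep <- function(base, grid, vary, modify, ...) {
  stopifnot(inherits(base, "acr_design"))
  rows <- lapply(grid, function(v) {
    d <- base
    d$params <- modify(base$params, v)
    tr <- run_design(d, ...)
    fr <- final_phage_ratio(tr)
    data.frame(grid_value = v, ratio = fr$ratio, log_ratio = fr$log_ratio,
               v1_extinct = fr$v1_extinct, v2_extinct = fr$v2_extinct,
               integral_S = trapezoid(tr$t, tr$S), peak_S = max(tr$S))
  })
  structure(do.call(rbind, rows), vary = vary,
            class = c("acr_sweep", "data.frame"))
}

#' @keywords internal
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

#' @export
print.acr_sweep <- function(x, ...) {
  cat(sprintf("Parameter sweep over %s (%d points)\n", attr(x, "vary"),
              nrow(x)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
plot.acr_sweep <- function(x, ...) {
  lr <- x$log_ratio
  lr[!is.finite(lr)] <- NA
  graphics::plot(x$grid_value, lr, type = "b", pch = 16,
                 log = if (attr(x, "vary") == "gamma_inv") "x" else "",
                 xlab = attr(x, "vary"), ylab = "log(V1/V2) at t_end", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
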