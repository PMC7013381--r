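#' Model parameters for the anti-CRISPR infection model
#'
#' Constructs and validates the full parameter set of the compartment model:
#' sensitive (`W`), CRISPR-resistant (`R`) and immunosuppressed (`S`) bacteria
#' plus free Acr-positive (`V1`) and Acr-negative (`V2`) phage.
#'
#' Adsorption of a free phage to a sensitive cell either lyses it (probability
#' `1 - A`, releasing `B` new particles) or confers CRISPR resistance
#' (probability `A`). An Acr-positive phage adsorbing to a resistant cell is
#' destroyed before `acr` expression with probability `rho`; otherwise it
#' completes lysis with probability `phi` or leaves the cell immunosuppressed
#' with probability `1 - phi`. Immunosuppressed cells revert to the resistant
#' state at rate `gamma`, so `1/gamma` is the mean immunosuppression duration.
#' Bacteria grow logistically at maximal rate `r` with density-dependence
#' intensity `k` and die at rate `m`.
#'
#' Defaults are the mixed-infection reference parameter set
#' (`a = 0.001`, `A = 0.2`, `B = 5`, `rho = 0.5`, `phi = 0.3`, `gamma = 1`)
#' completed by package conventions `r = 1`, `k = 1e-6`, `m = 0.1`.
#'
#' @param a adsorption rate (per phage per cell density per time), `>= 0`.
#' @param A probability that infection of a sensitive cell yields CRISPR
#'   resistance instead of lysis, in `[0, 1]`.
#' @param B burst size (particles released per lysis), `>= 0`.
#' @param rho probability that an Acr-positive phage genome is destroyed on a
#'   resistant cell before `acr` expression, in `[0, 1]`.
#' @param phi probability that, `acr` expression having succeeded, the
#'   Acr-positive phage completes lysis of a resistant cell, in `[0, 1]`.
#' @param gamma reversion rate of immunosuppressed cells (per time), `>= 0`.
#' @param r maximal bacterial growth rate (per time), `>= 0`.
#' @param k intensity of density dependence (inverse cell density), `>= 0`.
#' @param m bacterial mortality rate (per time), `>= 0`.
#'
#' @return An object of class `acr_params`: a named list of the nine rates
#'   and probabilities.
#' @examples
#' p <- acr_params()
#' p$phi
#' acr_params(phi = 0.9, gamma = 1 / 4)
#' @export
acr_params <- function(a = 0.001, A = 0.2, B = 5, rho = 0.5, phi = 0.3,
                       gamma = 1, r = 1, k = 1e-6, m = 0.1) {
  p <- list(a = a, A = A, B = B, rho = rho, phi = phi, gamma = gamma,
            r = r, k = k, m = m)
  validate_acr_params(p)
  p <- lapply(p, as.numeric)  # doubles throughout, so serialised
                              # parameters re-load identically
  structure(p, class = "acr_params")
}

#' @keywords internal
validate_acr_params <- function(p) {
  for (nm in c("a", "A", "B", "rho", "phi", "gamma", "r", "k", "m")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be >= 0 (got ", v, ")", call. = FALSE)
  }
  for (nm in c("A", "rho", "phi")) {
    if (p[[nm]] > 1)
      stop("parameter '", nm, "' must lie in [0, 1] (got ", p[[nm]], ")",
           call. = FALSE)
  }
  # gamma = 0 with an open immunosuppression route means S cells never revert;
  # permitted, but flagged so the run is self-describing.
  if (p$gamma == 0 && p$phi < 1 && p$rho < 1)
    warning("gamma = 0 with phi < 1 and rho < 1: immunosuppressed cells ",
            "accumulate without reversion", call. = FALSE)
  invisible(p)
}

#' @export
print.acr_params <- function(x, ...) {
  cat("Anti-CRISPR infection model parameters\n")
  cat(sprintf("  adsorption a = %g, resistance acquisition A = %g, burst B = %g\n",
              x$a, x$A, x$B))
  cat(sprintf("  resistance rho = %g, Acr lysis phi = %g, reversion gamma = %g (duration 1/gamma = %g)\n",
              x$rho, x$phi, x$gamma, if (x$gamma > 0) 1 / x$gamma else Inf))
  cat(sprintf("  growth r = %g, density dependence k = %g, mortality m = %g\n",
              x$r, x$k, x$m))
  invisible(x)
}

#' Population state of the five compartments
#'
#' Builds a named state vector for the model. Totals `N = W + R + S` and
#' `V = V1 + V2` are always derived, never stored.
#'
#' @param W,R,S densities of sensitive, CRISPR-resistant and immunosuppressed
#'   bacteria (`>= 0`).
#' @param V1,V2 densities of free Acr-positive and Acr-negative phage (`>= 0`).
#' @return Named numeric vector with elements `W`, `R`, `S`, `V1`, `V2`.
#' @examples
#' acr_state(W = 1000, V1 = 100, V2 = 100)
#' @export
acr_state <- function(W = 0, R = 0, S = 0, V1 = 0, V2 = 0) {
  s <- c(W = W, R = R, S = S, V1 = V1, V2 = V2)
  storage.mode(s) <- "double"
  validate_acr_state(s)
  s
}

#' @keywords internal
validate_acr_state <- function(s) {
  if (!is.numeric(s) || length(s) != 5L ||
      !identical(names(s), c("W", "R", "S", "V1", "V2")))
    stop("state must be a named numeric vector (W, R, S, V1, V2)",
         call. = FALSE)
  bad <- names(s)[!is.finite(s)]
  if (length(bad))
    stop("non-finite state density in compartment '", bad[1L], "'",
         call. = FALSE)
  neg <- names(s)[s < 0]
  if (length(neg))
    stop("negative state density in compartment '", neg[1L], "'",
         call. = FALSE)
  invisible(s)
}
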