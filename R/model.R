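#' Time derivatives of the infection model
#'
#' Evaluates the right-hand side of the compartment model at one state:
#' \deqn{\dot W = rW(1-kN) - (aV_1 + aV_2 + m)W}
#' \deqn{\dot R = A a V W + rR(1-kN) - (a(1-\rho)V_1 + m)R + \gamma S}
#' \deqn{\dot S = a(1-\rho)(1-\phi)V_1 R - (aV + m + \gamma)S}
#' \deqn{\dot V_1 = a(1-\rho)\phi B V_1 R + a B V_1(S + (1-A)W) - aNV_1}
#' \deqn{\dot V_2 = a B V_2(S + (1-A)W) - aNV_2}
#' with \eqn{N = W + R + S} and \eqn{V = V_1 + V_2}.
#'
#' @param state named numeric vector from [acr_state()].
#' @param params an [acr_params()] object.
#' @return Named numeric vector of the five derivatives
#'   (`dW`, `dR`, `dS`, `dV1`, `dV2`).
#' @examples
#' acr_rhs(acr_state(W = 100), acr_params(r = 1, k = 0.001, m = 0.1))
#' @export
acr_rhs <- function(state, params) {
  validate_acr_state(state)
  validate_acr_params(params)
  d <- acr_rhs_unsafe(state, params)
  names(d) <- c("dW", "dR", "dS", "dV1", "dV2")
  d
}

# Validation-free RHS used inside the integrator loop.
#' @keywords internal
acr_rhs_unsafe <- function(s, p) {
  W <- s[[1L]]; R <- s[[2L]]; S <- s[[3L]]; V1 <- s[[4L]]; V2 <- s[[5L]]
  N <- W + R + S
  V <- V1 + V2
  growth <- p$r * (1 - p$k * N)
  c(growth * W - (p$a * V + p$m) * W,
    p$A * p$a * V * W + growth * R - (p$a * (1 - p$rho) * V1 + p$m) * R +
      p$gamma * S,
    p$a * (1 - p$rho) * (1 - p$phi) * V1 * R - (p$a * V + p$m + p$gamma) * S,
    p$a * (1 - p$rho) * p$phi * p$B * V1 * R +
      p$a * p$B * V1 * (S + (1 - p$A) * W) - p$a * N * V1,
    p$a * p$B * V2 * (S + (1 - p$A) * W) - p$a * N * V2)
}

#' Simulate the infection model forward in time
#'
#' Integrates the model with a controlled-error stiff-capable method
#' (`deSolve::ode`, lsoda) and optionally applies serial-transfer dilution
#' events. At each transfer time every compartment is multiplied by the
#' dilution factor and a `transfer` event is recorded; a sample time that
#' coincides with a transfer reports the pre-transfer state. Post-step
#' densities in `(-clip_tol, 0)` are treated as integrator round-off and
#' clipped to zero; anything more negative aborts as integrator failure
#' (distinguishing round-off from genuine blow-up). The default
#' `clip_tol = 1e-9` is matched to the default tolerances; looser
#' tolerances warrant a proportionally looser clip. The first
#' time a compartment falls below `extinction_threshold` (having been at or
#' above it) an `extinction` event is recorded; extinction is a reporting
#' concept only — integration continues on the raw values.
#'
#' @param initial named state vector from [acr_state()].
#' @param params an [acr_params()] object.
#' @param t_end end time (model time units), `> 0`.
#' @param sample_times times at which the state is reported; defaults to 301
#'   equally spaced points on `[0, t_end]`. Time 0 is always included.
#' @param transfers optional data frame with columns `time` (strictly
#'   increasing, in `(0, t_end]`) and `dilution` (factors in `(0, 1]`).
#' @param rtol,atol relative and absolute integration tolerances.
#' @param extinction_threshold density below which a compartment is reported
#'   extinct (default `1e-3`, i.e. less than one particle per notional
#'   culture volume).
#' @param clip_tol magnitude below zero still attributed to round-off.
#' @param method integration method passed to [deSolve::ode()].
#' @return An object of class `acr_trajectory`: a data frame with columns
#'   `t`, `W`, `R`, `S`, `V1`, `V2`, `N`, `V` and attributes `params`,
#'   `events` (data frame `time`, `kind`, `detail`) and
#'   `extinction_threshold`.
#' @examples
#' tr <- acr_simulate(acr_state(W = 1000, V1 = 100, V2 = 100), acr_params(),
#'                    t_end = 30)
#' tail(tr, 2)
#' final_phage_ratio(tr)
#' @export
acr_simulate <- function(initial, params, t_end = 30, sample_times = NULL,
                         transfers = NULL, rtol = 1e-8, atol = 1e-10,
                         extinction_threshold = 1e-3, clip_tol = 1e-9,
                         method = "lsoda") {
  validate_acr_state(initial)
  validate_acr_params(params)
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
      t_end <= 0)
    stop("t_end must be a single positive number", call. = FALSE)
  if (is.null(sample_times))
    sample_times <- seq(0, t_end, length.out = 301L)
  sample_times <- sort(unique(c(0, sample_times)))
  if (any(sample_times < 0) || any(sample_times > t_end))
    stop("sample_times must lie in [0, t_end]", call. = FALSE)
  transfers <- validate_transfers(transfers, t_end)

  comp <- c("W", "R", "S", "V1", "V2")
  parvec <- as.numeric(unlist(params[c("a", "A", "B", "rho", "phi", "gamma",
                                       "r", "k", "m")]))

  seg_bounds <- c(0, transfers$time, t_end)
  seg_bounds <- unique(seg_bounds[seg_bounds <= t_end])
  state <- initial
  out_rows <- list(c(t = 0, clip_state(state, 0)))
  events <- data.frame(time = numeric(0), kind = character(0),
                       detail = character(0), stringsAsFactors = FALSE)

  for (i in seq_len(length(seg_bounds) - 1L)) {
    t0 <- seg_bounds[i]; t1 <- seg_bounds[i + 1L]
    if (t1 <= t0) next
    inner <- sample_times[sample_times > t0 & sample_times <= t1]
    times <- unique(c(t0, inner, t1))
    run_ode <- function(meth) deSolve::ode(
      y = state, times = times, func = "acr_derivs",
      initfunc = "acr_initmod", dllname = "acrdyn",
      parms = parvec, method = meth, rtol = rtol, atol = atol)
    sol <- tryCatch(run_ode(method), error = function(e) e)
    if (inherits(sol, "error") || attr(sol, "istate")[1L] < 0 ||
        any(!is.finite(sol))) {
      # lsoda's dense-output interpolation can fail on very stiff decays;
      # retry once with a pure BDF method before declaring failure
      sol <- tryCatch(run_ode("vode"), error = function(e) e)
      if (inherits(sol, "error") || attr(sol, "istate")[1L] < 0 ||
          any(!is.finite(sol)))
        stop(integrator_failure(state, t0), call. = FALSE)
    }
    mat <- unname(sol[, comp, drop = FALSE])
    if (min(mat) <= -clip_tol)
      stop(integrator_failure(state, t0), call. = FALSE)
    keep <- sol[, "time"] %in% inner
    if (any(keep)) {
      kt <- sol[keep, "time"]
      km <- mat[keep, , drop = FALSE]
      for (j in seq_along(kt))
        out_rows[[length(out_rows) + 1L]] <- c(t = kt[j],
                                               clip_state_vec(km[j, ], comp))
    }
    state <- clip_state_vec(mat[nrow(mat), ], comp)
    # transfer event at t1 (unless t1 == t_end with no transfer scheduled)
    ti <- match(t1, transfers$time)
    if (!is.na(ti)) {
      state <- state * transfers$dilution[ti]
      events <- rbind(events, data.frame(
        time = t1, kind = "transfer",
        detail = sprintf("dilution=%g", transfers$dilution[ti]),
        stringsAsFactors = FALSE))
    }
  }

  df <- as.data.frame(do.call(rbind, out_rows))
  names(df) <- c("t", comp)
  df <- df[!duplicated(df$t), , drop = FALSE]
  df <- df[df$t %in% sample_times, , drop = FALSE]
  rownames(df) <- NULL
  df$N <- df$W + df$R + df$S
  df$V <- df$V1 + df$V2

  # first downward crossing of the extinction threshold, per compartment
  for (cn in comp) {
    below <- df[[cn]] < extinction_threshold
    n_s <- length(below)
    cross <- which(below[-1L] & !below[-n_s]) + 1L
    if (length(cross)) {
      events <- rbind(events, data.frame(
        time = df$t[cross[1L]], kind = "extinction", detail = cn,
        stringsAsFactors = FALSE))
    }
  }
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL

  structure(df,
            params = params,
            events = events,
            extinction_threshold = extinction_threshold,
            class = c("acr_trajectory", "data.frame"))
}

#' @keywords internal
validate_transfers <- function(transfers, t_end) {
  if (is.null(transfers))
    return(data.frame(time = numeric(0), dilution = numeric(0)))
  if (!is.data.frame(transfers) ||
      !all(c("time", "dilution") %in% names(transfers)))
    stop("transfers must be a data frame with columns 'time' and 'dilution'",
         call. = FALSE)
  tt <- transfers$time; dd <- transfers$dilution
  if (any(!is.finite(tt)) || any(tt <= 0) || any(tt > t_end) ||
      any(diff(tt) <= 0))
    stop("transfer times must be strictly increasing and lie in (0, t_end]",
         call. = FALSE)
  if (any(!is.finite(dd)) || any(dd <= 0) || any(dd > 1))
    stop("transfer dilution factors must lie in (0, 1]", call. = FALSE)
  data.frame(time = tt, dilution = dd)
}

#' @keywords internal
clip_state_vec <- function(x, comp) {
  x[x < 0] <- 0  # magnitude already checked against the clip_tol abort level
  names(x) <- comp
  x
}

#' @keywords internal
clip_state <- function(s, t) {
  s[s < 0 & s > -1e-9] <- 0
  s
}

#' @keywords internal
integrator_failure <- function(state, t) {
  paste0("integrator failure near t = ", format(t), "; last valid state: ",
         paste(sprintf("%s=%.6g", names(state), state), collapse = ", "))
}

#' @export
print.acr_trajectory <- function(x, ...) {
  ev <- attr(x, "events")
  cat(sprintf("Infection-model trajectory: %d samples on t in [%g, %g]\n",
              nrow(x), min(x$t), max(x$t)))
  last <- x[nrow(x), ]
  cat(sprintf("  final state: W=%.4g R=%.4g S=%.4g V1=%.4g V2=%.4g\n",
              last$W, last$R, last$S, last$V1, last$V2))
  if (nrow(ev)) {
    cat("  events:\n")
    for (i in seq_len(nrow(ev)))
      cat(sprintf("    t=%-8g %s (%s)\n", ev$time[i], ev$kind[i], ev$detail[i]))
  } else cat("  events: none\n")
  invisible(x)
}

#' @export
plot.acr_trajectory <- function(x, log = "y", floor = NULL, ...) {
  if (is.null(floor)) floor <- attr(x, "extinction_threshold") / 10
  comp <- c("W", "R", "S", "V1", "V2")
  mat <- as.matrix(x[comp])
  if (grepl("y", log)) mat <- pmax(mat, floor)
  graphics::matplot(x$t, mat, type = "l", lty = 1, log = log,
                    col = c("grey40", "black", "orange", "red", "blue"),
                    xlab = "time (model units)", ylab = "density", ...)
  graphics::legend("topright", legend = comp, lty = 1,
                   col = c("grey40", "black", "orange", "red", "blue"),
                   bty = "n")
  invisible(x)
}

#' Final Acr-positive to Acr-negative phage ratio
#'
#' Ratio `V1/V2` at the last sampled time of a trajectory, the summary used
#' to quantify the fitness advantage of the Acr-positive phage after
#' infection of sensitive hosts. Extinctions are reported as sentinels, not
#' raw divisions: if `V2` is below the extinction threshold while `V1` is
#' not, the ratio is an "infinite advantage" (`Inf`); the converse gives 0;
#' both extinct gives `NaN` with status `"both_extinct"`.
#'
#' @param traj an `acr_trajectory`.
#' @param threshold extinction threshold; defaults to the trajectory's own.
#' @return List of class `acr_ratio` with elements `ratio`, `log_ratio`,
#'   `status` (`"ok"`, `"v1_extinct"`, `"v2_extinct"` or `"both_extinct"`),
#'   `v1_extinct`, `v2_extinct`, `t`.
#' @export
final_phage_ratio <- function(traj, threshold = NULL) {
  if (!inherits(traj, "acr_trajectory") || nrow(traj) == 0L)
    stop("traj must be a nonempty acr_trajectory", call. = FALSE)
  if (is.null(threshold)) threshold <- attr(traj, "extinction_threshold")
  last <- traj[nrow(traj), ]
  v1e <- last$V1 < threshold
  v2e <- last$V2 < threshold
  if (v1e && v2e) {
    ratio <- NaN; status <- "both_extinct"
  } else if (v2e) {
    ratio <- Inf; status <- "v2_extinct"
  } else if (v1e) {
    ratio <- 0; status <- "v1_extinct"
  } else {
    ratio <- last$V1 / last$V2; status <- "ok"
  }
  structure(list(ratio = ratio, log_ratio = log(ratio), status = status,
                 v1_extinct = v1e, v2_extinct = v2e, t = last$t),
            class = "acr_ratio")
}

#' @export
print.acr_ratio <- function(x, ...) {
  cat(sprintf("V1/V2 at t = %g: %s (status: %s)\n", x$t,
              format(x$ratio), x$status))
  invisible(x)
}
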