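# Independent oracles, written against the model equations directly and
# kept separate from the package's integration path.

# Term-by-term RHS evaluation, spelled out rather than factored, so it can
# disagree with acr_rhs() if either is wrong.
oracle_rhs <- function(W, R, S, V1, V2, a, A, B, rho, phi, gamma, r, k, m) {
  N <- W + R + S
  V <- V1 + V2
  c(dW = r * W * (1 - k * N) - (a * V1 + a * V2 + m) * W,
    dR = A * a * V * W + r * R * (1 - k * N) -
      (a * (1 - rho) * V1 + m) * R + gamma * S,
    dS = a * (1 - rho) * (1 - phi) * V1 * R - (a * V + m + gamma) * S,
    dV1 = a * (1 - rho) * phi * B * V1 * R +
      a * B * V1 * (S + (1 - A) * W) - a * N * V1,
    dV2 = a * B * V2 * (S + (1 - A) * W) - a * N * V2)
}

# Classical fixed-step RK4 using the oracle RHS; returns the state matrix
# at the requested output times (which must be multiples of h).
oracle_rk4 <- function(init, params, t_end, h, out_times) {
  f <- function(y) unname(do.call(oracle_rhs,
                                  c(unname(as.list(y)), unclass(params))))
  y <- unname(init)
  n_steps <- round(t_end / h)
  out <- matrix(NA_real_, length(out_times), 5L,
                dimnames = list(NULL, c("W", "R", "S", "V1", "V2")))
  out_idx <- round(out_times / h)
  hit <- match(0L, out_idx)
  if (!is.na(hit)) out[hit, ] <- y
  for (i in seq_len(n_steps)) {
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    hit <- match(i, out_idx)
    if (!is.na(hit)) out[hit, ] <- y
  }
  out
}

# Reference parameter set used across mixed-infection checks.
ref_params <- function(...) {
  defaults <- list(a = 0.001, A = 0.2, B = 5, rho = 0.5, phi = 0.3,
                   gamma = 1, r = 1, k = 1e-6, m = 0.1)
  do.call(acr_params, utils::modifyList(defaults, list(...)))
}

mixed_design <- function(params = ref_params(), ...) {
  acr_design("sensitive", v1 = 100, v2 = 100, params = params, ...)
}
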