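#' Fraction of a competitor from paired quantities
#'
#' Relative frequency of competitor 1 from paired abundance measurements
#' (colony counts or qPCR quantities): `q1 / (q1 + q2)`.
#'
#' @param q1,q2 non-negative quantities of competitors 1 and 2 (vectorised).
#' @return Fractions in `[0, 1]`; `phage_fraction(q1, q2) +
#'   phage_fraction(q2, q1)` is always 1.
#' @examples
#' phage_fraction(3e7, 1e7)  # 0.75
#' @export
phage_fraction <- function(q1, q2) {
  if (any(q1 < 0, na.rm = TRUE) || any(q2 < 0, na.rm = TRUE))
    stop("quantities must be >= 0", call. = FALSE)
  tot <- q1 + q2
  if (any(tot == 0, na.rm = TRUE))
    stop("undefined fraction: q1 + q2 = 0", call. = FALSE)
  q1 / tot
}

#' Relative fitness of a competitor (odds-ratio form)
#'
#' Change in a competitor's odds between the start and end of a competition:
#' \deqn{w = \frac{f_x (1 - f_0)}{f_0 (1 - f_x)}}
#' where `f_0` and `f_x` are the focal competitor's fractions at the first
#' and later timepoint. Equals 1 when the fractions are unchanged, and the
#' fitness of the other competitor is the exact reciprocal.
#'
#' Boundary fractions (0 or 1) arise when one competitor is below the
#' detection limit; these give sentinel values `Inf` (focal fixed or rival
#' undetected) or `0` (focal undetected), with attribute `boundary` naming
#' which input hit the boundary, and a warning. They are never produced by
#' silent division.
#'
#' @param fraction_t0 focal fraction at the first timepoint.
#' @param fraction_tx focal fraction at the later timepoint.
#' @return Positive relative fitness (vectorised); sentinel `Inf`/`0`/`NaN`
#'   at boundaries, flagged via the `boundary` attribute.
#' @examples
#' relative_fitness(0.5, 0.8)  # 4
#' relative_fitness(0.2, 0.1)  # 4/9
#' @export
relative_fitness <- function(fraction_t0, fraction_tx) {
  f0 <- fraction_t0; fx <- fraction_tx
  if (any(f0 < 0 | f0 > 1 | fx < 0 | fx > 1, na.rm = TRUE))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  n <- max(length(f0), length(fx))
  f0 <- rep_len(f0, n); fx <- rep_len(fx, n)
  w <- numeric(n)
  boundary <- rep(NA_character_, n)
  interior <- f0 > 0 & f0 < 1 & fx > 0 & fx < 1
  w[interior] <- (fx[interior] * (1 - f0[interior])) /
    (f0[interior] * (1 - fx[interior]))
  for (i in which(!interior)) {
    lo <- fx[i] == 0 || f0[i] == 1   # focal undetected at end / rival at start
    hi <- fx[i] == 1 || f0[i] == 0   # rival undetected at end / focal at start
    boundary[i] <- paste(c(
      if (f0[i] == 0) "fraction_t0=0", if (f0[i] == 1) "fraction_t0=1",
      if (fx[i] == 0) "fraction_tx=0", if (fx[i] == 1) "fraction_tx=1"),
      collapse = ",")
    w[i] <- if (lo && hi) NaN else if (hi) Inf else 0
  }
  if (any(!interior))
    warning("boundary fraction(s) (competitor below detection): ",
            paste(unique(boundary[!interior]), collapse = "; "),
            "; sentinel fitness returned", call. = FALSE)
  if (any(!interior)) attr(w, "boundary") <- boundary
  w
}

#' Per-replicate relative fitness from a long-form competition table
#'
#' Computes, for each replicate, the focal competitor's fraction at the two
#' timepoints and the odds-ratio relative fitness. With
#' `average_quantities = TRUE` the quantities are first averaged across
#' replicates (as done for qPCR-derived phage quantities) and a single
#' fitness value is returned.
#'
#' @param obs data frame with columns `replicate`, `timepoint`,
#'   `competitor`, `quantity` (long form).
#' @param focal label of the focal competitor (default: first level found).
#' @param t0,tx the two timepoints compared (defaults: min and max present).
#' @param average_quantities average quantities over replicates before
#'   forming fractions.
#' @return Data frame with columns `replicate`, `fraction_t0`,
#'   `fraction_tx`, `fitness` (one row per replicate, or a single row with
#'   `replicate = "pooled"`).
#' @export
competition_fitness <- function(obs, focal = NULL, t0 = NULL, tx = NULL,
                                average_quantities = FALSE) {
  need <- c("replicate", "timepoint", "competitor", "quantity")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  comps <- unique(obs$competitor)
  if (length(comps) != 2L)
    stop("expected exactly 2 competitors, found ", length(comps),
         call. = FALSE)
  if (is.null(focal)) focal <- comps[1L]
  rival <- setdiff(comps, focal)
  if (length(rival) != 1L)
    stop("focal competitor '", focal, "' not found", call. = FALSE)
  if (is.null(t0)) t0 <- min(obs$timepoint)
  if (is.null(tx)) tx <- max(obs$timepoint)
  if (tx <= t0) stop("tx must be later than t0", call. = FALSE)

  q <- function(rep_id, tp, comp) {
    sel <- obs$timepoint == tp & obs$competitor == comp
    if (!is.null(rep_id)) sel <- sel & obs$replicate == rep_id
    v <- obs$quantity[sel]
    if (is.null(rep_id)) mean(v) else {
      if (length(v) != 1L)
        stop("expected one quantity for replicate ", rep_id, ", timepoint ",
             tp, ", competitor ", comp, call. = FALSE)
      v
    }
  }
  one <- function(rep_id) {
    f0 <- phage_fraction(q(rep_id, t0, focal), q(rep_id, t0, rival))
    fx <- phage_fraction(q(rep_id, tx, focal), q(rep_id, tx, rival))
    data.frame(replicate = if (is.null(rep_id)) "pooled" else rep_id,
               fraction_t0 = f0, fraction_tx = fx,
               fitness = suppressWarnings(relative_fitness(f0, fx)),
               stringsAsFactors = FALSE)
  }
  if (average_quantities) return(one(NULL))
  do.call(rbind, lapply(unique(obs$replicate), one))
}

#' Efficiency of centres of infection (ECOI)
#'
#' Fraction of pre-adsorbed cells that yield a productive infection (a
#' plaque on an indicator lawn): `centres / (cells * moi)`. Values above 1
#' can occur with noisy counts and are flagged with a warning, never
#' clamped. Scale-invariant: multiplying `centres` and `cells * moi` by the
#' same factor leaves the ECOI unchanged.
#'
#' @param centres centres-of-infection (plaque) count, `>= 0`.
#' @param cells pre-adsorbed cell count, `> 0`.
#' @param moi multiplicity of infection used, `> 0`.
#' @return Non-negative ECOI values (vectorised).
#' @examples
#' ecoi(200, 1e4, 1)  # 0.02
#' @export
ecoi <- function(centres, cells, moi) {
  if (any(centres < 0, na.rm = TRUE))
    stop("centres must be >= 0", call. = FALSE)
  if (any(cells <= 0, na.rm = TRUE))
    stop("cells must be > 0", call. = FALSE)
  if (any(moi <= 0, na.rm = TRUE))
    stop("moi must be > 0", call. = FALSE)
  e <- centres / (cells * moi)
  if (any(e > 1, na.rm = TRUE))
    warning("ECOI > 1: more centres than adsorbed phage; counts are noisy",
            call. = FALSE)
  e
}

#' Estimate the Acr lysis probability phi from paired ECOIs
#'
#' Normalises the ECOI on a CRISPR-resistant host by the ECOI on the
#' isogenic CRISPR-knockout host, giving a direct estimate of the success
#' rate of the first infection of a resistant cell — the model parameter
#' `phi`.
#'
#' @param ecoi_resistant ECOI measured on the resistant (BIM) host.
#' @param ecoi_knockout ECOI measured on the CRISPR-knockout host, `> 0`.
#' @return Estimate of `phi`, `>= 0`; values above 1 are inconsistent with
#'   the model and flagged with a warning.
#' @examples
#' phi_estimate(0.02, 0.8)  # 0.025
#' @export
phi_estimate <- function(ecoi_resistant, ecoi_knockout) {
  if (any(ecoi_resistant < 0, na.rm = TRUE))
    stop("ecoi_resistant must be >= 0", call. = FALSE)
  if (any(ecoi_knockout <= 0, na.rm = TRUE))
    stop("ecoi_knockout must be > 0 (normalisation impossible)",
         call. = FALSE)
  est <- ecoi_resistant / ecoi_knockout
  if (any(est > 1, na.rm = TRUE))
    warning("phi estimate > 1: inconsistent with the infection model",
            call. = FALSE)
  est
}

#' One-sample t test on replicate estimates
#'
#' Tests whether per-replicate estimates (e.g. relative fitness or phage
#' amplification across 6 biological replicates) differ from a theoretical
#' null value. Ratio-type estimates are log-transformed by default, so the
#' test compares `log(values)` with `log(null_value)` and the estimate and
#' 95% confidence interval are back-transformed for reporting. The tail
#' must be chosen by the caller. A Shapiro-Wilk normality check is run on
#' the analysis scale and reported as advisory only.
#'
#' @param values per-replicate estimates, `n >= 2`; strictly positive when
#'   `log_scale = TRUE`.
#' @param null_value theoretical value under the null (e.g. 1).
#' @param tail `"two"`, `"greater"` (alternative: mean above null) or
#'   `"less"`.
#' @param log_scale analyse on the log scale (default `TRUE`).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return Object of class `acr_test`: list with `estimate` (back-
#'   transformed), `conf_int`, `statistic` (t), `df` (`n - 1`), `p_value`,
#'   `tail`, `n`, `null_value`, `log_scale`, `shapiro_p`, `flag`.
#' @examples
#' one_sample_test(c(1.8, 2.4, 2.1, 1.6, 2.8, 2.2), null_value = 1,
#'                 tail = "greater")
#' @export
one_sample_test <- function(values, null_value = 1,
                            tail = c("two", "greater", "less"),
                            log_scale = TRUE, conf_level = 0.95) {
  tail <- match.arg(tail)
  if (length(values) < 2L)
    stop("need at least 2 replicate values", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  if (log_scale) {
    if (any(values <= 0) || null_value <= 0)
      stop("log-scale analysis needs strictly positive values and null",
           call. = FALSE)
    x <- log(values); mu <- log(null_value)
  } else {
    x <- values; mu <- null_value
  }
  n <- length(x)
  flag <- NULL
  if (stats::sd(x) == 0) {
    # zero-variance fast path: exact equality or a sign-determined extreme
    delta <- mean(x) - mu
    stat <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else if (tail == "two") 0
         else if (tail == "greater") as.numeric(delta < 0)
         else as.numeric(delta > 0)
    ci <- rep(mean(x), 2L)
    flag <- "zero variance among replicates"
  } else {
    alt <- switch(tail, two = "two.sided", greater = "greater", less = "less")
    tt <- stats::t.test(x, mu = mu, alternative = alt,
                        conf.level = conf_level)
    # report the two-sided CI regardless of the test's tail
    ci <- stats::t.test(x, mu = mu, conf.level = conf_level)$conf.int
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  shapiro_p <- if (n >= 3 && stats::sd(x) > 0)
    stats::shapiro.test(x)$p.value else NA_real_
  est <- mean(x)
  if (log_scale) {
    est <- exp(est); ci <- exp(ci)
  }
  structure(list(estimate = est, conf_int = as.numeric(ci),
                 statistic = stat, df = n - 1L, p_value = p, tail = tail,
                 n = n, null_value = null_value, log_scale = log_scale,
                 shapiro_p = shapiro_p, flag = flag),
            class = "acr_test")
}

#' @export
print.acr_test <- function(x, ...) {
  cat(sprintf("One-sample t test (%s-tailed%s) vs null = %g\n", x$tail,
              if (x$log_scale) ", log scale" else "", x$null_value))
  cat(sprintf("  n = %d, estimate = %.4g, 95%% CI [%.4g, %.4g]\n",
              x$n, x$estimate, x$conf_int[1], x$conf_int[2]))
  cat(sprintf("  t_%d = %.3g, p = %.4g\n", x$df, x$statistic, x$p_value))
  if (!is.na(x$shapiro_p))
    cat(sprintf("  Shapiro-Wilk (advisory): p = %.3g\n", x$shapiro_p))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_comparisons`, the family-wise threshold applied to each of
#' `a` comparisons.
#'
#' @param alpha family-wise significance level, in `(0, 1)`.
#' @param n_comparisons number of comparisons, `>= 1`.
#' @return The adjusted per-comparison threshold.
#' @examples
#' bonferroni_threshold(0.05, 3)
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_comparisons) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(n_comparisons) || n_comparisons < 1 ||
      n_comparisons != round(n_comparisons))
    stop("n_comparisons must be an integer >= 1", call. = FALSE)
  alpha / n_comparisons
}
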