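#' Measurement-noise model for synthetic assay data
#'
#' Describes how true abundances are corrupted on the bench: multiplicative
#' log-normal noise on titres/qPCR quantities (sd `sigma_log` on the natural
#' log scale), and optionally Poisson counting noise from plating/plaquing a
#' diluted sample (`count` events drawn at expected count
#' `quantity * dilution`, back-scaled to a quantity).
#'
#' @param sigma_log standard deviation of log-scale multiplicative noise,
#'   `>= 0`. Default 0.2 (roughly a 20% coefficient of variation, typical of
#'   serial-dilution titre measurements).
#' @param poisson apply Poisson counting noise after the log-normal stage.
#' @param dilution dilution factor applied before counting (expected count =
#'   `quantity * dilution`); only used when `poisson = TRUE`.
#' @return Object of class `acr_noise`.
#' @export
noise_model <- function(sigma_log = 0.2, poisson = FALSE, dilution = 1e-5) {
  if (sigma_log < 0) stop("sigma_log must be >= 0", call. = FALSE)
  if (dilution <= 0 || dilution > 1)
    stop("dilution must lie in (0, 1]", call. = FALSE)
  structure(list(sigma_log = sigma_log, poisson = poisson,
                 dilution = dilution), class = "acr_noise")
}

# Run code with a local, restorable RNG state. seed = NULL leaves the
# global stream untouched.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @keywords internal
apply_noise <- function(q, noise) {
  if (noise$sigma_log > 0)
    q <- q * exp(stats::rnorm(length(q), 0, noise$sigma_log))
  if (noise$poisson)
    q <- stats::rpois(length(q), q * noise$dilution) / noise$dilution
  q
}

#' Generate a synthetic competition experiment
#'
#' Emulates a two-competitor competition assay: per replicate, the focal
#' competitor's odds evolve by the (per-day) fitness ratio, quantities are
#' split from a fixed total according to the resulting fraction, and
#' measurement noise is applied. Defaults emulate the bench design: 6
#' biological replicates sampled at 0, 1 and 3 days.
#'
#' @param true_fitness per-day relative fitness of competitor 1, `> 0`.
#' @param n_replicates number of biological replicates, `>= 2`.
#' @param timepoints sampling days.
#' @param noise an [noise_model()] object.
#' @param f0 true initial fraction of competitor 1.
#' @param total_quantity true total abundance at each timepoint.
#' @param seed RNG seed for reproducibility (`NULL`: use current stream).
#' @return Long-form data frame (`replicate`, `timepoint`, `competitor`,
#'   `quantity`) with attributes `truth`, `noise`, `seed`.
#' @examples
#' obs <- generate_competition(true_fitness = 4, noise = noise_model(0),
#'                             timepoints = c(0, 1), seed = 1)
#' competition_fitness(obs)$fitness  # exactly 4
#' @export
generate_competition <- function(true_fitness, n_replicates = 6,
                                 timepoints = c(0, 1, 3),
                                 noise = noise_model(), f0 = 0.5,
                                 total_quantity = 1e7, seed = NULL) {
  if (true_fitness <= 0) stop("true_fitness must be > 0", call. = FALSE)
  if (n_replicates < 2) stop("need n_replicates >= 2", call. = FALSE)
  if (f0 <= 0 || f0 >= 1) stop("f0 must lie in (0, 1)", call. = FALSE)
  odds0 <- f0 / (1 - f0)
  with_seed(seed, {
    rows <- expand.grid(replicate = seq_len(n_replicates),
                        timepoint = sort(timepoints),
                        competitor = c("competitor1", "competitor2"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    odds <- odds0 * true_fitness^rows$timepoint
    frac <- ifelse(rows$competitor == "competitor1",
                   odds / (1 + odds), 1 / (1 + odds))
    rows$quantity <- apply_noise(total_quantity * frac, noise)
    rows <- rows[order(rows$replicate, rows$timepoint, rows$competitor), ]
    rownames(rows) <- NULL
    structure(rows,
              truth = list(true_fitness = true_fitness, f0 = f0,
                           total_quantity = total_quantity),
              noise = noise, seed = seed)
  })
}

#' Generate a synthetic ECOI assay
#'
#' Emulates paired efficiency-of-centres-of-infection measurements on a
#' CRISPR-resistant host and its CRISPR-knockout control at MOI ~1. The
#' expected centres count on the knockout is `ecoi_ko * cells * moi`; on the
#' resistant host it is further multiplied by `true_phi`. Plaque counts are
#' drawn Poisson.
#'
#' @param true_phi true lysis probability on the resistant host, in `[0, 1]`.
#' @param ecoi_ko true ECOI on the knockout host, in `(0, 1]`.
#' @param cells pre-adsorbed cell count per assay.
#' @param moi multiplicity of infection.
#' @param counts_scale integer `>= 1` multiplying all counts (large values
#'   approach the noise-free limit).
#' @param seed RNG seed.
#' @return Data frame with rows for hosts `"bim"` and `"crispr_ko"` and
#'   columns `host`, `centres`, `cells`, `moi`; attribute `truth`.
#' @export
generate_ecoi <- function(true_phi, ecoi_ko = 0.8, cells = 1e4, moi = 1,
                          counts_scale = 1, seed = NULL) {
  if (true_phi < 0 || true_phi > 1)
    stop("true_phi must lie in [0, 1]", call. = FALSE)
  if (ecoi_ko <= 0 || ecoi_ko > 1)
    stop("ecoi_ko must lie in (0, 1]", call. = FALSE)
  if (counts_scale < 1 || counts_scale != round(counts_scale))
    stop("counts_scale must be an integer >= 1", call. = FALSE)
  cells_sc <- cells * counts_scale
  with_seed(seed, {
    mu_ko <- ecoi_ko * cells_sc * moi
    centres <- stats::rpois(2L, c(true_phi * mu_ko, mu_ko))
    structure(data.frame(host = c("bim", "crispr_ko"),
                         centres = centres,
                         cells = rep(cells_sc, 2L),
                         moi = rep(moi, 2L),
                         stringsAsFactors = FALSE),
              truth = list(true_phi = true_phi, ecoi_ko = ecoi_ko))
  })
}

#' Generate a noisy observed trajectory
#'
#' Simulates a design and reports log-densities of the observable
#' quantities with i.i.d. Gaussian noise of sd `sigma_log` added on the log
#' scale. On the bench only total bacteria and the two phage titres are
#' measurable without clone typing, so the default observables are `N`,
#' `V1`, `V2`; a full-observation mode (`observe = c("W","R","S","V1","V2")`)
#' exists for oracle checks. Densities of zero are floored at the
#' trajectory's extinction threshold before taking logs (a detection
#' limit).
#'
#' @param design an [acr_design()].
#' @param noise an [noise_model()]; only `sigma_log` is used here.
#' @param sample_times observation times (default: 20 equally spaced points
#'   on `(0, t_end]`).
#' @param observe character vector of observed columns.
#' @param seed RNG seed.
#' @return Long-form data frame (`time`, `compartment`, `log_density`) with
#'   attributes `design`, `noise`, `seed`, `floor`.
#' @export
generate_noisy_trajectory <- function(design, noise = noise_model(0.1),
                                      sample_times = NULL,
                                      observe = c("N", "V1", "V2"),
                                      seed = NULL) {
  stopifnot(inherits(design, "acr_design"))
  if (is.null(sample_times))
    sample_times <- seq(design$t_end / 20, design$t_end, length.out = 20L)
  d <- design
  d$sample_times <- sample_times
  tr <- run_design(d)
  bad <- setdiff(observe, names(tr))
  if (length(bad))
    stop("unknown observable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  floor_val <- attr(tr, "extinction_threshold")
  obs <- tr[tr$t %in% sample_times, c("t", observe), drop = FALSE]
  long <- data.frame(
    time = rep(obs$t, times = length(observe)),
    compartment = rep(observe, each = nrow(obs)),
    log_density = log(pmax(unlist(obs[observe], use.names = FALSE),
                           floor_val)),
    stringsAsFactors = FALSE)
  with_seed(seed, {
    long$log_density <- long$log_density +
      stats::rnorm(nrow(long), 0, noise$sigma_log)
    structure(long, design = design, noise = noise, seed = seed,
              floor = floor_val)
  })
}
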