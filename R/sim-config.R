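#' Simulation configuration for a synthetic Rusitec experiment
#'
#' Builds and validates the configuration object consumed by
#' [simulate_counts()], [simulate_enrichment()], [simulate_covariates()] and
#' [simulate_spectra()]. Defaults reproduce the statistical structure of a
#' 2 x 2 factorial (forage GRA/HAY, vitamin E -/+) repeated-measures design
#' with four fermentation vessels per treatment sampled at
#' 0, 2, 4, 8, 24 and 48 h post-feeding, and a sequencing depth floor of
#' 11,265 reads per sample.
#'
#' @param n_replicates vessels per treatment (default 4).
#' @param time_points_h strictly increasing sampling times in hours.
#' @param n_taxa number of genera in the simulated community.
#' @param depth_range length-2 integer vector, min/max reads per sample.
#' @param planted_blocks list of blocks, each
#'   `list(taxa = <1-based indices>, rho = <|rho| < 1>, sign = "+"|"-")`,
#'   planted as latent log-scale correlation structure. Negative blocks use
#'   alternating factor loadings so the implied correlation matrix stays
#'   positive definite.
#' @param colonization_params per-forage colonization curve m(t) giving the
#'   microbial fraction of plant-residue nitrogen. Each entry is either
#'   `list(type = "anchors", t = ..., m = ...)` (monotone piecewise-linear
#'   interpolation; the default anchors follow the canonical GRA
#'   16/28/42/61 % and HAY 9/14/17/61 % trajectories) or
#'   `list(type = "logistic", m_max = , rate = , lag = )`.
#' @param effect_sizes list of treatment effects, each
#'   `list(factor = "forage"|"vitE"|"time", taxa = <indices>, logfc = <log-fold
#'   effect on the latent scale>, times = <optional subset of time points where
#'   the effect is active>)`. For `factor = "time"` the effect ramps linearly
#'   from 0 at the first time point to `logfc` at the last.
#' @param noise_sd latent log-scale residual standard deviation.
#' @param fractions community fractions to simulate (default solid-associated
#'   bacteria only).
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_replicates = 4,
                       time_points_h = c(0, 2, 4, 8, 24, 48),
                       n_taxa = 120,
                       depth_range = c(11265, 30000),
                       planted_blocks = list(),
                       colonization_params = default_colonization(),
                       effect_sizes = list(),
                       noise_sd = 1,
                       fractions = "SAB",
                       seed = 1L) {
  cfg <- structure(list(
    n_replicates = as.integer(n_replicates),
    time_points_h = as.numeric(time_points_h),
    n_taxa = as.integer(n_taxa),
    depth_range = as.integer(round(depth_range)),
    planted_blocks = planted_blocks,
    colonization_params = colonization_params,
    effect_sizes = effect_sizes,
    noise_sd = as.numeric(noise_sd),
    fractions = as.character(fractions),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default colonization curves
#'
#' Anchor-based monotone curves for the microbial nitrogen fraction m(t):
#' GRA passes through 0.16, 0.28, 0.42 at 2, 4, 8 h and 0.61 at 48 h;
#' HAY through 0.09, 0.14, 0.17 and 0.61. Both start at 0 at feeding.
#' @return named list of per-forage curve specifications.
#' @export
default_colonization <- function() {
  list(
    GRA = list(type = "anchors", t = c(0, 2, 4, 8, 48),
               m = c(0, 0.16, 0.28, 0.42, 0.61)),
    HAY = list(type = "anchors", t = c(0, 2, 4, 8, 48),
               m = c(0, 0.09, 0.14, 0.17, 0.61))
  )
}

validate_sim_config <- function(cfg) {
  if (cfg$n_replicates < 1) stopf("invalid config: n_replicates must be >= 1")
  tp <- cfg$time_points_h
  if (length(tp) < 1 || any(diff(tp) <= 0))
    stopf("invalid config: time_points_h must be strictly increasing")
  if (length(cfg$depth_range) != 2 || cfg$depth_range[1] < 1)
    stopf("invalid config: depth_range min must be >= 1")
  if (cfg$depth_range[2] < cfg$depth_range[1])
    stopf("invalid config: depth_range max < min")
  for (b in cfg$planted_blocks) {
    if (is.null(b$taxa) || is.null(b$rho))
      stopf("invalid config: planted_blocks entries need 'taxa' and 'rho'")
    if (abs(b$rho) >= 1)
      stopf("invalid config: planted_blocks rho must satisfy |rho| < 1")
    if (max(b$taxa) > cfg$n_taxa)
      stopf("invalid config: n_taxa (%d) smaller than largest planted index (%d)",
            cfg$n_taxa, max(b$taxa))
    if (min(b$taxa) < 1)
      stopf("invalid config: planted_blocks taxa are 1-based indices")
  }
  for (f in names(cfg$colonization_params)) {
    m <- colonization_curve(cfg$colonization_params[[f]], tp)
    if (any(m < 0 | m > 1)) stopf("invalid config: colonization_params[%s] m(t) outside [0,1]", f)
    if (any(diff(m) < -1e-12)) stopf("invalid config: colonization_params[%s] not nondecreasing", f)
  }
  for (e in cfg$effect_sizes) {
    if (is.null(e$factor) || is.null(e$taxa) || is.null(e$logfc))
      stopf("invalid config: effect_sizes entries need 'factor', 'taxa', 'logfc'")
    if (!e$factor %in% c("forage", "vitE", "time"))
      stopf("invalid config: effect_sizes factor must be forage, vitE or time")
    if (max(e$taxa) > cfg$n_taxa)
      stopf("invalid config: effect taxa index exceeds n_taxa")
  }
  if (cfg$noise_sd < 0) stopf("invalid config: noise_sd must be >= 0")
  invisible(cfg)
}

# Evaluate a colonization curve specification at times t.
colonization_curve <- function(spec, t) {
  type <- if (is.null(spec$type)) "anchors" else spec$type
  if (type == "anchors") {
    stats::approx(spec$t, spec$m, xout = pmin(pmax(t, min(spec$t)), max(spec$t)),
                  method = "linear", rule = 2)$y
  } else if (type == "logistic") {
    base <- function(x) 1 / (1 + exp(-spec$rate * (x - spec$lag)))
    b0 <- base(0)
    spec$m_max * (base(t) - b0) / (1 - b0)
  } else stopf("unknown colonization curve type '%s'", type)
}
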