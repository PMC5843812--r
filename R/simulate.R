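# Synthetic-data generators emulating the two wet-lab measurement types the
# labelling calculators consume: instant thin-layer chromatography (ITLC)
# incorporation yields against peptide amount, and HPLC radiochemical-purity
# (RCP) stability series at several ascorbic-acid levels. Truth parameters
# are always returned alongside the data so recovery can be audited.

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the experimental design emulated throughout the package:
#' incorporation measured in >= 3 replicates at 1.7, 3.5 and 7.0 nmol plus
#' transition points, a logistic truth with 50 % point 2.4 nmol, slope
#' 0.25 nmol and asymptote 99 %, Gaussian noise of 3 percentage points;
#' stability followed 0-120 min at ascorbic-acid levels 0-71 mmol/L with
#' exponential RCP decay that switches off at >= 0.9 mmol/L quencher.
#'
#' @param seed integer seed.
#' @param n_replicates replicates per design point, >= 1.
#' @param noise_sd_pct Gaussian noise standard deviation on the % scale.
#' @param peptide_nmol incorporation design points (nmol).
#' @param m50_nmol,slope_nmol,asymptote_pct logistic truth parameters.
#' @param ascorbic_mmol_L stability design: quencher concentrations.
#' @param time_min stability design: measurement times (min).
#' @param rcp0_pct named-by-nothing function or numeric vector giving the
#'   initial RCP per ascorbic level; default interpolates the observed
#'   pattern (near-zero without quencher, ~75 % at 0.1 mmol/L, >= 85 % from
#'   0.9 mmol/L up).
#' @param decay_per_min RCP decay-rate function of ascorbic concentration
#'   (1/min); default k(c) = 0.004 * max(0, 1 - c/0.9)^2, zero at >= 0.9.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_replicates = 3L, noise_sd_pct = 3,
                             peptide_nmol = c(1.7, 2.0, 2.2, 2.4, 2.6, 2.8, 3.5, 7.0),
                             m50_nmol = 2.4, slope_nmol = 0.25,
                             asymptote_pct = 99,
                             ascorbic_mmol_L = c(0, 0.1, 0.3, 0.9, 2.6, 7.9, 24, 71),
                             time_min = seq(0, 120, by = 30),
                             rcp0_pct = NULL, decay_per_min = NULL) {
  stopifnot(n_replicates >= 1, noise_sd_pct >= 0, all(peptide_nmol > 0),
            all(ascorbic_mmol_L >= 0), slope_nmol > 0,
            asymptote_pct > 0, asymptote_pct <= 100)
  if (is.null(rcp0_pct))
    rcp0_pct <- function(c) ifelse(c <= 0, 3, ifelse(c < 0.9, 75 + (c - 0.1) / 0.8 * 12, 87))
  if (is.null(decay_per_min))
    decay_per_min <- function(c) 0.004 * pmax(0, 1 - c / 0.9)^2
  structure(list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
                 noise_sd_pct = noise_sd_pct, peptide_nmol = peptide_nmol,
                 m50_nmol = m50_nmol, slope_nmol = slope_nmol,
                 asymptote_pct = asymptote_pct,
                 ascorbic_mmol_L = ascorbic_mmol_L, time_min = time_min,
                 rcp0_pct = rcp0_pct, decay_per_min = decay_per_min),
            class = "generator_config")
}

#' Logistic incorporation model
#' @param m peptide amounts (nmol).
#' @param m50,s,asymptote logistic parameters (nmol, nmol, %).
#' @return incorporation in %.
#' @export
logistic_incorporation <- function(m, m50, s, asymptote) {
  asymptote / (1 + exp(-(m - m50) / s))
}

#' Generate a synthetic incorporation-yield dataset
#'
#' Incorporation = clamp(logistic(m) + Gaussian noise, 0, 100), replicated
#' per design point. The truth parameters travel with the data as the
#' `truth` attribute.
#'
#' @param config a `generator_config`.
#' @return data.frame `peptide_nmol`, `replicate`, `incorporation_pct`, with
#'   attribute `truth`.
#' @export
sim_incorporation <- function(config = generator_config()) {
  set.seed(config$seed)
  d <- expand.grid(peptide_nmol = config$peptide_nmol,
                   replicate = seq_len(config$n_replicates))
  mu <- logistic_incorporation(d$peptide_nmol, config$m50_nmol,
                               config$slope_nmol, config$asymptote_pct)
  y <- mu + stats::rnorm(nrow(d), 0, config$noise_sd_pct)
  d$incorporation_pct <- pmin(100, pmax(0, y))
  attr(d, "truth") <- list(m50_nmol = config$m50_nmol,
                           slope_nmol = config$slope_nmol,
                           asymptote_pct = config$asymptote_pct,
                           noise_sd_pct = config$noise_sd_pct)
  d
}

#' Generate a synthetic RCP stability dataset
#'
#' RCP(t) = RCP0(c) * exp(-k(c) t) + Gaussian noise, clamped to [0, 100],
#' with the decay rate k a decreasing function of the ascorbic-acid
#' concentration that vanishes for c >= 0.9 mmol/L (quenched regime).
#'
#' @param config a `generator_config`.
#' @return data.frame `ascorbic_mmol_L`, `time_min`, `replicate`, `rcp_pct`,
#'   with attribute `truth` (the RCP0 and k values per condition).
#' @export
sim_stability <- function(config = generator_config()) {
  set.seed(config$seed + 1L)
  d <- expand.grid(ascorbic_mmol_L = config$ascorbic_mmol_L,
                   time_min = config$time_min,
                   replicate = seq_len(config$n_replicates))
  rcp0 <- config$rcp0_pct(d$ascorbic_mmol_L)
  k <- config$decay_per_min(d$ascorbic_mmol_L)
  mu <- rcp0 * exp(-k * d$time_min)
  d$rcp_pct <- pmin(100, pmax(0, mu + stats::rnorm(nrow(d), 0, config$noise_sd_pct)))
  attr(d, "truth") <- data.frame(
    ascorbic_mmol_L = config$ascorbic_mmol_L,
    rcp0_pct = config$rcp0_pct(config$ascorbic_mmol_L),
    decay_per_min = config$decay_per_min(config$ascorbic_mmol_L))
  d
}
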