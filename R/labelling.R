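# Radiolabelling chemistry calculators: specific activity, osmolarity,
# dilution, logistic incorporation fitting, quencher requirement and
# radiochemical-purity (RCP) thresholds.

#' Maximum theoretical (carrier-free) specific activity
#'
#' For a 1:1 metal:chelator stoichiometry the carrier-free ceiling is
#' lambda * N_A atoms per mole, i.e. lambda * N_A * 1e-9 Bq per nmol.
#'
#' @param half_life_s radionuclide half-life in seconds, > 0.
#' @return specific activity in GBq per nmol.
#' @export
max_specific_activity <- function(half_life_s) {
  stopifnot(all(half_life_s > 0))
  lambda <- log(2) / half_life_s
  lambda * AVOGADRO * 1e-9 / 1e9
}

#' Achievable specific activity at a metal:chelator mole ratio
#'
#' @param max_sa carrier-free specific activity (GBq/nmol).
#' @param mole_ratio achieved metal:chelator mole ratio, in [0, 1].
#' @return specific activity in GBq/nmol.
#' @export
achievable_sa <- function(max_sa, mole_ratio) {
  if (any(mole_ratio < 0 | mole_ratio > 1)) stop("mole_ratio must be in [0, 1]")
  max_sa * mole_ratio
}

#' Labelling recipe
#'
#' Solution composition of a labelling reaction. Each component carries
#' either a stock concentration plus added volume, or directly a final
#' concentration (`volume_uL = NA`), and an osmotic dissociation count
#' (ions per formula unit: 2 for fully dissociating 1:1 salts/strong acids,
#' 1 for non-electrolytes and buffers counted once).
#'
#' @param components data.frame with columns `name`, `stock_mol_L`,
#'   `volume_uL` (NA when `stock_mol_L` is already the final concentration),
#'   `osmoles_per_unit`.
#' @param total_volume_uL final reaction volume.
#' @param peptide_nmol peptide amount.
#' @param activity_MBq activity at t = 0.
#' @return a `labelling_recipe` with a `final_mol_L` column added.
#' @export
labelling_recipe <- function(components, total_volume_uL,
                             peptide_nmol = NA_real_, activity_MBq = NA_real_) {
  stopifnot(all(c("name", "stock_mol_L", "volume_uL", "osmoles_per_unit")
                %in% names(components)),
            all(components$stock_mol_L >= 0), total_volume_uL > 0)
  # components may share an added volume (e.g. NaI and HCl in one eluate),
  # so each added volume is bounded by the total rather than their sum
  vol <- components$volume_uL
  if (any(vol > total_volume_uL + 1e-9, na.rm = TRUE))
    stop("a component volume exceeds the total volume")
  components$final_mol_L <- ifelse(is.na(vol), components$stock_mol_L,
                                   components$stock_mol_L * vol / total_volume_uL)
  structure(list(components = components, total_volume_uL = total_volume_uL,
                 peptide_nmol = peptide_nmol, activity_MBq = activity_MBq),
            class = "labelling_recipe")
}

#' Standard labelling recipe
#'
#' 0.34 mol/L TRIS, 71 mmol/L ascorbic acid, 600 uL generator eluate
#' (0.1 mol/L NaI / 0.1 mol/L HCl) in a final volume of 800 uL, 7 nmol
#' peptide. DTPA (50 nmol) is carried for dilution bookkeeping; its osmotic
#' contribution is neglected.
#'
#' @param activity_MBq activity at t = 0 (default 100).
#' @return a `labelling_recipe`.
#' @export
standard_recipe <- function(activity_MBq = 100) {
  comps <- data.frame(
    name = c("TRIS", "ascorbic acid", "NaI", "HCl", "DTPA"),
    stock_mol_L = c(0.34, 0.071, 0.1, 0.1, 50 / (800 * 1e-6) * 1e-9),
    volume_uL = c(NA, NA, 600, 600, NA),
    osmoles_per_unit = c(1, 1, 2, 2, 0),
    stringsAsFactors = FALSE)
  labelling_recipe(comps, 800, peptide_nmol = 7, activity_MBq = activity_MBq)
}

#' Optimized labelling recipe
#'
#' 0.15 mol/L TRIS and 2.6 mmol/L ascorbic acid with the same eluate,
#' lowering the osmolarity to physiologic-compatible levels.
#'
#' @inheritParams standard_recipe
#' @param peptide_nmol peptide amount (default 3.5).
#' @return a `labelling_recipe`.
#' @export
optimized_recipe <- function(activity_MBq = 100, peptide_nmol = 3.5) {
  comps <- data.frame(
    name = c("TRIS", "ascorbic acid", "NaI", "HCl", "DTPA"),
    stock_mol_L = c(0.15, 0.0026, 0.1, 0.1, 50 / (800 * 1e-6) * 1e-9),
    volume_uL = c(NA, NA, 600, 600, NA),
    osmoles_per_unit = c(1, 1, 2, 2, 0),
    stringsAsFactors = FALSE)
  labelling_recipe(comps, 800, peptide_nmol = peptide_nmol,
                   activity_MBq = activity_MBq)
}

#' Calculated osmolarity of a recipe
#'
#' Sum over components of final concentration times the osmotic dissociation
#' count. Fully dissociating salts and strong acids count one osmole per
#' ion; buffers and non-electrolytes count once; trace components (peptide,
#' DTPA) are neglected via a zero count. This is a calculated, not measured,
#' osmolarity.
#'
#' @param recipe a `labelling_recipe`.
#' @return osmolarity in Osmol/L.
#' @export
osmolarity <- function(recipe) {
  sum(recipe$components$final_mol_L * recipe$components$osmoles_per_unit)
}

#' Concentrations after diluting an aliquot of a recipe
#'
#' @param recipe a `labelling_recipe`.
#' @param aliquot_uL aliquot volume taken from the reaction.
#' @param final_volume_uL total volume after dilution, >= aliquot.
#' @return data.frame `name`, `conc_mmol_L` of each component in the diluted
#'   medium.
#' @export
dilute_recipe <- function(recipe, aliquot_uL, final_volume_uL) {
  if (aliquot_uL > final_volume_uL) stop("aliquot exceeds the final volume")
  f <- aliquot_uL / final_volume_uL
  data.frame(name = recipe$components$name,
             conc_mmol_L = recipe$components$final_mol_L * f * 1e3,
             stringsAsFactors = FALSE)
}

#' Fit a logistic incorporation curve
#'
#' Least-squares fit of I(m) = asymptote / (1 + exp(-(m - m50)/s)) to
#' incorporation-yield measurements against peptide amount, by
#' Levenberg-Marquardt. The asymptote is a free parameter bounded at 100 %;
#' with fewer than 5 distinct peptide amounts it is fixed to the mean of the
#' plateau points (amounts above the midpoint start value) to keep the
#' problem well-posed. Data whose overall trend is decreasing are rejected.
#'
#' @param peptide_nmol peptide amounts (nmol).
#' @param incorporation_pct measured incorporation yields (%).
#' @return an `incorporation_fit`: list with `m50_nmol`, `slope_nmol`,
#'   `asymptote_pct`, standard errors, the `nls` fit object and a residual
#'   summary.
#' @export
fit_incorporation <- function(peptide_nmol, incorporation_pct) {
  stopifnot(length(peptide_nmol) == length(incorporation_pct))
  if (length(unique(peptide_nmol)) < 4)
    stop("need measurements at >= 4 peptide amounts spanning the transition")
  if (stats::cor(peptide_nmol, incorporation_pct) < 0)
    stop("incorporation decreases with peptide amount; ",
         "a rising logistic cannot describe these data")
  d <- data.frame(m = peptide_nmol, y = incorporation_pct)
  m50_0 <- stats::median(d$m)
  free_asym <- length(unique(d$m)) >= 5
  asym_fix <- mean(d$y[d$m > m50_0])
  start <- list(m50 = m50_0, s = diff(range(d$m)) / 10)
  if (free_asym) start$asym <- min(max(d$y), 100)
  fml <- if (free_asym) y ~ asym / (1 + exp(-(m - m50) / s))
         else stats::as.formula(sprintf("y ~ %.10g / (1 + exp(-(m - m50) / s))",
                                        asym_fix))
  lower <- if (free_asym) c(m50 = min(d$m) / 10, s = 1e-6, asym = 1)
           else c(m50 = min(d$m) / 10, s = 1e-6)
  upper <- if (free_asym) c(m50 = max(d$m) * 10, s = diff(range(d$m)), asym = 100)
           else c(m50 = max(d$m) * 10, s = diff(range(d$m)))
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = d, start = start, lower = lower,
                      upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("incorporation fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  structure(list(
    m50_nmol = unname(cf["m50"]), slope_nmol = unname(cf["s"]),
    asymptote_pct = if (free_asym) unname(cf["asym"]) else asym_fix,
    se_m50 = unname(se["m50"]), se_slope = unname(se["s"]),
    se_asymptote = if (free_asym) unname(se["asym"]) else NA_real_,
    asymptote_fixed = !free_asym,
    residual_sd = stats::sd(stats::resid(fit)),
    fit = fit), class = "incorporation_fit")
}

#' @export
print.incorporation_fit <- function(x, ...) {
  cat(sprintf(paste0("logistic incorporation fit: 50%% point %.3g +/- %.2g nmol, ",
                     "slope %.3g +/- %.2g nmol, asymptote %.3g%%%s\n"),
              x$m50_nmol, x$se_m50, x$slope_nmol, x$se_slope,
              x$asymptote_pct, if (x$asymptote_fixed) " (fixed)" else ""))
  invisible(x)
}

#' Minimum peptide amount for a target incorporation
#'
#' Inverts a logistic incorporation curve. A target at or above the
#' asymptote cannot be reached exactly; it is then replaced by 99.5 % of the
#' asymptote and the result flagged `at_asymptote`.
#'
#' @param fit an `incorporation_fit` (or list with `m50_nmol`, `slope_nmol`,
#'   `asymptote_pct`).
#' @param target_pct target incorporation (%).
#' @return list with `peptide_nmol`, `target_used_pct`, `at_asymptote`.
#' @export
min_peptide_for_incorporation <- function(fit, target_pct) {
  stopifnot(target_pct > 0)
  at_asym <- target_pct >= fit$asymptote_pct
  tgt <- if (at_asym) 0.995 * fit$asymptote_pct else target_pct
  m <- fit$m50_nmol - fit$slope_nmol * log(fit$asymptote_pct / tgt - 1)
  list(peptide_nmol = m, target_used_pct = tgt, at_asymptote = at_asym)
}

#' Ascorbic-acid requirement for a given absorbed dose
#'
#' Step-plus-linear rule anchored at the empirical requirement of
#' 0.9 mmol/L ascorbic acid for an absorbed dose of ~200 Gy in an 800 uL
#' reaction: doses up to the anchor need the anchor concentration, and the
#' requirement is extrapolated linearly in dose above it (flagged
#' `extrapolated`, as only the qualitative trend is established there).
#'
#' @param dose_Gy absorbed dose in the reaction fluid, >= 0.
#' @param volume_uL reaction volume; the anchor is calibrated at 800 uL and
#'   results for other volumes are flagged extrapolated.
#' @param anchor_conc_mmol_L,anchor_dose_Gy the calibration anchor.
#' @return list with `conc_mmol_L`, `extrapolated`, `anchor`.
#' @export
required_ascorbic <- function(dose_Gy, volume_uL = 800,
                              anchor_conc_mmol_L = 0.9, anchor_dose_Gy = 200) {
  if (dose_Gy < 0) stop("dose_Gy must be >= 0")
  conc <- if (dose_Gy == 0) 0
          else if (dose_Gy <= anchor_dose_Gy) anchor_conc_mmol_L
          else anchor_conc_mmol_L * dose_Gy / anchor_dose_Gy
  list(conc_mmol_L = conc,
       extrapolated = dose_Gy > anchor_dose_Gy || volume_uL != 800,
       anchor = c(dose_Gy = anchor_dose_Gy, conc_mmol_L = anchor_conc_mmol_L))
}

#' Radiochemical-purity threshold check over a time horizon
#'
#' @param series data.frame with columns `time_min` and `rcp_pct` (optionally
#'   `ascorbic_mmol_L`; multiple conditions are checked jointly).
#' @param threshold_pct RCP threshold (%), default 85.
#' @param horizon_min time horizon (min), default 120.
#' @return list with `pass` (TRUE iff all RCP values within the horizon meet
#'   the threshold), `n_points`, and `violations` (the failing rows).
#' @export
rcp_pass <- function(series, threshold_pct = 85, horizon_min = 120) {
  stopifnot(is.data.frame(series), nrow(series) > 0,
            all(c("time_min", "rcp_pct") %in% names(series)))
  w <- series[series$time_min <= horizon_min, , drop = FALSE]
  if (nrow(w) == 0) stop("no measurements within the horizon")
  bad <- w[w$rcp_pct < threshold_pct, , drop = FALSE]
  list(pass = nrow(bad) == 0, n_points = nrow(w), violations = bad)
}
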