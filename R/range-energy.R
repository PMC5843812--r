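# Range-energy models in water. Charged-particle CSDA ranges are modelled
# as a polynomial in log-log space, ln R = c0 + c1 ln E + c2 (ln E)^2 ...
# Degree 1 is the classic power law R = k E^p, adequate for the two alpha
# calibration points; the six electron calibration points over
# 0.197-1.94 MeV show enough curvature that a quadratic is needed to honour
# every point within 5 %. The quadratic inverse E(R) is closed-form.

#' Fit a range-energy model
#'
#' Least-squares polynomial fit of ln(range) against ln(energy).
#'
#' @param energy_MeV calibration energies (MeV).
#' @param range_um calibration CSDA ranges in water (micrometres).
#' @param particle "alpha" or "electron" (metadata only).
#' @param degree polynomial degree in log-log space; default 1 (pure power
#'   law) for alphas, 2 for electrons.
#' @return a `range_energy_model` with coefficients, the implied local
#'   power-law exponent, and the calibration points.
#' @export
fit_range_energy <- function(energy_MeV, range_um,
                             particle = c("alpha", "electron"),
                             degree = if (match.arg(particle) == "alpha") 1L else 2L) {
  particle <- match.arg(particle)
  min_pts <- if (particle == "alpha") 2L else 4L
  if (length(energy_MeV) < min_pts)
    stop("need at least ", min_pts, " calibration points for ", particle)
  stopifnot(length(energy_MeV) == length(range_um),
            all(energy_MeV > 0), all(range_um > 0))
  x <- log(energy_MeV); y <- log(range_um)
  X <- stats::poly(x, degree = degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), y)
  coefs <- unname(fit$coefficients)
  m <- structure(list(particle = particle, coefs = coefs, degree = degree,
                      calibration = data.frame(energy_MeV = energy_MeV,
                                               range_um = range_um)),
                 class = "range_energy_model")
  # monotonicity over (1 keV, 1.25 * max calibration energy)
  eg <- exp(seq(log(1e-3), log(1.25 * max(energy_MeV)), length.out = 200))
  if (any(diff(range_at_energy(m, eg)) <= 0))
    stop("fitted range-energy model is not strictly increasing")
  m
}

#' @export
print.range_energy_model <- function(x, ...) {
  if (x$degree == 1)
    cat(sprintf("%s range-energy power law: R = %.4g * E^%.4g um (E in MeV)\n",
                x$particle, exp(x$coefs[1]), x$coefs[2]))
  else
    cat(sprintf("%s range-energy log-log polynomial, coefs: %s\n",
                x$particle, paste(signif(x$coefs, 5), collapse = ", ")))
  invisible(x)
}

#' Range at a given energy
#' @param model a `range_energy_model`.
#' @param energy_MeV energies (MeV); 0 gives range 0.
#' @return CSDA range in micrometres.
#' @export
range_at_energy <- function(model, energy_MeV) {
  out <- numeric(length(energy_MeV))
  pos <- energy_MeV > 0
  lx <- log(energy_MeV[pos])
  ly <- Reduce(`+`, lapply(seq_along(model$coefs), function(i)
    model$coefs[i] * lx^(i - 1)))
  out[pos] <- exp(ly)
  out
}

#' Energy with a given residual range (inverse model)
#' @param model a `range_energy_model`.
#' @param range_um residual ranges (micrometres); 0 gives energy 0.
#' @return energy in MeV.
#' @export
energy_at_range <- function(model, range_um) {
  out <- numeric(length(range_um))
  pos <- range_um > 0
  y <- log(range_um[pos])
  cf <- model$coefs
  if (model$degree == 1) {
    lx <- (y - cf[1]) / cf[2]
  } else if (model$degree == 2) {
    # c2 x^2 + c1 x + (c0 - y) = 0; increasing branch (x below the vertex
    # for c2 < 0, above for c2 > 0)
    disc <- cf[2]^2 - 4 * cf[3] * (cf[1] - y)
    lx <- (-cf[2] + sqrt(pmax(disc, 0))) / (2 * cf[3])
  } else {
    lx <- vapply(y, function(yy) {
      stats::uniroot(function(x) sum(cf * x^(seq_along(cf) - 1)) - yy,
                     lower = log(1e-9), upper = log(1e4))$root
    }, numeric(1))
  }
  out[pos] <- exp(lx)
  out
}

#' Default alpha-particle range-energy model
#'
#' Power law through the two alpha calibration points of the embedded chain
#' (5.87 MeV / 46.47 um and 8.38 MeV / 81.75 um, SRIM in water).
#' @param chain a `decay_chain`; calibration points are taken from its alpha
#'   lines.
#' @return a `range_energy_model`.
#' @export
alpha_range_model <- function(chain = bi213_chain()) {
  pts <- calibration_points(chain, "alpha")
  fit_range_energy(pts$energy_MeV, pts$range_um, "alpha")
}

#' Default electron range-energy model
#'
#' Log-log quadratic through the six beta (E_mean, E_max) range calibration
#' points of the embedded chain (NIST ESTAR in water).
#' @inheritParams alpha_range_model
#' @return a `range_energy_model`.
#' @export
electron_range_model <- function(chain = bi213_chain()) {
  pts <- calibration_points(chain, "electron")
  fit_range_energy(pts$energy_MeV, pts$range_um, "electron")
}

# Gather (energy, range) calibration pairs from a chain's emission tables.
# Beta spectra contribute both the mean and the endpoint energy with their
# tabulated ranges; the stored csda_range_um of a beta row refers to E_max,
# and mean-energy ranges are tabulated alongside in `beta_mean_ranges`.
calibration_points <- function(chain, particle) {
  if (particle == "alpha") {
    rows <- do.call(rbind, lapply(chain$nuclides, function(n)
      n$emissions[n$emissions$kind == "alpha" & !is.na(n$emissions$csda_range_um), ]))
    data.frame(energy_MeV = rows$energy_MeV, range_um = rows$csda_range_um)
  } else {
    pts <- list()
    for (n in chain$nuclides) {
      b <- n$emissions[n$emissions$kind == "beta_spectrum", ]
      if (nrow(b) == 0) next
      pts[[length(pts) + 1L]] <- data.frame(energy_MeV = b$energy_MeV,
                                            range_um = b$csda_range_um)
      mr <- beta_mean_ranges()
      key <- sprintf("%.3f", b$mean_energy_MeV)
      if (key %in% names(mr))
        pts[[length(pts) + 1L]] <- data.frame(energy_MeV = b$mean_energy_MeV,
                                              range_um = mr[[key]])
    }
    unique(do.call(rbind, pts))
  }
}

# ESTAR water CSDA ranges (um) at the spectrum-mean energies of the chain's
# three beta emitters.
beta_mean_ranges <- function() {
  list("0.434" = 1450, "0.655" = 2550, "0.197" = 440)
}
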