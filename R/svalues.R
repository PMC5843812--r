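# S-values: absorbed dose rate in the vial fluid per unit activity of a
# source nuclide, mGy per MBq.s. S_n(V) = sum over emission lines of
# yield * mean deposited energy per emission * conversion / fluid mass.
# Components are scored per emission class: alpha, beta, electron
# (Auger + internal conversion), gamma.

#' Compute an S-value table by Monte Carlo transport
#'
#' Runs the transport engine for every emission line of every nuclide in the
#' chain at each fill volume and assembles per-component and total S-values.
#' Alpha-recoil nuclei (sub-micrometre range) are excluded by default; with
#' `include_recoil = TRUE` their energy is deposited locally and added to the
#' alpha component.
#'
#' @param chain a `decay_chain`.
#' @param geometry a `vial_geometry`.
#' @param volumes_uL fill volumes (uL), each in (0, capacity].
#' @param n histories per (emission, volume).
#' @param seed master seed; every transport task derives its own substream.
#' @param include_recoil deposit alpha-recoil energies locally.
#' @return an `svalue_table`: data.frame with columns `nuclide`, `component`
#'   ("alpha", "beta", "electron", "gamma", "total"), `volume_uL`, `svalue`,
#'   `phi`, `se_phi`, `approximate`, `provenance` ("computed").
#' @export
compute_svalues <- function(chain, geometry, volumes_uL, n = 1e5, seed = 1L,
                            include_recoil = FALSE) {
  if (any(volumes_uL <= 0) || any(volumes_uL > geometry$capacity_uL))
    stop("volumes_uL must lie in (0, capacity]")
  rm_alpha <- alpha_range_model(chain)
  rm_el <- electron_range_model(chain)
  comp_of <- c(alpha = "alpha", beta_spectrum = "beta",
               electron_line = "electron", gamma_line = "gamma")
  rows <- list()
  for (V in volumes_uL) {
    mass <- fluid_mass_kg(geometry, V)
    conv <- svalue_conversion(mass)
    for (nuc in chain$nuclides) {
      daughter_Z <- 83  # beta-minus daughter in this chain: Z of Po/Pb/Bi ~ 82-84
      em <- nuc$emissions
      comp_s <- c(alpha = 0, beta = 0, electron = 0, gamma = 0)
      comp_phi <- comp_se <- c(alpha = NA_real_, beta = NA_real_,
                               electron = NA_real_, gamma = NA_real_)
      comp_apx <- c(alpha = FALSE, beta = FALSE, electron = FALSE, gamma = FALSE)
      for (i in seq_len(nrow(em))) {
        line <- em[i, ]
        rmod <- if (line$kind == "alpha") rm_alpha else rm_el
        tr <- absorbed_fraction(geometry, V, line, rmod, n = n,
                                seed = derive_seed(seed, paste(nuc$name, line$kind,
                                                               line$energy_MeV, V)),
                                daughter_Z = daughter_Z)
        cl <- comp_of[[line$kind]]
        # mean emitted energy per emission comes from the sampled spectrum
        # for betas, the line energy otherwise
        comp_s[cl] <- comp_s[cl] +
          line$yield_per_decay * tr$mean_emitted_MeV * tr$phi * conv
        comp_phi[cl] <- tr$phi
        comp_se[cl] <- tr$se
        comp_apx[cl] <- comp_apx[cl] || isTRUE(line$approximate)
      }
      if (include_recoil && !is.na(nuc$recoil_energy_MeV)) {
        a_yield <- sum(em$yield_per_decay[em$kind == "alpha"])
        comp_s["alpha"] <- comp_s["alpha"] +
          a_yield * nuc$recoil_energy_MeV * conv   # phi = 1, local deposition
      }
      for (cl in names(comp_s)) {
        if (comp_s[[cl]] == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          nuclide = nuc$name, component = cl, volume_uL = V,
          svalue = comp_s[[cl]], phi = comp_phi[[cl]], se_phi = comp_se[[cl]],
          approximate = comp_apx[[cl]], provenance = "computed",
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        nuclide = nuc$name, component = "total", volume_uL = V,
        svalue = sum(comp_s), phi = NA_real_, se_phi = NA_real_,
        approximate = any(comp_apx), provenance = "computed",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_histories") <- n
  class(out) <- c("svalue_table", "data.frame")
  out
}

#' Published reference S-value table
#'
#' The full-physics Monte Carlo (MCNP5/MCNPX) reference S-values for the
#' Bi-213 chain in the 1 mL conical vial, per nuclide, emission component
#' and fill volume (10-800 uL), in mGy per MBq.s, as published. Used for
#' regression comparison against [compute_svalues()] and as an alternative
#' S-value source for dose calculations.
#'
#' @return an `svalue_table` with `provenance = "reference"`.
#' @export
reference_svalues <- function() {
  vols <- c(10, 50, 100, 200, 400, 800)
  row <- function(nuclide, component, svalues)
    data.frame(nuclide = nuclide, component = component, volume_uL = vols,
               svalue = svalues, phi = NA_real_, se_phi = NA_real_,
               approximate = FALSE, provenance = "reference",
               stringsAsFactors = FALSE)
  out <- rbind(
    row("Bi-213", "alpha",    c(1.94, 0.39, 0.19, 0.097, 0.049, 0.024)),
    row("Bi-213", "beta",     c(2.98, 0.80, 0.44, 0.24, 0.13, 0.066)),
    row("Bi-213", "electron", c(0.20, 0.048, 0.026, 0.013, 0.0067, 0.0034)),
    row("Bi-213", "gamma",    c(0.0054, 0.0019, 0.0012, 0.0007, 0.0005, 0.0003)),
    row("Bi-213", "total",    c(5.12, 1.24, 0.67, 0.35, 0.18, 0.094)),
    row("Po-213", "alpha",    c(130, 26.4, 13.3, 6.6, 3.3, 1.7)),
    row("Po-213", "total",    c(130, 26.4, 13.3, 6.6, 3.3, 1.7)),
    row("Tl-209", "beta",     c(3.17, 0.94, 0.55, 0.30, 0.17, 0.08)),
    row("Tl-209", "electron", c(0.36, 0.08, 0.04, 0.02, 0.01, 0.01)),
    row("Tl-209", "gamma",    c(0.04, 0.02, 0.01, 0.01, 0.00, 0.00)),
    row("Tl-209", "total",    c(3.57, 1.03, 0.60, 0.33, 0.18, 0.09)),
    row("Pb-209", "beta",     c(2.33, 0.53, 0.28, 0.14, 0.07, 0.04)),
    row("Pb-209", "total",    c(2.33, 0.53, 0.28, 0.14, 0.07, 0.04))
  )
  class(out) <- c("svalue_table", "data.frame")
  out
}

#' Extract S-values for one component across nuclides
#'
#' @param svalues an `svalue_table`.
#' @param component emission component ("alpha", "beta", "electron",
#'   "gamma", "total").
#' @param volume_uL fill volume present in the table.
#' @return named numeric vector (nuclide -> S-value, mGy/MBq.s); nuclides
#'   without that component get 0.
#' @export
svalue_vector <- function(svalues, component, volume_uL) {
  sub <- svalues[svalues$component == component &
                   abs(svalues$volume_uL - volume_uL) < 1e-9, ]
  nucs <- unique(svalues$nuclide)
  out <- stats::setNames(numeric(length(nucs)), nucs)
  out[sub$nuclide] <- sub$svalue
  out
}

#' Compare a computed S-value table against the published reference
#'
#' @param computed an `svalue_table` from [compute_svalues()].
#' @param reference reference table, default [reference_svalues()].
#' @return data.frame with computed, reference and relative deviation per
#'   (nuclide, component, volume) present in both.
#' @export
svalue_report <- function(computed, reference = reference_svalues()) {
  key <- function(d) paste(d$nuclide, d$component, d$volume_uL)
  m <- merge(
    data.frame(key = key(computed), nuclide = computed$nuclide,
               component = computed$component, volume_uL = computed$volume_uL,
               computed = computed$svalue, stringsAsFactors = FALSE),
    data.frame(key = key(reference), reference = reference$svalue,
               stringsAsFactors = FALSE),
    by = "key")
  m$rel_dev <- ifelse(m$reference > 0, m$computed / m$reference - 1, NA_real_)
  m[order(m$nuclide, m$component, m$volume_uL),
    c("nuclide", "component", "volume_uL", "computed", "reference", "rel_dev")]
}
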