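# Physical constants used across the package (SI-derived working units:
# energies in MeV, activities in MBq, masses in kg, lengths in mm unless
# a function documents otherwise).

#' @keywords internal
MEV_TO_J <- 1.602176634e-13

#' @keywords internal
AVOGADRO <- 6.02214076e23

# S-value conversion: MeV per decay -> mGy per MBq.s for a target mass in kg.
# 1 MBq.s = 1e6 decays; 1 Gy = 1 J/kg; reported in mGy.
#' @keywords internal
svalue_conversion <- function(mass_kg) {
  MEV_TO_J * 1e6 / mass_kg * 1e3
}

#' Derive a per-task substream seed from one master seed
#'
#' Deterministic hash of a master seed and a task label, kept inside the
#' 32-bit integer range, so that every stochastic task in a run can record
#' its own reproducible seed.
#'
#' @param seed master integer seed.
#' @param task character task label.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, task) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(task)) * seq_along(utf8ToInt(as.character(task))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
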