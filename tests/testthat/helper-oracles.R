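# Independent oracles used by the property tests. These deliberately avoid
# the package's own closed forms and transport engine.

# Absorbed fraction for a uniform isotropic source of straight CSDA tracks
# in a sphere of radius R_mm, by 2-D midpoint quadrature over source radius
# and direction cosine. `range_um` is the track length; `energy_at` maps a
# residual range (um) to the energy still carried (MeV).
sphere_absorbed_fraction <- function(R_mm, range_um, E0_MeV, energy_at,
                                     n_r = 400, n_mu = 400) {
  u <- (seq_len(n_r) - 0.5) / n_r          # source radius fraction, weight 3u^2
  mu <- -1 + (2 * (seq_len(n_mu) - 0.5)) / n_mu
  r <- u * R_mm
  dep <- outer(r, mu, function(r, mu) {
    d <- -r * mu + sqrt(R_mm^2 - r^2 * (1 - mu^2))   # ray length to boundary
    residual <- pmax(0, range_um - d * 1e3)
    E0_MeV - energy_at(residual)
  })
  w_r <- 3 * u^2 / n_r
  mean_dep <- sum(w_r * rowMeans(dep))
  mean_dep / E0_MeV
}

# Brute-force fixed-step RK4 integration of the chain's nuclide numbers,
# with the microsecond-lived Po-213 contracted to a pass-through (its
# feed of Pb-209 happens at the parent's decay rate). Returns activities
# (MBq) of Bi, Tl, Pb at `t_end` for a pure-parent start of A0 MBq.
rk4_chain_activities <- function(A0, t_end, dt = 1e-3,
                                 hl = c(Bi = 45.6 * 60, Tl = 2.16 * 60,
                                        Pb = 3.25 * 3600),
                                 b_alpha = 0.0209) {
  l1 <- log(2) / hl[["Bi"]]; l2 <- log(2) / hl[["Tl"]]; l3 <- log(2) / hl[["Pb"]]
  b_beta <- 1 - b_alpha
  deriv <- function(y) {
    c(-l1 * y[1],
      b_alpha * l1 * y[1] - l2 * y[2],
      b_beta * l1 * y[1] + l2 * y[2] - l3 * y[3])
  }
  y <- c(A0 / l1, 0, 0)
  n_steps <- round(t_end / dt)
  for (i in seq_len(n_steps)) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  c(Bi = l1 * y[1], Tl = l2 * y[2], Pb = l3 * y[3])
}

# Default geometry shared by transport tests.
test_geometry <- function() vial_geometry()
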