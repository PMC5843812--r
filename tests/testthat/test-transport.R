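g <- test_geometry()
ch <- bi213_chain()
rm_a <- alpha_range_model(ch)
rm_e <- electron_range_model(ch)

test_that("beta spectrum samples stay within support and match tabulated means", {
  specs <- list(list(Emax = 1.422, Z = 84, mean = 0.434),
                list(Emax = 1.94, Z = 82, mean = 0.655),
                list(Emax = 0.644, Z = 83, mean = 0.197))
  for (s in specs) {
    E <- sample_beta_energy(2e5, s$Emax, s$Z, seed = 21)
    expect_true(all(E > 0 & E < s$Emax))
    expect_lt(abs(mean(E) / s$mean - 1), 0.15)
  }
})

test_that("energy is conserved per run and zero-range particles deposit fully", {
  tr <- absorbed_fraction(g, 50, emission_line("alpha", 1, 8.38), rm_a,
                          n = 5e4, seed = 31)
  expect_equal(tr$deposited_MeV + tr$escaped_MeV, tr$emitted_MeV,
               tolerance = 1e-12)
  expect_true(tr$phi >= 0 && tr$phi <= 1)

  # a hypothetical particle with vanishing range deposits locally: phi = 1
  m0 <- fit_range_energy(c(1, 2), c(1e-9, 2e-9), "alpha")
  tr0 <- absorbed_fraction(g, 10, emission_line("alpha", 1, 1), m0,
                           n = 1e4, seed = 32)
  expect_equal(tr0$phi, 1, tolerance = 1e-12)
})

test_that("fixed seeds give bit-identical absorbed fractions", {
  a <- absorbed_fraction(g, 100, emission_line("alpha", 1, 8.38), rm_a,
                         n = 2e4, seed = 5)
  b <- absorbed_fraction(g, 100, emission_line("alpha", 1, 8.38), rm_a,
                         n = 2e4, seed = 5)
  expect_identical(a$phi, b$phi)
  expect_identical(a$se, b$se)
})

test_that("alpha absorbed fractions agree with the equal-volume sphere oracle", {
  # straight-line CSDA escape is controlled by the surface-to-volume ratio;
  # a uniform source in the equal-volume sphere gives an independent
  # quadrature value that must sit within 1 % absolute of the cone result
  for (case in list(list(V = 10, E = 8.38), list(V = 100, E = 5.87),
                    list(V = 800, E = 8.38))) {
    tr <- absorbed_fraction(g, case$V, emission_line("alpha", 1, case$E),
                            rm_a, n = 2e5, seed = 41)
    R_s <- (3 * case$V / (4 * pi))^(1 / 3)
    phi_sph <- sphere_absorbed_fraction(R_s, range_at_energy(rm_a, case$E),
                                        case$E,
                                        function(r) energy_at_range(rm_a, r))
    expect_lt(abs(tr$phi - phi_sph), 0.01)
  }
})

test_that("absorbed fraction rises with fill volume for all emission classes", {
  vols <- c(10, 100, 800)
  for (em in list(emission_line("alpha", 1, 8.38),
                  emission_line("beta_spectrum", 1, 1.422,
                                mean_energy_MeV = 0.434),
                  emission_line("electron_line", 1, 0.35))) {
    phi <- vapply(vols, function(v)
      absorbed_fraction(g, v, em, if (em$kind == "alpha") rm_a else rm_e,
                        n = 5e4, seed = 43)$phi, numeric(1))
    expect_true(all(diff(phi) > 0), info = em$kind)
  }
})

test_that("gamma lines use the single-interaction model with small phi", {
  bi <- ch$nuclides[["Bi-213"]]$emissions
  gline <- bi[bi$kind == "gamma_line", ]
  tr <- absorbed_fraction(g, 10, gline, n = 5e4, seed = 44)
  expect_lt(tr$phi, 0.02)
  expect_gt(tr$phi, 0)
  expect_equal(tr$deposited_MeV + tr$escaped_MeV, tr$emitted_MeV,
               tolerance = 1e-12)
})

test_that("unknown emission kinds and missing range models error", {
  expect_error(absorbed_fraction(g, 10, data.frame(kind = "neutron"),
                                 n = 10, seed = 1), "unknown emission")
  expect_error(absorbed_fraction(g, 10, emission_line("alpha", 1, 5),
                                 range_model = NULL, n = 10, seed = 1),
               "range_model")
})

test_that("cone-angle sweep reports the geometric sensitivity", {
  sw <- sweep_cone_angle(half_angles_deg = c(15, 19.06, 25), volume_uL = 10,
                         n = 2e4, seed = 3)
  expect_equal(nrow(sw), 3)
  expect_true(all(sw$phi > 0.9 & sw$phi < 1))
  expect_true(all(sw$se > 0))
})
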