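test_that("carrier-free specific activity follows lambda * N_A", {
  sa <- max_specific_activity(45.6 * 60)
  expect_equal(sa, log(2) / 2736 * 6.02214076e23 * 1e-18, tolerance = 1e-12)
  expect_equal(sa, 152.6, tolerance = 0.001)
  # inverse proportionality to the half-life
  expect_equal(max_specific_activity(2 * 45.6 * 60), sa / 2)
  # a 6.71 day half-life nuclide
  expect_equal(max_specific_activity(6.71 * 86400), 0.72, tolerance = 0.01)
})

test_that("achievable specific activity scales with the mole ratio", {
  expect_equal(achievable_sa(155, 0.6), 93)
  expect_equal(achievable_sa(155, 0), 0)
  expect_equal(achievable_sa(155, 1), 155)
  expect_error(achievable_sa(155, 1.2), "mole_ratio")
  sa <- max_specific_activity(2736)
  expect_true(all(achievable_sa(sa, c(0, 0.3, 1)) <= sa))
})

test_that("osmolarity reproduces both recipe values and is additive", {
  expect_equal(osmolarity(standard_recipe()), 0.7, tolerance = 0.02)
  expect_equal(osmolarity(optimized_recipe()), 0.45, tolerance = 0.01)
  # pure water
  w <- labelling_recipe(data.frame(name = "water", stock_mol_L = 0,
                                   volume_uL = NA, osmoles_per_unit = 1), 800)
  expect_equal(osmolarity(w), 0)
  # linear in each component: doubling TRIS adds exactly its contribution
  r1 <- standard_recipe()
  comps <- r1$components
  comps$stock_mol_L[comps$name == "TRIS"] <- 0.68
  r2 <- labelling_recipe(comps[names(comps) != "final_mol_L"], 800)
  expect_equal(osmolarity(r2) - osmolarity(r1), 0.34, tolerance = 1e-12)
})

test_that("dilution reproduces the incubation-medium concentrations", {
  d <- dilute_recipe(standard_recipe(), 400, 8400)
  conc <- stats::setNames(d$conc_mmol_L, d$name)
  expect_equal(unname(conc["TRIS"]), 16, tolerance = 0.02)
  expect_equal(unname(conc["ascorbic acid"]), 3.4, tolerance = 0.01)
  expect_equal(unname(conc["NaI"]), 3.6, tolerance = 0.01)
  # unchanged when aliquot equals the final volume
  d0 <- dilute_recipe(standard_recipe(), 800, 800)
  expect_equal(d0$conc_mmol_L,
               standard_recipe()$components$final_mol_L * 1e3)
  expect_error(dilute_recipe(standard_recipe(), 900, 800), "aliquot")
})

test_that("noiseless logistic data are recovered exactly", {
  m <- c(1.7, 2.0, 2.2, 2.4, 2.6, 2.8, 3.5, 7.0)
  y <- logistic_incorporation(m, 2.4, 0.25, 99)
  f <- fit_incorporation(m, y)
  expect_equal(f$m50_nmol, 2.4, tolerance = 1e-6)
  expect_equal(f$slope_nmol, 0.25, tolerance = 1e-6)
  expect_equal(f$asymptote_pct, 99, tolerance = 1e-6)
})

test_that("m50 is recovered within 3 SE under the design noise level", {
  cfg <- generator_config(seed = 2024, noise_sd_pct = 3)
  d <- sim_incorporation(cfg)
  f <- fit_incorporation(d$peptide_nmol, d$incorporation_pct)
  expect_lt(abs(f$m50_nmol - 2.4), 3 * f$se_m50)
  expect_gt(f$slope_nmol, 0)
})

test_that("fit bias of m50 shrinks as noise shrinks", {
  bias <- vapply(c(3, 1, 0.1), function(sd) {
    errs <- vapply(1:20, function(i) {
      d <- sim_incorporation(generator_config(seed = 100 + i,
                                              noise_sd_pct = sd))
      fit_incorporation(d$peptide_nmol, d$incorporation_pct)$m50_nmol - 2.4
    }, numeric(1))
    mean(abs(errs))
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
  expect_lt(bias[3], 0.005)
})

test_that("decreasing incorporation data are rejected, not silently fitted", {
  m <- c(1, 2, 3, 4, 5)
  expect_error(fit_incorporation(m, c(90, 70, 40, 20, 5)), "decreases")
  expect_error(fit_incorporation(c(1, 2, 3), c(10, 50, 90)), ">= 4")
})

test_that("asymptote is fixed to the plateau with sparse designs", {
  m <- rep(c(1.7, 2.4, 3.5, 7.0), each = 3)
  y <- logistic_incorporation(m, 2.4, 0.25, 99)
  f <- fit_incorporation(m, y)
  expect_true(f$asymptote_fixed)
  expect_equal(f$m50_nmol, 2.4, tolerance = 0.05)
})

test_that("minimum peptide inverts the logistic and flags asymptote targets", {
  fit <- list(m50_nmol = 2.4, slope_nmol = 0.25, asymptote_pct = 99)
  r <- min_peptide_for_incorporation(fit, 90)
  expect_equal(logistic_incorporation(r$peptide_nmol, 2.4, 0.25, 99), 90,
               tolerance = 1e-9)
  r99 <- min_peptide_for_incorporation(fit, 99)
  expect_true(r99$at_asymptote)
  expect_gt(r99$peptide_nmol, 3)
  expect_lt(r99$peptide_nmol, 7)
})

test_that("ascorbic requirement anchors at 0.9 mmol/L for 200 Gy and extrapolates", {
  expect_equal(required_ascorbic(200)$conc_mmol_L, 0.9)
  expect_false(required_ascorbic(200)$extrapolated)
  expect_equal(required_ascorbic(0)$conc_mmol_L, 0)
  expect_equal(required_ascorbic(50)$conc_mmol_L, 0.9)
  r <- required_ascorbic(400)
  expect_equal(r$conc_mmol_L, 1.8)
  expect_true(r$extrapolated)
  expect_error(required_ascorbic(-1), ">= 0")
})

test_that("RCP threshold check passes stable series and fails degraded ones", {
  stable <- data.frame(time_min = seq(0, 120, 30), rcp_pct = 88)
  expect_true(rcp_pass(stable, 85, 120)$pass)
  # the low-quencher condition: 75 +/- 8 percent at labelling
  low <- data.frame(time_min = c(0, 60, 120), rcp_pct = c(75, 60, 48))
  r <- rcp_pass(low, 85, 120)
  expect_false(r$pass)
  expect_equal(nrow(r$violations), 3)
  expect_error(rcp_pass(stable, 85, -10), "horizon")
})
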