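ch <- bi213_chain()
rv <- reference_svalues()

test_that("dose rate is the S-weighted activity with consistent components", {
  act <- chain_activities(ch, 100, default_time_grid())
  dose <- dose_rate_curve(rv, act, 800)
  expect_true(all(dose$rate_mGy_s >= 0))
  expect_equal(dose$rate_mGy_s[, "total"],
               rowSums(dose$rate_mGy_s[, c("alpha", "beta", "electron", "gamma")]))
  expect_equal(dose$cumulative_Gy[1], 0)
  expect_true(all(diff(dose$cumulative_Gy) >= 0))
  # zero activity gives identically zero dose
  act0 <- chain_activities(ch, 0, c(0, 60, 600))
  expect_true(all(dose_rate_curve(rv, act0, 800)$rate_mGy_s == 0))
})

test_that("nuclide mismatch between S-values and activities errors", {
  act <- chain_activities(ch, 100, c(0, 60))
  expect_error(dose_rate_curve(rv[rv$nuclide != "Pb-209", ], act, 800),
               "lacks nuclides")
})

test_that("initial dose rate uses the equilibrated fast daughter", {
  init <- initial_dose_rate(rv, ch, 100, 800)
  manual_alpha <- (0.024 + 0.9791 * 1.7) * 100
  expect_equal(unname(init["alpha"]), manual_alpha, tolerance = 1e-12)
  expect_equal(unname(init["beta"]), 0.066 * 100, tolerance = 1e-12)
  expect_equal(unname(init["total"]), sum(init[c("alpha", "beta",
                                                 "electron", "gamma")]))
})

test_that("analytic cumulative dose matches trapezoid refinement within 0.1 percent", {
  for (T in c(600, 1800)) {
    an <- cumulative_dose(rv, ch, 100, 800, T)
    tz <- cumulative_dose(rv, ch, 100, 800, T, method = "trapezoid", tol = 1e-4)
    expect_equal(tz / an, 1, tolerance = 1e-3)
  }
})

test_that("dose rate decreases monotonically beyond 10 minutes", {
  act <- chain_activities(ch, 100, default_time_grid())
  dose <- dose_rate_curve(rv, act, 800)
  late <- dose$time_s > 600
  expect_true(all(diff(dose$rate_mGy_s[late, "total"]) < 0))
})

test_that("alpha dose share is bounded and equals 1 for an alpha-only chain", {
  act <- chain_activities(ch, 100, default_time_grid())
  dose <- dose_rate_curve(rv, act, 800)
  shares <- vapply(c(60, 600, 3600, 7200), function(t)
    alpha_dose_share(dose, t), numeric(1))
  expect_true(all(shares >= 0 & shares <= 1))
  # alpha-only table: share is exactly 1
  rv_a <- rv[rv$nuclide == "Po-213", ]
  rv_a <- rbind(rv_a,
                transform(rv_a[rv_a$component == "alpha", ],
                          nuclide = "Bi-213"),
                transform(rv_a[rv_a$component == "alpha", ],
                          nuclide = "Tl-209"),
                transform(rv_a[rv_a$component == "alpha", ],
                          nuclide = "Pb-209"))
  rv_a$component[rv_a$component == "total"] <- "total"
  dose_a <- dose_rate_curve(rv_a, act, 800)
  expect_equal(alpha_dose_share(dose_a, 600), 1)
  expect_error(alpha_dose_share(dose, 1e6), "outside")
})

test_that("molar energy rate converts dose rate to chemistry units", {
  me <- molar_energy_rate(165, 800, 7)
  expect_equal(me$power_mJ_s, 165e-3 * 8e-4 * 1e3, tolerance = 1e-12)
  expect_equal(me$molar_rate_kJ_mol_s, me$power_mJ_s / 7 * 1e3,
               tolerance = 1e-12)
  # doubling the compound amount halves the molar rate
  me2 <- molar_energy_rate(165, 800, 14)
  expect_equal(me2$molar_rate_kJ_mol_s, me$molar_rate_kJ_mol_s / 2)
  expect_equal(me$time_to_threshold_s,
               65 / me$molar_rate_kJ_mol_s, tolerance = 1e-12)
  expect_error(molar_energy_rate(165, 800, 0), "amount_nmol")
})
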