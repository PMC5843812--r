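test_that("run config applies YAML overrides on defaults and validates", {
  cfg <- read_run_config()
  expect_s3_class(cfg$geometry, "vial_geometry")
  expect_equal(cfg$A0_MBq, 100)

  tf <- tempfile(fileext = ".yaml")
  writeLines(c("A0_MBq: 71", "seed: 9", "volumes_uL: [800]",
               "geometry:", "  height_mm: 25", "  capacity_uL: 1000"), tf)
  cfg2 <- read_run_config(tf, overrides = list(horizon_s = 1800))
  expect_equal(cfg2$A0_MBq, 71)
  expect_equal(cfg2$seed, 9L)
  expect_equal(cfg2$horizon_s, 1800)
  expect_equal(cfg2$geometry$height_mm, 25)

  bad <- tempfile(fileext = ".yaml")
  writeLines("A0_MBq: -5", bad)
  expect_error(read_run_config(bad))
  expect_error(read_run_config("no/such/file.yaml"), "not found")
})

test_that("dose report returns the headline quantities and writes outputs", {
  cfg <- read_run_config(overrides = list(horizon_s = 1800,
                                          output_dir = tempfile()))
  rep <- dose_report(cfg, volume_uL = 800, write = TRUE)
  expect_gt(rep$cumulative_Gy, 230)
  expect_equal(unname(rep$initial_rate_mGy_s["alpha"]),
               (0.024 + 0.9791 * 1.7) * 100, tolerance = 1e-9)
  expect_true(file.exists(file.path(cfg$output_dir, "dose_curve.csv")))
  smry <- jsonlite::read_json(file.path(cfg$output_dir, "dose_summary.json"))
  expect_equal(smry$inputs$seed, 1L)
  expect_gt(smry$results$cumulative_Gy, 230)
  # linearity in A0
  cfg71 <- read_run_config(overrides = list(A0_MBq = 71, horizon_s = 1800))
  expect_equal(dose_report(cfg71, 800)$cumulative_Gy, 0.71 * rep$cumulative_Gy,
               tolerance = 1e-9)
  # zero horizon dose
  expect_equal(cumulative_dose(reference_svalues(), cfg$chain, 100, 800, 0), 0)
})

test_that("labelling plan assembles chemistry and dosimetry consistently", {
  cfg <- read_run_config(overrides = list(horizon_s = 1800))
  plan <- labelling_plan(cfg)
  expect_equal(plan$osmolarity_Osmol_L, 0.45, tolerance = 0.01)
  expect_equal(plan$achievable_sa_GBq_nmol,
               0.6 * plan$max_specific_activity_GBq_nmol)
  expect_gt(plan$min_peptide_nmol, 3)
  expect_lt(plan$min_peptide_nmol, 7)
  expect_equal(plan$required_ascorbic_mmol_L,
               required_ascorbic(plan$predicted_dose_Gy, 800)$conc_mmol_L)
  # zero activity: zero dose and zero quencher
  plan0 <- labelling_plan(cfg, recipe = optimized_recipe(activity_MBq = 0))
  expect_equal(plan0$predicted_dose_Gy, 0)
  expect_equal(plan0$required_ascorbic_mmol_L, 0)
})

test_that("svalues report compares computed against reference tables", {
  cfg <- read_run_config(overrides = list(volumes_uL = 800,
                                          n_histories = 2e4,
                                          output_dir = tempfile()))
  out <- svalues_report(cfg, write = TRUE)
  expect_true(nrow(out$comparison) > 0)
  po <- out$comparison[out$comparison$nuclide == "Po-213" &
                         out$comparison$component == "alpha", ]
  expect_equal(po$reference, 1.7)
  expect_lt(abs(po$rel_dev), 0.1)
  expect_true(file.exists(file.path(cfg$output_dir, "svalues_comparison.csv")))
})
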