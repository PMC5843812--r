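ch <- bi213_chain()
g <- test_geometry()
# one moderately sized computed table shared across expectations
sv <- compute_svalues(ch, g, c(10, 800), n = 1e5, seed = 17)

test_that("computed tables are internally consistent", {
  expect_s3_class(sv, "svalue_table")
  expect_true(all(sv$svalue > 0))
  for (nuc in unique(sv$nuclide)) {
    for (v in c(10, 800)) {
      sub <- sv[sv$nuclide == nuc & sv$volume_uL == v, ]
      expect_equal(sub$svalue[sub$component == "total"],
                   sum(sub$svalue[sub$component != "total"]),
                   tolerance = 1e-9)
    }
  }
  # full-absorption bound: S <= sum(y E) * C / m with phi = 1
  for (v in c(10, 800)) {
    conv <- 1.602176634e-13 * 1e6 / (v * 1e-6) * 1e3
    for (nuc in ch$nuclides) {
      em <- nuc$emissions
      bound <- sum(em$yield_per_decay *
                     ifelse(is.na(em$mean_energy_MeV), em$energy_MeV,
                            em$mean_energy_MeV * 1.3)) * conv
      tot <- sv$svalue[sv$nuclide == nuc$name & sv$component == "total" &
                         sv$volume_uL == v]
      expect_lt(tot, bound)
    }
  }
})

test_that("S-values decrease with fill volume (mass dominates)", {
  for (nuc in unique(sv$nuclide)) {
    sub <- sv[sv$nuclide == nuc & sv$component == "total", ]
    expect_lt(sub$svalue[sub$volume_uL == 800], sub$svalue[sub$volume_uL == 10])
  }
})

test_that("reference table matches its own printed totals within rounding", {
  rv <- reference_svalues()
  for (nuc in c("Bi-213", "Tl-209")) {
    for (v in unique(rv$volume_uL)) {
      sub <- rv[rv$nuclide == nuc & rv$volume_uL == v, ]
      # four components each rounded to the printed precision can displace
      # the printed total by up to ~0.015
      expect_lt(abs(sub$svalue[sub$component == "total"] -
                      sum(sub$svalue[sub$component != "total"])), 0.015)
    }
  }
  expect_equal(rv$svalue[rv$nuclide == "Pb-209" & rv$component == "beta" &
                           rv$volume_uL == 800], 0.04)
  expect_equal(rv$svalue[rv$nuclide == "Bi-213" & rv$component == "total" &
                           rv$volume_uL == 10], 5.12)
  expect_true(all(rv$provenance == "reference"))
})

test_that("computed alpha S-values reproduce the reference within a few percent", {
  cmp <- svalue_report(sv)
  a <- cmp[cmp$component == "alpha", ]
  expect_true(all(abs(a$rel_dev) < 0.05))
})

test_that("svalue_vector extracts components with zero fill-ins", {
  s <- svalue_vector(reference_svalues(), "alpha", 800)
  expect_equal(unname(s["Po-213"]), 1.7)
  expect_equal(unname(s["Pb-209"]), 0)   # no alpha branch
  expect_equal(unname(s["Bi-213"]), 0.024)
})

test_that("recoil energy can be deposited locally on request", {
  sv_r <- compute_svalues(ch, g, 10, n = 2e4, seed = 17, include_recoil = TRUE)
  po <- function(t) t$svalue[t$nuclide == "Po-213" & t$component == "alpha" &
                               t$volume_uL == 10]
  conv <- 1.602176634e-13 * 1e6 / 1e-5 * 1e3
  expect_equal(po(sv_r) - po(compute_svalues(ch, g, 10, n = 2e4, seed = 17)),
               0.160 * conv, tolerance = 1e-9)
})
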