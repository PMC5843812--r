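ch <- bi213_chain()

test_that("parent decays exponentially and daughters start at zero", {
  a <- chain_activities(ch, 100, c(0, 45.6 * 60))
  expect_equal(unname(a$activity_MBq[1, "Bi-213"]), 100)
  expect_equal(unname(a$activity_MBq[1, c("Po-213", "Tl-209", "Pb-209")]),
               c(0, 0, 0))
  expect_equal(unname(a$activity_MBq[2, "Bi-213"]), 50, tolerance = 1e-12)
})

test_that("Po-213 reaches branch-weighted secular equilibrium within a second", {
  a <- chain_activities(ch, 100, c(0, 1))
  expect_equal(unname(a$activity_MBq[2, "Po-213"] / a$activity_MBq[2, "Bi-213"]),
               0.9791, tolerance = 1e-6)
})

test_that("all activities vanish at long times and are never negative", {
  a <- chain_activities(ch, 100, c(0, seq(60, 3e5, length.out = 80)))
  expect_true(all(a$activity_MBq >= 0))
  expect_true(all(a$activity_MBq[nrow(a$activity_MBq), ] < 1e-6))
})

test_that("argument violations are rejected", {
  expect_error(chain_activities(ch, -1, c(0, 10)), "non-negative")
  expect_error(chain_activities(ch, 10, c(0, 5, 3)), "sorted")
  expect_error(chain_activities(ch, 10, c(1, 5)), "start at 0")
  expect_error(integrated_activities(ch, 10, -5), ">= 0")
})

test_that("integrated parent activity matches its closed form, Po follows the branch", {
  lambda <- log(2) / 2736
  for (T in c(600, 1800, 7200)) {
    ia <- integrated_activities(ch, 100, T)
    expect_equal(unname(ia[1, "Bi-213"]), 100 * (1 - exp(-lambda * T)) / lambda,
                 tolerance = 1e-12)
    expect_equal(unname(ia[1, "Po-213"] / ia[1, "Bi-213"]), 0.9791, tolerance = 1e-4)
  }
  expect_equal(unname(integrated_activities(ch, 100, 0)[1, ]), rep(0, 4))
})

test_that("integrated activities are monotone non-decreasing in the horizon", {
  Ts <- seq(0, 7200, by = 300)
  ia <- integrated_activities(ch, 100, Ts)
  expect_true(all(diff(ia[, "Bi-213"]) >= 0))
  expect_true(all(apply(ia, 2, function(x) all(diff(x) >= -1e-9 * max(x)))))
})

test_that("nuclei are conserved: integrated parent activity equals parent atoms lost", {
  lambda <- log(2) / 2736
  A0 <- 100
  for (T in c(30, 1800, 10000)) {
    n_decays <- unname(integrated_activities(ch, A0, T)[1, "Bi-213"])
    n_lost <- A0 / lambda - (A0 * exp(-lambda * T)) / lambda
    expect_equal(n_decays, n_lost, tolerance = 1e-9)
  }
})

test_that("closed forms agree with a 1 ms fixed-step RK4 oracle over 10 min", {
  oracle <- rk4_chain_activities(A0 = 100, t_end = 600)
  a <- chain_activities(ch, 100, c(0, 600))$activity_MBq[2, ]
  expect_equal(unname(a["Bi-213"]), unname(oracle["Bi"]), tolerance = 1e-6)
  expect_equal(unname(a["Tl-209"]), unname(oracle["Tl"]), tolerance = 1e-6)
  expect_equal(unname(a["Pb-209"]), unname(oracle["Pb"]), tolerance = 1e-6)
})

test_that("default time grid starts at zero, is strictly increasing, ends at horizon", {
  g <- default_time_grid()
  expect_equal(g[1], 0)
  expect_true(all(diff(g) > 0))
  expect_equal(g[length(g)], 7200)
})
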