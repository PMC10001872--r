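test_that("hazard quotients reproduce the published national means", {
  expect_equal(hazard_quotient(6.35, 40), 0.159, tolerance = 0.002)
  expect_equal(hazard_quotient(0.250, 0.3), 0.834, tolerance = 0.002)
  expect_equal(hazard_quotient(0, 40), 0)
  expect_error(hazard_quotient(1, 0), "rfd")
})

test_that("hazard index sums element quotients, draw-wise over matrices", {
  expect_equal(hazard_index(c(0.108, 0.834, 0.0282, 0.159)), 1.1292)
  expect_equal(hazard_index(0.7), 0.7)
  expect_equal(hazard_index(c(0, 0, 0)), 0)
  m <- cbind(a = c(1, 2), b = c(3, 4))
  expect_equal(hazard_index(m), c(4, 6))
  expect_error(hazard_index(numeric(0)), "at least one")
})

test_that("carcinogenic risk converts intake to mg before the slope factor", {
  expect_equal(carcinogenic_risk(0.250, 1.5), 3.75e-4)
  expect_equal(carcinogenic_risk(0.100, 8.5e-3), 8.5e-7)
  expect_equal(carcinogenic_risk(0.108, 6.1), 6.588e-4)
  expect_equal(carcinogenic_risk(0, 1.5), 0)
  expect_error(carcinogenic_risk(1, -1), "sf")
})

test_that("total carcinogenic risk reproduces the published aggregate", {
  crs <- c(As = 3.75e-4, Cd = 6.62e-4, Pb = 8.54e-7)
  expect_equal(total_carcinogenic_risk(crs), 1.04e-3, tolerance = 0.005)
  expect_equal(total_carcinogenic_risk(5e-5), 5e-5)
  expect_equal(total_carcinogenic_risk(c(0, 0)), 0)
})

test_that("threshold classification is strict at every boundary", {
  expect_equal(classify_risk(1.04e-3, "tcr"), "unacceptable")
  expect_equal(classify_risk(8.54e-7, "cr"), "negligible")
  expect_equal(classify_risk(5e-5, "cr"), "acceptable")
  expect_equal(classify_risk(1e-4, "tcr"), "acceptable")  # boundary
  expect_equal(classify_risk(1e-6, "cr"), "acceptable")   # boundary
  expect_equal(classify_risk(1, "hq"), "ok")              # strict >
  expect_equal(classify_risk(1 + 1e-12, "hi"), "potential risk")
})

test_that("contribution shares match the published split and sum to one", {
  crs <- c(As = 3.75e-4, Cd = 6.62e-4, Pb = 8.54e-7)
  sh <- contribution_shares(crs)
  expect_equal(unname(sh["As"]), 0.361, tolerance = 0.002)
  expect_equal(unname(sh["Cd"]), 0.637, tolerance = 0.002)
  expect_equal(sum(sh), 1, tolerance = 1e-12)
  expect_equal(unname(contribution_shares(c(2, 2, 2))), rep(1 / 3, 3))
  expect_equal(unname(contribution_shares(c(0, 5, 0))), c(0, 1, 0))
  expect_error(contribution_shares(c(0, 0)), "zero total")
  expect_error(contribution_shares(c(-1, 2)), "nonnegative")
})

test_that("aggregates dominate their components on random draw vectors", {
  set.seed(99)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    n <- 500
    hq <- matrix(rlnorm(n * k, -1, 1), n, k)
    hi <- hazard_index(hq)
    expect_true(all(hi >= apply(hq, 1, max)))
    # draw-wise percentile of the sum dominates each component's percentile
    for (p in c(0.5, 0.9, 0.999)) {
      expect_true(all(percentile(hi, p) >=
                        apply(hq, 2, function(col) percentile(col, p))))
    }
  }
})

test_that("risk metrics are linear in intake and shares scale-free", {
  edi <- national_mean_edi()
  base <- risk_from_edi(edi, tox = quiet_tox())
  doubled <- risk_from_edi(2 * edi, tox = quiet_tox())
  expect_equal(doubled$hq, 2 * base$hq)
  expect_equal(doubled$hi, 2 * base$hi)
  expect_equal(doubled$cr, 2 * base$cr)
  expect_equal(doubled$tcr, 2 * base$tcr)
  expect_equal(doubled$hi_shares, base$hi_shares)
  expect_equal(doubled$tcr_shares, base$tcr_shares)
})
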