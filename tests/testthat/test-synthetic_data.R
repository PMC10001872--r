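test_that("lognormal moment fit agrees with an independent bisection oracle", {
  cases <- list(c(gm = 15.5, sd = 16.0),   # national Cd
                c(gm = 43.4, sd = 19.6),   # national As
                c(gm = 1066, sd = 1210),   # national Cu
                c(gm = 2, sd = 0.5))
  for (cs in cases) {
    spec <- fit_lognormal(cs[["gm"]], cs[["sd"]])
    oracle <- sigma_by_bisection(cs[["gm"]], cs[["sd"]])
    expect_equal(spec$params$meanlog, log(cs[["gm"]]))
    expect_equal(spec$params$sdlog, oracle, tolerance = 1e-8)
    # plug back: analytic arithmetic SD of the fit reproduces the target
    expect_equal(unname(dist_moments(spec)["sd"]), cs[["sd"]],
                 tolerance = 1e-6)
  }
})

test_that("vanishing SD degenerates to a point mass at the geometric mean", {
  expect_equal(fit_lognormal(1, 0)$family, "point")
  expect_equal(fit_lognormal(1, 0)$params$value, 1)
  spec <- fit_lognormal(1, 1e-9)
  expect_lt(spec$params$sdlog, 1e-6)
  expect_error(fit_lognormal(0, 1), "gm")
  expect_error(fit_lognormal(-3, 1), "gm")
})

test_that("large-sample arithmetic SD of draws matches the fitted target", {
  spec <- fit_lognormal(15.5, 16.0)
  set.seed(2024)
  x <- dist_draw(spec, 1e6)
  expect_equal(sd(x), 16.0, tolerance = 0.01)
  expect_equal(exp(mean(log(x))), 15.5, tolerance = 0.01)
})

test_that("generator reproduces the survey design deterministically", {
  targets <- nepal_table1(include_total = FALSE)
  s1 <- generate_samples(targets, seed = 5)
  s2 <- generate_samples(targets, seed = 5)
  expect_identical(s1, s2)
  # 170 samples per element across the seven provinces
  expect_equal(unname(table(s1$element)["Cd"]), 170)
  expect_equal(sort(unique(s1$province)), sort(unique(targets$stratum)))
  expect_true(all(s1$concentration_ug_per_kg > 0))
  # different seed, different data
  expect_false(identical(
    s1$concentration_ug_per_kg,
    generate_samples(targets, seed = 6)$concentration_ug_per_kg))
})

test_that("per-stratum streams are stable when strata are added", {
  targets <- nepal_table1(include_total = FALSE)
  sub <- targets[targets$stratum %in% c("Gandaki", "Karnali"), ]
  full <- generate_samples(targets, seed = 9)
  part <- generate_samples(sub, seed = 9)
  for (st in c("Gandaki", "Karnali")) {
    expect_identical(
      part$concentration_ug_per_kg[part$province == st],
      full$concentration_ug_per_kg[full$province == st]
    )
  }
})

test_that("truncation keeps every draw inside the printed range", {
  targets <- nepal_table1(include_total = FALSE)
  cd <- targets[targets$element == "Cd", ]
  s <- generate_samples(cd, seed = 3, truncate = TRUE, n_override = 500)
  for (st in cd$stratum) {
    x <- s$concentration_ug_per_kg[s$province == st]
    lims <- cd[cd$stratum == st, ]
    expect_true(all(x >= lims$min_ug_per_kg & x <= lims$max_ug_per_kg))
  }
})

test_that("log-transformed draws are consistent with normality", {
  # the generator really is lognormal: Shapiro rejections at alpha = 0.01
  # should not exceed the nominal rate (binomial bound over 40 seeds)
  spec <- fit_lognormal(43.4, 19.6)
  rejections <- 0
  for (seed in 1:40) {
    set.seed(seed)
    x <- dist_draw(spec, 500)
    if (stats::shapiro.test(log(x))$p.value < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 3)  # P(X > 3 | n = 40, p = 0.01) < 1e-3
})

test_that("population draws honour point values, medians and determinism", {
  g <- population_group("g", ir = 0.3, bw = 60)
  d <- generate_population(g, 5, seed = 1)
  expect_equal(d$ir, rep(0.3, 5))
  expect_equal(d$bw, rep(60, 5))

  glog <- population_group("g2", ir = 0.3,
                           bw = dist_spec("lognormal", meanlog = log(60),
                                          sdlog = 0.2))
  d2 <- generate_population(glog, 20000, seed = 4)
  expect_equal(median(d2$bw), 60, tolerance = 0.02)
  expect_identical(d2, generate_population(glog, 20000, seed = 4))

  # IR and BW streams are independent (near-zero correlation)
  gboth <- population_group("g3",
                            ir = dist_spec("lognormal", meanlog = log(0.3),
                                           sdlog = 0.3),
                            bw = dist_spec("lognormal", meanlog = log(60),
                                           sdlog = 0.2))
  d3 <- generate_population(gboth, 20000, seed = 4)
  expect_lt(abs(cor(d3$ir, d3$bw)), 0.03)
})

test_that("group constructor enforces positivity and exposure bounds", {
  expect_error(population_group("x", ir = -1, bw = 60), "ir")
  expect_error(population_group("x", ir = 0.3, bw = 0), "bw")
  expect_error(population_group("x", ir = 0.3, bw = 60, ef = 400), "ef")
  expect_error(population_group("x", ir = 0.3, bw = 60, ed = 0), "ed")
})
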