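test_that("deterministic EDI follows the intake equation", {
  expect_equal(edi_point(cf = 1000, ir = 0.1, bw = 50, ef = 365, ed = 30,
                         at = 10950), 2.0)
  expect_equal(edi_point(cf = 0, ir = 0.1, bw = 50), 0)
  # chronic factor ef*ed/at defaults to 1
  expect_equal(edi_point(cf = 500, ir = 0.2, bw = 40), 500 * 0.2 / 40)
  expect_error(edi_point(1, 1, bw = 0), "bw")
  expect_error(edi_point(1, 1, bw = 50, at = -1), "at")
  expect_error(edi_point(-1, 1, bw = 50), "cf")
})

test_that("published national exposure implies a plausible intake ratio", {
  # diagnostic consistency of the published tables: mean EDI / mean
  # concentration ~ IR/BW in kg/kg/day, here for As (0.250 / 43.4 * 1000)
  ratio <- 0.250 / 43.4 * 1000
  expect_equal(ratio, 5.76, tolerance = 0.001)
  # the bundled national group sits at that order of magnitude
  g <- nepal_groups()$national
  expect_equal(g$ir$params$value / g$bw$params$value * 1000, 5.33,
               tolerance = 0.01)
})

test_that("percentile rule is type-7 linear interpolation, monotone in p", {
  expect_equal(unname(percentile(1:100, 0.5)), 50.5)
  expect_equal(unname(percentile(rep(3.2, 50), c(0.1, 0.5, 0.999))),
               rep(3.2, 3))
  set.seed(21)
  draws <- rlnorm(10000)
  p <- sort(runif(20, 0.01, 0.999))
  q <- percentile(draws, p)
  expect_true(all(diff(q) >= 0))
  expect_gte(unname(percentile(draws, 0.999)), unname(percentile(draws, 0.99)))
  expect_error(percentile(numeric(0), 0.5), "empty")
  expect_error(percentile(1:10, 1), "p must")
})

test_that("degenerate inputs collapse the simulation to the point EDI", {
  g <- population_group("pt", ir = 0.1, bw = 50, ef = 365, ed = 30,
                        at = 10950)
  res <- edi_mcs(dist_spec("point", value = 1000), g, iterations = 10000,
                 seed = 3)
  expect_true(all(res$draws == 2.0))
  expect_equal(res$mean, edi_point(1000, 0.1, 50, 365, 30, 10950))
  expect_true(all(res$percentiles == 2.0))
})

test_that("simulated P50 matches the closed-form lognormal median", {
  # product/ratio of independent lognormals is lognormal; its median is
  # exp(mu_C + mu_IR - mu_BW) when ef*ed/at = 1
  mu_c <- log(43.4); mu_ir <- log(0.32); mu_bw <- log(60)
  g <- population_group(
    "ln", ir = dist_spec("lognormal", meanlog = mu_ir, sdlog = 0.25),
    bw = dist_spec("lognormal", meanlog = mu_bw, sdlog = 0.15))
  n <- 10000
  res <- edi_mcs(dist_spec("lognormal", meanlog = mu_c, sdlog = 0.4), g,
                 iterations = n, seed = 17)
  med_true <- exp(mu_c + mu_ir - mu_bw)
  # 99% binomial order-statistic interval around the median
  lo <- sort(res$draws)[qbinom(0.005, n, 0.5)]
  hi <- sort(res$draws)[qbinom(0.995, n, 0.5) + 1]
  expect_gte(med_true, lo)
  expect_lte(med_true, hi)
})

test_that("Monte Carlo mean converges to the analytic mean", {
  spec_c <- fit_lognormal(43.4, 19.6)
  g <- population_group(
    "ln", ir = dist_spec("lognormal", meanlog = log(0.32), sdlog = 0.2),
    bw = dist_spec("lognormal", meanlog = log(60), sdlog = 0.1))
  n <- 10000
  res <- edi_mcs(spec_c, g, iterations = n, seed = 23)
  # independence: E[EDI] = E[C] E[IR] E[1/BW]
  m <- dist_moments(spec_c)["mean"] * exp(log(0.32) + 0.2^2 / 2) *
    exp(-log(60) + 0.1^2 / 2)
  expect_equal(res$mean, unname(m), tolerance = 3 * sd(res$draws) / sqrt(n) / m)
})

test_that("EDI draws scale linearly in CF and IR and inversely in BW", {
  base <- edi_mcs(fit_lognormal(40, 20), population_group("a", 0.3, 60),
                  iterations = 2000, seed = 5)
  double_c <- edi_mcs(fit_lognormal(80, 40),  # doubles every draw of CF
                      population_group("a", 0.3, 60),
                      iterations = 2000, seed = 5)
  expect_equal(double_c$draws, 2 * base$draws)
  double_ir <- edi_mcs(fit_lognormal(40, 20), population_group("a", 0.6, 60),
                       iterations = 2000, seed = 5)
  expect_equal(double_ir$draws, 2 * base$draws)
  half_bw <- edi_mcs(fit_lognormal(40, 20), population_group("a", 0.3, 30),
                     iterations = 2000, seed = 5)
  expect_equal(half_bw$draws, 2 * base$draws)
})

test_that("resampling mode bootstraps the observed pool reproducibly", {
  pool <- c(10, 20, 30, 40)
  g <- population_group("b", ir = 0.3, bw = 60)
  r1 <- edi_mcs(pool, g, iterations = 5000, seed = 2)
  r2 <- edi_mcs(pool, g, iterations = 5000, seed = 2)
  expect_identical(r1$draws, r2$draws)
  expect_true(all(r1$draws %in% (pool * 0.3 / 60)))
  expect_error(suppressWarnings(edi_mcs(numeric(0), g, iterations = 100,
                                        seed = 1)), "empty")
})

test_that("iteration guard rails", {
  g <- population_group("c", ir = 0.3, bw = 60)
  expect_warning(edi_mcs(dist_spec("point", value = 1), g, iterations = 100,
                         seed = 1), "unstable")
  expect_error(edi_mcs(dist_spec("point", value = 1), g, iterations = 0,
                       seed = 1), "iterations")
})
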