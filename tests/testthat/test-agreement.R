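test_that("RMSE follows its defining arithmetic", {
  g <- c(100, 300)
  expect_equal(rmse_paired(g, g), list(rmse_abs = 0, rmse_rel_pct = 0))
  r <- rmse_paired(g, c(110, 290))
  expect_equal(r$rmse_abs, 10)
  expect_equal(r$rmse_rel_pct, 5)
  # differences of +3 and -4 ms around a nonzero gold level
  expect_equal(rmse_paired(c(10, 10), c(13, 6))$rmse_abs, sqrt(25 / 2))
  expect_error(rmse_paired(c(-1, 1), c(0, 0)), "undefined")
})

test_that("Bland-Altman bias, LoA, and SRD match hand arithmetic", {
  ba <- bland_altman(gold = c(0, 0, 0), est = c(1, 2, 3))
  expect_equal(ba$bias, 2, tolerance = 1e-10)
  expect_equal(ba$sd_diff, 1, tolerance = 1e-10)
  expect_equal(ba$srd, 1.96, tolerance = 1e-10)
  expect_equal(ba$loa_lower, 0.04, tolerance = 1e-10)
  expect_equal(ba$loa_upper, 3.96, tolerance = 1e-10)
  expect_equal(ba$ci_bias, 2 + c(-1, 1) * qt(0.975, 2) / sqrt(3))
  expect_equal(ba$ci_loa_lower, 0.04 + c(-1, 1) * qt(0.975, 2) * sqrt(3 / 3))

  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$bias, same$srd, same$loa_lower, same$loa_upper),
               rep(0, 4))

  # antisymmetry under swapping the methods
  set.seed(4)
  g <- rnorm(12); e <- rnorm(12)
  ab <- bland_altman(g, e); ba2 <- bland_altman(e, g)
  expect_equal(ab$bias, -ba2$bias)
  expect_equal(ab$loa_lower, -ba2$loa_upper)
  expect_equal(ab$loa_upper, -ba2$loa_lower)

  expect_error(bland_altman(1:2, 2:3), "insufficient pairs")
  expect_equal(srd(10), 19.6)
  expect_equal(srd(0.1378), 0.270, tolerance = 1e-3)
  expect_error(srd(-1), "non-negative")
})

test_that("proportional bias equals the closed-form OLS slope", {
  set.seed(8)
  g <- rnorm(20, 100, 10); e <- rnorm(20, 100, 10)
  pb <- proportional_bias(g, e)
  x <- (g + e) / 2; y <- e - g
  slope_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(pb$slope, slope_cf, tolerance = 1e-10)

  # constructed exact relation diff = -0.4*mean + c
  e2 <- (g * (1 - 0.2) + 3) / (1 + 0.2)  # gives est - gold = -0.4*mean + c'
  pb2 <- suppressWarnings(proportional_bias(g, e2))  # exact fit
  expect_equal(pb2$slope, -0.4, tolerance = 1e-10)
  expect_lt(pb2$p, 1e-10)

  # constant difference: zero slope, p ~ 1
  pb3 <- suppressWarnings(proportional_bias(g, g + 5))  # exact fit
  expect_equal(pb3$slope, 0, tolerance = 1e-10)
  expect_error(proportional_bias(rep(1, 5), rep(1, 5)), "variance")
  expect_error(proportional_bias(1:3, 2:4), "at least 4")
})

test_that("Cohen's d uses the pooled SD and the gold-minus-estimate sign", {
  expect_equal(as.numeric(cohens_d(c(0, 2), c(1, 3))), -1 / sqrt(2),
               tolerance = 1e-10)
  expect_equal(as.numeric(cohens_d(c(1, 2, 3), c(1, 2, 3))), 0)
  # overestimating method gives negative d
  set.seed(15)
  g <- rnorm(30, 2.37, 0.19); e <- rnorm(30, 2.42, 0.14) + 0.2
  expect_lt(as.numeric(cohens_d(g, e)), 0)
  expect_equal(attr(cohens_d(c(0, 2), c(1, 3)), "band"), "large")
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
  # paired variant: mean diff over sd of diffs
  d_p <- cohens_d(c(1, 2, 4), c(2, 3, 6), method = "paired")
  expect_equal(as.numeric(d_p), mean(c(-1, -1, -2)) / sd(c(-1, -1, -2)))
})

test_that("agreement statistics are permutation invariant and internally consistent", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    g <- rnorm(n, 250, 20); e <- g + rnorm(n, 10, 8)
    r <- rmse_paired(g, e); ba <- bland_altman(g, e)
    # RMSE^2 = bias^2 + sd^2 (n-1)/n
    expect_lt(abs(r$rmse_abs^2 - (ba$bias^2 + ba$sd_diff^2 * (n - 1) / n)),
              1e-10)
    expect_equal((ba$loa_lower + ba$loa_upper) / 2, ba$bias)
    expect_equal(srd(ba$sd_diff), (ba$loa_upper - ba$loa_lower) / 2,
                 tolerance = 1e-10)
    p <- sample.int(n)
    ba_p <- bland_altman(g[p], e[p])
    expect_equal(ba_p$bias, ba$bias)
    expect_equal(ba_p$srd, ba$srd)
    expect_equal(proportional_bias(g[p], e[p])$slope,
                 proportional_bias(g, e)$slope)
  }
})

test_that("validate assembles one report row per variable and speed", {
  set.seed(31)
  n <- 12
  tcg <- rnorm(n, 270, 15); tfg <- rnorm(n, 100, 12)
  # small mean-free measurement wobble so the injected bias stays exact
  wob <- function() { w <- rnorm(n, 0, 0.5); w - mean(w) }
  pairs <- rbind(
    data.frame(participant = 1:n, speed_kmh = 9, variable = "tc",
               gold = tcg, est = tcg + 10 + wob()),
    data.frame(participant = 1:n, speed_kmh = 9, variable = "tf",
               gold = tfg, est = tfg - 10 + wob()),
    data.frame(participant = 1:n, speed_kmh = 11, variable = "tc",
               gold = tcg, est = tcg + 4 + wob()))
  rep <- validate_agreement(pairs)
  expect_equal(nrow(rep), 3)
  r_tc9 <- rep[rep$variable == "tc" & rep$speed_kmh == 9, ]
  r_tf9 <- rep[rep$variable == "tf" & rep$speed_kmh == 9, ]
  # injected +/-10 ms errors: the true bias lies inside the reported CI and
  # the antisymmetric construction is reproduced
  expect_true(r_tc9$ci_bias_lower < 10 && 10 < r_tc9$ci_bias_upper)
  expect_true(r_tf9$ci_bias_lower < -10 && -10 < r_tf9$ci_bias_upper)
  expect_equal(r_tc9$bias, 10)
  expect_equal(r_tf9$bias, -10)
  expect_equal(r_tc9$rmse_abs, 10, tolerance = 0.1)
  expect_equal(rep[rep$speed_kmh == 11, "bias"], 4, tolerance = 0.1)

  # identical methods: all-zero errors (perfect-fit regression is expected)
  same <- suppressWarnings(
    validate_agreement(data.frame(participant = 1:5, speed_kmh = 9,
                                  variable = "fz_max", gold = 2:6,
                                  est = 2:6)))
  expect_equal(same$bias, 0)
  expect_equal(same$rmse_abs, 0)

  # incomplete pairs are excluded with a warning
  pairs$est[1] <- NA
  expect_warning(rep2 <- validate_agreement(pairs), "excluded")
  expect_equal(rep2$n[rep2$variable == "tc" & rep2$speed_kmh == 9], n - 1L)
})
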