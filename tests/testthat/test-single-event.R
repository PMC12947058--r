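test_that("event frequency enforces mean specific energy = dose", {
  m <- single_event_model("delta", mu1 = 0.003)
  expect_equal(event_frequency(m, 0.003), 1)
  expect_equal(event_frequency(m, 0), 0)
  # anchored engine: lambda = -ln(0.65) at 0.003 Gy, proportional in dose
  expect_equal(event_frequency(engine_sm, 0.003), -log(0.65))
  expect_equal(event_frequency(engine_sm, 0.03), -log(0.65) * 10,
               tolerance = 1e-12)
  expect_error(event_frequency(m, -0.1), "dose")
})

test_that("anchor calibration reproduces the printed summaries exactly", {
  # small voxels: lambda = -ln 0.65, mu1 = D/lambda, m2/mu1^2 = spread^2*lambda
  expect_equal(engine_sm$mu1, 6.964064e-3, tolerance = 1e-6)
  expect_equal(engine_sm$m2 / engine_sm$mu1^2, 5.068118, tolerance = 1e-6)
  expect_equal(zero_fraction(engine_sm, 0.003), 0.65)
  expect_equal(analytic_spread(engine_sm, 0.003), 3.43)
  # large voxels
  expect_equal(event_frequency(engine_lg, 0.003), 1.049822, tolerance = 1e-6)
  expect_equal(engine_lg$mu1, 2.857627e-3, tolerance = 1e-6)
  expect_equal(zero_fraction(engine_lg, 0.003), 0.35)
  expect_equal(analytic_spread(engine_lg, 0.003), 2.05)
  # lambda = 1 anchor with unit spread is delta-like: mu1 = D, m2 = mu1^2
  m <- calibrate_from_anchor(0.01, exp(-1), 1.0, family = "delta")
  expect_equal(m$mu1, 0.01)
  expect_equal(m$m2, 1e-4)
  expect_error(calibrate_from_anchor(0.1, 0, 1.0), "impossible")
})

test_that("analytic spread scales as inverse square root of dose", {
  # anchored small-voxel model at 0.03 Gy: tabulated 108%
  expect_equal(analytic_spread(engine_sm, 0.03), 1.084661, tolerance = 1e-6)
  # exact 1/sqrt(D) scaling
  for (D in c(0.003, 0.05, 0.4)) {
    expect_equal(analytic_spread(engine_sm, D) / analytic_spread(engine_sm, 4 * D),
                 2, tolerance = 1e-12)
  }
  # spread * sqrt(D) is constant in D
  sp <- analytic_spread(engine_lg, c(0.003, 0.03, 0.3)) *
    sqrt(c(0.003, 0.03, 0.3))
  expect_equal(max(sp) - min(sp), 0, tolerance = 1e-12)
  # delta model at lambda = 100: sqrt(1/lambda) = 0.1
  d <- single_event_model("delta", mu1 = 1e-4)
  expect_equal(analytic_spread(d, 100 * 1e-4), 0.1)
  expect_error(analytic_spread(d, 0), "dose")
})

test_that("zero fraction is exp(-lambda)", {
  expect_equal(zero_fraction(engine_sm, 0), 1)
  m <- single_event_model("delta", mu1 = 0.01)
  expect_equal(zero_fraction(m, 0.01), exp(-1), tolerance = 1e-12)
  # strictly decreasing in dose
  zf <- zero_fraction(engine_sm, seq(0, 0.05, by = 0.005))
  expect_true(all(diff(zf) < 0))
})

test_that("Laplace transforms are valid and match quadrature", {
  alphas <- c(0, 0.1, 1, 10, 100)
  models <- list(
    single_event_model("delta", mu1 = 0.005),
    single_event_model("exponential", mu1 = 0.005),
    engine_sm,
    single_event_model("lognormal", mu1 = 0.005, m2 = 1e-4),
    single_event_model("empirical", values = c(0.002, 0.01),
                       probs = c(0.7, 0.3))
  )
  for (m in models) {
    M <- laplace_transform(m, alphas)
    expect_equal(M[1], 1)
    expect_true(all(diff(M) < 0))   # strictly decreasing
    expect_true(all(M > 0 & M <= 1))
  }
  # gamma closed form against a brute-force Monte Carlo estimate
  g <- engine_sm
  set.seed(10)
  gdraws <- stats::rgamma(2e5, shape = g$shape, scale = g$scale)
  for (a in c(0.5, 5, 50)) {
    est <- mean(exp(-a * gdraws))
    se <- stats::sd(exp(-a * gdraws)) / sqrt(length(gdraws))
    expect_lt(abs(laplace_transform(g, a) - est), 3 * se)
  }
  # lognormal quadrature against a Monte Carlo estimate
  ln <- single_event_model("lognormal", mu1 = 0.005, m2 = 1e-4)
  set.seed(11)
  draws <- stats::rlnorm(2e5, ln$meanlog, ln$sdlog)
  for (a in c(1, 20)) {
    est <- mean(exp(-a * draws))
    se <- stats::sd(exp(-a * draws)) / sqrt(length(draws))
    expect_lt(abs(laplace_transform(ln, a) - est), 3 * se + 1e-9)
  }
})

test_that("survival transform is the compound-Poisson closed form", {
  expect_equal(survival_transform(engine_sm, 0.01, 0), 1)
  # large-alpha limit is the zero fraction (slow power-law approach for
  # the heavy-near-zero gamma spectrum, hence the very large alpha)
  expect_equal(survival_transform(engine_sm, 0.003, 1e12),
               zero_fraction(engine_sm, 0.003), tolerance = 2e-3)
  # delta model against a brute-force Monte Carlo estimate
  z0 <- 0.004
  m <- single_event_model("delta", mu1 = z0)
  D <- 0.01
  lam <- D / z0
  set.seed(12)
  zs <- stats::rpois(2e5, lam) * z0
  for (a in c(0.5, 5, 50)) {
    est <- mean(exp(-a * zs))
    se <- stats::sd(exp(-a * zs)) / sqrt(length(zs))
    expect_lt(abs(survival_transform(m, D, a) - est), 3 * se)
    expect_equal(survival_transform(m, D, a),
                 exp(-lam * (1 - exp(-a * z0))), tolerance = 1e-12)
  }
})

test_that("model construction validates its moment inputs", {
  expect_error(single_event_model("gamma", mu1 = 0.01), "m2")
  expect_error(single_event_model("gamma", mu1 = 0.01, m2 = 1e-5), "m2 >")
  expect_error(single_event_model("delta", mu1 = -1), "positive")
  expect_error(single_event_model("empirical", values = c(1, 2),
                                  probs = c(0.5, 0.6)), "summing to 1")
})
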