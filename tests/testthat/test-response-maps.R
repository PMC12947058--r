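test_that("optical density follows log10(I0/I)", {
  expect_equal(od_from_transmission(1000, 1000), 0)
  expect_equal(od_from_transmission(1000, 100), 1)
  # additive under successive attenuation
  expect_equal(od_from_transmission(900, 30 / 10),
               od_from_transmission(900, 30) + 1)
  expect_error(od_from_transmission(0, 10), "> 0")
})

test_that("block averaging reduces resolution and noise", {
  expect_true(all(block_average(matrix(4, 9, 9)) == 4))
  # known 3x3 blocks reduce to their means
  img <- kronecker(matrix(c(1, 2, 3, 4), 2, 2), matrix(1, 3, 3))
  expect_equal(block_average(img, 3), matrix(c(1, 2, 3, 4), 2, 2))
  # global mean preserved on exact tiling
  set.seed(41)
  img <- matrix(runif(90 * 90), 90, 90)
  expect_equal(mean(block_average(img, 3)), mean(img), tolerance = 1e-12)
  # i.i.d. noise SD shrinks by about the block size
  noise <- matrix(rnorm(300 * 300), 300, 300)
  expect_equal(stats::sd(as.numeric(block_average(noise, 3))), 1 / 3,
               tolerance = 0.1)
  # non-divisible dims are cropped
  expect_equal(dim(block_average(matrix(1, 10, 11), 3)), c(3L, 3L))
})

test_that("net OD maps compare control to irradiated scans", {
  set.seed(42)
  ctrl <- matrix(round(runif(36, 30000, 60000)), 6, 6)
  expect_true(all(net_od_map(ctrl, ctrl, factor = 3)$values == 0))
  # uniform 10x attenuation gives a map of ones
  m <- net_od_map(round(ctrl / 10), ctrl, factor = 3)
  expect_equal(as.numeric(m$values), rep(1, 4), tolerance = 1e-3)
  expect_error(net_od_map(ctrl, ctrl[1:3, ]), "differ")
  # both averaging orders agree for smooth images
  m2 <- net_od_map(round(ctrl / 10), ctrl, factor = 3, order = "od_first")
  expect_equal(m2$values, m$values, tolerance = 1e-3)
})

test_that("high-dose OD maps are far more uniform than low-dose maps", {
  # net OD against the 0 Gy control film: the offset cancels, leaving the
  # dose-dependent signal whose relative spread collapses with dose
  fm <- film_model("OD")
  ctrl <- synth_od_scan(0, fm, engine_sm, vx_sm, seed = 43)
  rel_sd_at <- function(dose, seed) {
    sc <- synth_od_scan(dose, fm, engine_sm, vx_sm, seed = seed)
    map_stats(net_od_map(sc, ctrl))$relative_sd
  }
  expect_gt(rel_sd_at(0.003, 44), 5 * rel_sd_at(0.5, 45))
})

test_that("offset correction nulls the control signal", {
  set.seed(45)
  ctrl <- matrix(rnorm(100, 2, 0.1), 10, 10)
  # a map equal to the control corrects to exactly zero
  expect_true(all(offset_correct(ctrl, ctrl)$values == 0))
  # control with mean c, map with mean c + s -> corrected mean s
  s <- 0.7
  m <- ctrl + s
  expect_equal(mean(offset_correct(m, ctrl)$values), s, tolerance = 1e-12)
  # corrected control mean is 0 exactly, for both methods
  expect_equal(mean(offset_correct(ctrl, ctrl, method = "mean")$values), 0,
               tolerance = 1e-12)
  expect_error(offset_correct(matrix(0, 2, 2), ctrl), "differ")
})

test_that("offset-corrected synthetic series has decreasing relative SD", {
  fm <- film_model("OD", inhomogeneity_cv = 0)
  white <- matrix(fm$i0, 45, 45)
  ctrl <- synth_od_scan(0, fm, engine_sm, vx_sm, pixels = c(45, 45),
                        seed = 46)
  ctrl_map <- net_od_map(ctrl, white)
  rel <- vapply(c(0.01, 0.1, 0.5), function(D) {
    sc <- synth_od_scan(D, fm, engine_sm, vx_sm, pixels = c(45, 45),
                        seed = round(D * 1e5))
    map_stats(offset_correct(net_od_map(sc, white), ctrl_map))$relative_sd
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
})

test_that("power-law fits recover noise-free trends exactly", {
  doses <- c(0.003, 0.01, 0.05, 0.2, 0.5)
  fit <- power_law_fit(doses, 2 * doses^(-0.5))
  expect_equal(fit$amplitude, 2, tolerance = 1e-10)
  expect_equal(fit$exponent, -0.5, tolerance = 1e-10)
  expect_equal(power_law_fit(doses, rep(3, 5))$exponent, 0,
               tolerance = 1e-10)
  # compound-Poisson analytic spreads: exponent exactly -1/2
  fit <- power_law_fit(doses, analytic_spread(engine_sm, doses))
  expect_equal(fit$exponent, -0.5, tolerance = 1e-10)
  expect_gt(fit$r_squared, 1 - 1e-10)
  expect_error(power_law_fit(c(0.1), c(1)), "at least 2")
})

test_that("film inhomogeneity flattens the spread-dose exponent", {
  doses <- c(0.003, 0.01, 0.03, 0.1, 0.3)
  exponent_for <- function(cv) {
    fm <- film_model("OD", inhomogeneity_cv = cv, noise_sd = 0)
    white <- matrix(fm$i0, 60, 60)
    ctrl <- synth_od_scan(0, fm, engine_sm, vx_sm, pixels = c(60, 60),
                          seed = 47)
    cm <- net_od_map(ctrl, white)
    rel <- vapply(seq_along(doses), function(i) {
      sc <- synth_od_scan(doses[i], fm, engine_sm, vx_sm,
                          pixels = c(60, 60), seed = 100 + i)
      map_stats(offset_correct(net_od_map(sc, white), cm))$relative_sd
    }, numeric(1))
    power_law_fit(doses, rel)$exponent
  }
  exps <- vapply(c(0, 0.05, 0.15), exponent_for, numeric(1))
  # exponents rise monotonically toward 0 as the dose-independent
  # inhomogeneity floor grows
  expect_true(all(diff(exps) > 0))
  expect_equal(exps[1], -0.5, tolerance = 0.1)
})
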