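make_clean_stack <- function(n_chan = 425, n_rep = 5, sd = 2, seed = 31) {
  set.seed(seed)
  base <- 200 + 50 * sin(seq(0, 3, length.out = n_chan))
  base + matrix(rnorm(n_chan * n_rep, 0, sd), n_chan, n_rep)
}

test_that("despiking removes injected cosmic rays and spares clean data", {
  st <- make_clean_stack()
  sigma <- 2
  spiked <- st
  spiked[100, 2] <- spiked[100, 2] + 10 * sigma
  out <- despike(spiked)
  expect_lt(abs(out[100, 2] - st[100, 2]), 3 * sigma)
  # all-identical repeats with one outlier channel: replaced by common value
  flat <- matrix(5, 50, 4)
  flat[10, 3] <- 500
  out <- despike(flat)
  expect_equal(out[10, 3], 5)
  expect_true(all(out == 5))
  # single repeat passes through with a warning
  expect_warning(out1 <- despike(st[, 1, drop = FALSE]), "single repeat")
  expect_equal(out1, st[, 1, drop = FALSE])
})

test_that("despike false-positive rate is below 1% on clean spectra", {
  changed <- 0
  n_tot <- 0
  for (seed in 32:36) {
    st <- make_clean_stack(seed = seed)
    out <- despike(st)
    changed <- changed + sum(out != st)
    n_tot <- n_tot + length(st)
  }
  expect_lt(changed / n_tot, 0.01)
})

test_that("despiking is idempotent on its own output", {
  st <- make_clean_stack(seed = 37)
  st[c(40, 200, 390), c(1, 3, 5)] <- st[c(40, 200, 390), c(1, 3, 5)] + 40
  once <- despike(st)
  expect_equal(despike(once), once)
})

test_that("pixel averaging is the channel-wise mean", {
  st <- matrix(c(1, 2, 3, 5, 7, 9), 3, 2)
  expect_equal(pixel_average(st), c(3, 4.5, 6))
  flat <- matrix(2, 10, 5)
  expect_equal(pixel_average(flat), rep(2, 10))
  # k i.i.d. repeats: noise SD reduced by about sqrt(k)
  set.seed(38)
  noise <- matrix(rnorm(2000 * 5, 0, 1), 2000, 5)
  expect_equal(stats::sd(pixel_average(noise)), 1 / sqrt(5),
               tolerance = 0.1)
})

test_that("SNIP reproduces smooth baselines and preserves peaks", {
  x <- raman_axis()
  # flat spectrum: baseline equals the spectrum
  flat <- rep(100, length(x))
  out <- snip_baseline(flat, 40)
  expect_equal(out$baseline, flat, tolerance = 1e-6)
  expect_lt(max(abs(out$corrected)), 1e-4)
  # Gaussian peak (FWHM 20 cm^-1) on a linear baseline
  sg <- 20 / (2 * sqrt(2 * log(2)))
  truth_base <- 100 + 0.05 * (x - min(x))
  peak <- 400 * exp(-(x - 1445)^2 / (2 * sg^2))
  out <- snip_baseline(truth_base + peak, 40)
  under <- abs(x - 1445) < 30
  expect_lt(max(abs(out$baseline[under] - truth_base[under]) /
                  truth_base[under]), 0.05)
  true_area <- band_area(x, peak, 1445, width = 80)
  got_area <- band_area(x, out$corrected, 1445, width = 80)
  expect_equal(got_area, true_area, tolerance = 0.1)
  # monotone smooth background with no peaks: corrected is ~ 0
  bg <- 800 * exp(-(x - min(x)) / 1200)
  out <- snip_baseline(bg, 40)
  expect_lt(max(abs(out$corrected)), 0.01 * max(bg))
  # corrected spectrum is stable under a second SNIP pass (< 1% change)
  again <- snip_baseline(out$corrected, 40)$corrected
  expect_lt(max(abs(again - out$corrected)), 0.01 * max(bg))
  expect_error(snip_baseline(rep(1, 20), 40), "too short")
})

test_that("vector normalization yields unit Euclidean norm", {
  expect_equal(vector_normalize(c(3, 4)), c(0.6, 0.8))
  v <- vector_normalize(rnorm(100))
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  expect_equal(vector_normalize(v), v)  # idempotent
  x <- c(1, 5, 2)
  expect_equal(vector_normalize(10 * x), vector_normalize(x))  # scale-free
  expect_error(vector_normalize(rep(0, 5)), "all-zero")
})

test_that("band areas integrate the stated window", {
  x <- raman_axis()
  expect_equal(band_area(x, rep(0, length(x)), 1445), 0)
  expect_equal(band_area(x, rep(1, length(x)), 1445, width = 14), 14)
  # unit-area Gaussian fully inside the band
  sg <- 3
  g <- exp(-(x - 1086)^2 / (2 * sg^2)) / (sg * sqrt(2 * pi))
  expect_equal(band_area(x, g, 1086, width = 40), 1, tolerance = 0.01)
  expect_error(band_area(x, g, 2320, width = 14), "outside")
})

test_that("the RS chain extracts a dose response invariant to drift", {
  eng <- engine_sm
  fm <- film_model("RS", inhomogeneity_cv = 0, noise_sd = 0, spike_rate = 0)
  doses <- c(0.003, 0.03, 0.1, 0.3, 0.5)
  sets <- lapply(doses, function(D) {
    synth_raman_roiset(D, fm, eng, vx_sm, seed = round(D * 1e4))
  })
  dr <- rs_dose_response(sets)
  # noise-free response is near-linear over the dose range
  r2 <- summary(stats::lm(dr$curve$responses ~ doses))$r.squared
  expect_gt(r2, 0.99)
  expect_true(all(diff(dr$curve$responses) > 0))
  # doubling every intensity (laser-power drift) leaves the curve unchanged
  doubled <- sets[[3]]
  doubled$cube <- 2 * doubled$cube
  expect_equal(rs_pixel_map(doubled)$values, dr$maps[[3]]$values,
               tolerance = 1e-6)
  # uniform response: map constant up to noise
  expect_lt(map_stats(dr$maps[[5]])$relative_sd,
            analytic_spread(eng, 0.5) + 0.05)
})

test_that("the 2260 band is dose-independent in synthetic spectra", {
  fm <- film_model("RS", inhomogeneity_cv = 0, noise_sd = 0, spike_rate = 0)
  areas <- vapply(c(0.003, 0.1, 0.5), function(D) {
    rs <- synth_raman_roiset(D, fm, engine_sm, vx_sm, grid = c(3, 3),
                             seed = round(D * 2e4))
    sp <- snip_baseline(pixel_average(rs$cube[, , 1]), 40)$corrected
    band_area(rs$shifts, sp, 2260, 14)
  }, numeric(1))
  expect_lt(diff(range(areas)) / mean(areas), 0.02)
})
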