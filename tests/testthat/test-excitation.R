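test_that("effective profile matches the reduced form |gamma - x| e^-x", {
  cfg <- excitation_config(gamma = 1.16)
  r <- seq(0, 3, length.out = 301)
  prof <- effective_profile(cfg, r)
  x <- 2 * r^2
  expect_equal(prof$value, (2 / pi) * abs(1.16 - x) * exp(-x), tolerance = 1e-12)
  # reduced-units central value is gamma itself
  expect_equal(prof$value[1] * pi / 2, 1.16, tolerance = 1e-12)
  # zero crossing at x = gamma, i.e. r = w0 sqrt(gamma/2)
  rz <- sqrt(1.16 / 2)
  expect_equal(rz, 0.76158, tolerance = 1e-5)
  expect_equal(effective_profile(cfg, c(0, rz))$value[2], 0, tolerance = 1e-15)
  # no modulation, no AC component
  cfg0 <- excitation_config(gamma = 1.16, modulation_depth = 0)
  expect_true(all(effective_profile(cfg0, r)$value == 0))
})

test_that("lobe metrics at gamma = 1.16 reproduce the reference operating point", {
  m <- measure_psf(excitation_config(gamma = 1.16))
  expect_equal(m$fwhm, 0.828, tolerance = 5e-4)
  expect_equal(m$sidelobe_ratio, exp(-2.16) / 1.16, tolerance = 1e-12)
  expect_lt(m$sidelobe_ratio, 0.10)
  expect_gt(m$sidelobe_ratio, 0.09)
  expect_gt(m$zero_crossing, m$fwhm / 2)
  expect_error(measure_psf(excitation_config(gamma = -1)), "gamma")
})

test_that("the large power ratio limit recovers the Gaussian width", {
  expect_equal(measure_psf(excitation_config(gamma = 1000))$fwhm,
               1.177, tolerance = 1e-3)
  expect_equal(enhancement_factor(1e6), 1, tolerance = 1e-4)
})

test_that("analytic FWHM agrees with the densely sampled profile oracle", {
  set.seed(42)
  for (g in runif(20, 0.6, 2)) {
    m <- measure_psf(excitation_config(gamma = g))
    expect_equal(m$fwhm, sampled_fwhm(g), tolerance = 1e-4)
    # and with an independent bisection in the reduced coordinate
    expect_equal(m$fwhm, 2 * sqrt(bisect_half_max_x(g) / 2), tolerance = 1e-9)
  }
})

test_that("the side lobe sits at x = 1 + gamma with height e^-(1+gamma)", {
  for (g in c(0.6, 1.16, 2)) {
    opt <- optimize(function(x) (x - g) * exp(-x), c(g, g + 20),
                    maximum = TRUE, tol = 1e-12)
    expect_equal(opt$maximum, 1 + g, tolerance = 1e-6)
    expect_equal(opt$objective, exp(-(1 + g)), tolerance = 1e-8)
    expect_equal(measure_psf(excitation_config(gamma = g))$sidelobe_peak,
                 opt$objective, tolerance = 1e-8)
  }
})

test_that("effective profile is bounded by the stronger beam and reduces to it alone", {
  r <- seq(0, 3, length.out = 500)
  ig <- gaussian_intensity(r, beam_spec(1.16, 1))
  id <- donut_intensity(r, beam_spec(1, 1))
  expect_true(all(abs(ig - id) <= pmax(ig, id) + 1e-15))
  # with no donut power the effective profile is exactly the Gaussian
  expect_equal(abs(ig - donut_intensity(r, beam_spec(0, 1))), ig)
})

test_that("power-ratio sweep is monotone: wider lobe, weaker ring", {
  sw <- power_ratio_sweep()
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 141L)
  expect_true(all(diff(sw$fwhm) > 0))
  expect_true(all(diff(sw$sidelobe_ratio) < 0))
  expect_lt(sw$fwhm[1], sw$fwhm[141])
  expect_true(all(sw$fwhm < 1.17741))
  expect_equal(sw$sidelobe_ratio[sw$gamma == 2], exp(-3) / 2, tolerance = 1e-12)
  expect_equal(sw$sidelobe_ratio[sw$gamma == 1.6], 0.046, tolerance = 1e-2)
  expect_error(power_ratio_sweep(numeric(0)), "empty")
  expect_error(power_ratio_sweep(c(1, 0.9)), "increasing")
  expect_error(power_ratio_sweep(c(-1, 1)), "> 0")
})

test_that("the selected operating ratio is the smallest one meeting the ring ceiling", {
  sw <- power_ratio_sweep()
  expect_equal(select_optimal_ratio(sw, 0.10), 1.16)
  # oracle: smallest grid gamma with e^-(1+g)/g <= threshold
  oracle <- function(thr) min(sw$gamma[exp(-(1 + sw$gamma)) / sw$gamma <= thr])
  expect_equal(select_optimal_ratio(sw, 0.05), oracle(0.05))
  expect_equal(select_optimal_ratio(sw, 0.05), 1.56)
  expect_equal(select_optimal_ratio(sw, 1.0), 0.6)   # vacuous constraint
  expect_error(select_optimal_ratio(sw, 0.001), "not.*meet|meets|no power ratio")
})

test_that("resolution enhancement is ~1.42 at the operating point and grows at low ratios", {
  expect_equal(enhancement_factor(1.16), 1.42, tolerance = 2e-3)
  expect_equal(enhancement_factor(1.16),
               sqrt(2 * log(2)) / (2 * sqrt(bisect_half_max_x(1.16) / 2)),
               tolerance = 1e-9)
  # oracle for gamma = 0.6 via independent bisection
  fw06 <- 2 * sqrt(bisect_half_max_x(0.6) / 2)
  expect_equal(enhancement_factor(0.6), sqrt(2 * log(2)) / fw06, tolerance = 1e-9)
  expect_equal(enhancement_factor(0.6), 1.76, tolerance = 1e-2)
})

test_that("excitation configuration rejects invalid parameters", {
  expect_error(excitation_config(gamma = 0), "gamma")
  expect_error(excitation_config(modulation_depth = 1.2), "m must")
  expect_error(excitation_config(mu_a = -1), "mu_a")
})
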