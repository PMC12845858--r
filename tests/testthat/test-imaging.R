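sys532 <- optical_system(532, 1.4)

test_that("derived waist gives the 142 nm diffraction-limited Gaussian FWHM", {
  expect_equal(sys532$waist_nm, 532 / (pi * 1.4), tolerance = 1e-12)
  expect_equal(gaussian_fwhm(sys532$waist_nm), 142.4, tolerance = 1e-3)
  expect_error(optical_system(532, 0), "aperture")
  expect_error(optical_system(532, 1.7), "aperture")
  expect_error(optical_system(-5, 1.4), "wavelength")
})

test_that("PSF kernels are odd, unit-sum, center-peaked and match analytic widths", {
  kg <- build_psf_kernel(sys532, "gaussian", pixel_size_nm = 10)
  kp <- build_psf_kernel(sys532, "phase_shifted", excitation_config(1.16),
                         pixel_size_nm = 10)
  for (k in list(kg, kp)) {
    expect_true(nrow(k$values) %% 2L == 1L)
    expect_equal(sum(k$values), 1, tolerance = 1e-12)
    ctr <- (nrow(k$values) + 1L) / 2L
    expect_equal(max(k$values), k$values[ctr, ctr])
  }
  # discrete FWHM within one pixel of the analytic values
  expect_equal(kernel_fwhm(kg), 1.17741 * sys532$waist_nm, tolerance = 10 / 142)
  expect_equal(kernel_fwhm(kg), 142, tolerance = 5e-3)
  expect_equal(kernel_fwhm(kp), 100, tolerance = 5e-3)
  # the ring survives discretization at its analytic relative height
  ctr <- (nrow(kp$values) + 1L) / 2L
  rpx <- sqrt(outer((seq_len(nrow(kp$values)) - ctr)^2,
                    (seq_len(ncol(kp$values)) - ctr)^2, "+"))
  ring <- max(kp$values[rpx * 10 > sqrt(1.16 / 2) * sys532$waist_nm])
  expect_equal(ring / kp$values[ctr, ctr], exp(-2.16) / 1.16, tolerance = 0.02)
  expect_error(build_psf_kernel(sys532, "gaussian", pixel_size_nm = 30),
               "undersample|w0/5")
  expect_error(build_psf_kernel(sys532, "gaussian", truncation = 2), "truncation")
})

test_that("phantom generation is seed-deterministic and validates widths", {
  p1 <- generate_phantom(seed = 7, field_nm = 2560)
  p2 <- generate_phantom(seed = 7, field_nm = 2560)
  expect_identical(p1$image, p2$image)
  p3 <- generate_phantom(seed = 8, field_nm = 2560)
  expect_false(identical(p1$image, p3$image))
  empty <- generate_phantom(vessel_spec(n_vessels = 0, include_junction = FALSE),
                            field_nm = 2560)
  expect_true(all(empty$image == 0))
  expect_error(generate_phantom(vessel_spec(n_vessels = 1,
                                            width_range = c(15, 15)),
                                field_nm = 2560, seed = 1),
               "below 2 pixels")
  # generation must not disturb the session RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_phantom(seed = 3, field_nm = 2560))
  expect_identical(runif(1), before)
})

test_that("the calibrated junction embeds two branches 120 nm apart on the test line", {
  ph <- generate_phantom(seed = 0)
  prof <- line_profile(ph, ph$test_line$start, ph$test_line$end, n = 601L)
  pk <- psexcite:::find_peaks(prof$value)
  pos <- prof$radius[pk$index[pk$prominence >= 0.05]]
  expect_length(pos, 2L)
  expect_equal(diff(pos), 120, tolerance = 10 / 120)   # within one pixel
})

test_that("convolution reproduces the kernel from a point source and preserves flat fields", {
  k <- build_psf_kernel(sys532, "phase_shifted", pixel_size_nm = 10)
  n <- 101L; h <- (nrow(k$values) - 1L) / 2L
  delta <- matrix(0, n, n); delta[51, 51] <- 1
  out <- simulate_image(list(image = delta, pixel_size = 10), k)
  expect_equal(out$image[(51 - h):(51 + h), (51 - h):(51 + h)],
               k$values, tolerance = 1e-7)
  flat <- simulate_image(list(image = matrix(1, n, n), pixel_size = 10), k)
  expect_equal(flat$image, matrix(1, n, n), tolerance = 1e-6)
  expect_error(simulate_image(list(image = delta, pixel_size = 5), k),
               "pixel sizes")
})

test_that("interior signal is conserved and convolution is linear", {
  k <- build_psf_kernel(sys532, "gaussian", pixel_size_nm = 10)
  n <- 201L
  xs <- seq_len(n)
  blob <- exp(-((outer(xs, rep(101, n), "-"))^2 +
                (outer(rep(101, n), xs, "-"))^2) / (2 * 15^2))
  blob[blob < 1e-10] <- 0   # compact support well inside the border
  out <- simulate_image(list(image = blob, pixel_size = 10), k)
  expect_equal(sum(out$image), sum(blob), tolerance = 1e-6)
  set.seed(1)
  p1 <- matrix(runif(n * n), n, n); p2 <- matrix(runif(n * n), n, n)
  s1 <- simulate_image(list(image = p1, pixel_size = 10), k)$image
  s2 <- simulate_image(list(image = p2, pixel_size = 10), k)$image
  s12 <- simulate_image(list(image = 2 * p1 + 3 * p2, pixel_size = 10), k)$image
  expect_equal(s12, 2 * s1 + 3 * s2, tolerance = 1e-9)
})

test_that("line profiles interpolate bilinearly and validate their segment", {
  ph <- parallel_pair_phantom(400, vessel_width_nm = 80, field_nm = 1280)
  # a single straight vessel cut yields one peak
  one <- line_profile(ph, c(640, 340), c(640, 540), n = 101L)
  expect_equal(count_resolved_peaks(one), 1L)
  expect_equal(max(one$value), 1)
  expect_error(line_profile(ph, c(640, 340), c(640, 340), n = 11L), "degenerate")
  expect_error(line_profile(ph, c(-50, 0), c(640, 640)), "inside")
  # monotone profile has no interior peaks
  expect_equal(count_resolved_peaks(radial_profile(0:10, seq(0, 1, 0.1))), 0L)
})

test_that("the 120 nm junction is unresolved by Gaussian but resolved by phase-shifted excitation", {
  ph <- generate_phantom(seed = 0)
  kg <- build_psf_kernel(sys532, "gaussian", pixel_size_nm = 10)
  kp <- build_psf_kernel(sys532, "phase_shifted", excitation_config(1.16),
                         pixel_size_nm = 10)
  profs <- lapply(list(ph,
                       simulate_image(ph, kg),
                       simulate_image(ph, kp)),
                  function(im) line_profile(im, ph$test_line$start,
                                            ph$test_line$end, n = 201L))
  expect_equal(count_resolved_peaks(profs[[1]]), 2L)   # ground truth
  expect_equal(count_resolved_peaks(profs[[2]]), 1L)   # single broad peak
  expect_equal(count_resolved_peaks(profs[[3]]), 2L)   # two distinct maxima
})

test_that("two-point resolution thresholds sit near the respective central-lobe widths", {
  kg <- build_psf_kernel(sys532, "gaussian", pixel_size_nm = 10)
  kp <- build_psf_kernel(sys532, "phase_shifted", excitation_config(1.16),
                         pixel_size_nm = 10)
  tg <- resolution_threshold_nm(kg)
  tp <- resolution_threshold_nm(kp)
  expect_lt(tp, tg)
  expect_gte(tg, 142 - 20); expect_lte(tg, 142 + 20)
  expect_gte(tp, 100 - 20); expect_lte(tp, 100 + 20)
})
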