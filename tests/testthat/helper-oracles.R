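# Independent numerical oracles used across the suite.

# total beam power by adaptive quadrature of I(r) * 2 pi r
quad_power <- function(intensity_fn, upper, rel.tol = 1e-9) {
  stats::integrate(function(r) intensity_fn(r) * 2 * pi * r, 0, upper,
                   rel.tol = rel.tol, abs.tol = 0)$value
}

# FWHM of the effective excitation profile measured on a dense sampled
# curve (linear interpolation of the half-max crossing), independent of the
# analytic root-finding path
sampled_fwhm <- function(gamma, n = 1e5, rmax = 4) {
  r <- seq(0, rmax, length.out = n)
  v <- abs(gaussian_intensity(r, beam_spec(gamma, 1)) -
           donut_intensity(r, beam_spec(1, 1)))
  half <- v[1] / 2
  i <- which(v < half)[1]
  frac <- (v[i - 1] - half) / (v[i - 1] - v[i])
  2 * (r[i - 1] + frac * (r[i] - r[i - 1]))
}

# half-max reduced coordinate by plain bisection on (gamma - x) e^-x = gamma/2
bisect_half_max_x <- function(gamma, tol = 1e-12) {
  f <- function(x) (gamma - x) * exp(-x) - gamma / 2
  lo <- 0; hi <- gamma
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# smallest separation (nm) on a grid that a kernel resolves into two peaks
# on the parallel-pair target
resolution_threshold_nm <- function(kernel, separations = seq(80, 160, 10)) {
  for (s in separations) {
    ph <- parallel_pair_phantom(s)
    im <- simulate_image(ph, kernel)
    pr <- line_profile(im, ph$test_line$start, ph$test_line$end, n = 201L)
    if (count_resolved_peaks(pr) == 2L) return(s)
  }
  NA_real_
}
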