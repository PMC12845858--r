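#' Focused beam specification
#'
#' Bundles the optical power and beam waist of one focused beam. Both beams
#' of a phase-shifted pair share the same waist because they are assumed
#' confocally focused by the same objective at identical wavelength; in
#' normalized mode `waist = 1` and lengths are expressed in waist units.
#'
#' @param power Optical power (arbitrary power units, >= 0).
#' @param waist Beam waist `w0` at the focal plane (length units, > 0).
#' @return An object of class `beam_spec`.
#' @examples
#' beam_spec(power = 1.16, waist = 1)
#' @export
beam_spec <- function(power = 1, waist = 1) {
  stopifnot(is.numeric(power), length(power) == 1L, is.finite(power),
            is.numeric(waist), length(waist) == 1L, is.finite(waist))
  if (power < 0) stop("beam power must be >= 0")
  if (waist <= 0) stop("beam waist must be > 0")
  structure(list(power = power, waist = waist), class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("<beam_spec> power = %g, waist = %g\n", x$power, x$waist))
  invisible(x)
}

check_radius <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0))
    stop("radius must be finite and >= 0")
  r
}

#' Focal-plane intensity of a focused Gaussian (TEM00) beam
#'
#' Average intensity of a Gaussian beam of power `P` and waist `w0` at the
#' focal plane: `I(r) = 2P/(pi w0^2) * exp(-2 r^2 / w0^2)`. Integrating the
#' profile over the transverse plane recovers the full power `P`.
#'
#' @param r Radial coordinate(s), same length units as the waist; >= 0.
#' @param beam A [beam_spec()].
#' @return Intensity value(s), vectorized over `r`.
#' @examples
#' gaussian_intensity(0, beam_spec(1, 1))   # peak 2/pi
#' @export
gaussian_intensity <- function(r, beam) {
  check_radius(r)
  w0 <- beam$waist
  2 * beam$power / (pi * w0^2) * exp(-2 * r^2 / w0^2)
}

#' Focal-plane intensity of an LG01 donut beam
#'
#' Average intensity of the power-normalized Laguerre-Gaussian donut mode
#' (radial index 0, azimuthal index 1):
#' `I(r) = 4P/(pi w0^4) * r^2 * exp(-2 r^2 / w0^2)`. The profile is zero on
#' axis and peaks at `r = w0 / sqrt(2)`.
#'
#' @inheritParams gaussian_intensity
#' @return Intensity value(s), vectorized over `r`.
#' @examples
#' donut_intensity(1 / sqrt(2), beam_spec(1, 1))   # ring peak 2/(pi e)
#' @export
donut_intensity <- function(r, beam) {
  check_radius(r)
  w0 <- beam$waist
  4 * beam$power / (pi * w0^4) * r^2 * exp(-2 * r^2 / w0^2)
}

#' Complex field amplitude of the LG01 donut mode (unnormalized shape)
#'
#' Field shape `E(r, theta) = (sqrt(2) r / w0) exp(-r^2 / w0^2) exp(i theta)`:
#' an on-axis null with a helical phase that winds once per azimuthal
#' revolution. Multiplying `|E|^2` by the power normalization
#' `A = 2P/(pi w0^2)` reproduces [donut_intensity()]. The phase factor is
#' carried for completeness; all downstream computation uses average
#' intensities because the beams are non-interfering (orthogonal circular
#' polarizations in the proposed hardware).
#'
#' @inheritParams gaussian_intensity
#' @param theta Azimuthal angle(s) in radians.
#' @return Complex field value(s), vectorized over `r` and `theta`.
#' @export
donut_field_amplitude <- function(r, theta, beam) {
  check_radius(r)
  w0 <- beam$waist
  (sqrt(2) * r / w0) * exp(-r^2 / w0^2) * exp(1i * theta)
}

#' Radial profile container
#'
#' An ordered set of radii (starting at 0, strictly increasing) with a
#' nonnegative value at each radius: an intensity curve or an effective
#' excitation (|difference|) curve.
#'
#' @param radii Strictly increasing nonnegative radii, first element 0.
#' @param values Nonnegative values, same length as `radii`.
#' @return A `radial_profile` data frame with columns `radius`, `value`.
#' @export
radial_profile <- function(radii, values) {
  stopifnot(is.numeric(radii), is.numeric(values),
            length(radii) == length(values), length(radii) >= 2L)
  if (radii[1] != 0) stop("radial profile must start at r = 0")
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (any(values < 0)) stop("profile values must be >= 0")
  structure(data.frame(radius = radii, value = values),
            class = c("radial_profile", "data.frame"))
}

#' Sampled 2D intensity map
#'
#' A square grid of nonnegative values with odd side length so the optical
#' axis falls exactly on the central sample, plus the physical pixel
#' spacing. Coordinates are centered: pixel `(i, j)` sits at
#' `((j - c) * pixel_size, (i - c) * pixel_size)` with `c` the center index.
#'
#' @param values Square numeric matrix with odd dimensions, all >= 0.
#' @param pixel_size Grid spacing (length units, > 0).
#' @return An `intensity_map` object.
#' @export
intensity_map <- function(values, pixel_size) {
  stopifnot(is.matrix(values), is.numeric(values))
  n <- nrow(values)
  if (n != ncol(values)) stop("intensity map must be square")
  if (n %% 2L == 0L) stop("intensity map side must be odd (center sample required)")
  if (any(values < 0)) stop("intensity map values must be >= 0")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(values = values, pixel_size = pixel_size,
                 origin = c((n + 1) / 2, (n + 1) / 2)),
            class = "intensity_map")
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf("<intensity_map> %d x %d, pixel %g, peak %g\n",
              nrow(x$values), ncol(x$values), x$pixel_size, max(x$values)))
  invisible(x)
}

#' Render a radial intensity function on a centered Cartesian grid
#'
#' Samples `intensity_fn(r)` on an odd `n x n` grid spanning
#' `[-extent, extent]` in both axes. A radially symmetric input yields a map
#' symmetric under x/y reflection and transposition.
#'
#' @param intensity_fn Function of radius returning nonnegative intensity.
#' @param extent Half-width of the grid (length units, > 0).
#' @param n Samples per side; odd, >= 3.
#' @return An [intensity_map()].
#' @examples
#' m <- render_map(function(r) gaussian_intensity(r, beam_spec()), 3, 101)
#' m$values[51, 51]   # on-axis peak 2/pi
#' @export
render_map <- function(intensity_fn, extent, n = 501L) {
  stopifnot(is.function(intensity_fn), extent > 0)
  n <- as.integer(n)
  if (n < 3L || n %% 2L == 0L) stop("n must be odd and >= 3 so the axis lies on a sample")
  xs <- seq(-extent, extent, length.out = n)
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  vals <- matrix(intensity_fn(as.vector(rr)), n, n)
  intensity_map(vals, pixel_size = xs[2] - xs[1])
}
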