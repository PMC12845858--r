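#' Thermal diffusion length under harmonic heating
#'
#' Characteristic penetration length of the periodic temperature field for
#' sinusoidal heating at frequency `f`: `L = sqrt(alpha / (pi f))`. Thermal
#' confinement requires `L` to be small compared with the excitation spot
#' within one modulation cycle. Units are fixed: `alpha` in m^2/s, `f` in
#' MHz, result in nm.
#'
#' @param alpha Thermal diffusivity in m^2/s (> 0). Soft tissue is about
#'   1.3e-7 m^2/s.
#' @param f_mhz Modulation frequency in MHz (> 0).
#' @return Diffusion length in nm.
#' @examples
#' diffusion_length(1.3e-7, 4.14)   # ~100 nm
#' @export
diffusion_length <- function(alpha = 1.3e-7, f_mhz) {
  if (alpha <= 0) stop("thermal diffusivity must be > 0")
  if (f_mhz <= 0) stop("modulation frequency must be > 0")
  sqrt(alpha / (pi * f_mhz * 1e6)) * 1e9
}

#' Modulation frequency at which the diffusion length equals a spot size
#'
#' Inverts [diffusion_length()]: `f = alpha / (pi L^2)`, reported in MHz for
#' `L` in nm. For soft tissue (`alpha = 1.3e-7 m^2/s`) this is
#' `~4.14e4 / L_nm^2` MHz, so a 100 nm effective excitation spot requires
#' about 4.14 MHz; confinement calls for operating well above this value.
#'
#' @inheritParams diffusion_length
#' @param L_nm Diffusion length (spot size scale) in nm (> 0).
#' @return Frequency in MHz.
#' @examples
#' min_confinement_frequency(1.3e-7, 100)   # ~4.14 MHz
#' @export
min_confinement_frequency <- function(alpha = 1.3e-7, L_nm) {
  if (alpha <= 0) stop("thermal diffusivity must be > 0")
  if (L_nm <= 0) stop("diffusion length must be > 0")
  alpha / (pi * (L_nm * 1e-9)^2) / 1e6
}

#' Advisory check of the thermal confinement condition
#'
#' TRUE when the modulation frequency exceeds the minimum confinement
#' frequency for the given spot size by at least `safety_factor`. The
#' default factor of 5 reflects that confinement requires operating
#' significantly above the break-even frequency (tens of MHz for a
#' ~100 nm spot).
#'
#' @inheritParams min_confinement_frequency
#' @param f_mhz Modulation frequency in MHz.
#' @param safety_factor Multiplicative margin, >= 1. Default 5.
#' @return Logical advisory.
#' @export
is_confined <- function(f_mhz, L_nm, alpha = 1.3e-7, safety_factor = 5) {
  if (safety_factor < 1) stop("safety_factor must be >= 1")
  f_mhz >= safety_factor * min_confinement_frequency(alpha, L_nm)
}
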