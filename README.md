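# psexcite

Numerical model of **phase-shifted dual-beam excitation** for
frequency-domain photoacoustic microscopy (FD-PAM), for researchers
designing or evaluating sub-diffraction photoacoustic imaging systems.

A focused TEM₀₀ Gaussian beam (power *P<sub>G</sub>*) and an LG₀₁ donut
beam (power *P<sub>D</sub>*), co-focused with identical waist *w₀*, are
sinusoidally intensity-modulated at the same frequency with the donut π
radians out of phase. The lock-in-detected photoacoustic amplitude is then
proportional to the AC component of the absorbed power density,

> p(r) ∝ μ<sub>a</sub> · m · |I<sub>G</sub>(r) − I<sub>D</sub>(r)|,

with I<sub>G</sub>(r) = (2P<sub>G</sub>/πw₀²)·exp(−2r²/w₀²) and
I<sub>D</sub>(r) = (4P<sub>D</sub>/πw₀⁴)·r²·exp(−2r²/w₀²). In the reduced
coordinate x = 2r²/w₀² this effective excitation profile is
|γ − x|·e<sup>−x</sup> (γ = P<sub>G</sub>/P<sub>D</sub>), which the package
analyzes exactly: central-lobe FWHM by root-finding, side lobe at
x = 1 + γ with ratio e<sup>−(1+γ)</sup>/γ, power-ratio trade-off sweeps,
time-domain modulation snapshots, physical-unit PSF kernels
(w₀ = λ/(π·NA)), convolution imaging on a seeded synthetic
microvasculature phantom, absorbed-energy SNR estimates and a thermal
confinement calculator.

## Worked example

```r
library(psexcite)

measure_psf(excitation_config(gamma = 1.16))
#> <psf_metrics> gamma = 1.16
#>   central-lobe FWHM : 0.8280 w0
#>   side-lobe / peak  : 0.0994
#>   zero crossing     : 0.7616 w0
enhancement_factor(1.16)
#> [1] 1.421924
```

At the operating power ratio γ = 1.16 the effective excitation lobe is
0.828 w₀ wide versus 1.177 w₀ for the Gaussian focus — a ~1.42-fold
lateral confinement — while the ring artifact stays just below 10% of the
central peak. The ratio itself falls out of the trade-off sweep:

```r
select_optimal_ratio(power_ratio_sweep(), sidelobe_threshold = 0.10)
#> [1] 1.16
snr_ratio(1.16)
#> <snr_result> gamma = 1.16, x_delta = 0.4946
#>   absorbed energy (Gaussian 1/e)      : 0.73326
#>   absorbed energy (difference region) : 0.36404
#>   SNR ratio 0.4965  (penalty 6.08 dB)
min_confinement_frequency(1.3e-7, 100)   # MHz to confine heat in a 100 nm spot
#> [1] 4.138029
```

In physical units (λ = 532 nm, NA = 1.4) the Gaussian PSF is ~142 nm FWHM
and the phase-shifted central lobe ~100 nm; on the synthetic phantom's
calibrated junction (two 60 nm vessels, 120 nm apart) the
Gaussian-convolved image shows one merged peak and the phase-shifted image
two resolved ones:

```r
sys <- optical_system(532, 1.4)
ph  <- generate_phantom(seed = 0)
kp  <- build_psf_kernel(sys, "phase_shifted", pixel_size_nm = 10)
pr  <- line_profile(simulate_image(ph, kp), ph$test_line$start, ph$test_line$end)
count_resolved_peaks(pr)
#> [1] 2
```

## Command line

The installed script drives every analysis and writes CSV/TIFF/PNG
artifacts, a metrics JSON and a manifest of all effective parameters:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","psexcite.R",package="psexcite"))')" \
  psf --gamma 1.16 --out out/
# also: sweep, snapshots, image, snr, thermal  (--help per subcommand)
```

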