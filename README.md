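# pbiphase

Single-distance phase retrieval for propagation-based X-ray
phase-contrast imaging (PBI), with both the classical continuous-kernel
Lorentzian filter and its discrete-mathematics rederivation, and the
tooling needed to quantify what the discrete kernel buys you on a real
detector.

## The problem

PBI converts phase gradients into edge fringes by letting the beam
propagate a distance Δ after the sample. For a homogeneous object the
transport-of-intensity equation (TIE) gives a one-step retrieval of the
contact (pure attenuation) image as a Fourier filter:

    I_ret = F⁻¹[ F[I/I₀] / (1 + (δΔ/µ) k⊥²) ]

The standard filter uses the continuous squared frequency
k⊥² = kx² + ky² ("PM" kernel). On sampled images the Fourier
derivative theorem actually holds for the five-point discrete
Laplacian, whose eigenvalues replace it with the cosine kernel
("GPM")

    k⊥² = −(2/W²)[cos(W kx) + cos(W ky) − 2],

which is smaller near the Nyquist frequency π/W, so the discrete
filter blurs less and retrieves a sharper image. The catch: the gain
lives at high spatial frequencies, exactly where the detector point
spread function (PSF) attenuates. This package implements both kernels
behind every retrieval operator, the transfer-function algebra
(ratio R = H_GPM/H_PM, fractional difference D, PSF-blurred D̄), a
deterministic TIE forward simulator with disc phantoms, Pearson VII
line-spread-function metrology of the resulting resolution, rebinning
analysis, parallel-beam FBP, the two-material boundary filter, and
dual-energy photoelectric/electron-density decomposition — all with
the kernel as a switch.

For whom: anyone processing PBI projections or CT (synchrotron or
lab), choosing between retrieval kernels, or needing to predict
whether their detector's PSF will let the discrete kernel matter.

## Worked example

Simulate the disc-phantom study at reduced scale (512² detector grid,
25 µm pixels, 6 mm water cylinder, ×5 upsampled projection, distance
set by the single-fringe criterion), and measure the LSF width of the
edge after retrieval with each kernel at detector PSFs of 1–3 px:

```r
library(pbiphase)
res <- fig2_resolution_sweep(c(1, 2, 3), shape = 512,
                             radius_px = 225.125)
res
#>   psf_fwhm gamma_pc gamma_pm gamma_gpm improvement improvement_se
#> 1        1 1.240435 1.511366  1.412739 0.065256839    0.009932265
#> 2        2 2.110349 2.328088  2.295514 0.013991717    0.010145545
#> 3        3 3.052065 3.218093  3.203964 0.004390587    0.010326705
```

`gamma_pc` is the fitted FWHM (pixels) of the phase-contrast edge
before retrieval; `gamma_pm`/`gamma_gpm` after retrieval with each
kernel. With a single-pixel PSF the discrete kernel narrows the LSF by
~6.5%; by a 3-pixel PSF the detector has removed the frequencies where
the kernels differ and the gain is under half a percent.

The filter algebra behind that trend is available in closed form:

```r
g <- frequency_grid(512, 25e-6)
opt <- builtin_material("water", 24)
r <- transfer_ratio(g, opt$delta, opt$mu, distance = 9.3e-3)
max(r)          # GPM/PM amplification at the grid corner
#> [1] 1.665703
```

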