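# Example run configuration.  Every physical quantity carries an
# explicit unit; unknown keys are rejected.
geometry:
  pixel_size: 25 um
  distance: 9.25 mm
  psf_fwhm: 1 px
  shape: [1024, 1024]
materials:
  water:
    delta: 3.99e-7
    mu: 57.2 1/m
    energy: 24 keV
  pmma:
    delta: 4.63e-7
    mu: 51.1 1/m
    energy: 24 keV
kernel: gpm
simulation:
  radius: 450.25 px
  thickness: 6 mm
  upsample: 5
  pre_blur: 1 px
metrology:
  r_min: 435 px
  r_max: 465 px
  arc: [0 deg, 360 deg]
  bin_width: 0.1 px
spectral:
  energy_a: 30 keV
  energy_b: 40 keV
seed: 1
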