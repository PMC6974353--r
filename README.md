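# onloptics

Wave-optical modelling of how rod-photoreceptor nuclear architecture shapes
light scattering in the retinal outer nuclear layer (ONL), with the
image-quality analytics used to measure the consequences.

Rod nuclei of nocturnal mammals fuse their many heterochromatin bodies
(chromocenters) into a single central one — the "inverted" architecture.
Heterochromatin (refractive index ≈ 1.382) is optically denser than
euchromatin (≈ 1.357), so every nucleus is a weak phase object in the light
path, and the arrangement of the dense phase — at *fixed* composition —
changes how much light is thrown sideways into a contrast-degrading veil.
`onloptics` is for vision scientists and tissue-optics modellers who want to
quantify that effect in silico and to analyze the corresponding
measurements.

## What is inside

| module | exported surface |
|---|---|
| Mie core | `sphere_spec()`, `mie_efficiencies()`, `phase_function()`, `fusion_series()`, `dependent_packing_factor()` |
| ONL phantom builder | `generate_packed_nuclei()`, `chromatin_params()`, `assign_inverted()`, `assign_chromocenters()`, `smooth_and_embed()`, `sphere_phantom()` |
| Beam propagation | `propagate()`, `angular_spectrum()`, `large_angle_fraction()`, `compare_models()`, `gaussian_beam()`, `farfield_psf()` |
| Image quality | `stripe_contrast()`, `mtf_curve()`, `strehl_ratio()`, `psf_metrics()`, `diffuse_transmission()`, `scattering_to_mtf()`, `volume_specific_scattering()`, `aulc()` |
| Synthetic data | `make_stripe_stack()`, `make_psf_image()`, `make_facs_table()`, `make_cs_trials()`, `estimate_thresholds()` |
| Pipeline / IO | `pipeline_config()`, `run_pipeline()`, `read_volume()`/`write_volume()` (float TIFF + JSON sidecar), `read_curve()`/`write_curve()`; CLI at `inst/cli/onloptics.R` |

The core quantity ranking scatterers is the **hiding power**
`H = Qsca (1 − g)` — the scattering efficiency weighted by the non-forward
fraction of the phase function — reported per particle and per unit
scatterer volume along a volume-conserving fusion series (N chromocenters of
diameter `d·N^(−1/3)`).

## Worked example

```r
library(onloptics)

## Mie scattering of a fused 2 um chromocenter (2% contrast, 500 nm)
eff <- mie_efficiencies(sphere_spec(2, 1.04, 1.02, wavelength = 500,
                                    n_medium_abs = 1.357))
print(eff)
#> Mie efficiencies (x = 17.053, 30 orders):
#>   Qsca = 0.21998  Qext = 0.21998  g = 0.988032
#>   Csca = 0.691087 um^2  hiding power Qsca(1-g) = 0.00263275  Qsca*g = 0.217347

## split the same heterochromatin volume into N chromocenters
fusion_series(2, counts = c(1, 2, 4, 8, 12))[, c("N", "d_sub", "volume_specific_H")]
#>    N  d_sub volume_specific_H
#> 1  1 2.0000          0.001975
#> 2  2 1.5874          0.002285
#> 3  4 1.2599          0.002662
#> 4  8 1.0000          0.003050
#> 5 12 0.8736          0.003282

## paired phantom experiment: same nuclei, two chromatin architectures
lv  <- generate_packed_nuclei(12, c(128, 128, 96), 0.166, 2.2, 0.2, seed = 1)
cmp <- compare_models(lv, chromatin_params(), seed = 2)
print(cmp)
#> paired ONL scattering comparison (theta > 30 deg):
#>   inverted architecture:      fraction 8.4796e-07 (side Csca 0.00038284 um^2)
#>   chromocenter architecture:  fraction 6.7879e-06 (side Csca 0.0030646 um^2)
#>   chromocenter / inverted ratio: 8.005
```

Reading the numbers: a single fused 2 µm chromocenter has volume-specific
hiding power 0.0020 µm⁻¹, rising monotonically to 0.0033 µm⁻¹ when the same
volume is split into 12 chromocenters — many small scatterers throw more
light sideways per unit heterochromatin. The full-wave phantom experiment
agrees in direction: with identical nucleus geometry, the multi-chromocenter
painting sends about eight times more power beyond 30° than the inverted
painting.

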