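# pamrs — powder-averaged analysis of diffusion-weighted MR spectroscopy

Diffusion-weighted MR spectroscopy (DW-MRS) follows the diffusion of
metabolites like N-acetyl aspartate inside neurons, but its large voxels
mix the anisotropy of single fibers with the orientation dispersion of
fiber bundles. `pamrs` implements the powder-averaging analysis of such
data: averaging signals over uniformly distributed gradient directions
yields a decay identical to that of a fully dispersed sample, and
fitting orientation-averaged compartment models to it recovers
*microscopic* diffusivities unconfounded by dispersion.

The core models are the uniformly dispersed axisymmetric tensor

S(b) = S₀ e^(−bD_T) (√π/2) erf(√(b(D_L−D_T))) / √(b(D_L−D_T))

and its stick limit (D_T = 0), with derived compartment
MD = (D_L + 2D_T)/3 and microscopic anisotropy
μFA = (D_L − D_T)/√(D_L² + 2D_T²). Around them the package provides:

- constrained nonlinear least-squares fitting of powder-averaged decays,
  high-b `b^(-1/2)`-asymptote diagnostics, and the sensitivity optimum
  of the stick model (bD_L ≈ 2.284);
- the macroscopic (voxel-averaged) diffusion tensor from per-direction
  initial-slope diffusivities (gamma-distributed-diffusivity fits), its
  FA, and the dispersed-stick angular spread
  θ = arccos√(⟨D_L⟩/(3⟨MD⟩));
- electrostatic-repulsion gradient schemes, uniform rotation sampling,
  bipolar PRESS-style encoding waveforms and exact b-matrix computation
  with cross-terms;
- simulation studies: noise propagation over a μFA grid, rotational
  variance of finite direction sets, their combination, and compiled
  Monte Carlo random walks in impermeable cylinders under the
  experimental waveforms;
- a synthetic-data generator emulating directional metabolite
  acquisitions from dispersed-fiber substrates (Watson-type angular
  spread, repetition-level noise), for end-to-end testing without any
  scanner data.

## Worked example

Generate a synthetic dispersed-white-matter acquisition (12 directions,
five b-values to 14.5 ms/μm², 12 repetitions, SNR 50, stick fibers with
D_L = 0.5 μm²/ms at 46° angular spread) and run the full pipeline:

```r
library(pamrs)
pre <- scenario_preset("PWM")
ds  <- generate_dataset(pre, preset_scheme(pre), seed = 1)
run_full_pipeline(ds)
#> pipeline_result
#> powder_fit [stick]: S0 = 1.004, D_L = 0.5088, D_T = 0 um^2/ms (MD = 0.1696, uFA = 1.000)
#> powder_fit [tensor]: S0 = 1.004, D_L = 0.5088, D_T = 0 um^2/ms (MD = 0.1696, uFA = 1.000)
#> macro_tensor: eigenvalues (0.279, 0.177, 0.13), MD = 0.195, FA = 0.371
#> dispersion angle theta = 46.4 deg
```

The stick fit recovers the microscopic D_L (0.509 vs. truth 0.5)
regardless of the substrate's orientation dispersion, the tensor fit
confirms a near-unity microscopic anisotropy, and the macroscopic tensor
— much less anisotropic than a single fiber — yields the angular spread
θ ≈ 46.4° (truth 46°). `analysis/05_end_to_end_pipeline.R` extends this
to a five-subject comparison of an aligned (CC-like) and a dispersed
(PWM-like) region: the microscopic metrics are statistically
indistinguishable between regions while macroscopic FA and θ separate
them at p < 10⁻⁴.

The `analysis/` directory holds the numbered study drivers
(`01_models_and_schemes.R` … `05_end_to_end_pipeline.R`); each prints
its findings and writes tidy tables under `results/`.

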