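# kfactor3d

K-factor image deshadowing for three-dimensional single-molecule
localization microscopy.

Localization microscopy (PALM/STORM and relatives) estimates emitter
positions far below the diffraction limit by fitting a point-spread-function
(PSF) model to each spot. In 3D z-stacks this is hampered by the elongated
axial PSF, out-of-focus rings, background noise, and overlapping emitters.
`kfactor3d` implements a nonlinear multiplicative image decomposition — the
K-factor transform — and the deshadowing filter built on it, plus everything
needed to study it quantitatively: Gaussian and Gibson–Lanni PSF simulators
with Poisson noise, least-squares 3D single-emitter localization, and Monte
Carlo harnesses for localization precision and two-emitter resolvability.
It is aimed at microscopy method developers and analysts who want a fully
scripted, reproducible 3D localization pipeline in R.

## The method in brief

A frame `I`, normalized to its maximum, is factorized into `M` contrast
factors with a decreasing schedule of contrast depths `k_n ∈ (0,1)`
(default: `k_n = 1 − n/10`, nine factors):

    g_n = [ I / (f_1 ⋯ f_{n−1}) ≥ k_n ],     f_n = g_n + k_n (1 − g_n)

Each binary mask `g_n` thresholds the running residual; the factor is 1 on
the mask and `k_n` off it; the product of all factors reconstructs the image
up to one contrast-quantization step. **Deshadowing** multiplies the image
by all of its factors, which squares the effective contrast: peaks narrow,
background and diffraction rings are floored, and a plain 3D Gaussian fit
then localizes emitters accurately. Supporting models:

* Gaussian PSF with aberration-free widths
  `σ_xy = √3·λ/(4·NA)`, `σ_z = 3·λ/(2·NA²)`
  (167 nm and 413 nm for a 1.4 NA oil objective at 540 nm);
* Gibson–Lanni scalar-diffraction PSF
  `I(r,z) ∝ |∫₀¹ J₀(k·NA·r·ρ) e^{ikW(ρ;z)} ρ dρ|²` over immersion,
  coverslip and sample strata;
* Poisson shot noise plus Poisson background with mean `N_b`.

## Worked example

Simulate one emitter (N = 5000 photons, background 5 photons/pixel) under
the diffraction PSF, deshadow every plane, and localize with a Gaussian fit:

```r
library(kfactor3d)

cfg <- optical_config()      # 1.4 NA oil, 540 nm, 102 nm px, 200 nm z-step
theoretical_sigmas(cfg)
#> sigma_xy  sigma_z
#> 167.0192 413.2653

em <- data.frame(x0 = 1020, y0 = 1020, z0 = 1600, photons = 5000)
stack <- gibson_lanni_psf_stack(em, gibson_lanni_params(), cfg) |>
  add_noise(noise_model(background_mean = 5, seed = 1))

processed <- deshadow_stack(stack)
localize_stack(processed, cfg, model = "gaussian", min_peak = 10)
#> # A tibble: 1 × 11
#>    x_nm  y_nm  z_nm photons model    converged residual ...
#> 1 1022. 1030. 1581.    904. gaussian TRUE        0.0500
```

The emitter sits at (1020, 1020, 1600) nm; the fit lands within ~10 nm
laterally and one tenth of a z-step axially. (The photon estimate on
deshadowed data is a contrast-compressed effective count, not the raw
photon number — use raw-stack fits when absolute intensities matter.)

Harness one-liners, each returning a tidy object with `tidy()`, `glance()`
and `autoplot()` methods:

```r
mc <- mc_localization_experiment(photon_levels = c(1000, 5000), L = 50, seed = 1)
autoplot(mc)   # RMS error vs photon count per method, lateral and axial

res <- min_resolvable_distance(axis = "lateral", method = "kfactor",
                               trials = 50, seed = 1)
glance(res)    # smallest separation resolved in ≥ 80% of trials
```

A thin command-line wrapper for shell pipelines lives at
`inst/cli/kfactor3d` (subcommands `simulate`, `kfactor`, `localize`,
`evaluate`, `pipeline`, `fixtures`); after installation call it as
`Rscript $(Rscript -e 'cat(system.file("cli/kfactor3d", package="kfactor3d"))') <subcommand> ...`.

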