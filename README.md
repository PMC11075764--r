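# lcfr

**Localized convolutional function regression for dynamic contrast-enhanced
MRI** — simultaneous, voxelwise recovery of effective diffusion, 3D
interstitial fluid velocity, and extended Tofts–Kety perfusion parameters
from 4D DCE-MRI concentration data.

## The problem

Interstitial fluid flow shapes drug delivery, immune-cell trafficking and
tumor invasion, but measuring it noninvasively is hard: standard DCE-MRI
analysis fits an ordinary differential equation to each voxel in isolation
and throws away the spatial information that advection and diffusion leave
in the data. `lcfr` is for imaging scientists who want the full transport
picture from a routine dynamic acquisition.

## The method

Contrast transport is modelled by an advection–diffusion–reaction PDE with
vascular forcing:

```
∂t c = ∇·(D ∇c) − ∇·(u c) + Ktrans·VIF(t) − Kep·c + vp·∂t VIF
```

Instead of differentiating noisy images, the data are *convolved* with a
compactly supported polynomial test function Ψ and its analytic
derivatives, moving every derivative onto Ψ by integration by parts (the
weak form). The projected PDE becomes a small linear model

```
c~t = Θ Ξ,   Θ = [c~xx, c~yy, c~zz, c~x, c~y, c~z, c~, VIF~, VIF~t]
```

solved by ordinary least squares on every 3×3×3 voxel window over all time
points. The local coefficient vector Ξ maps directly to physical fields:
`D = ξ_D` (mm²/s), `u = −ξ_u` (mm/s, reported as speed `|ξ_u|` plus
direction), `Ktrans = ξ_trans` (1/s), `vp = ξ_VIF`, efflux `−ξ_ep` (1/s).
FFT-equivalent separable convolutions and closed-form Gram matrices make a
64×64×5×49 fit run in seconds on one CPU.

The package also ships the surrounding practice: forward
advection–diffusion and Tofts–Kety simulators with three validation
phantoms and a calibrated noise model; variable-flip-angle T1 mapping,
SPGR signal-to-concentration conversion, bolus-arrival-time estimation by
bilinear regression, automatic vascular-input-function extraction and
per-voxel VIF alignment; NIfTI/CSV/YAML IO, ggplot2 `autoplot()` methods,
broom-style `tidy()`/`glance()`, and a four-subcommand CLI
(`system.file("cli", "lcfr.R", package = "lcfr")`).

## Worked example

Simulate the divergent-flow phantom (unit-speed outward flow, D = 0.75
mm²/s), add 0.1 % Gaussian noise, recover the transport fields, and score
them against the ground truth:

```r
library(lcfr)

cfg   <- default_config()
sim   <- simulate_scenario("divergent", cfg)
noisy <- add_noise(sim$conc, noise_spec(0.001, seed = 1))
fit   <- recover_transport(noisy, support = c(4, 4, 1, 3))
summarize_recovery(fit$physical, sim$truth, mask = mask_enhancing(sim$conc))
```

```
#> # A tibble: 7 × 9
#>   parameter units      n      mean     sd   rmse median_rel_err rel_err_q25 rel_err_q75
#>   <chr>     <chr>  <int>     <dbl>  <dbl>  <dbl>          <dbl>       <dbl>       <dbl>
#> 1 D_x       mm^2/s  2244  0.944    0.413   0.456          41.1        31.1        51.0
#> 2 u_x       mm/s    2244 -0.000381 0.647   0.207           3.88        2.14        8.45
#> 3 D_y       mm^2/s  2244  0.937    0.414   0.454          40.5        30.8       50.1
#> 4 u_y       mm/s    2244  0.000394 0.648   0.207           3.69        2.10        8.92
#> 5 D_z       mm^2/s  2244  0.00335  0.0130 NA              NA          NA          NA
#> 6 u_z       mm/s    2244  0        0      NA              NA          NA          NA
#> 7 speed     mm/s    2244  0.896    0.187   0.214           3.56        2.39        7.89
```

Reading the table: the recovered speed is 0.90 ± 0.19 mm/s against a true
1 mm/s everywhere — a median relative error of ~3.6 % at this noise level,
with the RMSE (0.21 mm/s) dominated by the band around the axes where the
velocity reverses sign and any locally-constant model smooths the jump.
`u_z` is exactly zero (the phantom is replicated in z), and the recovered
`D` exceeds the nominal 0.75 mm²/s because the upwind forward scheme adds
numerical diffusion — the estimator reports the transport actually present
in the data. `autoplot(fit$physical, channel = "speed")` and
`plot_velocity_field(fit$physical)` display the maps;
`run_validation_suite(cfg)` reruns the full noise-convergence sweep.

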