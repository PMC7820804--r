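# slbtools

Quantitative analysis of polymer-supported lipid bilayers and the T cell
contacts formed on them.

Model membranes built on soft PDMS gels (~4 kPa, matching the stiffness of
antigen-presenting cells) extend the classic glass-supported lipid bilayer:
they keep the fluidity and imaging convenience of a bilayer while presenting a
physiologically soft surface. Characterizing such a system — and the T cells
signaling on it — requires five quantitative readouts, and this package
implements all of them as a single tested toolbox:

1. **Single-particle diffusion** — particle detection, nearest-neighbor
   linking, and diffusion coefficients from the ensemble mean-square
   displacement with localization-error and motion-blur terms,
   MSD(t) = 4Dt + 4σ² − (4/3)D·t_E, plus two-component jump-distance
   (JD) mixture fits of the squared single-frame displacements,
   P(r², Δt) = Σ_j f_j/(4D_jΔt) · exp(−r²/(4D_jΔt)).
2. **FRAP** — trace normalization, effective beam radius from the bleach
   profile exp(−K·e^(−2r²/w²)), the Axelrod series fit for (K, τ_D, M_f),
   mobile fraction f_mobile = (F∞ − F0)/(F_i − F0), and D = w²/(4τ_D).
3. **Calcium signaling** — per-cell trace extraction from time-lapse stacks,
   transient detection by height and prominence in baseline multiples, and
   population metrics: fraction responding (peaks ≥ 1), fraction of
   responders with multiple peaks (> 1), latency, height, integrated
   intensity.
4. **Receptor exclusion** — two-channel contact quantification with
   rolling-ball background subtraction and Otsu masks:
   Exclusion = 1 − mean(CD45 in)/mean(CD45 out).
5. **AFM force curves** — Young's modulus by the spherical Hertz model
   F = (4/3)·E/(1−ν²)·√R·δ^(3/2), and bilayer push-through detection from
   gradient changes, measuring the z-jump (bilayer thickness), breakthrough
   force, and before/after slope ratio.

Every stage ships with a synthetic-data generator (`simulate_*()`,
`render_*()`) carrying its ground truth as an attribute, so the whole
pipeline is verifiable end to end without experimental data. Functions take
data frames first and return tibbles; fitted objects have broom-style
`tidy()`/`glance()` methods and ggplot2 `autoplot()` methods.

## Worked example

Simulate lipid tracking at one of the characterized conditions (D = 1.3
μm²/s, 264 tracks, 10 ms frames) and recover the diffusion coefficient:

```r
library(slbtools)

tracks <- simulate_tracks(n_tracks = 264, track_length = 20, d_coef = 1.3,
                          sigma_loc = 0.05, frame_interval = 0.01, seed = 11)
msd <- compute_ensemble_msd(tracks, frame_interval = 0.01)
fit <- fit_msd(msd, n_points = 5, exposure_time = 0.01)
fit
#> MSD fit (5 points, exposure model): D = 1.296 um^2/s, sigma_loc = 0.08308 um
autoplot(msd, fit)   # MSD curve with the fitted line over the first 5 lags
```

The fitted D of 1.296 μm²/s recovers the simulated 1.3 μm²/s within 0.3%;
`sigma_loc` is the static localization error implied by the fitted intercept.

AFM, same pattern — generate a noisy indentation curve on a 4.59 kPa gel and
a push-through curve with a 3.9 nm bilayer breakthrough, then analyze:

```r
fc <- simulate_force_curve(young_modulus = 4590,
                           indenter = list(type = "sphere", radius_um = 18.5),
                           contact_point_um = 1, z_range_um = 3,
                           sampling_step_nm = 2, noise_sd_nn = 1, seed = 301)
fit_hertz(fc, radius_um = 18.5)
#> Hertz fit: E = 4.632 kPa (R = 18.5 um, nu = 0.5, contact at 1.009 um, 948 pts)

pt <- simulate_force_curve(1e6,
                           indenter = list(type = "pyramid", half_angle_deg = 20),
                           contact_point_um = 1, z_range_um = 1.2,
                           sampling_step_nm = 0.5, z_jump_nm = 3.9,
                           breakthrough_force_nn = 5, noise_sd_nn = 0.02,
                           seed = 105)
detect_push_through(pt)[, c("z_jump_nm", "breakthrough_force_nn", "slope_ratio")]
#>   z_jump_nm breakthrough_force_nn slope_ratio
#> 1   3.58431              4.997236    0.951826
```

One event is found: a 3.6 nm jump at ~5 nN (true thickness 3.9 nm, within one
noise-limited estimate), with slope ratio ≈ 0.95 — the near-unity value
expected when the stiffness is the same on both sides of the bilayer.

See `vignette("slbtools-methods")` (source under `vignettes/`) for the
models, parameter defaults and numerical choices, and
`inst/scripts/slb-cli.R` for the command-line interface
(`Rscript slb-cli.R <synth|spt|frap|calcium|exclusion|afm> [options]`).

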