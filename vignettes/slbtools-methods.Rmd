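---
title: "Models and methods behind slbtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slbtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slbtools)
```

slbtools quantifies the physics and early signaling of T cells interacting
with lipid bilayers formed on soft polymer (PDMS) supports: how fast lipids
and receptors diffuse in the bilayer, how mobile the lipid population is, how
strongly the large phosphatase CD45 is excluded from close contacts, whether
a single bilayer (rather than a stack) formed on the gel, and how stiff the
gel is. Every analysis stage is paired with a generator that produces
synthetic inputs with known ground truth, so the full pipeline is testable
without any microscope or AFM data. This vignette records the models, the
parameter choices, and the numerical decisions, in that order of importance.

## Single-particle diffusion

### Model

For 2D Brownian motion imaged with static localization error $\sigma$ and
camera exposure (integration) time $t_E$, the ensemble mean-square
displacement at lag time $t$ is fitted as

$$\mathrm{MSD}(t) = 4Dt + 4\sigma^2 - \tfrac{4}{3} D\, t_E .$$

The negative term is the standard motion-blur correction: averaging the
position over the exposure reduces the apparent offset. A second reading of
this expression, in which the blur time is taken equal to the lag itself,
collapses the model to $\mathrm{MSD} = \tfrac{8}{3} D t + 4\sigma^2$;
`fit_msd(blur_model = "lag")` provides it, but the exposure-time reading is
the default because it matches the error model under which the correction was
derived. Either way $D$ comes from the slope of the first `n_points = 5` lags
(50 ms at 10 ms frames) by ordinary least squares — the model is linear, so no
iterative optimization is involved.

Because the offset conventions in the literature vary, `tidy()` on an MSD fit
reports the localization error three ways: $\sigma$ (`sigma_loc`, um),
$\sigma^2$ (`sigma_loc_sq`, um\(^2\)) and the raw fitted intercept
(`offset_4sigma_sq`, um\(^2\)).

Jump-distance (JD) analysis fits the distribution of squared single-frame
displacements $r^2$ to a mixture of freely diffusing populations,

$$P(r^2, \Delta t) = \sum_j \frac{f_j}{4 D_j \Delta t}
  \, e^{-r^2 / (4 D_j \Delta t)},$$

i.e. a mixture of exponentials with means $4 D_j \Delta t$. The default
objective is the likelihood of the raw $r^2$ sample, maximized by
expectation-maximization: the M-step is closed-form, every iteration provably
increases the likelihood, and no binning choices enter. A binned least-squares
mode (`method = "histogram"`) is kept as a cross-check because it is the more
common description in the imaging literature. Two safeguards handle
degeneracy: components whose coefficients differ by less than a factor 1.25
are collapsed into one, and a two-component fit that the Bayesian information
criterion does not support over a one-component fit is likewise collapsed
(flagged `components_collapsed`). Both matter in practice — a genuinely single
population otherwise splits arbitrarily into two near-identical components.

Detection and linking are deliberately plain: local maxima above a threshold,
refined by a least-squares 2D Gaussian fit in a window (falling back to an
intensity centroid), then greedy nearest-neighbor linking between consecutive
frames with no gap closing — a missed detection ends the track. Tracks of five
frames or fewer are discarded (`filter_tracks`, `min_length = 6`). Positions
are pixels at the detection layer and micrometers from `link_tracks()` onward,
with a required `pixel_size`; the origin is the center of the top-left pixel,
x right, y down.

### Study conditions in the generators

`simulate_tracks()` assigns each track to one diffusive component, draws
per-axis displacements with variance $2D\Delta t$, and adds independent
Gaussian localization noise to every coordinate. Motion blur is *not*
simulated by sub-frame integration; it enters only through the fit's exposure
term — the generator matches the fitted model's error structure, which is what
parameter-recovery tests require. Fixture defaults: 10 ms frames and 10 ms
exposure with $\sigma_{loc} = 0.05$ um and 20-frame tracks for lipid imaging;
31 ms frames, $\sigma_{loc} = 0.01$ um and ~40 tracks of 16 frames per cell
for receptor (TCR) tracking. The receptor value is deliberately small: the JD
density has no localization-error term, so the recoverable quantity is the
apparent $D$; at 0.01 um the apparent shift ($\sigma^2/\Delta t \approx 2\%$)
is negligible, which is the regime of high-SNR Fab imaging. Receptor-level
recovery is assessed the way the experiments report it: one two-component JD
fit per cell and the dominant component averaged over 12 cells.

## FRAP

The recovery of a Gaussian-beam bleach spot on a 2D membrane follows the
Axelrod series, here with an immobile fraction:

$$F(t) = M_f \sum_{n \ge 0} \frac{(-K)^n}{n!}
  \frac{1}{1 + n(1 + 2t/\tau_D)} + (1 - M_f)\, F_0,$$

with bleach depth $K$, characteristic diffusion time $\tau_D$, mobile
fraction $M_f$, and $F_0$ the normalized intensity of the first post-bleach
frame (the level at which the immobile molecules stay). Useful limits that the
implementation reproduces and the tests assert: $F(0) = (1-e^{-K})/K$ for a
fully mobile membrane, and $F(\infty) = M_f + (1-M_f)F_0$. The series is
truncated when a term drops below $10^{-10}$ in absolute value or at $n = 60$;
with the bound $K \le 10$ the alternating terms decay fast enough that the
truncation error is far below measurement noise.

`normalize_frap()` performs the standard preprocessing: background
subtraction, division by a background-subtracted reference region (correcting
acquisition photobleaching), location of the bleach frame as the largest
single-frame drop (a relative drop of at least `min_drop = 0.1` is required —
a constant trace is an error, not a zero), and scaling so the mean of the 10
pre-bleach frames is 1. `fit_axelrod()` then runs bounded
Levenberg-Marquardt for $(K, \tau_D, M_f)$: initial $K$ from the observed
bleach depth, $\tau$ from the half-recovery time, $M_f$ from the last-decile
mean; bounds $K \in (0, 10]$, $\tau \in (0, 10\,t_{max}]$, $M_f \in [0, 1]$,
with a flag when a bound is hit. $D = w^2 / (4\tau_D)$ with the beam radius
$w$ estimated separately by fitting the post/pre ratio image to
$\exp(-K e^{-2r^2/w^2})$. Because some studies instead use the simplified
half-time formula, `tidy()` also reports
$D_{1/2} = 0.88\, w^2/(4 t_{1/2})$ with $t_{1/2}$ read off the fitted curve.

One subtlety: with $F_0$ treated as a free generator parameter, a trace is
only self-consistent when $F_0 = (1-e^{-K})/K$ (the bleach profile applies
equally to mobile and immobile molecules). The simulator records its $F_0$
parameter as the trace's post-bleach intensity so the forward/inverse
roundtrip is exact; on normalized experimental data the two coincide by
construction. Fixtures use the acquisition protocol of the FRAP experiments:
10 pre-bleach frames, then 1 s sampling over 3 min (181 post-bleach points).

## Calcium signaling metrics

Per-cell intensity traces come either from the generator or from a time-lapse
stack via per-frame segmentation (Gaussian smoothing, Otsu threshold,
connected components of at least `min_cell_area` pixels) and
nearest-centroid tracking. The baseline of a trace is the median of its first
10 valid frames and is never refreshed; both choices are exposed as
parameters. A peak is a local maximum with height at least
`min_height_multiple = 1.5` times baseline *and* topographic prominence at
least `min_prominence_multiple = 0.5` times baseline. These two defaults are
implementation choices — the original detection criteria are not published —
so every quantitative test states its thresholds explicitly, and no test
asserts agreement with published population boxplots; recovery is assessed
against the generator's ground-truth labels instead. A cell responds if it
has at least one peak; it "blinks" if it has more than one; the multi-peak
fraction is computed over responders only and is reported as missing (never
zero) when there are no responders. All metrics are ratios to baseline and are
therefore invariant under rescaling the whole movie, which is asserted as a
property test.

The generator plants Gaussian-shaped transients (any unimodal pulse passing
the prominence rule would do; the waveform is not constrained by the
detector) with amplitudes of 3-8 baseline multiples, width 10 s, at 1 s
frames over 10 min. First-peak latencies are 20 s plus an exponential with
mean 90 s, truncated to the first 80% of the movie. The 20 s floor reflects
the time a cell needs to land on and engage the surface before signaling; it
also guarantees the baseline window contains no transient, which the
baseline-from-first-frames convention assumes. The default responder fraction
of 0.7 matches the 60-80% triggering typically seen on stimulating
antibody-coated glass.

## Receptor exclusion from contacts

The exclusion statistic for a probe channel (CD45) relative to an
adhesion-marker channel (rCD2) is

$$\mathrm{Exclusion} = 1 - \overline{I_{in}} / \overline{I_{out}},$$

where "in" is the contact mask (Otsu threshold of the adhesion channel) and
"out" is the rest of the cell footprint, defined as the set union of the
contact mask and the Otsu mask of the probe channel minus the contact. The
union is the only set reading under which "outside the contact" remains
restricted to the cell. Values can be negative (enrichment) and are reported
unclamped; the statistic is invariant under multiplying both channels by a
positive constant. Preprocessing follows the standard recipe: average the
stack, subtract a rolling-ball background (default radius 50 px).

Numerical conventions worth stating: the Otsu threshold is computed on a
256-equal-width-bin histogram spanning the image range, the returned
threshold is the upper edge of the maximizing bin, and the foreground is
strictly above it. When the between-class variance has a flat plateau (well
separated modes with an empty gap) the first maximizer is returned — any
threshold in the gap yields the same mask on data, but the tie-break is fixed
for reproducibility. The rolling-ball background is realized as grayscale
morphological opening with a flat disk of the stated radius, the standard
fast approximation; because the morphology library operates on $[0,1]$
intensities, images are affinely rescaled first (min/max commute with affine
maps, so the opening is unchanged). The ball must be larger than any
structure that should *not* be treated as background — for the synthetic
contact images, larger than the cell.

The contact-image generator builds an elliptical cell containing a disk
contact; channel 1 is multiplied by an enrichment factor inside the contact
and channel 2 by a depletion factor, so that exclusion computed on the
ground-truth masks equals $1 - \text{depletion}$ exactly in the noiseless,
gradient-free case. Measured through the Otsu masks the agreement is within
0.05 (mask-edge pixels), and exactly 0 or 1 at the trivial extremes.

## AFM force curves

Approach curves are analyzed in two independent ways.

**Young's modulus.** After locating the contact point $z_c$ (baseline mean
plus $3\times$ noise, refined by minimizing the residual of a power-law fit
just past contact), the spherical Hertz model

$$F = \tfrac{4}{3}\, \frac{E}{1-\nu^2} \sqrt{R}\, \delta^{3/2},
  \qquad \delta = z - z_c$$

is linear in $E$, so $E$ is obtained in closed form; the contact point is
jointly refined by a bounded 1D search, which also makes the fit invariant to
a constant force offset. Defaults mirror the measurement hardware: a
polystyrene bead of nominal 37 um diameter glued to a tipless cantilever
($R = 18.5$ um, always supplied explicitly, never inferred) and $\nu = 0.5$,
the standard incompressible value for PDMS-like elastomers. A pyramidal
(Sneddon-type) variant $F = \tfrac{2}{\pi} \frac{E}{1-\nu^2}
\tan(\alpha)\,\delta^2$ is implemented in the generator for the sharp
cantilever used in push-through experiments; the $2/\pi$ prefactor is the
cone-type convention and is shared between generator and any fit, so no
prefactor ambiguity can enter a roundtrip.

**Push-through events.** A bilayer breakthrough appears as a stretch where
the piezo advances but the force stays near-constant between two regions of
positive stiffness. The detector resamples the curve to uniform $z$ spacing,
computes the local gradient $dF/dz$ by a sliding linear regression over
`gradient_window = 7` points, estimates the gradient noise from the
pre-contact baseline, and flags contiguous in-contact runs where the gradient
falls below `drop_threshold = 5` gradient-noise sds, requiring significantly
positive slopes on both sides (this kills candidates near the contact point,
where the true stiffness is still small). Both thresholds are parameters; the
defaults were fixed before the recovery tests were written and are asserted
by them (zero false events on 50 smooth noisy curves; at least 49/50
detections of a 3.9 nm, 5 nN event at 0.5 nm sampling and 0.02 nN noise).

The z-jump itself is *not* read off the thresholded run, whose ends are
smeared by the regression window. Instead the force branches before and after
the event are fitted by lines and the jump is the horizontal offset between
them at the breakthrough force. The bracketing slopes reported per event (and
their ratio, near 1 for a bilayer on a matched substrate) use the
`gradient_window`-point fits immediately adjacent to the run; the branch
lines used for the z-jump refinement use three windows' worth of points,
which cuts the extrapolation error to well below one sampling step at the
fixture's noise level. This is the one place the implementation distinguishes
"reported slope" from "refinement fit"; with equal stiffness on both sides
the distinction is immaterial for the ratio, and the longer fit is what makes
the sub-nanometer jump estimate possible.

The generator produces: flat pre-contact force, the contact law for the
stated indenter, and at each breakthrough force a constant-force plateau
while the piezo advances by the bilayer thickness, after which the contact
law resumes shifted toward the substrate — so slopes before and after match
and several stacked bilayers can be simulated by passing vectors.

## Reproducibility, I/O, problem sizes

Every stochastic function takes a `seed` and restores the caller's RNG state,
so generators are bit-reproducible given (parameters, seed) and never perturb
the session. Image stacks are written as 16-bit multi-page TIFF (lossless for
photon counts; the reader undoes the TIFF library's $[0,1]$ normalization so
raw counts come back), tables as delimited text with schema validation, and
every result table embeds its full resolved parameter set (including seed and
package version) as a comment header, from which the run can be reproduced.
`run_pipeline()` binds the stages behind one validated configuration;
a thin command-line wrapper is installed at
`system.file("scripts", "slb-cli.R", package = "slbtools")` with exit codes
0 (success), 1 (user/config error), 2 (internal error).

Test problem sizes were chosen so estimator noise sits well inside each
tolerance while the whole suite stays light: 120-500 tracks for MSD/JD
property tests (the acceptance conditions use the published track counts, up
to 5430), 20 seeded FRAP traces, 200-cell calcium populations plus one
16-cell rendered movie, 128 px contact images, 16 noisy Hertz curves and 100
detector curves. The full suite runs in well under a minute.

## What passing tests do and do not show

The generators emulate the *error structure assumed by each estimator*:
Gaussian localization noise, Poisson shot noise, Gaussian trace and force
noise, ideal Hertzian contact, disk/ellipse geometry. Passing recovery tests
therefore demonstrates that the estimators are correctly implemented and
unbiased under their own assumptions at realistic noise levels. They do not
certify performance on real data, which additionally contains fluorophore
blinking and bleaching, anomalous subdiffusion and membrane topography,
ratiometric indicator nonlinearity, cell movement and segmentation ambiguity,
viscoelastic (creep) responses, and cantilever-specific artifacts — all
explicitly out of scope. Known limitations, by module: no gap closing or
merge/split handling in tracking; single-bleach circular-spot FRAP only; one
cell per cropped field assumed for exclusion; no absolute calcium
calibration; no vendor AFM file formats and no retract-segment analysis.
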