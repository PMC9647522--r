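---
title: "Models and methods behind holomito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind holomito}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`holomito` analyzes dual-channel time-lapse movies of mitochondria — a
refractive-index (RI) channel from holographic reconstruction and a TMRM
fluorescence channel reporting membrane potential — to separate two distinct
events of the permeability transition: *depolarization* (TMRM loss) and
*high-conductance permeabilization* (the organelle's disappearance from the
RI channel as its matrix equilibrates with the cytosol). This vignette
documents the models, parameters and numerical decisions; the README shows
the user-facing workflow.

## The forward simulator

Because raw assay movies are not publicly deposited, the package ships a
forward simulator whose defaults *are* the study conditions, and all
quantitative claims in the test suite are made against its known ground
truth.

### Kinetic model

Each organelle `i` has a dimensionless potential `V_i(t)` with basal level
`v_basal` (1 for wild type). After drug addition at `t_drug`, the
depolarization onset is jittered per organelle,
`o_i = t_drug + |N(0, onset_jitter_sd)|`, and the potential decays as a
single exponential:

    V_i(t) = v_basal                                  for t < o_i
    V_i(t) = v_basal * exp(-(t - o_i) / tau_depol)    for t >= o_i

The assay's published traces are empirical; we chose the single-exponential
form because it is the simplest decay with a closed-form threshold-crossing
time, which makes ground truth analytic and testable:
`t* - o_i = tau_depol * log(1 / perm_threshold)`.

Where the condition permits permeabilization (wild type + ferutinin only),
the organelle permeabilizes at `t* + lag`, where the lag is Gaussian
truncated at zero (`perm_lag_mean`, `perm_lag_sd`). A threshold trigger
plus lag — rather than a hazard process — directly encodes the observed
ordering "depolarize first, then collapse" and keeps every event time exact.
After permeabilization the organelle's RI contrast decays with
`tau_ri_collapse`; before it, contrast is identically 1.

### Condition archetypes

| condition          | depolarization            | permeabilization | basal potential |
|--------------------|---------------------------|------------------|-----------------|
| `WT_FERUTININ`     | exponential after onset   | yes              | 1.0             |
| `WT_FERUTININ_CSA` | none (cyclosporin A)      | no               | 1.0             |
| `FCCP_ONLY`        | fast collapse (`tau_fccp`)| no               | 1.0             |
| `KO_FERUTININ`     | exponential after onset   | no               | 0.6             |

The knockout archetype (ATP-synthase- or ANT-deficient cells) depolarizes
but never opens the high-conductance pore; its reduced basal potential
reflects the lower resting potential those cells exhibit. 0.6 is a
representative choice — the analysis never uses the absolute level, only
the FCCP-normalized relative potential.

### The terminal FCCP pulse

In the real protocol the protonophore FCCP is added at the *end of every
experiment* to fully collapse the potential and anchor TMRM normalization.
The simulator therefore applies a terminal FCCP pulse (collapse with
`tau_fccp = 5` s) over the last `fccp_frames = 5` frames in **all**
conditions; in `FCCP_ONLY` the drug itself is FCCP, so the pulse is a
no-op. This matters twice:

- Without it, the cyclosporin-A archetype would have a flat trace and the
  normalization denominator `F̄_baseline − F̄_FCCP` would be zero — exactly
  the degenerate case the `normalizable` flag guards against.
- Because the pulse collapses the potential in *every* condition, the onset
  detector scans only `[drug_frame, fccp_frame)`. Otherwise cyclosporin-A
  movies would show a spurious "onset" at the FCCP pulse, contradicting the
  biology the archetype encodes.

### Defaults and calibration

| parameter          | default | unit    | rationale                                           |
|--------------------|---------|---------|-----------------------------------------------------|
| `frame_interval`   | 15      | s       | the assay's acquisition rate                        |
| `tau_depol`        | 79      | s       | `79 · ln(1/0.15) = 149.9 s`: crossing ≈ 150 s       |
| `perm_threshold`   | 0.15    | —       | residual potential fraction at the trigger          |
| `onset_jitter_sd`  | 30      | s       | per-organelle onset spread, order of 1–2 frames     |
| `perm_lag_mean/sd` | 0 / 0   | s       | zero by default so the calibration above is exact   |
| `tau_ri_collapse`  | 10      | s       | sub-frame-interval: disappearance within ~1 frame   |
| `tau_fccp`         | 5       | s       | protonophore acts fast relative to the frame rate   |
| `bleach_rate`      | 0       | /frame  | normalization absorbs slow drift; knob for testing  |
| noise sd (both)    | 0.02    | —       | ~9% of the RI amplitude; realistic yet comfortably segmentable |

The two calibrated targets — residual fraction 0.15 and mean delay ≈ 150 s —
are the only summary statistics available to anchor the kinetics; per-
organelle decay constants are not published, so `tau_depol` is fixed by the
delay identity rather than fitted.

### Image formation

Organelles are ellipses (axes 3–8 px) on a jittered grid, so default
geometries do not overlap and ROI counts equal organelle counts; overlap is
permitted (intensities sum) when a custom geometry asks for it. Each RI
frame is `background + amplitude · Σ_i smooth(ellipse_i) · ri_contrast_i(t)`
with Gaussian edge smoothing (σ = 0.8 px) and additive Gaussian noise; the
TMRM frame replaces the contrast curve with `V_i(t)` (times a cumulative
bleach factor when enabled). TMRM intensity is *linear* in potential — no
Nernstian accumulation model — because the pipeline only ever consumes the
normalized relative potential, which is invariant to any monotone linear
map. The scene is 2-D (post-projection); `max_project()` is provided and
tested separately on synthetic volumes. One seed per scenario determines
geometry, kinetic draws and pixel noise in a documented order (seed,
seed + 1, seed + 2).

### What the simulator does not emulate

Organelle motion, fission/fusion, focus drift, structured background
(beyond an optional linear gradient), spectral crosstalk, photon-counting
noise statistics, and reconstruction artifacts of the holographic inversion
itself. Passing tests therefore demonstrate correctness of the *analysis*
under the stated image model, not robustness to every property of real
microscope data; the classifier-based segmentation path exists precisely
because thresholding alone is expected to degrade on real backgrounds.

## The analysis pipeline

### Segmentation

Two interchangeable front ends produce per-frame binary masks (no temporal
smoothing; temporal behaviour belongs to tracking):

- **Pixel classifier** — a random forest over a multiscale filter bank
  (Gaussian, gradient magnitude, Laplacian of Gaussian, Hessian eigenvalue,
  difference of Gaussians), trained from sparse scribbles
  (0/1/2 = unlabeled/mitochondrion/background), with a 20 % scribble
  holdout reported as accuracy. This replaces the interactive tool used in
  the original workflow so the pipeline has no GUI dependency.
- **Threshold fallback** — large-scale Gaussian background subtraction,
  Otsu's between-class-variance threshold, then the size filter. The
  movie-level threshold is derived once from the mean pre-drug frame and
  applied to all frames: per-frame Otsu is undefined on late wild-type
  frames where *every* organelle has vanished and the histogram is pure
  noise. A separation guard (threshold must clear the background median by
  4 robust SDs) returns an empty mask instead of segmenting noise.

Components use 8-connectivity throughout; `min_object_px = 10` at the
simulator's scale. The monotone property (higher threshold never grows the
mask) and equivalence with a flood-fill oracle are tested.

### ROIs, traces, normalization

ROIs are fixed at baseline — Otsu on the time-averaged pre-drug TMRM image —
mirroring the original protocol's manual selection of regions with
functional, polarized mitochondria, and avoiding circularity with the
permeabilization readout (an ROI that followed the collapsing mask would
bias the area trace). Area traces divide per-frame mask pixels inside the
ROI by the baseline mean, so the baseline averages exactly 1; TMRM traces
are plain pixel means. Normalization maps the baseline window to 1 and the
terminal FCCP window (default: last 3 frames, inside the 5-frame pulse) to
0, exactly, and is invariant under positive rescaling of raw intensities.
Traces whose anchors differ by less than 3× the estimated trace noise
(SD of baseline first differences / √2) are flagged non-normalizable rather
than silently producing huge ratios.

### Tracking and event detection

Tracking is greedy frame-to-frame linking of mask components by maximal
overlap (IoU ≥ 0.3), ties broken by nearest centroid then lowest label,
with a 1-frame gap tolerance. One refinement proved necessary: during RI
collapse a shrinking remnant can drop below the IoU cut even though it lies
entirely inside the previous footprint, fragmenting the track at exactly
the moment that matters. A containment fallback (component ≥ 60 % inside
the previous footprint, and not growing) keeps the collapse within one
track. Tracks that vanish and stay vanished terminate as `disappeared`;
tracks whose footprint regains foreground terminate as `lost` and are
*never* scored as permeabilized (conservative).

Both detectors are deliberately rule-based rather than change-point models —
transparent, exhaustively checkable against a linear-scan oracle, and
adequate at the simulator's signal-to-noise ratio:

- **Onset**: first frame ≥ `drug_frame` with `F_norm < 1 − 0.1`, sustained
  3 consecutive frames, scanning only up to the FCCP pulse.
- **Permeabilization**: first frame with area < 20 % of the track's
  pre-drug mean, sustained 3 frames or through the movie end. The original
  report gives no quantitative disappearance criterion; 20 % is our
  operationalization, exposed as `area_floor_fraction`.

The delay is computed from the detected *onset* (start) of depolarization.
The source material is ambiguous on this point — one figure axis reads
"offset of depolarization" while the text says the delay is measured "from
the start of depolarization" — and we follow the text; with near-complete
depolarization before the collapse, the offset reading would make the
threshold-crossing identity incoherent.

### Known quantization bias

Events are detected on the frame grid, always *at or after* the true
crossing. The residual potential read at the detected frame is therefore
biased slightly low: with `tau_depol = 79` s and 15-s frames the expectation
is `0.15 · E[exp(-δ/79)]` for a sub-frame lateness δ, ≈ 0.12–0.13 against a
ground truth of 0.15. The onset detector is late by a comparable sub-frame
amount, so the *delay* is nearly unbiased (tests require the cohort mean
within one frame interval of ground truth). We report measurements as
defined — the value at the detected frame — rather than back-extrapolating
along an assumed decay model.

### Statistics

Summaries are mean ± SEM (`sd/√n`; `n = 1` groups are flagged degenerate
with SEM 0). Contrasts use one-way ANOVA (base `aov`) or a two-sided
t-test, equal-variance by default with Welch available — the original
analysis does not state pairing or pooling, so the default is declared, not
inferred. Star codes: `p < 0.05 (*) / 0.01 (**) / 0.001 (***)`. The unit of
analysis is the ROI/track, as in the source work (which reports n =
mitochondrial regions, N = experiments); per-movie nesting is carried in
the tables but not modeled (no mixed effects). No multiple-testing
correction is applied, matching the original analysis.

## Problem sizes and runtime

Unit tests run on small movies (3–5 organelles, 40–60 frames, ≲ 100 px
images); the acceptance suite and `scripts/acceptance.R` use the full study
geometry — 20 wild-type movies of 10 organelles × 80 frames plus 10 movies
per control archetype — which completes in about a minute on one CPU. All
fixtures are generated in code from fixed seeds; nothing binary is stored.

## Limitations

- The simulator's defaults are calibrated to two summary statistics; it is
  a test harness and benchmark generator, not a biophysical model of PTP
  gating.
- Tracking has no fission/fusion handling or track splitting/merging.
- Segmentation is 2-D and classical (no deep learning), by design.
- Real holographic movies enter at `cmd_analyze()`/`analyze_movie()`, but
  the package has only been validated on synthetic data, since the original
  raw movies are available on request only.
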