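# holomito

Simulation and analysis of a label-free holographic assay for the
mitochondrial permeability transition (PT).

## The problem

The permeability transition pore (PTP) is a calcium-induced,
cyclosporin-A-sensitive pore in the inner mitochondrial membrane that passes
solutes up to ~1.5 kDa and drives cell death in ischemic injury. Most live-cell
PTP assays actually measure membrane *depolarization* (loss of the
potentiometric dye TMRM), which is not the same thing: a mitochondrion can
depolarize without opening the high-conductance pore. Holographic
(refractive-index, RI) microscopy gives a direct readout of the pore itself —
PTP opening equilibrates solutes between matrix and cytosol, equalizes their
refractive indices, and the organelle literally vanishes from the RI image
while remaining in place.

Combining both channels per organelle yields two single-mitochondrion
statistics:

- **residual potential** — the normalized TMRM level
  `F_norm = (F − F̄_FCCP) / (F̄_baseline − F̄_FCCP)` at the frame the
  organelle disappears from the RI channel, and
- **delay** — the time from detected depolarization onset to disappearance,
  `Δt = (k_perm − k_onset) · Δt_frame`.

`holomito` implements the full computational side of this assay for R users:
a forward simulator of dual-channel time-lapse movies with per-organelle
ground truth (four condition archetypes: wild type + ferutinin, + cyclosporin
A, FCCP-only, and ATP-synthase/ANT-knockout + ferutinin), pixel
classification and threshold segmentation of the RI channel, baseline-defined
ROI quantification with FCCP-anchored TMRM normalization, overlap-based
single-organelle tracking with depolarization/permeabilization event
detection, and condition-level statistics (mean ± SEM, one-way ANOVA,
t-tests with star codes). Everything tabular is a tibble; plots are ggplot2.

## Worked example

```r
library(holomito)

sim <- simulate_experiment("WT_FERUTININ", n_mito = 5, n_frames = 60,
                           drug_frame = 8, seed = 42)
ana <- analyze_movie(sim$ri, sim$tmrm)
ana
#> <mito_analysis> 5 ROIs, 5 tracks, 5 events (5 with permeabilization)

ana$events
#> # A tibble: 5 × 9
#>   track_id roi_id termination onset_frame onset_s perm_frame perm_s residual_potential delay_s
#>      <int>  <int> <chr>             <int>   <dbl>      <int>  <dbl>              <dbl>   <dbl>
#> 1        1      1 disappeared           9     135         19    285              0.125     150
#> 2        2      2 disappeared          10     150         20    300              0.135     150
#> 3        3      3 disappeared          12     180         22    330              0.117     150
#> 4        4      4 disappeared          11     165         21    315              0.112     150
#> 5        5      5 disappeared          10     150         20    300              0.129     150
```

Every simulated organelle depolarizes after ferutinin (onset at 135–180 s),
keeps its RI contrast until the potential has fallen to ~15 % of baseline,
and then disappears from the RI channel ("disappeared" termination) 150 s
after its onset. The residual potential column reads 0.11–0.14 — the
normalized TMRM level at the disappearance frame — and `delay_s` is the
onset-to-permeabilization delay in seconds. In the cyclosporin-A, FCCP-only
and knockout archetypes the same call yields zero permeabilizations
(organelles persist in the RI channel) while FCCP/knockout movies still show
depolarization onsets.

`plot_traces(ana$traces)` overlays the per-ROI area-fraction and normalized
TMRM traces; `autoplot(ana$events)` shows the two event statistics with
mean ± SEM.

File-based workflows use the same machinery via
`cmd_simulate()` / `cmd_analyze()` / `cmd_report()` with flat YAML configs,
or the shell entry point `inst/scripts/holomito`.

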