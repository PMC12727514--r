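# calcitrace

Quantitative analysis of time-lapse **vertical scanning interferometry
(VSI)** records of microbial cells attached to a dissolving mineral
surface — and a **virtual interferometer** that generates such records from
known ground truth so the whole analysis chain can be validated.

## The scientific problem

Cyanobacteria and other microbes colonizing calcite can alter the
chemistry of the thin fluid film at the cell-mineral contact (most
plausibly by photosynthetic pH elevation) and thereby locally slow
dissolution. Imaged in a flow cell next to an inert quartz reference, the
calcite face retreats while the quartz stays put, so three things become
measurable at once:

* the **dissolution rate** as the slope of the quartz-calcite height
  difference, `d(Δz)/dt`, in µm/day;
* the **cell detachment rate** as the slope of the attached-cell count per
  area, in cells mm⁻² h⁻¹;
* the **protective effect of attached cells**: each pixel covered for a
  cumulative time τ by a cell that reduces the local rate from R to fR
  ends the run standing `(1 − f)·R·τ` above its surroundings, so the
  pixel-wise Pearson correlation between the **residence-time map**
  (summed per-frame occupancy masks × frame interval) and the final
  cell-free topography is the fingerprint of under-cell inhibition.

The observed rate reduction can then be pushed through open-system
carbonate chemistry: a flow-through mass balance
`[Ca] = r·M_Ca·SA/(10⁻⁶·ν)` fixes the dissolved Ca, a pluggable rate law
`R(Ω) = k(1 − Ω)ⁿ` converts the rate reduction into a local saturation
index, and the closed-form inversion
`{H⁺} = sqrt(γ_Ca[Ca]·K1·K2·KH·pCO₂/(Ω·Ksp))` (Davies activities,
Plummer & Busenberg constants) yields the interfacial pH.

Because raw VSI stacks of this kind are generally not deposited, the
package ships a first-class synthetic generator (`generate_experiment`)
producing co-registered height/grayscale stacks with configurable retreat
rate, inhibition factor, cell geometry, detachment schedule and noise,
plus the exact ground truth for every derived quantity.

## Worked example

```r
library(calcitrace)

cfg <- experiment_config(field_width_um = 120, field_height_um = 120,
                         duration_h = 6, frame_interval_min = 30,
                         retreat_rate_um_d = 10, inhibition_factor = 0.8,
                         quartz_fraction = 0.25, n_cells_initial = 30,
                         roughness_noise_nm = 20,
                         detachment_rate_cells_mm2_h = 386)
report <- run_pipeline(cfg, "run1")
report
#> calcitrace run report (seed 1, config 6d454f9d6af974eec7884cdb32bcc403)
#>   retreat rate: 9.973 +/- 0.003 um/d
#>   detachment rate: 354.1 +/- 19.3 cells/mm2/h (significant)
#>   Ra: 37.79 +/- 15.37 nm over 3 windows
#>   residence-topography r: 0.900 (n = 67500) -> protective effect
#>   under-cell rate reduction: 33.7% -> omega 0.176, pH 8.38
#>   outlet [Ca]: 3126 ppb
```

Reading the numbers: the fitted retreat rate recovers the configured
10 µm/d to 0.3 %; the detachment slope is significant (|slope| > 2 se)
and close to the configured 386 cells mm⁻² h⁻¹ once the declining portion
of the series is isolated; the residence-topography correlation r = 0.90
over 67 500 calcite pixels flags a protective effect (it collapses to
|r| < 0.05 when the same scenario is generated with `inhibition_factor =
1`); and the geochemical stage turns the estimated under-cell rate
reduction into a local saturation index and interfacial pH. Every
headline number is recomputable from the stage files (`coverage.csv`,
`retreat.csv`, `residence.tif`, `stack/`) written next to `report.json`.

Individual stages are exported on their own: `segment_by_height`,
`segment_by_grayscale`, `clean_and_label`, `area_to_cell_count`,
`residence_map`, `correlate_residence_topography`, `retreat_series`,
`fit_rate`, `roughness_Ra`, `subwindow_report`, `retreat_to_molar_flux`,
`saturation_index`, `solve_ph_for_omega`, `omega_from_rate_reduction`,
`outlet_ca_ppm`, and the streaming simulators `simulate_retreat_series`
and `simulate_coverage_series` for full-instrument-scale runs. A thin
command-line wrapper lives at `inst/scripts/run_pipeline.R`.

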