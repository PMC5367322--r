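# firecarb

Bottom-up accounting of the biomass consumed and the carbon released by
a large wildfire, by fusing postfire airborne LiDAR with multitemporal
six-band optical imagery.

Fire emission estimates usually lean on the identity

```
Cr = A × B × f_c × β
```

(burned area × biomass density × carbon fraction × combustion
completeness), with `B` and `β` taken from biome-level averages.
`firecarb` replaces those averages with maps: a least-squares
support-vector regression (LS-SVR) on LiDAR canopy metrics — calibrated
on field plots — provides postfire biomass; a fire-specific correction
re-weights the canopy height percentile H50 by its expected relationship
with the area under the canopy waveform (AUCW), removing the snag bias
in burned stands; optical LS-SVR models extrapolate the LiDAR biomass in
space and time to obtain prefire and postfire maps; differencing,
severity-stratified aggregation and a spatially-aware two-step error
budget deliver consumed biomass (Tg), carbon (TgC), CO2-equivalent mass
and per-severity combustion completeness, each with uncertainty.

The package is aimed at ecological remote-sensing researchers who want
to study or extend this estimation chain. Because the original airborne
and satellite acquisitions are not redistributable, `firecarb` ships a
synthetic-scene generator (`simulate_scene()`) that emulates the study
conditions — 30 m grid, ~20 LiDAR returns/m², a four-level burn-severity
mosaic inside a blob-shaped perimeter, a stratified 71-plot field
campaign in the unburned buffer — with known ground truth, so every
stage and the end-to-end recovery are testable offline.

## Worked example

```r
library(firecarb)

cfg <- pipeline_config(scene = scene_config(seed = 1))
run <- run_pipeline(cfg)          # ~2 minutes: 60x60 cells, 20 pts/m2

render_report(run$report)[, c("pair", "stratum", "dB_Tg", "C_TgC",
                              "CO2e_Tg", "CC")]
```

```
                          pair      stratum dB_Tg C_TgC CO2e_Tg   CC
1     landsat_pre-landsat_post          low  0.00  0.00    0.00 0.07
2     landsat_pre-landsat_post     moderate  0.00  0.00    0.00 0.13
3     landsat_pre-landsat_post         high  0.00  0.00    0.00 0.07
4     landsat_pre-landsat_post total_burned  0.00  0.00    0.01 0.08
5            landsat_pre-lidar          low  0.00  0.00    0.00 0.12
6            landsat_pre-lidar     moderate  0.00  0.00    0.01 0.25
7            landsat_pre-lidar         high  0.01  0.01    0.02 0.57
8            landsat_pre-lidar total_burned  0.02  0.01    0.03 0.33
9  landsat_pre-lidar_corrected          low  0.00  0.00    0.01 0.29
10 landsat_pre-lidar_corrected     moderate  0.01  0.00    0.01 0.48
11 landsat_pre-lidar_corrected         high  0.02  0.01    0.03 0.88
12 landsat_pre-lidar_corrected total_burned  0.03  0.01    0.05 0.57
```

Reading the corrected-LiDAR rows: the synthetic fire consumed about
0.03 Tg of biomass across this ~194 ha burn (0.01 TgC, 0.05 Tg CO2e at
the 2-decimal rendering; full precision sits in `run$report`), and the
recovered combustion completeness per severity (0.29 / 0.48 / 0.88)
brackets the generator's true consumption fractions (0.30 / 0.50 /
0.85). The optical-only and uncorrected-LiDAR pairs underestimate
consumption — char-confused postfire reflectance and high H50 over
standing dead trees both inflate postfire biomass — which is exactly
the bias the H50/AUCW correction removes. Model accuracies per stage
sit in `run$fits`; the two-step error composition, correlogram range
and stratum-mean standard errors in `run$uncertainty`.

## Package tour

| Area | Functions |
| --- | --- |
| Synthetic scenes | `scene_config`, `simulate_scene`, `generate_trees`, `simulate_point_cloud`, `simulate_reflectance`, `generate_field_plots`, `filter_plots`, `scene_tile` |
| LiDAR metrics | `normalize_intensity`, `height_metrics`, `intensity_metrics`, `build_pseudowaveform`, `waveform_metrics`, `cell_metrics`, `rasterize_metrics` |
| Optical features | `vegetation_indices`, `tasseled_cap`, `glcm_textures`, `terrain_features`, `feature_stack` |
| Biomass models | `train_lssvr`, `grid_search_cv`, `feature_select`, `fit_metrics`, `split_calibration_validation`, `stratified_histogram_sample` |
| Fire correction | `fit_h50_aucw_reference`, `correct_h50`, `agb_map_from_metrics` |
| Extrapolation | `build_training_table`, `predict_agb_map` |
| Emissions | `bias_correct`, `consumption_map`, `aggregate_by_stratum`, `carbon_release`, `co2_equivalent`, `combustion_completeness`, `seiler_crutzen` |
| Uncertainty | `compose_two_step_error`, `fit_correlogram`, `stratum_mean_se`, `difference_variance` |
| Orchestration | `pipeline_config`, `load_pipeline_config`, `run_pipeline`, `write_run` |

The methods vignette (`vignettes/fire-carbon-accounting.Rmd`) documents
the models, the generator's assumptions, and every numerical design
choice.
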