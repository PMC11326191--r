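# qdfim — quadrant darkfield microscopy in R

Label-free imaging of sub-cellular puncta (melanosomes, lysosomes and other
organelles) with conventional darkfield optics is frustrated by cell edges:
large features refract light directionally and their brightness depends
strongly on cell shape, drowning the broad, shape-independent Mie
scattering of sub-wavelength puncta. Quadrant darkfield (QDF) separates the
two regimes computationally from four images acquired under illumination
from the four quadrants of a darkfield LED annulus. Pixel-wise,

```
E   = |TL − BR| + |BL − TR|          (edge image: directional signal only)
DF  = TL + TR + BL + BR              (conventional darkfield)
QDF = c · DF − E                     (c: system scaling factor, ~0.8–1.0)
```

At a pure edge pixel only adjacent quadrants are lit, so `E = DF` there and
the subtraction removes the edge; an isotropic punctum cancels in `E` and
keeps its full darkfield signal. The factor `c` is calibrated once per
experiment by least squares of `E` against `DF` over edge pixels
(`calibrate_c()`).

`qdfim` is aimed at quantitative-microscopy groups who want to analyse
quadrant-illuminated acquisitions or to prototype against a fully
ground-truthed synthetic microscope. It provides:

* **Reconstruction** — bit-depth scaling, empty-reference subtraction, edge
  and darkfield combination, degree-8 polynomial background removal, scaling
  factor calibration (`reconstruct_qdf()`).
* **Quantification** — quantitative-phase dry mass via the specific
  refractive increment (`density_map()`, `cell_dry_mass()`), watershed
  single-cell segmentation with hysteresis skirt recovery
  (`segment_cells()`), exact minimum-cost track linking (`link_tracks()`),
  debris filtering, puncta SNR and population statistics (`puncta_mask()`,
  `cell_snr()`, `linreg_ftest()`, `binned_scatter()`).
* **Batch pipeline** — directory-level processing with a YAML config, track
  linking across timepoints, CSV/TIFF/JSON outputs and a run manifest
  (`run_pipeline()`, `validate_config()`); a thin CLI lives at
  `inst/scripts/qdf`.
* **Forward model** — an optical simulator (`render_quadrants()`,
  `render_phase()`, `render_reference()`, `morph_roundness()`,
  `sample_population()`) that renders quadrant-resolved edge refraction,
  isotropic puncta, smooth backgrounds, shot/read noise and quantization,
  with exact ground truth for every scene.

## Worked example

A 20 µm bead phantom with one interior "imperfection" punctum, rendered
noise-free and reconstructed:

```r
library(qdfim)
opt <- qdf_optics(pixel_size = 0.5)

scene <- qdf_scene(c(128, 128),
                   bodies = list(qdf_body(32, 32, radius_um = 20, height_um = 3)),
                   puncta = punctum(32, 32, amplitude = 2000),
                   shot_noise = FALSE, read_noise_sigma = 0)
q <- render_quadrants(scene, opt)

df <- sum_darkfield(q)
e  <- edge_image(q)
cal <- calibrate_c(df, e, default_edge_mask(e))
print(cal)
#> QDF calibration: c = 1.0000 (200 edge pixels, residual RMS 0.00 counts)

qdf <- qdf_image(df, e, cal$c)
edge_px <- e > 0.2 * max(e)
cat(sprintf("edge signal surviving in QDF : %.1f %%\n",
            100 * sum(qdf[edge_px]) / sum(df[edge_px])))
#> edge signal surviving in QDF : 0.0 %
ctr <- 32 / 0.5 + 1
cat(sprintf("punctum signal retained      : %.1f %%\n",
            100 * qdf[ctr, ctr] / df[ctr, ctr]))
#> punctum signal retained      : 100.0 %
```

The bead's bright rim is cancelled completely while the interior punctum is
untouched — the bead-phantom behaviour that motivates the method.

The headline biological property is shape invariance. A simulated adherent
cell rounding up before division (volume, dry mass and organelle content
conserved) brightens dramatically in darkfield but barely moves in QDF:

```r
r <- shape_invariance_experiment(seed = 1)
cat(sprintf("darkfield total change on rounding: +%.1f %%\n", r$pct_df_change))
cat(sprintf("QDF total change on rounding      :  %.1f %%\n", r$pct_qdf_change))
#> darkfield total change on rounding: +46.9 %
#> QDF total change on rounding      :  4.6 %
```

The residual few-percent QDF change is the shot-noise floor of the edge
image, not a shape response (noise-free the change is below 1%); see the
methods vignette (`vignettes/qdf-methods.Rmd`) for the model, the design
decisions and the validation strategy.

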