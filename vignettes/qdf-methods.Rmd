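---
title: "Quadrant darkfield: model, pipeline, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrant darkfield: model, pipeline, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdfim)
```

## The measurement problem

Transillumination darkfield imaging collects only light scattered or
refracted into the objective, giving label-free contrast for sub-cellular
structure. Its weakness is that two very different sources produce signal:

* **Large features** (cell boundaries, bead rims), much larger than the
  wavelength, refract light *directionally* (Snell regime). Their brightness
  depends strongly on shape: a rounding cell acts as an increasingly strong
  lens and its edges flare up.
* **Sub-wavelength puncta** (melanosomes, lysosomes and other organelles,
  roughly 0.1–1 µm), in the Mie regime, scatter into a broad cone and appear
  with nearly the same intensity whatever the illumination direction.

Quadrant darkfield (QDF) separates the two regimes with four images acquired
under illumination from the four quadrants of a darkfield LED annulus
(top-left, top-right, bottom-left, bottom-right). Pixel-wise,

$$E = |TL - BR| + |BL - TR|, \qquad QDF = c \cdot DF - E,$$

where $DF = TL + TR + BL + BR$ is the conventional darkfield image, $E$ is
the *edge image* (directional signal survives the anti-symmetric
combination; isotropic signal cancels exactly), and $c$ is a system-specific
scaling factor, typically 0.8–1.0, chosen so that $c \cdot DF$ matches $E$
at object edges. `calibrate_c()` implements that choice as least squares
over an edge mask: $c = \sum DF \cdot E / \sum DF^2$.

A key identity motivates the method: at a *pure* edge pixel only two
adjacent quadrants are lit, so $E = DF$ there and the subtraction removes
edges completely, while a pure punctum has $E = 0$ and keeps its full
darkfield signal (scaled by $c$).

## The forward model

The simulator (`render_quadrants()`, `render_phase()`,
`render_reference()`) renders scenes of circular bodies and point-like
puncta:

* **Edges.** For each body a height map $h(x, y)$ is built; under
  illumination azimuth $\hat u_q$ (the direction *toward* the illuminating
  LED quadrant, in image coordinates with y increasing downward), a pixel
  emits $g \cdot \max(0, \nabla h \cdot \hat u_q)$ with edge gain $g$. This
  is equivalent to $g\,|\nabla h|\max(0, -\hat n \cdot \hat u_q)$ with
  $\hat n$ the outward normal: the arc *opposite* the illumination lights
  up, and the lit arc rotates with the quadrant, as in bead-phantom
  experiments.
* **Puncta.** Perfect isotropy: each punctum deposits `amplitude/4` into
  every quadrant (bilinearly splatted at its sub-pixel position). Mie
  efficiency is *not* computed from first principles; the scattering
  amplitude is a free ground-truth parameter, because the method uses Mie
  theory qualitatively (broad versus directional cones), not
  quantitatively.
* **Optics.** Both components are convolved with a Gaussian PSF
  (default $\sigma = 0.21\lambda/\mathrm{NA}$), then stray light and a
  smooth 2D background polynomial are added.
* **Noise and quantization.** Poisson shot noise on the pre-quantization
  signal, additive Gaussian read noise, rounding, and clamping to the
  container bit depth. Scenes are specified at 16-bit container scale with
  12-bit data stored left-shifted (a common camera convention), so the
  pipeline's divide-by-16 bit-scaling stage is exercised. Noise streams are
  split deterministically from the scene seed (offsets 1–4 for the
  quadrants, 5 for phase, 6 for the reference), making every render
  bit-reproducible.
* **Phase channel.** $\phi = (2\pi/\lambda)\,\Delta n\, h$ plus small
  Gaussian bumps for puncta, a phase background polynomial, and Gaussian
  noise. Phase *reconstruction* from raw acquisitions is out of scope; the
  pipeline consumes phase images.

What the simulator does **not** emulate: wave-optical diffraction
(ringing, out-of-focus light), halo artifacts of phase imaging, partial
punctum anisotropy, polarization, sample drift, or segmentation-hostile
morphologies (touching irregular cells, debris clumps). Passing tests
therefore demonstrate the *algorithmic* correctness of the chain and the
self-consistency of the method's physics, not robustness to every real
microscope artifact.

### The flat-to-round morph

`morph_roundness()` models the mitotic shape change of an adherent cell at
constant volume. The height profile family is
$H\,(1-(r/R)^2)^{s/2}$ with footprint radius interpolating linearly between
the flat radius and the equal-volume hemisphere radius
$R_h = (3V/2\pi)^{1/3}$: at $s=0$ it is the original flat disc, at $s=1$
exactly an equal-volume hemisphere. $H$ is renormalised on the pixel grid so
the *discrete* volume (and hence dry mass) is conserved exactly. Puncta
contract affinely with the footprint, conserving count and total amplitude —
the ground truth of a shape change with constant organelle content.

## Dry mass, segmentation, tracking

Phase relates to dry-mass surface density through the specific refractive
increment $\alpha$: $\rho = \phi \lambda / (2\pi\alpha)$, with the standard
cell-average $\alpha = 1.8\times10^{-4}\,\mathrm{m^3/kg}$ (default,
configurable). With $\lambda$ in µm this yields pg/µm² via a factor
$10^{-3}$.

Segmentation (`segment_cells()`) is a defined recipe: Gaussian smoothing,
Otsu foreground threshold, watershed with seed-suppression depth `h_depth`
(radians) to split touching cells, and a hysteresis step that propagates
labels outward over a weak threshold (`skirt_frac` of the Otsu cut,
default 0.2). The hysteresis step matters quantitatively: cells thin toward
their margins, and a single global threshold loses the faint skirt and a
few percent of the dry mass — enough to break mass conservation checks
across shape changes.

Track linking (`link_tracks()`) solves each frame pair as an exact
minimum-cost one-to-one assignment with squared-displacement costs, a hard
gate at `max_disp`, and a cost of `max_disp^2` per unmatched object — so
the optimum links as many objects as the gate allows and, among those,
minimises total squared displacement. The assignment is solved exactly
(dynamic programming over column subsets after splitting the gated
feasibility graph into connected components), which makes the linker
testable against an exhaustive-permutation oracle. Gap closing is off by
default (`memory = 0`).

## Numerical and design choices

* **Processing order.** Per-quadrant bit scaling → reference subtraction →
  $E$ and $DF$ → polynomial background removal of $DF$ and $E$ over a
  cell-free mask → calibration → QDF. Background removal of $DF$ is
  equivalent to removing backgrounds from the four quadrants individually
  (the fit is linear), at a quarter of the cost.
* **Reference floor.** The standalone `subtract_reference()` floors
  negatives at zero (signal is physically nonnegative). Inside
  `reconstruct_qdf()` the floor is disabled: rectifying zero-mean
  difference noise adds a positive bias to exactly the signal-free pixels;
  the background polynomial fit then removes that bias *everywhere*,
  silently deducting a few counts from every signal pixel. Because a flat
  cell spreads its puncta over many more pixels than a rounded one, the
  deficit is shape-dependent and would masquerade as a shape–signal
  correlation.
* **Unclipped totals.** `qdf_image()` clips negative residuals by default
  for display and masking, but per-cell signal totals are computed on the
  unclipped image: clipping rectifies noise into a positive bias
  proportional to cell area.
* **One calibration per experiment.** $c$ is a property of the optical
  system, not of a cell. Calibrating per frame fails on weak-edged flat
  cells whose edge mask is noise-dominated; the pipeline calibrates once on
  a designated strong-edge field (a bead phantom or the first frame) and
  reuses the value.
* **Background polynomial.** 2D polynomial with all terms $x^i y^j$,
  $i+j \le 8$ (45 coefficients), ordinary least squares on coordinates
  normalised to $[-1,1]$ for conditioning; rank-deficient designs lower the
  degree automatically; background pixels are subsampled evenly to at most
  20,000 rows. The background mask must leave at least 30% of the field
  cell-free — single-cell fields need margins that scale with the cell
  (the population generator uses `max(8, R)` µm).
* **Percentiles** use linear interpolation between order statistics
  (R's default type 7); stated because dialects differ.
* **Puncta threshold** is $4\times$ the 99th percentile of the per-image
  background; per-cell SNR is the mean QDF over (label ∩ mask) divided by
  the standard deviation of the background outside dilated cells, reported
  as mean ± sd *over cells*.
* **Intercept-only null.** The regression F-test compares the linear fit
  against the horizontal (intercept-only) line — the only "no fit" model
  with a defined residual — using $F = (RSS_0 - RSS_1)/(RSS_1/(n-2))$ on
  $(1, n-2)$ degrees of freedom.
* **Coordinates.** Matrices are indexed `[row = y, col = x]`; the pixel
  centre of `(r, c)` is at `((c-1) * pixel_size, (r-1) * pixel_size)` µm.

## Validation design and problem sizes

The test suite builds every fixture from the simulator at fixed seeds.
The headline experiments (`shape_invariance_experiment()`,
`population_experiment()`, `edge_cancellation_experiment()`,
`calibration_recovery_experiment()`) use 0.5 µm pixels throughout. The
flat-to-round morph experiment places its 20 µm cell with 200 puncta in a
512×512-pixel field, mirroring real acquisitions where a cell occupies a
few percent of the camera FOV — essential because a degree-8 background
surface is well constrained only when it interpolates between background
pixels rather than extrapolating across a cell-sized hole. The population
analysis renders 300 cells spanning 0.1–1.0 pg/µm² mass per area in
per-cell fields whose empty border equals the cell's footprint radius.
These sizes keep the whole validation at laptop scale while preserving
meaningful counting statistics.

Under shot and read noise the edge image acquires a positive noise floor on
isotropic-signal pixels (the absolute difference of two noisy equal
quadrants has mean of order the pixel noise), which subtracts a few percent
from QDF puncta totals; the effect is part of the method itself, and is why
the flat-to-round QDF change is measured as a few percent rather than the
noise-free value below 1%.

One caveat is intrinsic to the population target: the sample Pearson
correlation of $n = 300$ independent pairs has a null sampling spread of
about $1/\sqrt{n} \approx 0.06$, so the measured correlation between QDF
per mass and mass per area scatters by that much around zero even when the
method is perfectly shape-decoupled.

## Known limitations

* Bodies are circular; arbitrary contours, irregular or concave cells are
  not modelled.
* The edge model is local and linear in the height gradient; real lensing
  at steep edges saturates and depends on the NA geometry.
* The noise model applies Poisson statistics at container scale, which
  overstates shot noise relative to a photoelectron-level model by the
  container gain; all validation targets are computed under the same
  convention.
* `c` calibration assumes the edge mask is dominated by true edges; fields
  with no large objects cannot be calibrated (`calibrate_c()` refuses
  masks with fewer than 100 signal pixels).
* The assignment solver is exact for gated components of up to 16 objects
  and refuses larger ones rather than silently approximating; lower
  `max_disp` if that occurs.
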