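---
title: "Counting circulating cells from line-scan kymographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting circulating cells from line-scan kymographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymoFlow)
```

## The measurement model

In intravital in vivo flow cytometry (IVFC), a scanning microscope images a
single line placed across a blood vessel at 650–850 lines per second. Stacking
successive scan lines produces a kymograph: columns are positions along the
line (micrometers), rows are time (one row per line period). A fluorescent
cell crossing the line appears as a bright elliptical streak. Because
circulating leukocytes are approximately round, the streak's spatial extent
approximates the cell diameter `d` (μm) and its temporal extent is the
traverse time `t` (ms), giving the cell's velocity

    v = d / t.

With the vessel lumen diameter `D` (from an intravascular dye channel), the
record duration `T`, and the mean velocity `ave(v)` of the cells in the
record, the volume of blood that crossed the scan plane is

    V = π (D/2)² · ave(v) · T,

and the circulating concentration is `n / V` for `n` detected cells.
Internally lengths are μm and volumes μm³; reported volumes use the fixed
factor 10¹² μm³/mL. Assumptions worth keeping in mind:

* **Plug flow.** A single `ave(v)` stands in for the full velocity profile
  across the lumen. The simulator's default matches this; a parabolic
  profile would make cells near the wall slower and is not modeled.
* **Round, free-flowing cells.** `d` approximates the traversing distance
  only for round cells moving perpendicular to the line; rolling or
  adhering cells violate this.
* **Per-record averaging.** `ave(v)` is the arithmetic mean of per-event
  velocities within one record, never pooled across records, because `V`
  combines it with that record's own `D` and `T`.

## Segmentation

Detection reproduces a threshold → binarize → label → measure chain:

1. **Threshold fitting** (`fitThreshold`). The threshold separating cells
   (brighter) from background (darker) is Otsu's histogram split (256 bins,
   maximizing between-class variance), guarded from below by a robust
   background floor `median + k·mad` with `k = 4`. The floor matters: in a
   120-s record at baseline concentration, streak pixels are on the order of
   10⁻⁴ of the reporter channel. For such a small foreground weight the
   between-class variance of the true cells-vs-background split (≈ weight ×
   SNR² × σ²) is smaller than that of a split inside the background mode
   (≈ 0.64 σ² for a Gaussian background), so an unguarded Otsu threshold
   lands inside the background noise and floods the mask. The floor keeps
   the threshold above background while leaving Otsu in charge whenever the
   foreground is substantial. Both pieces shift consistently under constant
   intensity offsets, so detection is equivariant to brightness pedestals.
2. **Brightness adaptation** (`adaptThreshold`). The threshold is fitted
   once on the first record of a session and rescaled to each later record
   by the ratio of median intensities, clipped to [0.5, 2] to guard against
   pathological records. The median is used as the brightness statistic
   because it is insensitive to how many streaks a record happens to
   contain.
3. **Labeling and measurement** (`detectCells`). Components are 8-connected
   (fast streaks can run diagonally); components smaller than 4 px are
   discarded as shot noise. Each remaining component yields one event row:
   `d` from the spatial bounding-box extent, `t` from the temporal extent,
   `v = d/t`, and per-channel mean/max intensities. A k-pixel extent has
   physical length k × pixel size (a 1-pixel object has nonzero size); this
   count convention is used consistently by the simulator and the detector.
   Overlapping streaks are not split; they merge into one event, and the
   simulator quantifies the resulting (small) undercount. Events touching
   the first or last scan line are flagged truncated: they are counted in
   `n` (the cell demonstrably traversed) but excluded from `ave(v)`
   (their `t` is censored and would bias velocity); both policies are
   configurable.

   One axis convention deserves a note: we measure `d` on the spatial axis
   and `t` on the temporal axis, consistent with treating the traversing
   distance of a round cell as its diameter. The converse reading
   (annotating length along the flow direction, i.e. the temporal axis)
   appears in some descriptions of such pipelines; it is available by
   swapping the axis roles but is not the default.
4. **Vessel diameter** (`measureVesselDiameter`). The dye channel is
   thresholded with plain Otsu (the lumen occupies a large fraction of the
   line, exactly the bimodal regime where Otsu is reliable; a median floor
   would sit above the dye level and is deliberately not applied). Each
   line contributes its longest above-threshold run; `D` is the median run
   length across lines, which makes the measurement insensitive to streaks
   inside the lumen and to occasional dropout lines. If more than half of
   the lines have no run, the vessel is reported as not found.

## Two-color gating

Detection runs on the reporter channel only; the antibody channel
contributes intensities. The gate is `background mean + k·SD` (default
`k = 3`) with the background estimated from non-cell pixels inside the
lumen — a bead-calibrated gate is not reproducible in software, and the
k·SD rule is standard flow-cytometry practice with an explicit, testable
definition. A fixed-threshold override exists. MFI is the
background-subtracted mean event intensity, floored at zero, reported for
the positive population and for all events. Reporter-negative,
marker-positive cells are recovered by a secondary detection pass on the
antibody channel restricted to the lumen, keeping components that do not
overlap any reporter event.

## The simulator

`simulateRecord` inverts the measurement model: cells arrive as a Poisson
process with rate λ = C · π(D/2)² · mean(v) · 10⁻¹² per second (volumetric
flux × concentration), each with diameter and velocity drawn from normal
distributions truncated at zero (only mean ± SD are typically reported for
these quantities; positivity is physical), a uniform lane within the lumen,
and an elliptical footprint with axes `d/pixelSize` and `(d/v)·scanRate`.
Arrivals extend into a margin around `[0, T]` so boundary truncation occurs
naturally, and the truth table records which events are truncated. Additive
Gaussian read noise (clipped at zero, rounded to integer intensities) is
the default noise model — the simplest that exercises thresholding; SNR is
defined as (signal − background)/noise SD and is a free parameter because
real records' noise is rarely characterized. The area-sampled rendering
carries the full analytic extent through the central row and column so
that rendered extents track `d` and `t` to within one pixel/line.

Defaults describe a baseline measurement: D = 40 μm, T = 120 s, 750
lines/s, 0.6 μm pixels, C = 1.3×10⁵ cells/mL, d ~ N(6.6, 1.4) μm,
v ~ N(1063, 357) μm/s, 16-bit-style levels (background 500, signal 3000).

What the simulator does **not** emulate: optical point-spread blur,
photobleaching, pulsatile or parabolic flow, cell rolling along the wall,
autofluorescence structure, or 3-D vessel geometry. Passing recovery tests
therefore demonstrates correctness of the estimators under the model's own
assumptions — not robustness to every property of real recordings.

## Validation scenarios and problem sizes

The test-suite scenarios are sized to validate each claim with adequate
statistical power while remaining routine to run:

* **Detection oracle / parameter recovery:** 20 records at full duration
  (T = 120 s, 750 Hz) with 0.8-μm pixels; recovery uses SNR 5, a
  conservative noise level.
* **Time-course fold-change:** 20 scenario replicates of 6 subjects/group ×
  9 timepoints, a 2× concentration step at minute 60 over a 2×10⁵/mL
  baseline. Records are 30 s at 650 Hz and rendered noise-free: at these
  event rates (~8 events/record at baseline), Poisson counting statistics
  dominate the group comparison, and detection robustness to noise is
  established separately by the recovery scenario.
* **Two-color mixture:** each replicate pools four simulated records
  (56 s at a 4×10⁵/mL post-challenge concentration) to reach ~120 events,
  the scale at which percent-positive figures are typically reported; the
  generating positive fraction is 20.8%. The gated fraction is compared
  with the exact binomial confidence interval at each replicate's own
  event count.
* **Statistical kernels:** the t-test power check uses an inter-animal SD
  of 1×10⁵ cells/mL around group means of 2 and 4×10⁵ — a realistic
  between-mouse spread for a 2× challenge response.

## Numerical choices and degenerate inputs

* Empty records report concentration 0 with a low-confidence flag and an
  undefined `V` (no `ave(v)` exists); they are not errors.
* A record whose events are all truncated falls back to the censored
  velocities and is flagged low-confidence.
* Zero pooled variance in the t-test returns t = 0, p = 1 for equal means
  and the smallest positive double for complete separation, rather than an
  error.
* Otsu ties resolve to the lowest maximizing bin edge; thresholds classify
  strictly-greater pixels as foreground.
* The vessel's reported pixel bounds are anchored at the median run start
  with width equal to the median run length, so `D` and the bounds are
  always consistent.
* Vessel diameters are accepted for any D > 0; range screening (e.g.
  restricting to 20–45 μm vessels) is a study-design choice left to
  configuration.

## File formats

Kymographs travel as 16-bit multi-page grayscale TIFFs (one page per
channel) with a JSON sidecar (`scan_rate_hz`, `pixel_size_um`, `n_lines`,
`n_pixels`, `channels`), written losslessly so that simulated records
round-trip bit-exactly. PrairieView-style XML metadata (`scanLinePeriod`,
`micronsPerPixel`, `linesPerFrame`, `pixelsPerLine`) is accepted as a
second dialect; the scan rate is the reciprocal of the line period. RGBA
composites are split green → reporter and max(red, blue) → vessel by
default (the common cyan/magenta rendering); the mapping is configurable
because composite exports rarely document it.

## Worked example

```{r example}
p <- simulationParams(seed = 7, TS = 20, noiseSd = 250)
sim <- simulateRecord(p)
res <- analyzeKymograph(sim$kymograph)
res$summary
nrow(truthEvents(sim$truth))   # ground-truth event count
```

## Known limitations

* Merged (overlapping) streaks are counted once; at baseline
  concentrations this biases counts by well under a percent, but the bias
  grows with concentration and record density.
* The concentration estimator is unbiased only under plug flow; with a
  real velocity profile, `ave(v)` over detected cells need not equal the
  volume-weighted mean velocity.
* Per-timepoint unpaired t-tests on repeated measures ignore within-mouse
  correlation; the package reproduces that procedure without endorsing it.
  Two-way ANOVA with multiplicity corrections is out of scope — any
  general statistics package can consume the exported per-record tables.
* IVFC counts are known to undershoot hematology-counter concentrations;
  no absolute calibration is attempted.
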