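# kymoFlow

In vivo flow cytometry (IVFC) from line-scan kymographs: detect fluorescent
circulating cells in intravital line-scan recordings, measure their
diameter, traverse time and velocity, and convert event counts into
circulating-cell concentrations.

## The measurement

A scanning microscope images one line placed across a blood vessel at
650–850 lines/s. Stacking the lines gives a kymograph (space × time) in
which each traversing cell leaves an elliptical streak. For a round cell
the streak's spatial extent is the cell diameter *d* (μm) and its temporal
extent is the traverse time *t* (ms), so

    v = d / t                      (cell velocity, μm/s)
    V = π (D/2)² · ave(v) · T      (sampled blood volume, 1 mL = 10¹² μm³)
    concentration = n / V          (cells/mL)

with *D* the vessel lumen diameter measured from an intravascular dye
channel, *T* the record duration and *n* the number of detected cells.

The package provides:

* `readKymograph` / `parseScanMetadata` — TIFF records (multi-page
  grayscale or RGBA composites) with JSON or PrairieView-style XML
  metadata;
* `fitThreshold` / `adaptThreshold` / `detectCells` — brightness-adaptive
  thresholding (Otsu with a robust background floor) and 8-connected
  streak labeling;
* `measureVesselDiameter` — median lumen run length on the dye channel;
* `summarizeRecord`, `buildTimecourse`, `foldChange`, `timecourseTTests` —
  record summaries and multi-subject time courses;
* `estimateBackground`, `gateEvents`, `dotplotTable` — two-color gating
  (percent positive, background-subtracted MFI);
* `pearsonWithRegression`, `unpairedTTest` — the accompanying statistics;
* `simulateRecord` / `simulateTimecourse` — a ground-truth synthetic
  kymograph generator, so every estimator is validated by parameter
  recovery;
* `inst/scripts/kymoflow.R` — a command-line interface
  (`simulate` / `analyze` / `timecourse` / `gate2c`).

## Worked example

Simulate a 20-second record of a 40-μm vessel at 750 lines/s with cells at
1.3×10⁵ cells/mL, then analyze it end to end:

```r
library(kymoFlow)
p <- simulationParams(seed = 7, TS = 20, noiseSd = 250)
sim <- simulateRecord(p)
res <- analyzeKymograph(sim$kymograph)
res$summary
#> RecordSummary: n = 8 | ave(v) = 978.125 um/s | D = 39.6 um | T = 20 s
#>   V = 2.40938e-05 mL | concentration = 332036 cells/mL
nrow(truthEvents(sim$truth))
#> [1] 8
```

All eight simulated cells are detected. The record's mean streak velocity
is ~978 μm/s; with the measured lumen (39.6 μm — the true 40-μm lumen
quantized to 0.6-μm pixels) and the 20-s duration this gives a sampled
volume of 2.41×10⁻⁵ mL, so the eight events correspond to 3.3×10⁵
cells/mL. A single 20-s record sees a handful of Poisson arrivals (expected
≈ 3.5 here), so individual records scatter widely around the generating
1.3×10⁵ cells/mL; concentration estimates average over replicate records
(see the methods vignette).

From the shell, the same pipeline:

```sh
Rscript inst/scripts/kymoflow.R simulate --config sim.json --out run/
Rscript inst/scripts/kymoflow.R analyze --image run/record.tif \
    --metadata run/record.json --out run/
```

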