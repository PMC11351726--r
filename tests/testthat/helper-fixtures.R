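# Shared fixtures: small simulation parameter sets and hand-built kymographs.

# quick record: ~10 events in 8 s, noise-free unless overridden
smallParams <- function(seed = 1L, ...) {
  args <- list(seed = seed, TS = 8, scanRateHz = 650, nPixels = 48L,
               pixelSizeUm = 1.0, concentrationPerMl = 1e6, noiseSd = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulationParams, args)
}

# 20 lines x 20 px, two channels; one 4-line x 3-px blob at rows 5:8,
# cols 10:12 in the reporter channel; dye channel fills cols 3:18
blobKymograph <- function(blobRows = 5:8, blobCols = 10:12,
                          pixelSizeUm = 0.6, scanRateHz = 750) {
  md <- ScanMetadata(scanRateHz, pixelSizeUm, 20L, 20L,
                     c("vessel", "reporter"))
  vessel <- matrix(100, 20, 20)
  vessel[, 3:18] <- 3000
  reporter <- matrix(10, 20, 20)
  reporter[blobRows, blobCols] <- 200
  Kymograph(array(c(vessel, reporter), c(20, 20, 2)), md)
}

# minimal events table for quantify-level tests
mkEvents <- function(v, truncated = rep(FALSE, length(v))) {
  n <- length(v)
  data.frame(event_id = seq_len(n), line_start = seq_len(n) * 10,
             line_end = seq_len(n) * 10 + 4, px_start = rep(5, n),
             px_end = rep(10, n), d_um = rep(6, n), t_ms = 6 / (v / 1000),
             v_um_s = v, truncated = truncated)
}
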