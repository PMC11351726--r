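# Streak segmentation: threshold -> binarize -> label -> measure.
# The threshold is fitted once (first record) and rescaled to later records'
# brightness; labeling is 8-connected; components become one CellEvent row
# each with d on the spatial axis and t on the temporal axis.

# Otsu's threshold: bin the intensity histogram and pick the split that
# maximizes between-class variance. Foreground is x > threshold.
.otsuThreshold <- function(x, levels = 256L) {
  r <- range(x)
  if (!is.finite(r[1]) || r[1] == r[2])
    stop("degenerate image: channel is constant, cannot fit a threshold")
  w <- (r[2] - r[1]) / levels
  b <- pmin(floor((x - r[1]) / w), levels - 1)    # bins 0 .. levels-1
  counts <- tabulate(b + 1L, nbins = levels)
  p <- counts / length(x)
  mids <- r[1] + (seq_len(levels) - 0.5) * w
  om <- cumsum(p)                                  # class-0 weight
  mu <- cumsum(p * mids)                           # class-0 mass
  muT <- mu[levels]
  k <- seq_len(levels - 1L)
  denom <- om[k] * (1 - om[k])
  sigmaB <- ifelse(denom > 0, (muT * om[k] - mu[k])^2 / denom, -Inf)
  kStar <- which.max(sigmaB)
  r[1] + kStar * w                                 # upper edge of bin kStar
}

#' Fit the streak-detection threshold on a reference record
#'
#' The threshold separating cells (brighter) from background (darker) is the
#' Otsu threshold of the channel's intensity histogram, guarded from below by
#' a robust background floor, median + kFloor * mad. The floor matters when
#' streaks cover a very small fraction of the record: between-class variance
#' is then dominated by splits inside the background mode and Otsu alone
#' would land there; the floor keeps the threshold above background noise.
#' The fitted state also stores the record's median brightness so the
#' threshold can be rescaled to later records
#' (\code{\link{adaptThreshold}}).
#'
#' @param channel numeric matrix, the reporter channel of the first record.
#' @param kFloor background-floor multiplier (default 4); \code{NA} disables
#'   the floor (pure Otsu).
#' @param scaleBounds clip factors for later brightness adaptation.
#' @param levels histogram bins for Otsu.
#' @return A \linkS4class{ThresholdState}.
#' @export
fitThreshold <- function(channel, kFloor = 4, scaleBounds = c(0.5, 2),
                         levels = 256L) {
  th <- .otsuThreshold(channel, levels)
  med <- stats::median(channel)
  if (is.finite(kFloor)) {
    floorTh <- med + kFloor * stats::mad(channel)
    th <- max(th, floorTh)
  }
  new("ThresholdState", baseThreshold = th, baseBrightness = med,
      scaleBounds = as.numeric(scaleBounds))
}

#' Adapt a fitted threshold to a record's brightness
#'
#' Returns baseThreshold * clip(median(channel)/baseBrightness, scaleBounds):
#' the threshold follows overall brightness changes between records, with
#' clipping to guard against pathological records.
#'
#' @param state a \linkS4class{ThresholdState} from \code{\link{fitThreshold}}.
#' @param channel numeric matrix.
#' @return Intensity threshold for this record.
#' @export
adaptThreshold <- function(state, channel) {
  if (!is.finite(state@baseBrightness) || state@baseBrightness <= 0)
    stop("degenerate state: reference brightness is zero")
  scale <- stats::median(channel) / state@baseBrightness
  scale <- min(max(scale, state@scaleBounds[1]), state@scaleBounds[2])
  state@baseThreshold * scale
}

#' Label connected components of a binary mask
#'
#' 8-connected by default (streaks are elongated and may run diagonally at
#' high velocity); 4-connected available.
#'
#' @param mask logical or 0/1 numeric matrix.
#' @param connectivity 8 or 4.
#' @return Integer matrix of component labels (0 = background), labeled in
#'   raster order.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)   # 4-connected
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  K <- max(lab)
  if (connectivity == 4L || K < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2L || nc < 2L) return(lab)
  # merge components touching diagonally (sparse: work on foreground only)
  idx <- which(lab > 0L)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- (idx - 1L) %/% nr + 1L
  diagPairs <- function(offset, valid) {
    nb <- idx[valid] + offset
    hit <- match(nb, idx)
    ok <- !is.na(hit)
    cbind(lab[idx[valid][ok]], lab[idx[hit[ok]]])
  }
  p1 <- diagPairs(1L + nr, rows < nr & cols < nc)   # down-right
  p2 <- diagPairs(1L - nr, rows < nr & cols > 1L)   # down-left
  pairs <- rbind(p1, p2)
  pairs <- unique(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(K)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- findRoot(pairs[k, 1]); rb <- findRoot(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(K), findRoot, integer(1))
  dense <- match(root, sort(unique(root)))
  lookup <- c(0L, as.integer(dense))
  matrix(lookup[lab + 1L], nr, nc)
}

#' Detect cell streaks in a kymograph channel
#'
#' Binarizes the channel at the threshold, labels 8-connected components,
#' drops components smaller than \code{minAreaPx} (shot-noise specks) and
#' measures each remaining component: spatial bounding-box extent gives the
#' cell diameter d (um), temporal extent gives the traverse time t (ms),
#' velocity v = d/t, and per-channel mean/max intensities are taken over the
#' component's pixels. Events whose box touches the first or last scan line
#' are flagged truncated (their t is censored).
#'
#' @param kymo a \linkS4class{Kymograph}.
#' @param channel channel name to detect on (e.g. "reporter").
#' @param threshold intensity threshold (from \code{\link{fitThreshold}} /
#'   \code{\link{adaptThreshold}}).
#' @param minAreaPx minimum component area in pixels.
#' @param connectivity 8 (default) or 4.
#' @param restrictPx optional half-open 0-based pixel range; detection is
#'   restricted to these columns (used for lumen-restricted passes).
#' @param channelData optional precomputed channel matrix (avoids a second
#'   extraction when the caller already holds it).
#' @return data.frame with one row per event, sorted by line_start: columns
#'   event_id, line_start/line_end/px_start/px_end (half-open, 0-based),
#'   centroid_line, centroid_px, area_px, d_um, t_ms, v_um_s, truncated, and
#'   mean_intensity_/max_intensity_ per channel.
#' @export
detectCells <- function(kymo, channel, threshold, minAreaPx = 4L,
                        connectivity = 8L, restrictPx = NULL,
                        channelData = NULL) {
  md <- kymo@metadata
  ch <- if (is.null(channelData)) channelMatrix(kymo, channel)
        else channelData
  mask <- ch > threshold
  if (!is.null(restrictPx)) {
    keepCols <- seq_len(md@nPixels) > restrictPx[1] &
                seq_len(md@nPixels) <= restrictPx[2]
    mask[, !keepCols] <- FALSE
  }
  lab <- labelComponents(mask, connectivity)
  nr <- nrow(lab)

  chanNames <- md@channelNames
  emptyEvents <- function() {
    cols <- c("event_id", "line_start", "line_end", "px_start", "px_end",
              "centroid_line", "centroid_px", "area_px", "d_um", "t_ms",
              "v_um_s", "truncated",
              paste0("mean_intensity_", chanNames),
              paste0("max_intensity_", chanNames))
    df <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(df) <- cols
    df$truncated <- logical(0)
    df
  }

  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(emptyEvents())
  lv <- lab[idx]
  area <- tabulate(lv)
  keepMask <- area >= minAreaPx
  sel <- keepMask[lv]
  idx <- idx[sel]; lv <- lv[sel]
  if (length(idx) == 0L) return(emptyEvents())

  rows <- ((idx - 1L) %% nr) + 1L
  cols <- (idx - 1L) %/% nr + 1L
  grp <- split(seq_along(lv), lv)
  nG <- length(grp)
  lineMin <- lineMax <- pxMin <- pxMax <- integer(nG)
  cLine <- cPx <- numeric(nG)
  areaG <- integer(nG)
  for (g in seq_len(nG)) {
    ii <- grp[[g]]
    r <- rows[ii]; cc <- cols[ii]
    lineMin[g] <- min(r); lineMax[g] <- max(r)
    pxMin[g] <- min(cc); pxMax[g] <- max(cc)
    cLine[g] <- mean(r) - 0.5; cPx[g] <- mean(cc) - 0.5
    areaG[g] <- length(ii)
  }
  dUm <- (pxMax - pxMin + 1L) * md@pixelSizeUm
  tMs <- (lineMax - lineMin + 1L) / md@scanRateHz * 1000
  ev <- data.frame(
    event_id = seq_len(nG),
    line_start = lineMin - 1L, line_end = lineMax,
    px_start = pxMin - 1L, px_end = pxMax,
    centroid_line = cLine, centroid_px = cPx,
    area_px = areaG,
    d_um = dUm, t_ms = tMs,
    v_um_s = cellVelocity(dUm, tMs),
    truncated = lineMin == 1L | lineMax == nr
  )
  stride <- as.numeric(nr) * md@nPixels
  for (k in seq_along(chanNames)) {
    vals <- kymo@pixels[idx + (k - 1L) * stride]
    nm <- chanNames[k]
    ev[[paste0("mean_intensity_", nm)]] <-
      vapply(grp, function(ii) mean(vals[ii]), numeric(1))
    ev[[paste0("max_intensity_", nm)]] <-
      vapply(grp, function(ii) max(vals[ii]), numeric(1))
  }
  ord <- order(ev$line_start, ev$px_start)
  ev <- ev[ord, , drop = FALSE]
  ev$event_id <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  ev
}

#' Measure the vessel lumen diameter from the dye channel
#'
#' Thresholds the intravascular-dye channel (Otsu), takes the longest
#' contiguous above-threshold run on each scan line, and reports the median
#' run length across lines as the lumen diameter. Cell streaks inside the
#' lumen do not affect the measurement (they sit within the run).
#'
#' @param kymo a \linkS4class{Kymograph}.
#' @param channel dye channel name.
#' @return A \linkS4class{VesselMeasurement}.
#' @export
measureVesselDiameter <- function(kymo, channel = "vessel") {
  md <- kymo@metadata
  ch <- channelMatrix(kymo, channel)
  r <- range(ch)
  if (r[1] == r[2])
    stop("vessel not found: dye channel is constant")
  th <- .otsuThreshold(ch)
  mi <- matrix(as.integer(ch > th), nrow(ch), ncol(ch))
  nr <- nrow(mi); np <- ncol(mi)
  cnt <- integer(nr); best <- integer(nr); bestEnd <- integer(nr)
  for (j in seq_len(np)) {
    cnt <- (cnt + 1L) * mi[, j]
    upd <- cnt > best
    if (any(upd)) {
      best[upd] <- cnt[upd]
      bestEnd[upd] <- j
    }
  }
  ok <- best > 0L
  if (mean(ok) <= 0.5)
    stop("vessel not found: no lumen run on more than half of the scan lines")
  L <- stats::median(best[ok])
  s <- stats::median(bestEnd[ok] - best[ok] + 1L)
  new("VesselMeasurement",
      DUm = L * md@pixelSizeUm,
      pxBounds = c(s - 1, s - 1 + L),
      linesUsed = sum(ok))
}
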