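# Ground-truth synthetic kymograph generator. Cells arrive as a Poisson
# process with rate lambda = C * pi*(D/2)^2 * mean(v) * 1e-12 per second
# (volumetric flux times concentration), each with diameter and velocity
# drawn from truncated normals, rendered as a filled ellipse in (line,
# pixel) space: spatial axis d/pixelSize, temporal axis (d/v)*scanRate.

#' Construct simulation parameters
#'
#' Defaults emulate a baseline intravital measurement: 40-um vessel scanned
#' at 750 lines/s for 120 s with 0.6-um pixels, circulating reporter cells
#' at 1.3e5 cells/mL with d ~ N(6.6, 1.4) um and v ~ N(1063, 357) um/s
#' (truncated at 0), 16-bit-style intensity levels (background 500, signal
#' 3000) and Gaussian read noise (SD 100).
#'
#' @param seed RNG seed; the whole record (arrivals, draws, noise) is
#'   reproducible from it.
#' @param DUm vessel lumen diameter (um).
#' @param TS record duration (s).
#' @param scanRateHz scan rate (lines/s).
#' @param pixelSizeUm pixel size (um).
#' @param nPixels pixels per scan line.
#' @param concentrationPerMl true concentration C (cells/mL).
#' @param vMeanUmS,vSdUmS velocity distribution (um/s), truncated at > 0.
#' @param dMeanUm,dSdUm diameter distribution (um), truncated at > 0.
#' @param backgroundLevel,dyeLevel,reporterLevel,antibodyLevel intensity
#'   levels.
#' @param noiseSd additive Gaussian noise SD (intensity units); SNR =
#'   (signal - background)/noiseSd.
#' @param positiveFraction fraction of reporter-positive cells also positive
#'   on the antibody channel (two-color mode).
#' @param gfpNegativeFraction fraction of cells visible only on the antibody
#'   channel (reporter-negative).
#' @param twoColor render an antibody channel.
#' @return A \linkS4class{SimulationParams}.
#' @export
simulationParams <- function(seed = 1L, DUm = 40, TS = 120,
                             scanRateHz = 750, pixelSizeUm = 0.6,
                             nPixels = 96L, concentrationPerMl = 1.3e5,
                             vMeanUmS = 1063, vSdUmS = 357,
                             dMeanUm = 6.6, dSdUm = 1.4,
                             backgroundLevel = 500, dyeLevel = 3000,
                             reporterLevel = 3000, antibodyLevel = 3000,
                             noiseSd = 100,
                             positiveFraction = 0, gfpNegativeFraction = 0,
                             twoColor = FALSE) {
  new("SimulationParams", seed = as.integer(seed), DUm = DUm, TS = TS,
      scanRateHz = scanRateHz, pixelSizeUm = pixelSizeUm,
      nPixels = as.integer(nPixels),
      concentrationPerMl = concentrationPerMl,
      vMeanUmS = vMeanUmS, vSdUmS = vSdUmS, dMeanUm = dMeanUm,
      dSdUm = dSdUm, backgroundLevel = backgroundLevel, dyeLevel = dyeLevel,
      reporterLevel = reporterLevel, antibodyLevel = antibodyLevel,
      noiseSd = noiseSd, positiveFraction = positiveFraction,
      gfpNegativeFraction = gfpNegativeFraction, twoColor = twoColor)
}

#' Expected event rate of a parameter set
#'
#' lambda = C * pi*(D/2)^2 * mean(v) * 1e-12 events per second: the
#' concentration times the volumetric flux through the vessel cross-section.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @return Events per second.
#' @export
expectedEventRate <- function(params) {
  params@concentrationPerMl * pi * (params@DUm / 2)^2 *
    params@vMeanUmS * 1e-12
}

.rtruncnormPos <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Simulate one line-scan record with ground truth
#'
#' Draws Poisson arrivals over the record plus a temporal margin (so
#' boundary-truncated streaks occur naturally), assigns each cell a
#' diameter, velocity, lane within the lumen and channel class, renders the
#' streaks as filled ellipses over a flat background, adds Gaussian read
#' noise (clipped at 0, rounded to integer intensities), and returns the
#' kymograph together with the true event table.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @param render render the pixel grid (FALSE returns ground truth only,
#'   with analytic bounding boxes).
#' @param avoidOverlap re-place events whose streaks would touch an earlier
#'   streak (detection-oracle scenarios); placement is redrawn, so event
#'   counts keep their Poisson law.
#' @param marginS temporal margin (s) around [0, T] in which cells may
#'   arrive.
#' @return list(kymograph = \linkS4class{Kymograph} or NULL,
#'   truth = \linkS4class{GroundTruth}).
#' @export
simulateRecord <- function(params, render = TRUE, avoidOverlap = FALSE,
                           marginS = 0.1) {
  p <- params
  nLines <- as.integer(round(p@TS * p@scanRateHz))
  nPx <- p@nPixels
  chans <- c("vessel", "reporter", if (p@twoColor) "antibody")
  md <- ScanMetadata(p@scanRateHz, p@pixelSizeUm, nLines, nPx, chans)
  lambda <- expectedEventRate(p)

  withr::with_seed(p@seed, {
    N <- stats::rpois(1, lambda * (p@TS + 2 * marginS))
    arrival <- sort(stats::runif(N, -marginS, p@TS + marginS))
    d <- .rtruncnormPos(N, p@dMeanUm, p@dSdUm)
    v <- .rtruncnormPos(N, p@vMeanUmS, p@vSdUmS)
    gfpNeg <- if (p@twoColor) stats::runif(N) < p@gfpNegativeFraction
              else rep(FALSE, N)
    abPos <- if (p@twoColor) {
      x <- stats::runif(N) < p@positiveFraction
      x | gfpNeg          # reporter-negative cells are marker-positive
    } else rep(FALSE, N)

    centerUm <- nPx * p@pixelSizeUm / 2
    lumenLo <- centerUm - p@DUm / 2
    lumenHi <- centerUm + p@DUm / 2
    laneLo <- pmin(lumenLo + d / 2, centerUm)
    laneHi <- pmax(lumenHi - d / 2, centerUm)
    lane <- stats::runif(N, laneLo, laneHi)

    # analytic streak geometry in pixel coordinates (0-based continuous)
    geom <- function(arrival, lane) {
      cl <- arrival * p@scanRateHz
      hl <- (d / v) * p@scanRateHz / 2
      cp <- lane / p@pixelSizeUm
      hw <- (d / p@pixelSizeUm) / 2
      iLo <- ceiling(cl - hl + 0.5); iHi <- floor(cl + hl + 0.5)
      jLo <- ceiling(cp - hw + 0.5); jHi <- floor(cp + hw + 0.5)
      snapRow <- pmin(pmax(round(cl + 0.5), 1), nLines)
      snapCol <- pmin(pmax(round(cp + 0.5), 1), nPx)
      noRow <- iHi < iLo
      iLo[noRow] <- iHi[noRow] <- snapRow[noRow]
      noCol <- jHi < jLo
      jLo[noCol] <- jHi[noCol] <- snapCol[noCol]
      list(cl = cl, hl = hl, cp = cp, hw = hw,
           iLo = iLo, iHi = iHi, jLo = jLo, jHi = jHi)
    }
    g <- geom(arrival, lane)

    if (avoidOverlap && N > 1) {
      for (i in seq_len(N)[-1]) {
        tries <- 0
        repeat {
          prev <- seq_len(i - 1)
          clash <- any(g$iLo[i] <= g$iHi[prev] + 1L &
                       g$iHi[i] >= g$iLo[prev] - 1L &
                       g$jLo[i] <= g$jHi[prev] + 1L &
                       g$jHi[i] >= g$jLo[prev] - 1L)
          if (!clash || tries > 200) break
          arrival[i] <- stats::runif(1, -marginS, p@TS + marginS)
          lane[i] <- stats::runif(1, laneLo[i], laneHi[i])
          gi <- geom(arrival[i], lane[i])
          for (nm in c("cl", "hl", "cp", "hw", "iLo", "iHi", "jLo", "jHi"))
            g[[nm]][i] <- gi[[nm]][i]
          tries <- tries + 1
        }
      }
    }

    visible <- g$iHi >= 1L & g$iLo <= nLines
    truncated <- visible & (g$iLo < 1L | g$iHi > nLines)

    lineStart <- pmax(g$iLo, 1L); lineEnd <- pmin(g$iHi, nLines)
    pxStart <- pmax(g$jLo, 1L); pxEnd <- pmin(g$jHi, nPx)

    kymo <- NULL
    if (render) {
      nCh <- length(chans)
      colCentersUm <- (seq_len(nPx) - 0.5) * p@pixelSizeUm
      lumenCols <- colCentersUm > lumenLo & colCentersUm < lumenHi
      arr <- array(p@backgroundLevel, c(nLines, nPx, nCh))
      arr[, lumenCols, 1] <- p@dyeLevel

      for (i in which(visible)) {
        ri <- lineStart[i]:lineEnd[i]
        cj <- pxStart[i]:pxEnd[i]
        m <- outer(((ri - 0.5 - g$cl[i]) / g$hl[i])^2,
                   ((cj - 0.5 - g$cp[i]) / g$hw[i])^2, "+") <= 1
        # area sampling lights the tangent pixels: carry the full spatial
        # diameter through the central row and the full traverse through the
        # central column, so rendered extents track the analytic ones
        rowC <- which.min(abs(ri - 0.5 - g$cl[i]))
        colC <- which.min(abs(cj - 0.5 - g$cp[i]))
        m[rowC, abs(cj - 0.5 - g$cp[i]) < g$hw[i]] <- TRUE
        m[abs(ri - 0.5 - g$cl[i]) < g$hl[i], colC] <- TRUE
        if (!any(m)) m[rowC, colC] <- TRUE
        if (!gfpNeg[i]) {
          blk <- arr[ri, cj, 2]
          blk[m] <- pmax(blk[m], p@reporterLevel)
          arr[ri, cj, 2] <- blk
        }
        if (p@twoColor && abPos[i]) {
          blk <- arr[ri, cj, 3]
          blk[m] <- pmax(blk[m], p@antibodyLevel)
          arr[ri, cj, 3] <- blk
        }
        # tighten truth bbox to the rendered support
        rs <- range(which(rowSums(m) > 0)); cs <- range(which(colSums(m) > 0))
        lineStart[i] <- ri[rs[1]]; lineEnd[i] <- ri[rs[2]]
        pxStart[i] <- cj[cs[1]]; pxEnd[i] <- cj[cs[2]]
      }

      if (p@noiseSd > 0)
        arr <- round(pmax(arr + stats::rnorm(length(arr), 0, p@noiseSd), 0))
      kymo <- Kymograph(arr, md)
    }

    ev <- data.frame(
      id = seq_len(N), arrival_s = arrival, lane_um = lane,
      d_um = d, v_um_s = v, t_ms = d / v * 1000,
      reporter_positive = !gfpNeg, antibody_positive = abPos,
      line_start = lineStart - 1L, line_end = lineEnd,
      px_start = pxStart - 1L, px_end = pxEnd,
      truncated = truncated
    )[visible, , drop = FALSE]
    rownames(ev) <- NULL

    truth <- new("GroundTruth", params = p, events = ev,
                 expectedRate = lambda)
    list(kymograph = kymo, truth = truth)
  })
}

#' Simulate (and optionally analyze) a multi-subject time course
#'
#' One record per (group, subject, time), with the true concentration scaled
#' by the group-by-time multiplier (e.g. a 2x step from minute 60 in the
#' treated group). When \code{analyze = TRUE} each record is run through the
#' full detection pipeline as it is generated (the detection threshold is
#' fitted on the first record and brightness-adapted to the rest), and the
#' per-record summaries are assembled into a \linkS4class{TimeCourse}.
#'
#' @param params baseline \linkS4class{SimulationParams}; \code{params@TS}
#'   is the per-record duration.
#' @param multipliers named list (one entry per group) of concentration
#'   multipliers, each a vector along \code{scheduleMin}.
#' @param scheduleMin measurement times (minutes).
#' @param nSubjectsPerGroup subjects per group.
#' @param seed scenario seed; per-record seeds are derived from it.
#' @param analyze run the detection pipeline on each record.
#' @param outDir if non-NULL, write each record (TIFF + JSON metadata) and
#'   the truth table there.
#' @return list(timecourse = \linkS4class{TimeCourse} or NULL, truth =
#'   data.frame with the true concentration and event count per record,
#'   manifest = data.frame of written files when \code{outDir} is set).
#' @export
simulateTimecourse <- function(params, multipliers,
                               scheduleMin = c(0, 10, 20, 30, 60, 90, 120,
                                               150, 180),
                               nSubjectsPerGroup = 6L,
                               seed = params@seed,
                               analyze = TRUE, outDir = NULL) {
  groups <- names(multipliers)
  if (is.null(groups) || any(groups == ""))
    stop("config error: multipliers must be a named list of groups")
  for (gname in groups) {
    m <- multipliers[[gname]]
    if (length(m) != length(scheduleMin))
      stop("config error: multipliers for '", gname,
           "' must match the schedule length")
    if (any(m < 0))
      stop("config error: negative concentration multiplier for '", gname, "'")
  }
  points <- list(); truthRows <- list(); manifest <- list()
  state <- NULL
  counter <- 0L
  for (gname in groups) {
    for (s in seq_len(nSubjectsPerGroup)) {
      subj <- paste0(gname, "_", s)
      for (ti in seq_along(scheduleMin)) {
        counter <- counter + 1L
        recSeed <- as.integer((as.numeric(seed) + counter * 7919) %%
                              2147483646) + 1L
        pi <- params
        pi@seed <- recSeed
        pi@concentrationPerMl <-
          params@concentrationPerMl * multipliers[[gname]][ti]
        sim <- simulateRecord(pi, render = analyze || !is.null(outDir))
        truthRows[[counter]] <- data.frame(
          subject_id = subj, group = gname, time_min = scheduleMin[ti],
          seed = recSeed,
          true_concentration_per_ml = pi@concentrationPerMl,
          true_n = nrow(sim$truth@events),
          true_mean_v = if (nrow(sim$truth@events))
            mean(sim$truth@events$v_um_s) else NA_real_)
        if (analyze) {
          res <- analyzeKymograph(sim$kymograph, state = state)
          state <- res$thresholdState
          points[[counter]] <- timeCoursePoint(subj, gname, scheduleMin[ti],
                                               res$summary)
        }
        if (!is.null(outDir)) {
          base <- file.path(outDir, sprintf("%s_t%03d", subj, scheduleMin[ti]))
          writeKymograph(sim$kymograph, paste0(base, ".tif"),
                         paste0(base, ".json"))
          utils::write.csv(sim$truth@events, paste0(base, "_truth.csv"),
                           row.names = FALSE)
          manifest[[counter]] <- data.frame(
            subject_id = subj, group = gname, time_min = scheduleMin[ti],
            image = paste0(base, ".tif"), metadata = paste0(base, ".json"))
        }
      }
    }
  }
  tc <- if (analyze)
    buildTimecourse(do.call(rbind, points), scheduleMin) else NULL
  list(timecourse = tc, truth = do.call(rbind, truthRows),
       manifest = if (length(manifest)) do.call(rbind, manifest) else NULL)
}
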