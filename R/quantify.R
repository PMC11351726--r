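# Record-level aggregation: n, ave(v), D, T -> V -> concentration, and
# time-course assembly over (subject, group, time) grids.

#' Summarize one record into count, velocity, volume and concentration
#'
#' n is the number of detected events; ave(v) is the arithmetic mean of
#' per-event velocities within this record. Truncated events (streak touches
#' the record boundary, so t is censored) are counted in n by default but
#' excluded from ave(v). The sampled volume is
#' V = pi*(D/2)^2 * ave(v) * T and the concentration n/V. An empty record
#' reports concentration 0 with the low-confidence flag set (ave(v) is then
#' undefined, so V is NA).
#'
#' @param events events data.frame from \code{\link{detectCells}}.
#' @param vessel a \linkS4class{VesselMeasurement}.
#' @param metadata a \linkS4class{ScanMetadata} (supplies T).
#' @param countTruncated count truncated events in n (default TRUE).
#' @param velocityExcludesTruncated exclude truncated events from ave(v)
#'   (default TRUE).
#' @return A \linkS4class{RecordSummary}.
#' @export
summarizeRecord <- function(events, vessel, metadata,
                            countTruncated = TRUE,
                            velocityExcludesTruncated = TRUE) {
  if (missing(vessel) || is.null(vessel))
    stop("measurement error: vessel measurement is required")
  if (!is.finite(metadata@durationS) || metadata@durationS <= 0)
    stop("measurement error: record duration must be positive")
  TS <- metadata@durationS
  D <- vessel@DUm
  if (!countTruncated && nrow(events) > 0)
    events <- events[!events$truncated, , drop = FALSE]
  n <- nrow(events)
  if (n == 0L)
    return(new("RecordSummary", nCells = 0L, aveVUmS = NA_real_, DUm = D,
               TS = TS, VMl = NA_real_, concentrationPerMl = 0,
               lowConfidence = TRUE))
  v <- if (velocityExcludesTruncated) events$v_um_s[!events$truncated]
       else events$v_um_s
  lowConf <- FALSE
  if (length(v) == 0L) {      # all events truncated: censored velocities
    v <- events$v_um_s
    lowConf <- TRUE
  }
  aveV <- mean(v)
  V <- sampledBloodVolume(D, aveV, TS)
  new("RecordSummary", nCells = as.integer(n), aveVUmS = aveV, DUm = D,
      TS = TS, VMl = V, concentrationPerMl = cellConcentration(n, V),
      lowConfidence = lowConf)
}

#' One time-course point as a data.frame row
#' @param subjectId subject identifier.
#' @param group group label (e.g. "treated"/"control").
#' @param timeMin time in minutes relative to challenge.
#' @param summary a \linkS4class{RecordSummary}.
#' @return One-row data.frame with the summary fields flattened.
#' @export
timeCoursePoint <- function(subjectId, group, timeMin, summary) {
  data.frame(subject_id = subjectId, group = group, time_min = timeMin,
             n_cells = summary@nCells, ave_v_um_s = summary@aveVUmS,
             D_um = summary@DUm, T_s = summary@TS, V_ml = summary@VMl,
             concentration_per_ml = summary@concentrationPerMl,
             low_confidence = summary@lowConfidence,
             stringsAsFactors = FALSE)
}

#' Assemble per-record summaries into a time course
#'
#' @param points data.frame of rows from \code{\link{timeCoursePoint}} (or
#'   with the same columns).
#' @param scheduleMin declared measurement times in minutes; defaults to the
#'   sorted unique times present.
#' @return A \linkS4class{TimeCourse}.
#' @export
buildTimecourse <- function(points, scheduleMin = sort(unique(points$time_min))) {
  if (anyDuplicated(points[, c("subject_id", "time_min")]))
    stop("data error: duplicate (subject, time) point")
  bad <- !points$time_min %in% scheduleMin
  if (any(bad))
    stop("data error: time(s) outside the declared schedule: ",
         paste(unique(points$time_min[bad]), collapse = ", "))
  new("TimeCourse", points = points, scheduleMin = as.numeric(scheduleMin),
      groups = sort(unique(points$group)))
}

#' Per-(group, time) mean and standard error of concentration
#'
#' @param tc a \linkS4class{TimeCourse}.
#' @return data.frame with group, time_min, n, mean_concentration,
#'   sem_concentration.
#' @export
timecourseMeans <- function(tc) {
  p <- tc@points
  sp <- split(p, list(p$group, p$time_min), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(group = d$group[1], time_min = d$time_min[1], n = nrow(d),
               mean_concentration = mean(d$concentration_per_ml),
               sem_concentration = stats::sd(d$concentration_per_ml) /
                 sqrt(nrow(d)))
  }))
  out <- out[order(out$group, out$time_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-timepoint fold change between two groups
#'
#' Fold change is the treated-group mean concentration divided by the
#' control-group mean at the same timepoint.
#'
#' @param tc a \linkS4class{TimeCourse}.
#' @param treated,control group labels.
#' @return data.frame with time_min and fold_change.
#' @export
foldChange <- function(tc, treated, control) {
  m <- timecourseMeans(tc)
  out <- do.call(rbind, lapply(tc@scheduleMin, function(tm) {
    a <- m$mean_concentration[m$group == treated & m$time_min == tm]
    b <- m$mean_concentration[m$group == control & m$time_min == tm]
    if (length(a) != 1 || length(b) != 1) return(NULL)
    data.frame(time_min = tm, fold_change = a / b)
  }))
  rownames(out) <- NULL
  out
}

#' Per-timepoint unpaired t-tests between two groups
#'
#' @param tc a \linkS4class{TimeCourse}.
#' @param groupA,groupB group labels.
#' @param welch use the Welch (unequal-variance) variant; default FALSE
#'   (pooled-variance Student test).
#' @return data.frame with time_min, t, df, p.
#' @export
timecourseTTests <- function(tc, groupA, groupB, welch = FALSE) {
  p <- tc@points
  out <- do.call(rbind, lapply(tc@scheduleMin, function(tm) {
    a <- p$concentration_per_ml[p$group == groupA & p$time_min == tm]
    b <- p$concentration_per_ml[p$group == groupB & p$time_min == tm]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    tt <- unpairedTTest(a, b, welch = welch)
    data.frame(time_min = tm, t = tt$t, df = tt$df, p = tt$p)
  }))
  rownames(out) <- NULL
  out
}

#' Write a time course as CSV
#' @param tc a \linkS4class{TimeCourse}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTimecourseCsv <- function(tc, path) {
  utils::write.csv(tc@points, path, row.names = FALSE)
  invisible(path)
}
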