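# Readers/writers for kymograph TIFFs, scan metadata (native JSON or
# PrairieView-style XML) and the tabular outputs (event CSV, summary JSON).

.tiffScale <- function(path) {
  info <- suppressWarnings(tiff::readTIFF(path, payload = FALSE, all = TRUE))
  bps <- info$bits.per.sample[1]
  # integer TIFFs are normalized to [0,1] on read; floats come back as-is
  if (bps >= 32) 1 else 2^bps - 1
}

#' Read a kymograph image with its scan metadata
#'
#' Accepts multi-page grayscale TIFFs (one page per channel), single-page
#' multi-sample TIFFs, or RGBA/RGB composites. Composites are split by the
#' color convention in \code{rgbaMap}: by default the reporter channel is the
#' green plane and the vessel-dye channel is the per-pixel max of the red and
#' blue planes (magenta rendering). Integer TIFFs are returned on their
#' native integer scale.
#'
#' @param imagePath path to the TIFF.
#' @param metadataPath path to the sidecar metadata (JSON or XML), or a
#'   \linkS4class{ScanMetadata} object.
#' @param rgbaMap named list mapping channel names to composite planes
#'   ("R","G","B"); multiple planes are combined by per-pixel max.
#' @param orientation "time-major" (rows are scan lines, the canonical
#'   layout) or "transpose" (input stored position-major, transposed on read).
#' @param channels optional channel names overriding the metadata's.
#' @return A \linkS4class{Kymograph}.
#' @export
readKymograph <- function(imagePath, metadataPath,
                          rgbaMap = list(reporter = "G", vessel = c("R", "B")),
                          orientation = c("time-major", "transpose"),
                          channels = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(imagePath))
    stop("I/O error: image file not found: ", imagePath)
  md <- if (is(metadataPath, "ScanMetadata")) metadataPath
        else parseScanMetadata(metadataPath)@resolved
  if (!is.null(channels)) md@channelNames <- as.character(channels)

  scale <- .tiffScale(imagePath)
  pages <- suppressWarnings(tiff::readTIFF(imagePath, all = TRUE))
  planes <- list()
  if (length(pages) > 1) {
    for (p in pages) {
      if (!is.matrix(p))
        stop("format error: multi-page TIFF must have grayscale pages")
      planes[[length(planes) + 1]] <- p * scale
    }
    names(planes) <- md@channelNames[seq_along(planes)]
  } else {
    p <- pages[[1]]
    if (is.matrix(p)) {
      planes <- list(p * scale)
      names(planes) <- md@channelNames[1]
    } else if (length(dim(p)) == 3 && dim(p)[3] %in% c(3L, 4L)) {
      rgb <- list(R = p[, , 1] * scale, G = p[, , 2] * scale,
                  B = p[, , 3] * scale)
      for (ch in names(rgbaMap)) {
        sel <- rgb[rgbaMap[[ch]]]
        planes[[ch]] <- Reduce(pmax, sel)
      }
    } else if (length(dim(p)) == 3) {
      for (i in seq_len(dim(p)[3])) planes[[i]] <- p[, , i] * scale
      names(planes) <- md@channelNames[seq_along(planes)]
    } else stop("format error: unsupported TIFF layout")
  }

  if (orientation == "transpose") planes <- lapply(planes, t)

  # order planes as the metadata declares
  if (!all(md@channelNames %in% names(planes)))
    stop("format error: channels in image (",
         paste(names(planes), collapse = ", "),
         ") do not cover metadata channels (",
         paste(md@channelNames, collapse = ", "), ")")
  planes <- planes[md@channelNames]

  d <- dim(planes[[1]])
  if (d[1] != md@nLines || d[2] != md@nPixels)
    stop("format error: image is ", d[1], " x ", d[2],
         " but metadata declares ", md@nLines, " x ", md@nPixels)
  arr <- array(unlist(planes, use.names = FALSE),
               dim = c(d[1], d[2], length(planes)))
  if (anyNA(arr) || min(arr) < 0)
    stop("data error: negative or NaN pixel intensities")
  Kymograph(arr, md)
}

#' Write a kymograph as a multi-page grayscale TIFF
#'
#' One 16-bit page per channel; intensities must be integers in
#' [0, 65535] so that write/read round-trips are exact.
#'
#' @param kymo a \linkS4class{Kymograph}.
#' @param imagePath output TIFF path.
#' @param metadataPath optional path for a native-JSON metadata sidecar.
#' @return \code{imagePath}, invisibly.
#' @export
writeKymograph <- function(kymo, imagePath, metadataPath = NULL) {
  mx <- 65535
  px <- kymo@pixels
  if (max(px) > mx)
    stop("I/O error: intensities exceed the 16-bit range")
  if (max(abs(px - round(px))) > 0)
    stop("I/O error: intensities must be integer-valued for lossless storage")
  pages <- lapply(seq_len(dim(px)[3]), function(i) px[, , i] / mx)
  tiff::writeTIFF(pages, imagePath, bits.per.sample = 16L, reduce = FALSE)
  if (!is.null(metadataPath)) writeScanMetadataJson(kymo@metadata, metadataPath)
  invisible(imagePath)
}

#' Parse a scan-metadata sidecar file
#'
#' Native dialect is JSON with keys \code{scan_rate_hz}, \code{pixel_size_um},
#' \code{n_lines}, \code{n_pixels}, \code{channels} (and optional
#' \code{duration_s}). PrairieView-style XML is supported as a second
#' dialect: \code{scanLinePeriod} (seconds per line, so scan rate is its
#' reciprocal), \code{micronsPerPixel} (XAxis indexed value),
#' \code{linesPerFrame}, \code{pixelsPerLine}.
#'
#' @param path metadata file (.json or .xml).
#' @param channels channel names to use when the file does not declare any.
#' @return A \linkS4class{MetadataDocument}.
#' @export
parseScanMetadata <- function(path, channels = c("vessel", "reporter")) {
  if (!file.exists(path))
    stop("metadata error: file not found: ", path)
  first <- readChar(path, nchars = 256, useBytes = TRUE)
  isXml <- grepl("^\\s*<", first)
  if (isXml) .parseMetadataXml(path, channels) else .parseMetadataJson(path)
}

.metaNum <- function(raw, key, what = key) {
  v <- raw[[key]]
  if (is.null(v)) stop("metadata error: ", what, " not found (key '", key, "')")
  v <- suppressWarnings(as.numeric(v))
  if (!is.finite(v) || v <= 0)
    stop("metadata error: ", what, " must be a positive number")
  v
}

.parseMetadataJson <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rate <- .metaNum(raw, "scan_rate_hz", "scan rate")
  px <- .metaNum(raw, "pixel_size_um", "pixel size")
  nl <- .metaNum(raw, "n_lines", "line count")
  np <- .metaNum(raw, "n_pixels", "pixels per line")
  ch <- if (!is.null(raw$channels)) as.character(raw$channels)
        else c("vessel", "reporter")
  dur <- if (!is.null(raw$duration_s)) as.numeric(raw$duration_s) else nl / rate
  md <- ScanMetadata(rate, px, nl, np, ch, dur)
  new("MetadataDocument", sourcePath = path, dialect = "native-json",
      raw = as.list(raw), resolved = md)
}

.parseMetadataXml <- function(path, channels) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//PVStateValue")
  raw <- list()
  known <- c("scanLinePeriod", "micronsPerPixel", "linesPerFrame",
             "pixelsPerLine")
  unknown <- character()
  for (nd in nodes) {
    key <- xml2::xml_attr(nd, "key")
    if (is.na(key)) next
    if (key == "micronsPerPixel") {
      iv <- xml2::xml_find_first(nd, ".//IndexedValue[@index='XAxis']")
      raw[[key]] <- if (inherits(iv, "xml_missing")) NULL
                    else xml2::xml_attr(iv, "value")
    } else {
      raw[[key]] <- xml2::xml_attr(nd, "value")
    }
    if (!key %in% known) unknown <- c(unknown, key)
  }
  if (length(unknown))
    message("ignoring unknown metadata keys: ", paste(unknown, collapse = ", "))
  period <- .metaNum(raw, "scanLinePeriod", "scan line period")
  px <- tryCatch(.metaNum(raw, "micronsPerPixel", "pixel size"),
                 error = function(e) stop("metadata error: pixel size not found"))
  nl <- .metaNum(raw, "linesPerFrame", "line count")
  np <- .metaNum(raw, "pixelsPerLine", "pixels per line")
  md <- ScanMetadata(1 / period, px, nl, np, channels)
  new("MetadataDocument", sourcePath = path, dialect = "prairie-xml",
      raw = raw, resolved = md)
}

#' Write scan metadata as native JSON
#' @param metadata a \linkS4class{ScanMetadata}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScanMetadataJson <- function(metadata, path) {
  jsonlite::write_json(list(
    scan_rate_hz = metadata@scanRateHz,
    pixel_size_um = metadata@pixelSizeUm,
    n_lines = metadata@nLines,
    n_pixels = metadata@nPixels,
    channels = metadata@channelNames,
    duration_s = metadata@durationS
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a detected-event table as CSV
#'
#' Columns: record_id, event_id, bounding box (half-open, 0-based), d_um,
#' t_ms, v_um_s, per-channel mean/max intensities, truncated flag. Write and
#' read round-trip values to better than 1e-9 relative.
#'
#' @param events events data.frame as returned by \code{\link{detectCells}}.
#' @param path output CSV path.
#' @param recordId record identifier written into every row.
#' @return \code{path}, invisibly.
#' @export
writeEventsCsv <- function(events, path, recordId = "record") {
  df <- cbind(record_id = rep(recordId, nrow(events)), events)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an event table written by \code{\link{writeEventsCsv}}
#' @param path CSV path.
#' @return data.frame of events (including the record_id column).
#' @export
readEventsCsv <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a record summary as JSON
#' @param summary a \linkS4class{RecordSummary}.
#' @param path output path.
#' @param extra named list of extra fields (e.g. provenance) to embed.
#' @return \code{path}, invisibly.
#' @export
writeSummaryJson <- function(summary, path, extra = list()) {
  out <- c(list(
    n_cells = summary@nCells,
    ave_v_um_s = summary@aveVUmS,
    D_um = summary@DUm,
    T_s = summary@TS,
    V_ml = summary@VMl,
    concentration_per_ml = summary@concentrationPerMl,
    low_confidence = summary@lowConfidence
  ), extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a record summary written by \code{\link{writeSummaryJson}}
#' @param path JSON path.
#' @return A \linkS4class{RecordSummary}.
#' @export
readSummaryJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  new("RecordSummary",
      nCells = as.integer(x$n_cells),
      aveVUmS = num(x$ave_v_um_s),
      DUm = num(x$D_um), TS = num(x$T_s), VMl = num(x$V_ml),
      concentrationPerMl = num(x$concentration_per_ml),
      lowConfidence = isTRUE(x$low_confidence))
}
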