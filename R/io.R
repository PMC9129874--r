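#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Frames-first (frames, y, x) stacks are stored as 32-bit pages, affinely
#' mapped to [0, 1]; the mapping (\code{offset}, \code{scale}) and the
#' acquisition metadata (\code{dt}, \code{pixel_size}) go into a
#' \code{<path>.json} sidecar. The 32-bit quantization resolves about 2e-10
#' of the stored range (finer than single-precision float), and a second
#' write/read cycle is bit-identical.
#'
#' @param stack (frames, y, x) numeric array.
#' @param path output TIFF path.
#' @param dt frame interval (s); default from the stack attribute.
#' @param pixelSize um/px; default from the stack attribute.
#' @param offset,scale affine storage mapping; by default the stack range.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, dt = attr(stack, "dt"),
                       pixelSize = attr(stack, "pixel_size"),
                       offset = NULL, scale = NULL) {
  if (length(dim(stack)) != 3) stop("stack must be a (frames, y, x) array")
  if (is.null(dt)) stop("metadata missing: 'dt' (frame interval in s)")
  if (is.null(pixelSize)) stop("metadata missing: 'pixel_size' (um/px)")
  if (is.null(offset)) offset <- min(stack)
  if (is.null(scale)) {
    scale <- max(stack) - offset
    if (scale <= 0) scale <- 1
  }
  v <- (stack - offset) / scale
  v <- pmin(pmax(v, 0), 1)
  pages <- lapply(seq_len(dim(stack)[1]), function(f) v[f, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(dt = dt, pixel_size = pixelSize, offset = offset, scale = scale,
         frames = dim(stack)[1]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack and its JSON sidecar
#'
#' @param path TIFF path written by [writeStack()] (or any frames-first
#'   TIFF with a sidecar carrying at least \code{dt} and
#'   \code{pixel_size}).
#' @return (frames, y, x) array with attributes \code{dt} and
#'   \code{pixel_size}.
#' @export
readStack <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("metadata sidecar not found: ", side,
         " (must provide keys 'dt' and 'pixel_size')")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (key in c("dt", "pixel_size")) {
    if (is.null(meta[[key]]))
      stop("metadata sidecar is missing required key '", key, "'")
  }
  offset <- if (is.null(meta$offset)) 0 else meta$offset
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  stack <- array(NA_real_, c(length(pages), ny, nx))
  for (f in seq_along(pages)) stack[f, , ] <- pages[[f]] * scale + offset
  attr(stack, "dt") <- meta$dt
  attr(stack, "pixel_size") <- meta$pixel_size
  stack
}

#' Read/write a fluorescence trace as CSV
#'
#' CSV columns \code{time_s, value}; sampling must be uniform.
#'
#' @param trace a [FluorTrace].
#' @param path CSV file path.
#' @return [readTraceCsv()] returns a [FluorTrace]; [writeTraceCsv()]
#'   returns \code{path} invisibly.
#' @export
writeTraceCsv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = traceTimes(trace),
                              value = trace@values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("trace CSV must have columns time_s, value")
  dts <- diff(df$time_s)
  if (length(dts) < 1) stop("trace CSV needs at least 2 samples")
  if (diff(range(dts)) > 1e-6 * mean(dts))
    stop("trace CSV is not uniformly sampled")
  FluorTrace(values = df$value, dt = mean(dts), t0 = df$time_s[1])
}

#' Read/write event lists as CSV
#'
#' @param eventList an [EventList].
#' @param path CSV file path.
#' @return [readEventsCsv()] returns an [EventList]; the writer returns
#'   \code{path} invisibly.
#' @export
writeEventsCsv <- function(eventList, path) {
  utils::write.csv(events(eventList), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsCsv
#' @export
readEventsCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "amplitude", "kind", "synapse_id")
  if (!all(need %in% names(df)))
    stop("events CSV must have columns ", paste(need, collapse = ", "))
  EventList(events = df)
}

#' Read/write FRAP triplets as CSV
#'
#' CSV columns \code{time_s, roi, reference, background}; the index of the
#' first post-bleach sample travels in a \code{<path>.json} sidecar (key
#' \code{bleach_end}) or is passed explicitly.
#'
#' @param curve a [FRAPCurve].
#' @param path CSV file path.
#' @param bleachEnd first post-bleach sample index (overrides the sidecar).
#' @return [readFrapCsv()] returns a [FRAPCurve]; the writer returns
#'   \code{path} invisibly.
#' @export
writeFrapCsv <- function(curve, path) {
  utils::write.csv(data.frame(time_s = curve@times, roi = curve@roiRaw,
                              reference = curve@refRaw,
                              background = curve@bgRaw),
                   path, row.names = FALSE)
  jsonlite::write_json(list(bleach_end = curve@bleachEnd),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFrapCsv
#' @export
readFrapCsv <- function(path, bleachEnd = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "roi", "reference", "background")
  if (!all(need %in% names(df)))
    stop("FRAP CSV must have columns ", paste(need, collapse = ", "))
  if (is.null(bleachEnd)) {
    side <- paste0(path, ".json")
    if (!file.exists(side))
      stop("bleachEnd not given and sidecar not found: ", side)
    bleachEnd <- jsonlite::read_json(side)$bleach_end
    if (is.null(bleachEnd)) stop("sidecar is missing required key 'bleach_end'")
  }
  FRAPCurve(times = df$time_s, roiRaw = df$roi, refRaw = df$reference,
            bgRaw = df$background, bleachEnd = as.integer(bleachEnd))
}

#' Read/write localization point patterns as CSV
#'
#' CSV columns \code{x_nm, y_nm} (plus optional \code{mark}).
#'
#' @param pattern a [PointPattern].
#' @param path CSV file path.
#' @param field field size (nm); inferred as the points' bounding box when
#'   absent.
#' @return [readPointsCsv()] returns a [PointPattern]; the writer returns
#'   \code{path} invisibly.
#' @export
writePointsCsv <- function(pattern, path) {
  utils::write.csv(as.data.frame(pattern), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePointsCsv
#' @export
readPointsCsv <- function(path, field = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("x_nm", "y_nm") %in% names(df)))
    stop("points CSV must have columns x_nm, y_nm")
  if (is.null(field)) field <- c(max(df$x_nm), max(df$y_nm))
  PointPattern(points = cbind(df$x_nm, df$y_nm), field = as.numeric(field),
               marks = if ("mark" %in% names(df)) as.integer(df$mark)
                       else integer(0))
}

#' Read a bleaching protocol from YAML
#'
#' The YAML file holds an ordered list of segments, each with keys
#' \code{duration}, \code{intensity}, and optional \code{stim_rate} and
#' \code{glutamate_perfusion}.
#'
#' @param path YAML file.
#' @return a [BleachProtocol].
#' @export
readBleachProtocolYaml <- function(path) {
  y <- yaml::read_yaml(path)
  segs <- if (!is.null(y$segments)) y$segments else y
  rows <- lapply(segs, function(s) {
    if (is.null(s$duration) || is.null(s$intensity))
      stop("each protocol segment needs 'duration' and 'intensity'")
    bleachSegment(s$duration, s$intensity,
                  stimRate = if (is.null(s$stim_rate)) 0 else s$stim_rate,
                  glutamatePerfusion = isTRUE(s$glutamate_perfusion))
  })
  BleachProtocol(segments = do.call(rbind, rows))
}
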