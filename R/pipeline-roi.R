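#' Locate synaptic ROIs from a stimulation-interval projection
#'
#' Sums the frames acquired during high-frequency stimulation (or KCl
#' depolarization), finds strict local fluorescence maxima above a
#' robust prominence threshold, and greedily prunes them so that centers
#' are at least \code{minSeparation} apart (highest peak wins). Circular
#' ROIs of the given diameter are centered on the surviving maxima.
#'
#' @param stack (frames, y, x) array, e.g. from [generateMovie()] or
#'   [readStack()].
#' @param stimFrames frame indices to sum over.
#' @param diameter ROI diameter (um).
#' @param minSeparation minimum center separation (um).
#' @param pixelSize um per pixel; taken from the stack's
#'   \code{pixel_size} attribute when NULL.
#' @param prominence threshold in robust SDs of the summed image above its
#'   median; maxima below it are ignored.
#' @return an [ROISet]; empty (with a warning) for a flat image.
#' @export
findROIs <- function(stack, stimFrames = seq_len(dim(stack)[1]), diameter = 2,
                     minSeparation = 2, pixelSize = NULL, prominence = 5) {
  if (length(dim(stack)) != 3) stop("stack must be a (frames, y, x) array")
  if (any(stimFrames < 1 | stimFrames > dim(stack)[1]))
    stop("stimFrames outside the stack")
  if (is.null(pixelSize)) pixelSize <- attr(stack, "pixel_size")
  if (is.null(pixelSize)) stop("pixelSize missing: pass it or set the 'pixel_size' attribute")

  img <- apply(stack[stimFrames, , , drop = FALSE], c(2, 3), sum)
  ny <- nrow(img); nx <- ncol(img)
  scale <- stats::mad(img)
  if (scale == 0 && stats::sd(img) == 0) {
    warning("flat image: no ROIs found")
    return(ROISet(centers = matrix(numeric(0), ncol = 2), diameter = diameter))
  }
  thr <- stats::median(img) + prominence * scale

  # strict 8-neighbor local maxima (interior pixels only)
  isMax <- matrix(FALSE, ny, nx)
  ii <- 2:(ny - 1); jj <- 2:(nx - 1)
  ctr <- img[ii, jj]
  isMax[ii, jj] <- ctr > img[ii - 1, jj] & ctr > img[ii + 1, jj] &
    ctr > img[ii, jj - 1] & ctr > img[ii, jj + 1] &
    ctr > img[ii - 1, jj - 1] & ctr > img[ii - 1, jj + 1] &
    ctr > img[ii + 1, jj - 1] & ctr > img[ii + 1, jj + 1] &
    ctr >= thr
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("no local maxima above prominence threshold")
    return(ROISet(centers = matrix(numeric(0), ncol = 2), diameter = diameter))
  }
  vals <- img[idx]
  ord <- order(vals, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  cx <- (idx[, 2] - 0.5) * pixelSize
  cy <- (idx[, 1] - 0.5) * pixelSize
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cx[i] - cx[keep])^2 + (cy[i] - cy[keep])^2
    if (all(d2 >= minSeparation^2)) keep[i] <- TRUE
  }
  ROISet(centers = cbind(x = cx[keep], y = cy[keep]), diameter = diameter)
}

#' Extract the mean-intensity trace of one circular ROI
#'
#' Averages, per frame, the pixels whose centers lie within
#' \code{diameter/2} of the ROI center.
#'
#' @param stack (frames, y, x) array with \code{dt} and \code{pixel_size}
#'   attributes (or pass them explicitly).
#' @param roi an [ROISet].
#' @param which which ROI of the set to extract.
#' @param dt,pixelSize overrides for the stack attributes.
#' @return a [FluorTrace].
#' @export
extractTrace <- function(stack, roi, which = 1L, dt = NULL, pixelSize = NULL) {
  if (length(dim(stack)) != 3) stop("stack must be a (frames, y, x) array")
  if (is.null(dt)) dt <- attr(stack, "dt")
  if (is.null(pixelSize)) pixelSize <- attr(stack, "pixel_size")
  if (is.null(dt) || is.null(pixelSize))
    stop("stack metadata missing: need 'dt' and 'pixel_size'")
  ctr <- roi@centers[which, ]
  ny <- dim(stack)[2]; nx <- dim(stack)[3]
  W <- nx * pixelSize; H <- ny * pixelSize
  if (ctr[1] < 0 || ctr[1] > W || ctr[2] < 0 || ctr[2] > H)
    stop("ROI center outside the image")
  xc <- (seq_len(nx) - 0.5) * pixelSize
  yc <- (seq_len(ny) - 0.5) * pixelSize
  inside <- outer(yc, xc, function(y, x)
    (x - ctr[1])^2 + (y - ctr[2])^2 <= (roi@diameter / 2)^2)
  if (!any(inside)) stop("ROI contains no pixel centers")
  flat <- matrix(stack, dim(stack)[1], ny * nx)
  FluorTrace(values = rowMeans(flat[, as.vector(inside), drop = FALSE]),
             dt = dt, t0 = 0)
}
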