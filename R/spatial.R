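#' Density-based clustering (DBSCAN) of a point pattern
#'
#' Classic DBSCAN: core points have at least \code{minPts} neighbors within
#' \code{eps} (counting themselves); clusters are maximal density-connected
#' sets of core points plus their border points. Border points reachable
#' from several clusters join the first claiming cluster in deterministic
#' input order, fixing DBSCAN's known border ambiguity for
#' reproducibility.
#'
#' @param pattern a [PointPattern] or an n x 2 coordinate matrix (nm).
#' @param eps neighborhood radius (nm), > 0.
#' @param minPts minimum neighborhood size for a core point, >= 1.
#' @return integer vector of cluster labels (1, 2, ...), with -1 marking
#'   noise points.
#' @examples
#' pp <- generatePointPattern(2, 20, 15, 0, field = c(2000, 2000), seed = 3)
#' table(dbscanCluster(pp, eps = 60, minPts = 4))
#' @export
dbscanCluster <- function(pattern, eps, minPts) {
  pts <- if (is(pattern, "PointPattern")) pattern@points else as.matrix(pattern)
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0")
  if (minPts < 1) stop("minPts must be >= 1")
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  d2 <- as.matrix(stats::dist(pts))^2
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  core <- lengths(nb) >= minPts
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (is.na(labels[j])) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][is.na(labels[nb[[j]]])])
      } else if (labels[j] == -1L) {
        labels[j] <- cl  # previously noise-labeled border point
      }
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}

#' Geometric center of one cluster
#'
#' @param pattern a [PointPattern] or coordinate matrix.
#' @param labels labels from [dbscanCluster()].
#' @param clusterId which cluster.
#' @return length-2 numeric (x, y) centroid (nm).
#' @export
clusterCenter <- function(pattern, labels, clusterId) {
  pts <- if (is(pattern, "PointPattern")) pattern@points else as.matrix(pattern)
  member <- labels == clusterId
  if (!any(member)) stop("cluster ", clusterId, " is empty")
  colMeans(pts[member, , drop = FALSE])
}

#' Centers of all detected clusters
#'
#' @inheritParams clusterCenter
#' @return k x 2 matrix of centroids, one row per cluster id in order.
#' @export
clusterCenters <- function(pattern, labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(matrix(numeric(0), ncol = 2))
  t(vapply(ids, function(id) clusterCenter(pattern, labels, id), numeric(2)))
}

# Area of a circle of radius r centered at (cx, cy) intersected with the
# rectangle [0, W] x [0, H]. Exact for circles fully inside/outside; clipped
# cases use adaptive quadrature of the chord length (abs. tol ~1e-10 of the
# circle area).
circleRectArea <- function(cx, cy, r, W, H) {
  if (r <= 0) return(0)
  if (cx - r >= 0 && cx + r <= W && cy - r >= 0 && cy + r <= H)
    return(pi * r^2)
  if (cx + r <= 0 || cx - r >= W || cy + r <= 0 || cy - r >= H) return(0)
  y1 <- -cy; y2 <- H - cy
  f <- function(x) {
    s <- sqrt(pmax(0, r^2 - x^2))
    pmax(0, pmin(y2, s) - pmax(y1, -s))
  }
  lo <- max(-r, -cx); hi <- min(r, W - cx)
  if (hi <= lo) return(0)
  # split at the kinks where the chord meets the horizontal clip lines
  brk <- c(y1, y2)
  brk <- sqrt(pmax(0, r^2 - brk[abs(brk) < r]^2))
  cuts <- sort(unique(pmin(hi, pmax(lo, c(lo, hi, brk, -brk)))))
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    a <- cuts[i]; b <- cuts[i + 1L]
    if (b - a < 1e-12 * r) next
    piece <- tryCatch(
      stats::integrate(f, a, b, subdivisions = 400L, rel.tol = 1e-9,
                       abs.tol = 1e-9 * pi * r^2)$value,
      error = function(e) {
        xm <- a + (b - a) * (seq_len(2000L) - 0.5) / 2000L
        sum(f(xm)) * (b - a) / 2000L
      })
    total <- total + piece
  }
  total
}

#' Center-referenced pair-correlation function g(r)
#'
#' For each annulus \code{[r_k, r_k+1)} around each reference center,
#' counts the localizations falling inside and divides by the annulus area
#' clipped to the field boundary; normalizing by the pattern's mean density
#' gives \deqn{g_k = \frac{\sum_c N_{k,c} / \sum_c A_{k,c}}{\lambda},}
#' the clipped-area-weighted average over centers. Under complete spatial
#' randomness every bin has expectation 1; clustering around the reference
#' centers produces g > 1 at small radii.
#'
#' @param pattern a [PointPattern].
#' @param centers reference centers: k x 2 matrix (nm), e.g. DBSCAN cluster
#'   centroids.
#' @param binEdges increasing annulus edges (nm); default 10 nm rings out
#'   to 500 nm.
#' @return data.frame with columns \code{r_lo}, \code{r_hi}, \code{g},
#'   \code{count}.
#' @export
pairCorrelation <- function(pattern, centers, binEdges = seq(0, 500, by = 10)) {
  validObject(pattern)
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (nrow(centers) == 0) stop("need at least one reference center")
  if (any(diff(binEdges) <= 0)) stop("binEdges must be strictly increasing")
  W <- pattern@field[1]; H <- pattern@field[2]
  if (any(centers[, 1] < 0 | centers[, 1] > W |
          centers[, 2] < 0 | centers[, 2] > H))
    stop("all centers must lie within the field")
  pts <- pattern@points
  n <- nrow(pts)
  lambda <- n / (W * H)
  if (lambda == 0) stop("empty point pattern")
  nBin <- length(binEdges) - 1L

  counts <- matrix(0, nrow(centers), nBin)
  areas <- matrix(0, nrow(centers), nBin)
  for (c_i in seq_len(nrow(centers))) {
    r <- sqrt((pts[, 1] - centers[c_i, 1])^2 + (pts[, 2] - centers[c_i, 2])^2)
    counts[c_i, ] <- tabulate(findInterval(r, binEdges,
                                           rightmost.closed = FALSE,
                                           left.open = FALSE), nBin)[seq_len(nBin)]
    discs <- vapply(binEdges, function(rr)
      circleRectArea(centers[c_i, 1], centers[c_i, 2], rr, W, H), numeric(1))
    areas[c_i, ] <- diff(discs)
  }
  A <- colSums(areas)
  if (any(A <= 0)) stop("zero-area annulus bin; shrink binEdges to the field")
  data.frame(r_lo = binEdges[-length(binEdges)], r_hi = binEdges[-1],
             g = (colSums(counts) / A) / lambda,
             count = colSums(counts))
}
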