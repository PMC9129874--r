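#' Simulate a clustered (Thomas-process) localization pattern
#'
#' Cluster parents are uniform in the field; each contributes
#' \code{ptsPerCluster} offspring displaced by isotropic Gaussian noise of
#' SD \code{clusterSigma}. Background points are uniform, so
#' \code{nClusters = 0} yields the complete-spatial-randomness (CSR)
#' control. Offspring falling outside the field are clamped to its boundary
#' so the pattern count is exact.
#'
#' @param nClusters number of cluster parents.
#' @param ptsPerCluster offspring per cluster.
#' @param clusterSigma Gaussian cluster spread (nm); 0 puts every offspring
#'   on its parent.
#' @param nBackground uniform background points.
#' @param field field width and height (nm).
#' @param seed integer seed.
#' @return a [PointPattern]; \code{marks} holds the parent index per point
#'   (-1 for background).
#' @export
generatePointPattern <- function(nClusters, ptsPerCluster, clusterSigma,
                                 nBackground, field = c(2000, 2000),
                                 seed = 1L) {
  if (any(c(nClusters, ptsPerCluster, nBackground) < 0))
    stop("counts must be >= 0")
  if (clusterSigma < 0) stop("clusterSigma must be >= 0")
  if (length(field) != 2 || any(field <= 0)) stop("field must be two positive lengths")
  withSeed(seed, {
    cx <- stats::runif(nClusters, 0, field[1])
    cy <- stats::runif(nClusters, 0, field[2])
    nMem <- nClusters * ptsPerCluster
    if (nMem > 0) {
      px <- rep(cx, each = ptsPerCluster) + stats::rnorm(nMem, 0, clusterSigma)
      py <- rep(cy, each = ptsPerCluster) + stats::rnorm(nMem, 0, clusterSigma)
      marks <- rep(seq_len(nClusters), each = ptsPerCluster)
    } else {
      px <- py <- numeric(0); marks <- integer(0)
    }
    bx <- stats::runif(nBackground, 0, field[1])
    by <- stats::runif(nBackground, 0, field[2])
    pts <- cbind(x = c(px, bx), y = c(py, by))
    pts[, 1] <- pmin(pmax(pts[, 1], 0), field[1])
    pts[, 2] <- pmin(pmax(pts[, 2], 0), field[2])
    PointPattern(points = pts, field = as.numeric(field),
                 marks = as.integer(c(marks, rep(-1L, nBackground))))
  })
}
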