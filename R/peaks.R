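# ODF peak extraction with the two rejection rules: a peak is dropped when
# it lies within the minimum separation of a larger peak (45 degrees by
# default) or when its value falls below the relative threshold (0.25) of
# the maximum of the ODF over the whole sampled sphere.

#' Find and refine ODF peaks
#'
#' Candidate peaks are strict local maxima of the (negativity-clipped,
#' antipodally symmetrised) ODF over the sampling sphere's vertex adjacency
#' graph, localised at the discrete vertex. Candidates are retained
#' greedily in descending value order (ties broken by vertex index),
#' rejecting any candidate closer than \code{minSeparationDeg} to an
#' already-retained larger peak (angles modulo antipodal symmetry) or with
#' value below \code{relThreshold} times the ODF maximum.
#'
#' @param odf numeric vector: either SH coefficients of one ODF, or values
#'   at the sphere vertices (recognised by length).
#' @param sphere sampling sphere from \code{\link{unitSphere}}.
#' @param minSeparationDeg minimum angular separation (degrees).
#' @param relThreshold relative value threshold against the ODF maximum.
#' @param k maximum number of peaks.
#' @return a \linkS4class{PeakSet}; empty when the ODF has no strict local
#'   maximum (e.g. a constant ODF).
#' @export
findPeaks <- function(odf, sphere = unitSphere(), minSeparationDeg = 45,
                      relThreshold = 0.25, k = 3L) {
  nv <- nrow(sphere$vertices)
  vals <- if (length(odf) == nv) odf else odfValues(odf, sphere = sphere)
  vals <- pmax(vals, 0)
  vals <- (vals + vals[sphere$antipode]) / 2
  mx <- max(vals)
  if (mx <= 0) return(peakSet())
  nbr <- sphere$neighbors
  nbrMax <- rep(-Inf, nv)
  for (j in seq_len(ncol(nbr))) {
    nj <- nbr[, j]
    v <- vals[nj]
    v[is.na(nj)] <- -Inf
    nbrMax <- pmax(nbrMax, v)
  }
  isMax <- vals > nbrMax & sphere$upper
  cand <- which(isMax)
  if (!length(cand)) return(peakSet())
  cand <- cand[order(-vals[cand], cand)]
  cosSep <- cos(minSeparationDeg * pi / 180)
  keptIdx <- integer()
  for (ci in cand) {
    if (length(keptIdx) >= k) break
    if (vals[ci] < relThreshold * mx) next
    if (length(keptIdx)) {
      d <- abs(sphere$vertices[keptIdx, , drop = FALSE] %*% sphere$vertices[ci, ])
      if (any(d > cosSep)) next
    }
    keptIdx <- c(keptIdx, ci)
  }
  peakSet(sphere$vertices[keptIdx, , drop = FALSE], vals[keptIdx])
}
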