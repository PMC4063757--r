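# Real symmetric spherical-harmonic basis.
#
# Basis convention (tag "rsh-even-orthonormal-v1"): real, orthonormal on the
# sphere, even orders only, Condon-Shortley phase inside the associated
# Legendre functions (pracma::legendre, MATLAB-compatible). Column ordering
# is fixed: l = 0, 2, ..., L and within each l, m = -l, ..., l.
#   m < 0: sqrt(2) N_l^|m| P_l^|m|(cos theta) sin(|m| phi)
#   m = 0:         N_l^0  P_l^0 (cos theta)
#   m > 0: sqrt(2) N_l^m  P_l^m (cos theta) cos(m phi)
# with N_l^m = sqrt((2l+1)/(4 pi) * (l-m)!/(l+m)!).

.shBasisTag <- "rsh-even-orthonormal-v1"

# (l, m) index table for even orders up to L
shIndexTable <- function(L) {
  ls <- seq(0L, L, by = 2L)
  do.call(rbind, lapply(ls, function(l) cbind(l = l, m = seq(-l, l))))
}

#' Evaluate the real symmetric SH basis at unit directions
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @param L maximum (even) SH order.
#' @return n x (L+1)(L+2)/2 basis matrix; attribute \code{lm} holds the
#'   (l, m) column table and \code{basis} the convention tag.
#' @export
realSphericalHarmonics <- function(dirs, L = 4L) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, 1L, 3L)
  if (L %% 2L != 0L) stop("L must be even")
  ct <- pmin(pmax(dirs[, 3L], -1), 1)
  phi <- atan2(dirs[, 2L], dirs[, 1L])
  lm <- shIndexTable(L)
  out <- matrix(0, nrow(dirs), nrow(lm))
  for (l in seq(0L, L, by = 2L)) {
    P <- pracma::legendre(l, ct)           # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, 1L)
    for (m in seq(-l, l)) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      col <- which(lm[, "l"] == l & lm[, "m"] == m)
      if (m < 0) {
        out[, col] <- sqrt(2) * N * P[am + 1L, ] * sin(am * phi)
      } else if (m == 0) {
        out[, col] <- N * P[1L, ]
      } else {
        out[, col] <- sqrt(2) * N * P[am + 1L, ] * cos(am * phi)
      }
    }
  }
  attr(out, "lm") <- lm
  attr(out, "basis") <- .shBasisTag
  out
}

#' Build the SH design matrix for a gradient table
#'
#' Rows are the diffusion-weighted (non-b0) gradient directions; columns the
#' real symmetric SH basis functions of even orders up to \code{L} in the
#' fixed (l, m) ordering documented in \code{\link{realSphericalHarmonics}}.
#'
#' @param gtab a \linkS4class{GradientTable}.
#' @param L maximum (even) SH order (default 4, 15 coefficients).
#' @return design matrix with attributes \code{lm} and \code{basis}.
#' @export
shDesignMatrix <- function(gtab, L = 4L) {
  dirs <- gtab@bvecs[!b0Mask(gtab), , drop = FALSE]
  ncoef <- (L + 1) * (L + 2) / 2
  if (nrow(dirs) < ncoef)
    stop(sprintf(
      "underdetermined SH fit: %d directions for %d coefficients (L = %d)",
      nrow(dirs), ncoef, L))
  realSphericalHarmonics(dirs, L)
}
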