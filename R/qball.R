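# Constant-solid-angle q-ball reconstruction: SH fit of the double-log
# transformed attenuation, per-harmonic CSA transform, and tensor-derived FA.

# cache sphere-basis matrices per (sphere level, L)
.sphereBasis <- function(sphere, L) {
  key <- sprintf("basis-%d-%d", sphere$level, L)
  b <- .sphereCache[[key]]
  if (is.null(b)) {
    b <- realSphericalHarmonics(sphere$vertices, L)
    .sphereCache[[key]] <- b
  }
  b
}

#' Fit the transformed diffusion signal with spherical harmonics
#'
#' Per voxel, the attenuation E = S/S0 at the diffusion-weighted directions
#' is clamped to [epsilon, 1 - epsilon] and the double-log transform
#' ln(-ln E) is least-squares fit in the real symmetric even-order SH basis.
#' Fitted values, residuals and the hat-matrix diagonal are retained so the
#' residual bootstrap can resample the fit without re-reading the data.
#'
#' @param dwi a \linkS4class{DWIVolume}.
#' @param L maximum (even) SH order (default 4).
#' @param mask optional 3D logical array restricting the fit; voxels with
#'   non-positive or non-finite b0 are always excluded.
#' @param epsilon attenuation clamp (default 1e-3).
#' @param lambda optional Laplace-Beltrami regularisation weight (default 0;
#'   55 directions for 15 coefficients is well conditioned without it).
#' @return a \linkS4class{SphHarmFit}.
#' @export
fitSignalSH <- function(dwi, L = 4L, mask = NULL, epsilon = 1e-3,
                        lambda = 0) {
  gtab <- dwi@gtab
  b0 <- b0Mask(gtab)
  d <- dim(dwi@data)
  nvox <- prod(d[1:3])
  sig <- matrix(dwi@data, nvox, d[4L])
  s0 <- if (sum(b0) > 1L) rowMeans(sig[, b0, drop = FALSE]) else sig[, b0]
  valid <- is.finite(s0) & s0 > 0 &
    rowSums(!is.finite(sig) | sig < 0) == 0 &
    rowSums(sig) > 0
  if (!is.null(mask)) valid <- valid & as.logical(mask)
  B <- shDesignMatrix(gtab, L)
  lm <- attr(B, "lm")
  if (lambda > 0) {
    reg <- diag((lm[, "l"] * (lm[, "l"] + 1))^2)
    P <- solve(crossprod(B) + lambda * reg, t(B))
  } else {
    P <- solve(crossprod(B), t(B))
  }
  h <- rowSums(B * t(P))
  E <- sig[valid, !b0, drop = FALSE] / s0[valid]
  E <- pmin(pmax(E, epsilon), 1 - epsilon)
  Y <- log(-log(E))
  C <- Y %*% t(P)
  Fv <- C %*% t(B)
  maskArr <- array(valid, dim = d[1:3])
  new("SphHarmFit", order = as.integer(L), basis = attr(B, "basis"),
      dirs = gtab@bvecs[!b0, , drop = FALSE], design = B, pinv = P,
      hatDiag = h, coeffs = C, fitted = Fv, residuals = Y - Fv,
      mask = maskArr, grid = dwi@grid, epsilon = epsilon)
}

# per-coefficient CSA multipliers for a given (l, m) table: the
# Funk-Radon/Laplace-Beltrami closed form -l(l+1) * 2*pi*P_l(0) / (16*pi^2)
# for l > 0; the l = 0 term is replaced by the normalising constant.
.csaMultipliers <- function(lm) {
  l <- lm[, "l"]
  legendre0 <- function(l) {
    # P_l(0) for even l: (-1)^(l/2) (l-1)!! / l!!
    ifelse(l == 0, 1,
           (-1)^(l / 2) * exp(lgamma(l + 1) - 2 * (l / 2) * log(2) -
                                2 * lgamma(l / 2 + 1)))
  }
  m <- -l * (l + 1) * 2 * pi * legendre0(l) / (16 * pi^2)
  m[l == 0] <- 0
  m
}

#' Constant-solid-angle ODF from an SH signal fit
#'
#' Applies the per-harmonic CSA closed form to the SH coefficients of the
#' double-log transformed attenuation: for l > 0 the ODF coefficient is
#' c_lm * (-l(l+1)) * 2*pi*P_l(0) / (16*pi^2); the l = 0 coefficient is set
#' to 1/sqrt(4*pi) so every ODF integrates to one over the sphere.
#'
#' @param fit a \linkS4class{SphHarmFit} of the transformed signal.
#' @return an \linkS4class{OdfField}.
#' @export
csaOdf <- function(fit) {
  if (fit@basis != .shBasisTag)
    stop("fit uses an unexpected SH basis convention: ", fit@basis)
  lm <- shIndexTable(fit@order)
  mult <- .csaMultipliers(lm)
  co <- sweep(fit@coeffs, 2L, mult, "*")
  co[, 1L] <- 1 / sqrt(4 * pi)
  new("OdfField", coeffs = co, order = fit@order, basis = fit@basis,
      mask = fit@mask, grid = fit@grid)
}

#' Evaluate ODFs on a sampling sphere
#'
#' @param odf an \linkS4class{OdfField}, or a numeric vector of SH
#'   coefficients for a single voxel.
#' @param voxels for a field, integer vector of (masked) voxel row indices
#'   to evaluate; default all.
#' @param sphere a sampling sphere from \code{\link{unitSphere}}.
#' @param clip clip negative values at 0 (used for peak finding; the stored
#'   SH representation is never clipped).
#' @return a matrix (voxels x vertices), or a vector for single-voxel input.
#' @export
odfValues <- function(odf, voxels = NULL, sphere = unitSphere(), clip = FALSE) {
  if (is.numeric(odf) && is.null(dim(odf))) {
    L <- as.integer((sqrt(8 * length(odf) + 1) - 3) / 2)
    v <- drop(.sphereBasis(sphere, L) %*% odf)
    if (clip) v <- pmax(v, 0)
    return(v)
  }
  co <- odf@coeffs
  if (!is.null(voxels)) co <- co[voxels, , drop = FALSE]
  v <- co %*% t(.sphereBasis(sphere, odf@order))
  if (clip) v <- pmax(v, 0)
  v
}

#' Integrate ODFs over the sphere
#'
#' Quadrature over the sampling sphere; with the CSA normalisation the
#' result is 1 for every voxel (up to quadrature error).
#'
#' @inheritParams odfValues
#' @return numeric vector of sphere integrals.
#' @export
odfIntegral <- function(odf, voxels = NULL, sphere = unitSphere()) {
  v <- odfValues(odf, voxels = voxels, sphere = sphere)
  if (is.null(dim(v))) sum(v * sphere$weights)
  else drop(v %*% sphere$weights)
}

# Log-linear least-squares tensor fit; shared by FA and the principal
# direction field used as the single-tensor tracking baseline.
.fitTensor <- function(dwi, mask = NULL) {
  gtab <- dwi@gtab
  b0 <- b0Mask(gtab)
  d <- dim(dwi@data)
  nvox <- prod(d[1:3])
  sig <- matrix(dwi@data, nvox, d[4L])
  s0 <- if (sum(b0) > 1L) rowMeans(sig[, b0, drop = FALSE]) else sig[, b0]
  valid <- is.finite(s0) & s0 > 0 & rowSums(sig <= 0 | !is.finite(sig)) == 0
  if (!is.null(mask)) valid <- valid & as.logical(mask)
  g <- gtab@bvecs[!b0, , drop = FALSE]
  b <- gtab@bvals[!b0]
  if (nrow(g) < 6L) stop("tensor fit needs at least 6 directions")
  X <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
             2 * g[, 2] * g[, 3]) * b
  P <- solve(crossprod(X), t(X))
  Y <- -log(sig[valid, !b0, drop = FALSE] / s0[valid])
  Dm <- Y %*% t(P)   # nvalid x 6: Dxx Dyy Dzz Dxy Dxz Dyz
  ev <- matrix(0, nrow(Dm), 3L)
  pd <- matrix(0, nrow(Dm), 3L)
  for (i in seq_len(nrow(Dm))) {
    D <- matrix(c(Dm[i, 1], Dm[i, 4], Dm[i, 5],
                  Dm[i, 4], Dm[i, 2], Dm[i, 6],
                  Dm[i, 5], Dm[i, 6], Dm[i, 3]), 3L, 3L)
    e <- eigen(D, symmetric = TRUE)
    ev[i, ] <- e$values
    pd[i, ] <- e$vectors[, 1L]
  }
  list(valid = valid, tensor = Dm, evals = ev, pdir = pd, dims = d[1:3])
}

#' Fractional anisotropy from a log-linear tensor fit
#'
#' Unweighted log-linear least-squares tensor fit per voxel; eigenvalues are
#' clipped at zero before the standard normalised-variance FA formula.
#' Voxels with non-positive signal are flagged invalid and get FA 0.
#'
#' @param dwi a \linkS4class{DWIVolume}.
#' @param mask optional 3D logical array restricting the fit.
#' @return a \linkS4class{ScalarVolume} of FA in [0, 1], with a logical
#'   attribute \code{flagged} marking invalid voxels.
#' @export
fitTensorFA <- function(dwi, mask = NULL) {
  ft <- .fitTensor(dwi, mask)
  ev <- pmax(ft$evals, 0)
  mn <- rowMeans(ev)
  num <- rowSums((ev - mn)^2)
  den <- rowSums(ev^2)
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  fa <- pmin(pmax(fa, 0), 1)
  vol <- array(0, ft$dims)
  vol[ft$valid] <- fa
  out <- scalarVolume(vol, dwi@grid)
  attr(out, "flagged") <- array(!ft$valid, ft$dims)
  out
}

#' Principal diffusion direction field
#'
#' Per-voxel principal eigenvector of the fitted diffusion tensor; the
#' deterministic single-tensor direction field used as the DTI-style
#' tracking baseline.
#'
#' @inheritParams fitTensorFA
#' @return list with \code{dirs} (nvox x 3 unit vectors in array order,
#'   zero rows for invalid voxels), \code{valid} (logical per voxel) and
#'   \code{grid}.
#' @export
principalDirectionField <- function(dwi, mask = NULL) {
  ft <- .fitTensor(dwi, mask)
  dirs <- matrix(0, prod(ft$dims), 3L)
  dirs[ft$valid, ] <- ft$pdir
  list(dirs = dirs, valid = ft$valid, grid = dwi@grid, dims = ft$dims)
}
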