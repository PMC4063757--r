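# Residual bootstrap of the per-voxel SH fit. Resampling operates on the
# transformed signal ln(-ln E) -- the quantity that is linear in the SH
# basis -- with leverage-corrected residuals r / sqrt(1 - h). Draws are
# keyed by a counter-based RNG (master seed, streamline id, step index) so
# the whole pipeline is reproducible independent of execution order.

# ---- 32-bit counter-based seed derivation (doubles used as u32) ----

.mod32 <- 4294967296

.mulmod32 <- function(a, b) {
  ah <- floor(a / 65536)
  al <- a %% 65536
  (((ah * b) %% .mod32 * 65536) %% .mod32 + al * b) %% .mod32
}

.xorshift32 <- function(x, k) {
  # x XOR (x >> k) on a double-held u32, via 16-bit halves
  y <- floor(x / 2^k)
  xh <- floor(x / 65536); xl <- x %% 65536
  yh <- floor(y / 65536); yl <- y %% 65536
  bitwXor(as.integer(xh), as.integer(yh)) * 65536 +
    bitwXor(as.integer(xl), as.integer(yl))
}

#' Derive a deterministic per-event seed from (master, id, step)
#'
#' Counter-based scheme: a 32-bit mix of the master seed, a streamline (or
#' event) id and a step counter. The result is a valid \code{set.seed}
#' integer and is independent of execution order.
#'
#' @param master master seed (integer).
#' @param id event id, e.g. streamline id.
#' @param step step counter within the event.
#' @return a positive integer seed.
#' @export
counterSeed <- function(master, id, step) {
  x <- master %% .mod32
  x <- (x + .mulmod32(id %% .mod32, 2654435761)) %% .mod32
  x <- (x + .mulmod32(step %% .mod32, 2246822519)) %% .mod32
  x <- .xorshift32(x, 16L)
  x <- .mulmod32(x, 2246822519)
  x <- .xorshift32(x, 13L)
  x <- .mulmod32(x, 3266489917)
  x <- .xorshift32(x, 16L)
  as.integer(x %% 2147483646) + 1L
}

#' Prepare the residual-bootstrap model from an SH fit
#'
#' Applies the leverage correction r_i / sqrt(1 - h_i) to the retained
#' residuals. Directions whose hat-matrix diagonal is >= 1 (degenerate
#' design rows) are dropped from resampling with a warning.
#'
#' @param fit a \linkS4class{SphHarmFit} with retained fit products.
#' @param masterSeed integer master seed for all bootstrap draws.
#' @return a \linkS4class{BootstrapModel}.
#' @export
prepareBootstrap <- function(fit, masterSeed = 1L) {
  h <- fit@hatDiag
  keep <- h < 1 - 1e-12
  if (!all(keep))
    warning(sum(!keep), " degenerate design row(s) dropped from resampling")
  corr <- sweep(fit@residuals, 2L, sqrt(pmax(1 - h, 1e-12)), "/")
  lm <- shIndexTable(fit@order)
  new("BootstrapModel", fit = fit, residCorrected = corr, keep = keep,
      csaMultiplier = .csaMultipliers(lm), masterSeed = as.integer(masterSeed))
}

# masked-row index of a 0-based voxel triplet; NA when outside mask
.maskRow <- function(model, vox) {
  grid <- model@fit@grid
  lin <- voxelLinearIndex(grid, matrix(vox, 1L, 3L))
  m <- model@fit@mask
  if (!m[lin]) return(NA_integer_)
  # row = rank of this voxel among TRUE mask entries in array order
  sum(m[seq_len(lin)])
}

#' Draw one bootstrap ODF for a voxel
#'
#' Resamples the voxel's leverage-corrected residuals with replacement,
#' adds them to the fitted transformed signal, refits the SH coefficients
#' through the cached design pseudo-inverse and applies the CSA transform.
#' Deterministic given \code{(masterSeed, id, step)}.
#'
#' @param model a \linkS4class{BootstrapModel}.
#' @param voxel 0-based voxel triplet, or a single (masked) row index via
#'   \code{row}.
#' @param id,step counters keying the draw (e.g. streamline id and step).
#' @param row optionally, the masked row index directly (skips lookup).
#' @return numeric vector of ODF SH coefficients, or NULL when the voxel is
#'   outside the fitted mask.
#' @export
bootstrapOdf <- function(model, voxel = NULL, id = 0L, step = 0L, row = NULL) {
  if (is.null(row)) row <- .maskRow(model, voxel)
  if (is.na(row)) return(NULL)
  fit <- model@fit
  nd <- ncol(fit@fitted)
  keepIdx <- which(model@keep)
  set.seed(counterSeed(model@masterSeed, id, step))
  pick <- keepIdx[sample.int(length(keepIdx), nd, replace = TRUE)]
  ystar <- fit@fitted[row, ] + model@residCorrected[row, pick]
  cstar <- drop(fit@pinv %*% ystar)
  co <- cstar * model@csaMultiplier
  co[1L] <- 1 / sqrt(4 * pi)
  co
}

#' Bootstrap SH coefficients (signal domain) for one voxel
#'
#' Like \code{\link{bootstrapOdf}} but returns the refit SH coefficients of
#' the transformed signal, without the CSA transform. Used for consistency
#' diagnostics of the resampling scheme.
#'
#' @inheritParams bootstrapOdf
#' @return numeric vector of signal-fit SH coefficients.
#' @export
bootstrapSignalSH <- function(model, voxel = NULL, id = 0L, step = 0L,
                              row = NULL) {
  if (is.null(row)) row <- .maskRow(model, voxel)
  if (is.na(row)) return(NULL)
  fit <- model@fit
  nd <- ncol(fit@fitted)
  keepIdx <- which(model@keep)
  set.seed(counterSeed(model@masterSeed, id, step))
  pick <- keepIdx[sample.int(length(keepIdx), nd, replace = TRUE)]
  drop(fit@pinv %*% (fit@fitted[row, ] + model@residCorrected[row, pick]))
}
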