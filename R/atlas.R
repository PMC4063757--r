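# Group-level products: streamline density maps, binary visitation masks,
# percentage probabilistic maps with thresholded rendering masks, and the
# subject x VOI termination tables with their per-VOI percentage summary.

#' Streamline density map
#'
#' Counts, per voxel, the number of distinct streamlines visiting it: a
#' streamline increments a voxel at most once, with voxel membership by
#' point containment after supersampling every segment at no more than
#' half-voxel spacing.
#'
#' @param tract a \linkS4class{Tractogram}.
#' @param grid target \linkS4class{ImageGrid} (defaults to the
#'   tractogram's).
#' @return a \linkS4class{ScalarVolume} of nonnegative integer counts.
#' @export
densityMap <- function(tract, grid = NULL) {
  if (is.null(grid)) grid <- tract@grid
  counts <- array(0L, grid@dims)
  maxStep <- min(grid@voxelSize) / 2
  for (s in tract@streamlines) {
    seg <- s[-1L, , drop = FALSE] - s[-nrow(s), , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    pts <- list(s[1L, , drop = FALSE])
    for (i in seq_len(nrow(seg))) {
      n <- max(1L, ceiling(len[i] / maxStep))
      tt <- seq_len(n) / n
      pts[[i + 1L]] <- matrix(s[i, ], n, 3L, byrow = TRUE) + outer(tt, seg[i, ])
    }
    vox <- round(worldToVoxel(grid, do.call(rbind, pts)))
    vox <- vox[inGrid(grid, vox), , drop = FALSE]
    lin <- unique(voxelLinearIndex(grid, vox))
    counts[lin] <- counts[lin] + 1L
  }
  scalarVolume(counts, grid)
}

#' Binary visitation mask from a density map
#'
#' All voxels visited by at least one streamline.
#'
#' @param density a density \linkS4class{ScalarVolume}.
#' @return a \linkS4class{ScalarVolume} with values in {0, 1}.
#' @export
binaryMask <- function(density) {
  scalarVolume(array(as.integer(density@values >= 1), density@grid@dims),
               density@grid)
}

#' Group percentage-probability map
#'
#' Sums subjects' binary visitation masks on a common grid and normalises
#' by the number of subjects: the value is the fraction of subjects whose
#' bundle visits the voxel (an exact multiple of 1/n).
#'
#' @param masks list of binary \linkS4class{ScalarVolume}s on one grid.
#' @return a \linkS4class{ScalarVolume} in [0, 1]; attribute
#'   \code{nSubjects}.
#' @export
probabilityMap <- function(masks) {
  if (!length(masks)) stop("need at least one mask")
  g0 <- masks[[1L]]@grid
  for (m in masks) {
    if (!all(m@grid@dims == g0@dims) ||
        max(abs(m@grid@affine - g0@affine)) > 1e-6)
      stop("all masks must share one grid (register upstream)")
  }
  s <- Reduce(`+`, lapply(masks, function(m) m@values))
  out <- scalarVolume(s / length(masks), g0)
  attr(out, "nSubjects") <- length(masks)
  out
}

#' Threshold a probability map
#'
#' Inclusive rule: voxels with value >= \code{level} are kept, so masks are
#' nested under increasing level.
#'
#' @param prob a probability \linkS4class{ScalarVolume}.
#' @param level threshold in (0, 1]; default 0.20, the rendering threshold
#'   used for the group maps.
#' @return a binary \linkS4class{ScalarVolume}.
#' @export
thresholdMap <- function(prob, level = 0.20) {
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  scalarVolume(array(as.integer(prob@values >= level), prob@grid@dims),
               prob@grid)
}

#' Assemble a termination table from subject rows
#'
#' @param rows list of per-subject rows from
#'   \code{\link{classifyTerminations}} (consistent VOI sets required), or
#'   a 0/1 indicator matrix with column names.
#' @param subjects optional subject ids (default from row attributes).
#' @param flags optional logical matrix marking low-support entries.
#' @return a \linkS4class{TerminationTable}.
#' @export
terminationTable <- function(rows, subjects = NULL, flags = NULL) {
  if (is.matrix(rows)) {
    ind <- rows
    cnt <- matrix(numeric(), 0L, 0L)
  } else {
    voi <- rows[[1L]]$name
    for (r in rows) {
      if (!identical(r$name, voi))
        stop("inconsistent VOI sets across subject rows")
    }
    ind <- do.call(rbind, lapply(rows, function(r) r$indicator))
    cnt <- do.call(rbind, lapply(rows, function(r) r$count))
    colnames(ind) <- colnames(cnt) <- voi
    if (is.null(subjects))
      subjects <- vapply(rows, function(r)
        as.character(attr(r, "subject") %||% NA_character_), character(1L))
  }
  if (is.null(subjects)) subjects <- as.character(seq_len(nrow(ind)))
  if (is.null(flags)) flags <- matrix(logical(), 0L, 0L)
  new("TerminationTable", indicators = ind, counts = cnt,
      flags = flags, subjects = as.character(subjects))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname terminationTable
#' @export
setMethod("indicators", "TerminationTable", function(x) x@indicators)

#' @rdname terminationTable
#' @export
setMethod("voiNames", "TerminationTable", function(x) colnames(x@indicators))

#' Per-VOI percentage summary of a termination table
#'
#' The "% of 1" row: 100 times the column mean of the indicators, exact.
#'
#' @param x a \linkS4class{TerminationTable}.
#' @param format return two-decimal percentage strings ("35.00%") instead
#'   of numbers.
#' @param ... unused.
#' @return named numeric (or character) vector of per-VOI percentages.
#' @export
setMethod("summarizeTerminations", "TerminationTable",
          function(x, format = FALSE, ...) {
  if (!nrow(x@indicators)) stop("empty termination table")
  pct <- 100 * colMeans(x@indicators)
  if (format) setNames(sprintf("%.2f%%", pct), names(pct)) else pct
})

#' Write a termination table as CSV
#'
#' Layout mirrors the published tables: one subject per row, VOI columns,
#' and a final "% of 1" summary row.
#'
#' @param x a \linkS4class{TerminationTable}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeTerminationTable <- function(x, path) {
  df <- data.frame(subject = x@subjects, x@indicators, check.names = FALSE)
  sm <- c(subject = "% of 1",
          setNames(sprintf("%.2f%%", 100 * colMeans(x@indicators)),
                   colnames(x@indicators)))
  df[] <- lapply(df, as.character)
  df <- rbind(df, as.list(sm))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
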