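# Discrete unit spheres for ODF sampling: subdivided icosahedra, with
# vertex adjacency (for local-maximum peak finding), antipodal pairing (the
# even SH basis makes ODFs symmetric) and quadrature weights (one third of
# the incident triangle area per vertex, rescaled to total 4*pi).

.sphereCache <- new.env(parent = emptyenv())

.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

.subdivide <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  key <- new.env(parent = emptyenv())
  nv <- nrow(v)
  verts <- vector("list", nv + 3L * nrow(f))
  for (i in seq_len(nv)) verts[[i]] <- v[i, ]
  midpoint <- function(a, b) {
    k <- paste(min(a, b), max(a, b))
    id <- key[[k]]
    if (!is.null(id)) return(id)
    nv <<- nv + 1L
    m <- (verts[[a]] + verts[[b]])
    verts[[nv]] <<- m / sqrt(sum(m^2))
    key[[k]] <- nv
    nv
  }
  newf <- matrix(0L, 4L * nrow(f), 3L)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1L]; b <- f[i, 2L]; c <- f[i, 3L]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    newf[4L * i - 3L, ] <- c(a, ab, ca)
    newf[4L * i - 2L, ] <- c(b, bc, ab)
    newf[4L * i - 1L, ] <- c(c, ca, bc)
    newf[4L * i, ] <- c(ab, bc, ca)
  }
  list(vertices = do.call(rbind, verts[seq_len(nv)]), faces = newf)
}

#' Discrete sampling sphere
#'
#' A subdivided icosahedral tessellation of the unit sphere, together with
#' the vertex adjacency graph, the antipodal vertex pairing and quadrature
#' weights. The default level (4 subdivisions) has 2562 vertices, about a 4
#' degree vertex spacing. The vertex set is antipodally symmetric, so every
#' direction and its negation are both present.
#'
#' @param level number of icosahedral subdivisions (0 = icosahedron).
#' @return a list with elements \code{vertices} (V x 3 unit vectors),
#'   \code{faces} (F x 3 vertex indices), \code{neighbors} (V x d index
#'   matrix padded with NA), \code{antipode} (index of -v per vertex),
#'   \code{weights} (quadrature weights summing to 4*pi) and \code{upper}
#'   (logical, TRUE on a canonical hemisphere representative of each
#'   antipodal pair).
#' @export
unitSphere <- function(level = 4L) {
  key <- as.character(level)
  if (!is.null(.sphereCache[[key]])) return(.sphereCache[[key]])
  mesh <- .icosahedron()
  for (i in seq_len(level)) mesh <- .subdivide(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  # adjacency
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  edges <- rbind(edges, edges[, c(2, 1)])
  edges <- unique(edges)
  nbrList <- split(edges[, 2L], edges[, 1L])
  deg <- max(vapply(nbrList, length, 1L))
  nbr <- matrix(NA_integer_, nv, deg)
  for (i in seq_len(nv)) {
    ni <- nbrList[[as.character(i)]]
    nbr[i, seq_along(ni)] <- ni
  }
  # antipodal map via rounded-coordinate keys
  keys <- apply(round(v, 9), 1L, paste, collapse = ",")
  akeys <- apply(round(-v, 9), 1L, paste, collapse = ",")
  antipode <- match(akeys, keys)
  stopifnot(!anyNA(antipode))
  # vertex quadrature weights: a third of incident triangle area, scaled
  a <- v[f[, 1L], ]; b <- v[f[, 2L], ]; cc <- v[f[, 3L], ]
  cr <- cbind((b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
              (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
              (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
  farea <- 0.5 * sqrt(rowSums(cr^2))
  w <- numeric(nv)
  for (j in 1:3) {
    t <- tapply(farea, f[, j], sum)
    w[as.integer(names(t))] <- w[as.integer(names(t))] + t / 3
  }
  w <- w * (4 * pi / sum(w))
  upper <- v[, 3L] > 1e-9 |
    (abs(v[, 3L]) <= 1e-9 & (v[, 2L] > 1e-9 |
                               (abs(v[, 2L]) <= 1e-9 & v[, 1L] > 0)))
  s <- list(vertices = v, faces = f, neighbors = nbr, antipode = antipode,
            weights = w, upper = upper, level = level)
  .sphereCache[[key]] <- s
  s
}
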