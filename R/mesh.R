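#' Triangle mesh objects
#'
#' A `tri_mesh` is the basic geometric container of the package: a closed (or
#' open, see [mesh_is_watertight()]) triangulated surface of one vertebra in
#' millimetres. It stores an `n x 3` matrix of vertex coordinates and an
#' `m x 3` integer matrix of 1-based vertex indices, one row per triangle,
#' outward-facing by the right-hand rule.
#'
#' A mesh may additionally carry a list of convex *pieces* (attribute
#' `"pieces"`), each itself a `tri_mesh`, when the surface is an assembly of
#' convex solids (as produced by the synthetic segment generator). The boolean
#' backend exploits this decomposition; it is never required.
#'
#' @param vertices numeric matrix, `n x 3`, finite coordinates (mm).
#' @param faces integer matrix, `m x 3`, 1-based vertex indices.
#' @param pieces optional list of convex `tri_mesh` pieces whose union is the
#'   surface (used by the exact boolean backend for non-convex assemblies).
#' @return An object of class `tri_mesh`.
#' @examples
#' cube <- box_mesh(c(0, 0, 0), c(1, 1, 1))
#' surface_area(cube)  # 6
#' @export
tri_mesh <- function(vertices, faces, pieces = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) == 0L) stop("mesh has zero triangles")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
  if (!is.null(pieces)) attr(m, "pieces") <- pieces
  m
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d triangles", nrow(x$vertices),
              nrow(x$faces)))
  p <- attr(x, "pieces")
  if (!is.null(p)) cat(sprintf(" (%d convex pieces)", length(p)))
  cat(sprintf("\n  surface area %.6g mm^2, watertight: %s\n",
              surface_area(x), mesh_is_watertight(x)))
  invisible(x)
}

#' Axis-aligned box mesh
#'
#' Convenience constructor for a closed axis-aligned box, triangulated with 12
#' outward-facing triangles. Used throughout the synthetic generator and tests.
#'
#' @param lo,hi numeric length-3 vectors, opposite corners with `lo < hi`.
#' @return A `tri_mesh` with 8 vertices and 12 triangles.
#' @export
box_mesh <- function(lo, hi) {
  stopifnot(length(lo) == 3L, length(hi) == 3L, all(hi > lo))
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  dimnames(v) <- NULL
  # vertex order: (x fastest) 1:(---) 2:(+--) 3:(-+-) 4:(++-) 5:(--+) 6:(+-+)
  # 7:(-++) 8:(+++); faces CCW seen from outside
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = lo
    c(5, 6, 8), c(5, 8, 7),   # z = hi
    c(1, 2, 6), c(1, 6, 5),   # y = lo
    c(3, 7, 8), c(3, 8, 4),   # y = hi
    c(1, 5, 7), c(1, 7, 3),   # x = lo
    c(2, 4, 8), c(2, 8, 6))   # x = hi
  tri_mesh(v, f)
}

#' Total surface area of a triangle mesh
#'
#' Sum of triangle areas via the cross product. For piece assemblies this
#' includes internal contact faces, matching a plain triangle-sum on the stored
#' surface.
#'
#' @param mesh a `tri_mesh`.
#' @return Surface area in mm^2.
#' @export
surface_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem volume; positive for outward-facing closed surfaces.
#' For assemblies of flush closed pieces volumes add exactly.
#'
#' @param mesh a `tri_mesh`.
#' @return Volume in mm^3 (signed).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

# Merge vertices closer than tol, returning a mesh with deduplicated indices.
# Needed before topological checks on meshes read from formats that repeat
# vertices per facet (STL).
merge_vertices <- function(mesh, tol = 1e-8) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  idx <- match(key, key)          # first occurrence per coordinate
  keep <- sort(unique(idx))
  remap <- match(idx, keep)
  f <- matrix(remap[mesh$faces], ncol = 3L)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  tri_mesh(v[keep, , drop = FALSE], f[!degen, , drop = FALSE],
           pieces = attr(mesh, "pieces"))
}

#' Is a mesh watertight?
#'
#' A mesh is reported watertight when every edge is shared by exactly two
#' triangles after coincident vertices are merged. Assemblies are watertight
#' when every piece-soup edge is two-manifold (each flush closed piece
#' contributes a closed surface).
#'
#' @param mesh a `tri_mesh`.
#' @param tol vertex merge tolerance (mm).
#' @return Logical flag.
#' @export
mesh_is_watertight <- function(mesh, tol = 1e-8) {
  m <- merge_vertices(mesh, tol)
  f <- m$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(paste(e[, 1], e[, 2]))
  all(cnt == 2L)
}

#' Is a mesh convex?
#'
#' True when every vertex lies on or behind the plane of every face, within a
#' tolerance relative to the mesh scale. Convexity selects the exact clipping
#' boolean backend.
#'
#' @param mesh a `tri_mesh`.
#' @param tol relative tolerance.
#' @return Logical flag.
#' @export
mesh_is_convex <- function(mesh, tol = 1e-7) {
  v <- mesh$vertices
  f <- mesh$faces
  scale <- max(apply(v, 2, function(c) diff(range(c))), 1)
  pl <- face_planes(mesh)
  for (i in seq_len(nrow(pl))) {
    if (any(v %*% pl[i, 1:3] - pl[i, 4] > tol * scale)) return(FALSE)
  }
  TRUE
}

# Outward unit normal n and offset d (n . x = d) per triangle; degenerate
# triangles dropped. Returns a k x 4 matrix.
face_planes <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  ok <- len > 1e-12
  n <- n[ok, , drop = FALSE] / len[ok]
  d <- rowSums(n * v[f[ok, 1], , drop = FALSE])
  cbind(n, d)
}

# Deduplicate near-identical planes (coplanar triangles of one facet).
unique_planes <- function(planes, tol = 1e-7) {
  key <- apply(round(planes / tol) * tol, 1, paste, collapse = "/")
  planes[!duplicated(key), , drop = FALSE]
}

#' Apply a rigid (or affine) transform to a mesh
#'
#' @param mesh a `tri_mesh`.
#' @param rotation 3x3 matrix applied to coordinates (about the origin).
#' @param translation length-3 vector added after rotation.
#' @param center optional point about which the rotation pivots.
#' @return Transformed `tri_mesh` (pieces transformed alongside).
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  tp <- function(v) {
    sweep(sweep(v, 2, center) %*% t(rotation), 2,
          center + translation, "+")
  }
  pieces <- attr(mesh, "pieces")
  if (!is.null(pieces)) {
    pieces <- lapply(pieces, transform_mesh, rotation = rotation,
                     translation = translation, center = center)
  }
  tri_mesh(tp(mesh$vertices), mesh$faces, pieces = pieces)
}
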