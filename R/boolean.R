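#' Boolean intersection of two vertebral meshes
#'
#' Measures the overlap between two solids, the quantity behind the bony-stop
#' constraint: motion ceases when the surface area of the intersection solid
#' exceeds a threshold fraction of mean vertebral surface area.
#'
#' Two backends are used. When both bodies are convex, or are assemblies of
#' convex pieces (as produced by the synthetic generator), the intersection is
#' computed exactly by half-space clipping: the intersection of convex solids
#' is the polytope bounded by both solids' face planes, whose surface area and
#' volume follow directly. Otherwise a voxel-overlap estimate is used and the
#' result is flagged approximate. For assemblies the reported area is the sum
#' over overlapping piece pairs, exact whenever a single piece pair overlaps
#' (the usual situation near first contact).
#'
#' @param a,b `tri_mesh` objects.
#' @param pitch voxel edge length (mm) for the fallback backend; default
#'   `sqrt(mean(surface areas))/200`, fine enough to resolve 0.25% area
#'   thresholds.
#' @return A list of class `bool_intersection`: `area` (mm^2), `volume`
#'   (mm^3), `method` (`"clip"` or `"voxel"`), `approximate` (logical).
#'   Disjoint or merely touching solids report area 0.
#' @examples
#' a <- box_mesh(c(0, 0, 0), c(1, 1, 1))
#' b <- box_mesh(c(0.5, 0, 0), c(1.5, 1, 1))
#' boolean_intersection(a, b)$area  # 4: the 0.5 x 1 x 1 overlap box
#' @export
boolean_intersection <- function(a, b, pitch = NULL) {
  pa <- convex_pieces(a)
  pb <- convex_pieces(b)
  if (!is.null(pa) && !is.null(pb)) {
    res <- tryCatch(clip_pairwise(pa, pb), error = function(e) NULL)
    if (!is.null(res))
      return(structure(list(area = res$area, volume = res$volume,
                            method = "clip", approximate = FALSE),
                       class = "bool_intersection"))
  }
  res <- voxel_intersection(a, b, pitch)
  structure(list(area = res$area, volume = res$volume, method = "voxel",
                 approximate = TRUE), class = "bool_intersection")
}

#' @rdname boolean_intersection
#' @export
boolean_intersection_area <- function(a, b, pitch = NULL) {
  boolean_intersection(a, b, pitch)$area
}

#' @export
print.bool_intersection <- function(x, ...) {
  cat(sprintf("boolean intersection: area %.6g mm^2, volume %.6g mm^3 [%s%s]\n",
              x$area, x$volume, x$method,
              if (x$approximate) ", approximate" else ""))
  invisible(x)
}

# Return the list of convex pieces of a mesh, or NULL if the mesh is neither
# convex nor an assembly of convex pieces.
convex_pieces <- function(mesh) {
  p <- attr(mesh, "pieces")
  if (!is.null(p)) {
    if (all(vapply(p, mesh_is_convex, TRUE))) return(p)
    return(NULL)
  }
  if (mesh_is_convex(mesh)) return(list(mesh))
  NULL
}

clip_pairwise <- function(pa, pb) {
  area <- 0
  volume <- 0
  ca <- lapply(pa, bounding_sphere)
  cb <- lapply(pb, bounding_sphere)
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      d <- sqrt(sum((ca[[i]]$center - cb[[j]]$center)^2))
      if (d > ca[[i]]$radius + cb[[j]]$radius) next
      r <- clip_convex_pair(pa[[i]], pb[[j]])
      area <- area + r$area
      volume <- volume + r$volume
    }
  }
  list(area = area, volume = volume)
}

bounding_sphere <- function(mesh) {
  ctr <- colMeans(mesh$vertices)
  list(center = ctr,
       radius = sqrt(max(rowSums(sweep(mesh$vertices, 2, ctr)^2))))
}

# Exact intersection of two convex solids: clip A's face polygons by each of
# B's (deduplicated) face half-spaces, adding a cap polygon on every plane
# that truly cuts. Touching without volumetric overlap reports zero.
clip_convex_pair <- function(a, b) {
  scale <- max(apply(rbind(a$vertices, b$vertices), 2,
                     function(x) diff(range(x))), 1)
  eps <- 1e-9 * scale
  polys <- lapply(seq_len(nrow(a$faces)),
                  function(i) a$vertices[a$faces[i, ], , drop = FALSE])
  planes <- unique_planes(face_planes(b), tol = 1e-7)
  for (k in seq_len(nrow(planes))) {
    n <- planes[k, 1:3]
    d <- planes[k, 4]
    kept <- list()
    cut_any <- FALSE
    for (P in polys) {
      s <- as.numeric(P %*% n) - d
      if (all(s <= eps)) { kept[[length(kept) + 1L]] <- P; next }
      if (all(s >= -eps)) next                    # fully outside
      cut_any <- TRUE
      kept[[length(kept) + 1L]] <- clip_polygon(P, s, eps)
    }
    if (cut_any) {
      cap <- cap_polygon(kept, n, d, eps * 10)
      if (!is.null(cap)) kept[[length(kept) + 1L]] <- cap
    }
    polys <- Filter(function(P) !is.null(P) && nrow(P) >= 3L, kept)
    if (length(polys) == 0L) return(list(area = 0, volume = 0))
  }
  vol <- abs(poly_soup_volume(polys))
  if (vol < (1e-6 * scale)^3) return(list(area = 0, volume = 0))
  list(area = poly_soup_area(polys), volume = vol)
}

# Sutherland-Hodgman: keep the s <= 0 side of one polygon; s precomputed.
clip_polygon <- function(P, s, eps) {
  n <- nrow(P)
  out <- matrix(0, n + 4L, 3L)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    si <- s[i]; sj <- s[j]
    if (si <= eps) { m <- m + 1L; out[m, ] <- P[i, ] }
    if ((si < -eps && sj > eps) || (si > eps && sj < -eps)) {
      t <- si / (si - sj)
      m <- m + 1L
      out[m, ] <- P[i, ] + t * (P[j, ] - P[i, ])
    }
  }
  if (m < 3L) return(NULL)
  out[seq_len(m), , drop = FALSE]
}

# Build the planar cap closing the clipped polytope on plane n.x = d: convex
# hull (in-plane) of all kept vertices lying on the plane, wound so the cap
# normal points along +n (outward).
cap_polygon <- function(polys, n, d, tol) {
  pts <- do.call(rbind, polys)
  if (is.null(pts) || nrow(pts) == 0L) return(NULL)
  on <- abs(as.numeric(pts %*% n) - d) <= tol
  pts <- pts[on, , drop = FALSE]
  if (nrow(pts) < 3L) return(NULL)
  # in-plane orthonormal basis
  u <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- u - sum(u * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  xy <- cbind(as.numeric(pts %*% e1), as.numeric(pts %*% e2))
  h <- grDevices::chull(xy)                       # clockwise in (e1,e2)
  if (length(h) < 3L) return(NULL)
  # reverse to counter-clockwise so the cap normal is +n (outward), keeping
  # the polytope's signed volume consistent
  pts[rev(h), , drop = FALSE]
}

poly_soup_area <- function(polys) {
  sum(vapply(polys, function(P) {
    a <- 0
    for (k in 2:(nrow(P) - 1L)) {
      u <- P[k, ] - P[1, ]
      v <- P[k + 1L, ] - P[1, ]
      a <- a + sqrt(sum(c(u[2] * v[3] - u[3] * v[2],
                          u[3] * v[1] - u[1] * v[3],
                          u[1] * v[2] - u[2] * v[1])^2)) / 2
    }
    a
  }, 1))
}

poly_soup_volume <- function(polys) {
  # volume relative to the vertex centroid: exact for closed outward-facing
  # polytopes, and identically zero for degenerate flat results (touching
  # solids), where the divergence sum about an arbitrary origin would not be
  tot <- 0
  ctr <- colMeans(do.call(rbind, polys))
  for (P in polys) {
    P <- sweep(P, 2, ctr)
    for (k in 2:(nrow(P) - 1L)) {
      p1 <- P[1, ]; p2 <- P[k, ]; p3 <- P[k + 1L, ]
      tot <- tot + (p1[1] * (p2[2] * p3[3] - p2[3] * p3[2]) -
                    p1[2] * (p2[1] * p3[3] - p2[3] * p3[1]) +
                    p1[3] * (p2[1] * p3[2] - p2[2] * p3[1])) / 6
    }
  }
  tot
}

# Voxel-overlap fallback for general meshes: occupancy of grid-cell centres
# inside both solids over the intersection of bounding boxes. Area is
# estimated from exposed voxel faces; both quantities are approximate.
voxel_intersection <- function(a, b, pitch = NULL) {
  if (is.null(pitch))
    pitch <- sqrt(mean(c(surface_area(a), surface_area(b)))) / 200
  lo <- pmax(apply(a$vertices, 2, min), apply(b$vertices, 2, min)) - pitch
  hi <- pmin(apply(a$vertices, 2, max), apply(b$vertices, 2, max)) + pitch
  if (any(hi <= lo)) return(list(area = 0, volume = 0))
  dims <- pmax(ceiling((hi - lo) / pitch), 1L)
  if (prod(dims) > 2e6) {                        # cap the grid size
    pitch <- pitch * (prod(dims) / 2e6)^(1 / 3)
    dims <- pmax(ceiling((hi - lo) / pitch), 1L)
  }
  # centre offsets avoid rays grazing axis-aligned faces
  gx <- lo[1] + (seq_len(dims[1]) - 0.5 + 1e-4) * pitch
  gy <- lo[2] + (seq_len(dims[2]) - 0.5 + 2e-4) * pitch
  gz <- lo[3] + (seq_len(dims[3]) - 0.5 + 3e-4) * pitch
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  occ <- points_in_mesh(pts, a) & points_in_mesh(pts, b)
  if (!any(occ)) return(list(area = 0, volume = 0))
  occ <- array(occ, dim = dims)
  exposed <- 0L
  pad <- function(arr, d, side) {               # neighbour occupancy shifted
    idx <- seq_len(dim(arr)[d])
    shifted <- if (side > 0) c(idx[-1], NA) else c(NA, idx[-length(idx)])
    slice <- switch(d, arr[shifted, , , drop = FALSE],
                    arr[, shifted, , drop = FALSE],
                    arr[, , shifted, drop = FALSE])
    slice[is.na(slice)] <- FALSE
    slice
  }
  for (d in 1:3) for (side in c(-1, 1))
    exposed <- exposed + sum(occ & !pad(occ, d, side))
  list(area = exposed * pitch^2, volume = sum(occ) * pitch^3)
}

# Parity ray cast along +x: a point is inside a closed mesh when a ray
# crosses the surface an odd number of times.
points_in_mesh <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  inside <- integer(nrow(points))
  py <- points[, 2]; pz <- points[, 3]; px <- points[, 1]
  for (i in seq_len(nrow(f))) {
    t1 <- v[f[i, 1], ]; t2 <- v[f[i, 2], ]; t3 <- v[f[i, 3], ]
    # 2D (y,z) barycentric membership
    d <- (t2[2] - t1[2]) * (t3[3] - t1[3]) - (t3[2] - t1[2]) * (t2[3] - t1[3])
    if (abs(d) < 1e-14) next                     # edge-on triangle
    w1 <- ((py - t1[2]) * (t3[3] - t1[3]) - (t3[2] - t1[2]) * (pz - t1[3])) / d
    w2 <- ((t2[2] - t1[2]) * (pz - t1[3]) - (py - t1[2]) * (t2[3] - t1[3])) / d
    hit <- w1 >= 0 & w2 >= 0 & (w1 + w2) <= 1
    if (!any(hit)) next
    xh <- t1[1] + w1[hit] * (t2[1] - t1[1]) + w2[hit] * (t3[1] - t1[1])
    cross <- xh > px[hit]
    inside[hit] <- inside[hit] + as.integer(cross)
  }
  inside %% 2L == 1L
}
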