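# Minimum distance from a point to a triangle mesh surface (brute force over
# triangles); used to check that generated landmarks lie on their meshes.
point_to_mesh_distance <- function(p, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  best <- Inf
  for (i in seq_len(nrow(f))) {
    best <- min(best, point_triangle_distance(p, v[f[i, 1], ], v[f[i, 2], ],
                                              v[f[i, 3], ]))
    if (best == 0) break
  }
  best
}

point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    t <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + t * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    t <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + t * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + t * (c - b)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  sqrt(sum((p - (a + ab * (vb * denom) + ac * (vc * denom)))^2))
}
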