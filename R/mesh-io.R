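#' Read a triangle mesh from STL, OBJ, or PLY
#'
#' Reads binary or ASCII STL, Wavefront OBJ (v/f records, polygonal faces are
#' fan-triangulated), or ASCII PLY. Coordinates are multiplied by
#' `units_scale`, so a mesh stored in metres becomes millimetres with
#' `units_scale = 1000`.
#'
#' @param path file path; format inferred from the extension
#'   (`.stl`, `.obj`, `.ply`).
#' @param units_scale positive scale factor applied to all coordinates.
#' @return A `tri_mesh` with attribute `"watertight"` (logical report).
#' @export
read_mesh <- function(path, units_scale = 1) {
  if (!is.numeric(units_scale) || length(units_scale) != 1L ||
      !is.finite(units_scale) || units_scale <= 0)
    stop("degenerate scale: units_scale must be a positive finite number")
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    stl = read_stl(path),
    obj = read_obj(path),
    ply = read_ply(path),
    stop("unsupported mesh format: .", ext, " (use STL, OBJ, or PLY)"))
  mesh$vertices <- mesh$vertices * units_scale
  m <- tri_mesh(mesh$vertices, mesh$faces)
  attr(m, "watertight") <- mesh_is_watertight(m)
  m
}

#' Write a triangle mesh to STL, OBJ, or PLY
#'
#' ASCII variants of all three formats are written; geometry round-trips
#' through [read_mesh()] within 1e-6.
#'
#' @param mesh a `tri_mesh`.
#' @param path output path; format inferred from the extension.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = write_stl(mesh, path),
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path),
    stop("unsupported mesh format: .", ext))
  invisible(path)
}

read_stl <- function(path) {
  # Sniff: ASCII STL starts with "solid" and contains "facet"; binary has an
  # 80-byte header plus little-endian records.
  head <- readBin(path, "raw", n = 512L)
  txt <- rawToChar(head[head != as.raw(0)])
  Encoding(txt) <- "bytes"
  if (grepl("^\\s*solid", txt, useBytes = TRUE) &&
      grepl("facet|endsolid", txt, useBytes = TRUE)) read_stl_ascii(path)
  else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0L) stop("no triangles in STL file: ", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  v <- do.call(rbind, nums)
  if (nrow(v) %% 3L != 0L) stop("malformed ASCII STL: vertex count not a multiple of 3")
  if (!all(is.finite(v))) stop("non-finite coordinates in STL file")
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = f)
}

read_stl_binary <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 84L) stop("truncated binary STL: ", path)
  n <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
  if (is.na(n) || n <= 0L) stop("no triangles in STL file: ", path)
  body <- raw[-(1:84)]
  if (length(body) < 50L * n) stop("truncated binary STL: ", path)
  v <- matrix(0, 3L * n, 3L)
  for (i in seq_len(n)) {
    off <- (i - 1L) * 50L
    vals <- readBin(body[(off + 13L):(off + 48L)], "numeric", n = 9L,
                    size = 4L, endian = "little")
    v[(3L * i - 2L):(3L * i), ] <- matrix(vals, 3L, 3L, byrow = TRUE)
  }
  if (!all(is.finite(v))) stop("non-finite coordinates in STL file")
  list(vertices = v, faces = matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE))
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  pl <- matrix(0, nrow(f), 3)
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  n <- n / ifelse(len > 0, len, 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid vertebend", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      p <- v[f[i, j], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid vertebend", con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(fl) == 0L) stop("no triangles in OBJ file: ", path)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[2:4])))
  if (!all(is.finite(v))) stop("non-finite coordinates in OBJ file")
  tris <- list()
  for (ln in fl) {
    idx <- vapply(strsplit(trimws(ln), "\\s+")[[1]][-1],
                  function(tok) as.integer(strsplit(tok, "/")[[1]][1]), 1L)
    idx[idx < 0L] <- nrow(v) + 1L + idx[idx < 0L]
    for (k in seq_len(length(idx) - 2L))          # fan triangulation
      tris[[length(tris) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  list(vertices = v, faces = do.call(rbind, tris))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# vertebend mesh", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  if (!any(grepl("format\\s+ascii", lines)))
    stop("only ASCII PLY is supported: ", path)
  endh <- match("end_header", trimws(lines))
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", lines, value = TRUE)[1]))
  if (is.na(nf) || nf == 0L) stop("no triangles in PLY file: ", path)
  body <- lines[(endh + 1L):length(lines)]
  v <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  if (!all(is.finite(v))) stop("non-finite coordinates in PLY file")
  tris <- list()
  for (ln in body[nv + seq_len(nf)]) {
    x <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
    idx <- x[2:(1 + x[1])] + 1L                  # PLY indices are 0-based
    for (k in seq_len(length(idx) - 2L))
      tris[[length(tris) + 1L]] <- idx[c(1L, k + 1L, k + 2L)]
  }
  list(vertices = v, faces = do.call(rbind, tris))
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
}
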