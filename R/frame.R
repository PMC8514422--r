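#' Joint coordinate frame
#'
#' The joint frame anchors all bending motion: `cor` is the centre of rotation
#' (mid-disk or zygapophyseal sphere centre), and the three axes define the
#' anatomical rotation planes. By convention the x-axis runs along the centrum
#' long axis (axial rotation), the y-axis dorsoventrally (lateral bending), and
#' the z-axis mediolaterally (sagittal bending). Axes must be orthonormal
#' within 1e-6 and right-handed.
#'
#' @param cor centre of rotation, length-3 numeric (mm).
#' @param x_axis,y_axis,z_axis unit axis vectors.
#' @return An object of class `joint_frame`.
#' @examples
#' joint_frame(c(0, 0, 0))
#' @export
joint_frame <- function(cor = c(0, 0, 0), x_axis = c(1, 0, 0),
                        y_axis = c(0, 1, 0), z_axis = c(0, 0, 1)) {
  cor <- as.numeric(cor); x_axis <- as.numeric(x_axis)
  y_axis <- as.numeric(y_axis); z_axis <- as.numeric(z_axis)
  stopifnot(length(cor) == 3L, all(is.finite(c(cor, x_axis, y_axis, z_axis))))
  ax <- rbind(x_axis, y_axis, z_axis)
  if (any(abs(sqrt(rowSums(ax^2)) - 1) > 1e-6))
    stop("frame axes must be unit length (within 1e-6)")
  g <- ax %*% t(ax)
  if (any(abs(g - diag(3)) > 1e-6))
    stop("frame axes must be mutually orthogonal (within 1e-6)")
  if (det(ax) < 0)
    stop("frame must be right-handed (x cross y = z)")
  structure(list(cor = cor, x_axis = x_axis, y_axis = y_axis, z_axis = z_axis),
            class = "joint_frame")
}

#' @export
print.joint_frame <- function(x, ...) {
  cat("joint_frame\n")
  cat(sprintf("  cor: (%.4g, %.4g, %.4g) mm\n", x$cor[1], x$cor[2], x$cor[3]))
  for (a in c("x_axis", "y_axis", "z_axis"))
    cat(sprintf("  %s: (%.4g, %.4g, %.4g)\n", a, x[[a]][1], x[[a]][2], x[[a]][3]))
  invisible(x)
}

# Rodrigues rotation matrix: angle in degrees about unit axis u.
rotation_matrix <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotate points or a mesh about a joint-frame axis
#'
#' Rigid rotation by `angle` degrees about the frame axis through the COR.
#' The rotation is always composed fresh from the supplied (neutral) pose:
#' callers pass the total angle, never an increment, so no floating-point
#' drift accumulates across probe angles.
#'
#' @param x a `tri_mesh` or an `n x 3` coordinate matrix.
#' @param frame a [joint_frame()].
#' @param axis which frame axis, `"x"`, `"y"`, or `"z"`.
#' @param angle rotation angle in degrees (right-hand rule about the axis).
#' @return Transformed copy of `x`.
#' @export
rotate_about_frame <- function(x, frame, axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  if (!is.finite(angle)) stop("non-finite rotation angle")
  R <- rotation_matrix(frame[[paste0(axis, "_axis")]], angle)
  apply_rigid(x, R, c(0, 0, 0), center = frame$cor)
}

#' Translate points or a mesh along a direction
#'
#' @param x a `tri_mesh` or an `n x 3` coordinate matrix.
#' @param frame a [joint_frame()] (kept for interface symmetry; the direction
#'   is interpreted in world coordinates, as frame axes are world vectors).
#' @param direction unit direction vector.
#' @param distance translation distance in mm.
#' @return Transformed copy of `x`.
#' @export
translate_along_frame <- function(x, frame, direction, distance) {
  if (!is.finite(distance)) stop("non-finite translation distance")
  len <- sqrt(sum(direction^2))
  if (abs(len - 1) > 1e-6) stop("direction must be a unit vector")
  apply_rigid(x, diag(3), direction * distance)
}

# Shared rigid-transform dispatcher for meshes and coordinate matrices.
apply_rigid <- function(x, R, t, center = c(0, 0, 0)) {
  if (inherits(x, "tri_mesh"))
    return(transform_mesh(x, rotation = R, translation = t, center = center))
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  sweep(sweep(x, 2, center) %*% t(R), 2, center + t, "+")
}

#' Fit a sphere to 3D points
#'
#' With exactly four non-coplanar points the unique interpolating sphere is
#' returned (the "four-point method" used for zygapophyseal COR placement);
#' with more points an algebraic least-squares fit is used. Degenerate
#' (coplanar or coincident) configurations raise an error rather than guessing.
#'
#' @param points `n x 3` matrix, `n >= 4`.
#' @return A list of class `sphere_fit`: `center`, `radius`, `rms_residual`
#'   (root-mean-square of point-to-surface distances, mm).
#' @examples
#' fit_sphere(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
#' @export
fit_sphere <- function(points) {
  p <- as.matrix(points)
  if (is.null(dim(p)) || ncol(p) != 3L) stop("points must be an n x 3 matrix")
  if (nrow(p) < 4L) stop("sphere fit needs at least 4 points")
  if (!all(is.finite(p))) stop("non-finite point coordinates")
  # algebraic form: |x|^2 = 2 c.x + k, linear in (c, k)
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  qr_A <- qr(A)
  if (qr_A$rank < 4L)
    stop("degenerate point configuration (coplanar or coincident): cannot fit sphere")
  # guard against near-singular systems that technically have full rank
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[4] / sv[1] < 1e-10)
    stop("degenerate point configuration (coplanar or coincident): cannot fit sphere")
  sol <- qr.coef(qr_A, b)
  center <- sol[1:3]
  r2 <- sol[4] + sum(center^2)
  if (r2 <= 0) stop("degenerate point configuration: non-positive radius")
  radius <- sqrt(r2)
  d <- sqrt(rowSums(sweep(p, 2, center)^2)) - radius
  structure(list(center = unname(center), radius = unname(radius),
                 rms_residual = sqrt(mean(d^2))), class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("sphere_fit: center (%.6g, %.6g, %.6g), radius %.6g mm, rms %.3g mm\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms_residual))
  invisible(x)
}
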