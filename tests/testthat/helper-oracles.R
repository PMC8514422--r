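# Independent oracles used to cross-check the implementation.

# --- Separating-axis overlap test for oriented boxes -------------------------
# Boxes given as center, half-extents, and a 3x3 matrix of unit axis columns.
# Returns TRUE when the interiors intersect. Entirely independent of the
# package's clipping backend.
obb_overlap <- function(c1, e1, A1, c2, e2, A2) {
  t <- c2 - c1
  axes <- cbind(A1, A2)
  for (i in 1:3) for (j in 1:3) {
    cr <- c(A1[2, i] * A2[3, j] - A1[3, i] * A2[2, j],
            A1[3, i] * A2[1, j] - A1[1, i] * A2[3, j],
            A1[1, i] * A2[2, j] - A1[2, i] * A2[1, j])
    axes <- cbind(axes, cr)
  }
  for (k in seq_len(ncol(axes))) {
    L <- axes[, k]
    n2 <- sum(L^2)
    if (n2 < 1e-12) next
    r1 <- sum(abs(crossprod(A1, L)) * e1)
    r2 <- sum(abs(crossprod(A2, L)) * e2)
    if (abs(sum(t * L)) >= r1 + r2 - 1e-10 * sqrt(n2)) return(FALSE)
  }
  TRUE
}

# Direction -> (axis vector, sign) per the documented convention: frame x
# caudal, y dorsal, z left; +z = dorsiflexion, -y = left lateral, +x = left
# axial.
oracle_direction_axis <- function(direction) {
  switch(direction,
         "dorsiflexion"  = list(axis = c(0, 0, 1), sign = 1),
         "ventroflexion" = list(axis = c(0, 0, 1), sign = -1),
         "left-lateral"  = list(axis = c(0, 1, 0), sign = -1),
         "right-lateral" = list(axis = c(0, 1, 0), sign = 1),
         "left-axial"    = list(axis = c(1, 0, 0), sign = 1),
         "right-axial"   = list(axis = c(1, 0, 0), sign = -1))
}

rot3 <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Fine-sampling contact oracle for tabless block segments: sweep the rotation
# angle in `step`-degree increments and report the last angle before the two
# cuboids' interiors intersect (cap if none does). Pure SAT, no meshes.
fine_contact_sweep <- function(width, height, length, gap, direction,
                               step = 0.01, max_angle = 45) {
  g <- gap / 2
  e <- c(length / 2, height / 2, width / 2)
  c_ant <- c(-g - length / 2, 0, 0)
  c_post0 <- c(g + length / 2, 0, 0)
  dd <- oracle_direction_axis(direction)
  n <- round(max_angle / step)
  for (k in seq_len(n)) {
    R <- rot3(dd$axis, dd$sign * k * step)
    if (obb_overlap(c_ant, e, diag(3), as.numeric(R %*% c_post0), e, R))
      return((k - 1) * step)
  }
  max_angle
}

# --- Sequential sums of squares via orthogonal projections -------------------
# Brute-force oracle: SS of term k is the squared-norm increase of the fitted
# values when term k's columns join the design, computed with QR projections.
ss_projection_oracle <- function(response, data, terms) {
  y <- data[[response]]
  X <- matrix(1, nrow(data), 1)
  fitted_norm <- function(X) {
    q <- qr(X)
    sum(qr.fitted(q, y)^2)
  }
  prev <- fitted_norm(X)
  out <- data.frame(term = character(0), ss = numeric(0))
  for (tm in terms) {
    mm <- stats::model.matrix(stats::as.formula(paste("~", tm)), data)
    X <- cbind(X, mm[, -1, drop = FALSE])
    cur <- fitted_norm(X)
    out <- rbind(out, data.frame(term = tm, ss = cur - prev))
    prev <- cur
  }
  rbind(out, data.frame(term = "Residuals", ss = sum(y^2) - prev))
}
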