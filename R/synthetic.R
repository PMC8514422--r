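#' Synthetic block motion segment
#'
#' Generates a two-vertebra motion segment with analytically known geometry:
#' cuboid centra of the given width (z), height (y), and length (x), separated
#' by `gap` along the craniocaudal axis, with the COR at mid-gap on the
#' centrum axis (the mid-disk convention) and frame axes aligned to the
#' cuboids (x caudal, y dorsal, z left). Eight centrum landmarks sit at the
#' endplate extremes, so every neutral reference length equals `gap` exactly.
#'
#' With `zyg_tab_length > 0`, overlapping dorsal tabs emulate the
#' zygapophyses: the anterior (post-zygapophyseal) tab cantilevers caudally
#' and the posterior (pre-zygapophyseal) tab cranially, interleaved side by
#' side so the neutral pose is intersection-free; the zygapophyseal landmark
#' pair sits at the tab tips, giving a neutral craniocaudal reference of
#' exactly `zyg_tab_overlap`. With `zyg_tab_length = 0` the centra are plain
#' convex cuboids and the zygapophyseal landmarks sit on the facing endplate
#' edges (reference length `gap`).
#'
#' Each vertebra is emitted as a watertight assembly of convex boxes (pieces
#' are carried for the exact boolean backend). Optional vertex jitter
#' (`jitter_sd` > 0, reproducible via `random_seed`) roughens the surfaces to
#' emulate mesh unevenness; jittered bodies are no longer convex and exercise
#' the voxel fallback and nonzero intersection thresholds.
#'
#' @param centrum_width,centrum_height,centrum_length cuboid extents (mm).
#' @param gap inter-endplate spacing (mm), > 0.
#' @param arch_height nominal vertebral arch height (mm), recorded for
#'   stiffness morphometrics (blocks carry no arch geometry).
#' @param zyg_tab_length tab extent along x (mm); 0 disables tabs.
#' @param zyg_tab_overlap neutral craniocaudal tab overlap (mm),
#'   `<= zyg_tab_length` and requiring
#'   `zyg_tab_length > (gap + zyg_tab_overlap)/2` so tabs stay attached.
#' @param zyg_tab_offset z-position of the left tab pair centre (mm).
#' @param bilateral_symmetry mirror the tabs to the right side (default TRUE).
#' @param random_seed seed for jitter.
#' @param jitter_sd standard deviation of vertex jitter (mm), >= 0.
#' @param segment_id identifier.
#' @return A list with `segment` (a [build_segment()] result), `ground_truth`
#'   (analytic landmark coordinates, per-vertebra surface areas, reference
#'   lengths, and closed-form first-contact angles where they exist), and
#'   `params`.
#' @examples
#' bs <- block_segment(gap = 2)
#' bs$segment$reference$centrum_d0  # 2 2 2 2
#' @export
block_segment <- function(centrum_width = 10, centrum_height = 10,
                          centrum_length = 12, gap = 2, arch_height = 3,
                          zyg_tab_length = 4, zyg_tab_overlap = 1,
                          zyg_tab_offset = 2, bilateral_symmetry = TRUE,
                          random_seed = 1L, jitter_sd = 0,
                          segment_id = "block") {
  w <- centrum_width; h <- centrum_height; L <- centrum_length
  stopifnot(w > 0, h > 0, L > 0, gap > 0, jitter_sd >= 0)
  params <- list(centrum_width = w, centrum_height = h, centrum_length = L,
                 gap = gap, arch_height = arch_height,
                 zyg_tab_length = zyg_tab_length,
                 zyg_tab_overlap = zyg_tab_overlap,
                 zyg_tab_offset = zyg_tab_offset,
                 bilateral_symmetry = bilateral_symmetry,
                 random_seed = random_seed, jitter_sd = jitter_sd)
  g <- gap / 2
  ant_pieces <- list(box_mesh(c(-g - L, -h / 2, -w / 2), c(-g, h / 2, w / 2)))
  post_pieces <- list(box_mesh(c(g, -h / 2, -w / 2), c(g + L, h / 2, w / 2)))
  tabbed <- zyg_tab_length > 0
  th <- h / 5; tw <- w / 5; clr <- tw / 4
  if (tabbed) {
    ov <- zyg_tab_overlap
    if (ov > zyg_tab_length) stop("zyg_tab_overlap must be <= zyg_tab_length")
    if (zyg_tab_length <= (gap + ov) / 2)
      stop("zyg_tab_length too short to attach tabs across the gap")
    if (zyg_tab_offset - tw / 2 <= 0)
      stop("zyg_tab_offset must exceed half the tab width (", tw / 2, " mm)")
    if (zyg_tab_offset + 3 * tw / 2 + clr >= w / 2 + tw)  # keep tabs near the body
      stop("zyg_tab_offset places tabs too far laterally")
    ant_tab <- box_mesh(c(ov / 2 - zyg_tab_length, h / 2, zyg_tab_offset - tw / 2),
                        c(ov / 2, h / 2 + th, zyg_tab_offset + tw / 2))
    post_tab <- box_mesh(c(-ov / 2, h / 2, zyg_tab_offset + tw / 2 + clr),
                         c(-ov / 2 + zyg_tab_length, h / 2 + th,
                           zyg_tab_offset + 3 * tw / 2 + clr))
    ant_pieces <- c(ant_pieces, list(ant_tab))
    post_pieces <- c(post_pieces, list(post_tab))
    if (bilateral_symmetry) {
      ant_pieces <- c(ant_pieces, list(mirror_z(ant_tab)))
      post_pieces <- c(post_pieces, list(mirror_z(post_tab)))
    }
  }
  if (jitter_sd > 0) {
    ant_pieces <- jitter_pieces(ant_pieces, jitter_sd, random_seed)
    post_pieces <- jitter_pieces(post_pieces, jitter_sd, random_seed + 1L)
  }
  anterior <- assemble_pieces(ant_pieces)
  posterior <- assemble_pieces(post_pieces)
  zyg <- if (tabbed) {
    rbind(zyg_post_caudal = c(zyg_tab_overlap / 2, h / 2 + th / 2, zyg_tab_offset),
          zyg_pre_cranial = c(-zyg_tab_overlap / 2, h / 2 + th / 2,
                              zyg_tab_offset + tw + clr))
  } else {
    rbind(zyg_post_caudal = c(-g, h / 2, zyg_tab_offset),
          zyg_pre_cranial = c(g, h / 2, zyg_tab_offset))
  }
  lmk <- landmark_set(rbind(
    zyg,
    ant_dorsal = c(-g, h / 2, 0), ant_ventral = c(-g, -h / 2, 0),
    ant_left = c(-g, 0, w / 2), ant_right = c(-g, 0, -w / 2),
    post_dorsal = c(g, h / 2, 0), post_ventral = c(g, -h / 2, 0),
    post_left = c(g, 0, w / 2), post_right = c(g, 0, -w / 2)))
  segment <- build_segment(anterior, posterior, joint_frame(),
                           lmk, segment_id = segment_id,
                           species = "synthetic", joint = "block")
  contact <- vapply(BENDING_DIRECTIONS, function(d)
    analytic_contact_angle(params, d), 1)
  gt <- list(landmarks = unclass(lmk),
             anterior_area = sum(vapply(ant_pieces, box_area_analytic, 1)),
             posterior_area = sum(vapply(post_pieces, box_area_analytic, 1)),
             zyg_d0 = if (tabbed) zyg_tab_overlap else gap,
             centrum_d0 = rep(gap, 4),
             contact_angles = contact)
  list(segment = segment, ground_truth = gt, params = params)
}

mirror_z <- function(mesh) {
  v <- mesh$vertices
  v[, 3] <- -v[, 3]
  tri_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE])  # restore orientation
}

assemble_pieces <- function(pieces) {
  if (length(pieces) == 1L) return(pieces[[1L]])
  offs <- 0L
  vs <- list(); fs <- list()
  for (p in pieces) {
    vs[[length(vs) + 1L]] <- p$vertices
    fs[[length(fs) + 1L]] <- p$faces + offs
    offs <- offs + nrow(p$vertices)
  }
  tri_mesh(do.call(rbind, vs), do.call(rbind, fs), pieces = pieces)
}

# analytic surface area for (possibly jittered) boxes: exact triangle sum
box_area_analytic <- function(mesh) surface_area(mesh)

jitter_pieces <- function(pieces, sd, seed) {
  state <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(state)) assign(".Random.seed", state, .GlobalEnv))
  set.seed(seed)
  lapply(pieces, function(p) {
    v <- p$vertices + matrix(stats::rnorm(length(p$vertices), 0, sd),
                             ncol = 3L)
    tri_mesh(v, p$faces)
  })
}

#' Closed-form first-contact angle for block segments
#'
#' For a tabless block segment rotating about the mid-gap COR, the first
#' bone-on-bone contact in a sagittal or lateral direction has a closed form
#' from the 2D cross-section: with half-gap `g = gap/2` and half-extent `c`
#' in the bending plane (height/2 sagittally, width/2 laterally), the
#' separating-axis condition `c sin(theta) - g cos(theta) = g` gives
#' `theta = atan2(g, c) + asin(g / sqrt(c^2 + g^2))`. Axial rotation of
#' tabless blocks never produces contact (`Inf`). Geometries with
#' zygapophyseal tabs or jitter have no closed form; `NA` is returned with a
#' `"reason"` attribute and the fine-sampling oracle must be used instead.
#'
#' @param params parameter list as stored in `block_segment()$params`.
#' @param direction one of [BENDING_DIRECTIONS].
#' @return First-contact angle in degrees; `Inf` when contact never occurs;
#'   `NA` (with attribute `reason = "no closed form"`) otherwise.
#' @export
analytic_contact_angle <- function(params, direction) {
  if (!direction %in% BENDING_DIRECTIONS)
    stop("invalid direction '", direction, "'")
  if (params$zyg_tab_length > 0 || params$jitter_sd > 0)
    return(structure(NA_real_, reason = "no closed form"))
  g <- params$gap / 2
  c_half <- switch(direction,
                   "dorsiflexion" = , "ventroflexion" = params$centrum_height / 2,
                   "left-lateral" = , "right-lateral" = params$centrum_width / 2,
                   "left-axial" = , "right-axial" = NA_real_)
  if (is.na(c_half)) return(Inf)    # parallel faces spin without contact
  (atan2(g, c_half) + asin(g / sqrt(c_half^2 + g^2))) * 180 / pi
}

#' Synthetic vertebra-like motion segment
#'
#' A more realistic composite for smoke tests: each vertebra is an assembly
#' of an elliptic-cylinder centrum (24-sided prism), a rectangular neural
#' arch, and paired zygapophyseal tabs, sharing the block generator's frame
#' and landmark conventions. Contact angles have no closed form; use the
#' fine-sampling oracle.
#'
#' @inheritParams block_segment
#' @param n_sides number of prism facets approximating the centrum cylinder.
#' @return As [block_segment()]: list with `segment`, `ground_truth`
#'   (landmarks, areas, reference lengths; no closed-form contact angles),
#'   and `params`.
#' @export
vertebra_segment <- function(centrum_width = 10, centrum_height = 8,
                             centrum_length = 12, gap = 2, arch_height = 3,
                             zyg_tab_length = 4, zyg_tab_overlap = 1,
                             zyg_tab_offset = 2, bilateral_symmetry = TRUE,
                             random_seed = 1L, jitter_sd = 0, n_sides = 24L,
                             segment_id = "vertebra") {
  w <- centrum_width; h <- centrum_height; L <- centrum_length
  stopifnot(w > 0, h > 0, L > 0, gap > 0, arch_height > 0, n_sides >= 8L)
  g <- gap / 2
  cyl <- function(x0, x1) elliptic_prism(x0, x1, h / 2, w / 2, n_sides)
  arch_w <- w / 3
  y0 <- (h / 2) * sqrt(1 - (arch_w / 2)^2 / (w / 2)^2) * 0.99  # embed slightly
  arch <- function(x0, x1) box_mesh(c(x0, y0, -arch_w / 2),
                                    c(x1, y0 + arch_height, arch_w / 2))
  ya <- y0 + arch_height
  th <- arch_height / 2; tw <- w / 5; clr <- tw / 4
  ov <- zyg_tab_overlap
  if (zyg_tab_length <= (gap + ov) / 2)
    stop("zyg_tab_length too short to attach tabs across the gap")
  ant_tab <- box_mesh(c(ov / 2 - zyg_tab_length, ya, zyg_tab_offset - tw / 2),
                      c(ov / 2, ya + th, zyg_tab_offset + tw / 2))
  post_tab <- box_mesh(c(-ov / 2, ya, zyg_tab_offset + tw / 2 + clr),
                       c(-ov / 2 + zyg_tab_length, ya + th,
                         zyg_tab_offset + 3 * tw / 2 + clr))
  ant_pieces <- list(cyl(-g - L, -g), arch(-g - L, -g), ant_tab)
  post_pieces <- list(cyl(g, g + L), arch(g, g + L), post_tab)
  if (bilateral_symmetry) {
    ant_pieces <- c(ant_pieces, list(mirror_z(ant_tab)))
    post_pieces <- c(post_pieces, list(mirror_z(post_tab)))
  }
  if (jitter_sd > 0) {
    ant_pieces <- jitter_pieces(ant_pieces, jitter_sd, random_seed)
    post_pieces <- jitter_pieces(post_pieces, jitter_sd, random_seed + 1L)
  }
  anterior <- assemble_pieces(ant_pieces)
  posterior <- assemble_pieces(post_pieces)
  lmk <- landmark_set(rbind(
    zyg_post_caudal = c(ov / 2, ya + th / 2, zyg_tab_offset),
    zyg_pre_cranial = c(-ov / 2, ya + th / 2, zyg_tab_offset + tw + clr),
    ant_dorsal = c(-g, h / 2, 0), ant_ventral = c(-g, -h / 2, 0),
    ant_left = c(-g, 0, w / 2), ant_right = c(-g, 0, -w / 2),
    post_dorsal = c(g, h / 2, 0), post_ventral = c(g, -h / 2, 0),
    post_left = c(g, 0, w / 2), post_right = c(g, 0, -w / 2)))
  segment <- build_segment(anterior, posterior, joint_frame(), lmk,
                           segment_id = segment_id, species = "synthetic",
                           joint = "vertebra")
  gt <- list(landmarks = unclass(lmk),
             anterior_area = surface_area(anterior),
             posterior_area = surface_area(posterior),
             zyg_d0 = ov, centrum_d0 = rep(gap, 4))
  list(segment = segment, ground_truth = gt,
       params = list(centrum_width = w, centrum_height = h,
                     centrum_length = L, gap = gap,
                     arch_height = arch_height,
                     zyg_tab_length = zyg_tab_length,
                     zyg_tab_overlap = ov, zyg_tab_offset = zyg_tab_offset,
                     bilateral_symmetry = bilateral_symmetry,
                     random_seed = random_seed, jitter_sd = jitter_sd,
                     n_sides = n_sides))
}

# closed elliptic prism along x with semi-axes ry (y) and rz (z)
elliptic_prism <- function(x0, x1, ry, rz, n) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  ring <- cbind(ry * cos(ang), rz * sin(ang))
  v <- rbind(cbind(x0, ring), cbind(x1, ring), c(x0, 0, 0), c(x1, 0, 0))
  i <- seq_len(n); j <- c(seq_len(n)[-1], 1L)
  side <- rbind(cbind(i, n + j, n + i), cbind(i, j, n + j))
  cap0 <- cbind(2L * n + 1L, j, i)          # x = x0, outward -x
  cap1 <- cbind(2L * n + 2L, n + i, n + j)  # x = x1, outward +x
  tri_mesh(v, rbind(side, cap0, cap1))
}
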