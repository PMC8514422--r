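#' Assemble a motion segment
#'
#' Builds the unit of analysis: two vertebral meshes, a joint frame, and ten
#' landmarks, with the neutral-pose reference quantities cached. The anterior
#' vertebra is fixed; all motion is expressed as rigid transforms of the
#' posterior body (mesh plus its five landmarks).
#'
#' Cached references, all measured at the neutral pose:
#' * `zyg_d0` — absolute craniocaudal (frame-x) component of the separation
#'   between the two zygapophyseal landmarks, the reference length for
#'   zygapophyseal strain. When zero the zygapophyseal constraint is flagged
#'   unusable rather than failing.
#' * `centrum_d0` — Euclidean distances of the four matched endplate landmark
#'   pairs (dorsal, ventral, left, right); all must be positive.
#' * `mean_spacing` — mean of `centrum_d0`, the working definition of joint
#'   spacing.
#' * `mean_area`, `sqrt_area` — mean vertebral surface area and its square
#'   root, the size scales for the intersection threshold and translation
#'   budget.
#'
#' @param anterior,posterior `tri_mesh` objects (mm).
#' @param frame a [joint_frame()].
#' @param landmarks a [landmark_set()].
#' @param segment_id identifier carried into result tables.
#' @param species,joint optional metadata strings.
#' @return An object of class `motion_segment`.
#' @export
build_segment <- function(anterior, posterior, frame, landmarks,
                          segment_id = "segment", species = NA_character_,
                          joint = NA_character_) {
  stopifnot(inherits(anterior, "tri_mesh"), inherits(posterior, "tri_mesh"),
            inherits(frame, "joint_frame"))
  landmarks <- landmark_set(unclass(landmarks))
  zyg_sep <- landmarks["zyg_pre_cranial", ] - landmarks["zyg_post_caudal", ]
  zyg_d0 <- abs(sum(zyg_sep * frame$x_axis))
  pairs <- c("dorsal", "ventral", "left", "right")
  centrum_d0 <- vapply(pairs, function(p) {
    sqrt(sum((landmarks[paste0("post_", p), ] - landmarks[paste0("ant_", p), ])^2))
  }, 1)
  if (any(centrum_d0 <= 0))
    stop("zero centrum reference length for pair(s): ",
         paste(pairs[centrum_d0 <= 0], collapse = ", "))
  zyg_usable <- zyg_d0 > 1e-12
  if (!zyg_usable)
    warning("zygapophyseal reference length is zero; zyg constraint flagged unusable")
  mean_area <- mean(c(surface_area(anterior), surface_area(posterior)))
  structure(list(
    anterior = anterior, posterior = posterior, frame = frame,
    landmarks = landmarks, segment_id = segment_id,
    species = species, joint = joint,
    reference = list(zyg_d0 = zyg_d0, zyg_usable = zyg_usable,
                     centrum_d0 = centrum_d0,
                     mean_spacing = mean(centrum_d0)),
    mean_area = mean_area, sqrt_area = sqrt(mean_area)),
    class = "motion_segment")
}

#' @export
print.motion_segment <- function(x, ...) {
  cat(sprintf("motion_segment '%s'\n", x$segment_id))
  cat(sprintf("  mean vertebral area %.5g mm^2 (sqrt %.4g mm)\n",
              x$mean_area, x$sqrt_area))
  cat(sprintf("  mean spacing %.4g mm; centrum d0: %s\n",
              x$reference$mean_spacing,
              paste(sprintf("%.4g", x$reference$centrum_d0), collapse = ", ")))
  cat(sprintf("  zygapophyseal d0: %.4g mm%s\n", x$reference$zyg_d0,
              if (!x$reference$zyg_usable) " (unusable)" else ""))
  invisible(x)
}

#' Adjust joint spacing
#'
#' Translates the posterior body (mesh and its landmarks) along the frame
#' x-axis by `fraction` of the current mean spacing, then rebuilds the segment
#' so the adjusted pose becomes the new neutral (all reference lengths are
#' recomputed). With landmark pairs parallel to x, the mean spacing scales by
#' exactly `1 + fraction`. Used by the sensitivity design's +/-10% spacing
#' levels.
#'
#' @param segment a `motion_segment`.
#' @param fraction signed spacing change, `|fraction| < 1`.
#' @return A new `motion_segment`; carries attribute `"neutral_overlap"` set
#'   to `TRUE` (with a warning) if the new neutral pose has positive boolean
#'   intersection area.
#' @export
adjust_spacing <- function(segment, fraction) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L, is.finite(fraction))
  if (abs(fraction) >= 1) stop("|fraction| must be < 1")
  if (fraction == 0) return(segment)
  shift <- fraction * segment$reference$mean_spacing
  dir <- segment$frame$x_axis
  post <- translate_along_frame(segment$posterior, segment$frame, dir, shift)
  lmk <- unclass(segment$landmarks)
  lmk[POSTERIOR_LANDMARKS, ] <-
    translate_along_frame(lmk[POSTERIOR_LANDMARKS, , drop = FALSE],
                          segment$frame, dir, shift)
  out <- build_segment(segment$anterior, post, segment$frame,
                       landmark_set(lmk), segment_id = segment$segment_id,
                       species = segment$species, joint = segment$joint)
  if (boolean_intersection_area(out$anterior, out$posterior) > 0) {
    warning("adjusted neutral pose has positive intersection area")
    attr(out, "neutral_overlap") <- TRUE
  }
  out
}

#' Chain motion segments craniocaudally
#'
#' Links segments into a column chain in cranial-to-caudal order, checking
#' that consecutive segments share a vertebra id. The chain composes world
#' poses hierarchically (a rotation at joint k carries all more caudal
#' vertebrae with it) for export and visualisation; per-joint range-of-motion
#' analysis still evaluates each segment from its own neutral pose, since a
#' rigid upstream rotation does not change a joint's admissible angles.
#'
#' @param segments list of `motion_segment`s, cranial to caudal.
#' @param vertebra_ids optional character matrix-like list: for each segment a
#'   length-2 vector `c(anterior_id, posterior_id)`; consecutive segments must
#'   satisfy `posterior_id[k] == anterior_id[k+1]`. Defaults to sequential ids.
#' @return An object of class `column_chain`.
#' @export
chain_segments <- function(segments, vertebra_ids = NULL) {
  stopifnot(length(segments) >= 1L,
            all(vapply(segments, inherits, TRUE, "motion_segment")))
  n <- length(segments)
  if (is.null(vertebra_ids))
    vertebra_ids <- lapply(seq_len(n), function(k) c(paste0("v", k), paste0("v", k + 1L)))
  for (k in seq_len(n - 1L)) {
    if (!identical(vertebra_ids[[k]][2], vertebra_ids[[k + 1L]][1]))
      stop(sprintf("shared vertebra id mismatch between segments %d and %d: '%s' vs '%s'",
                   k, k + 1L, vertebra_ids[[k]][2], vertebra_ids[[k + 1L]][1]))
  }
  structure(list(segments = segments, vertebra_ids = vertebra_ids),
            class = "column_chain")
}

#' World poses of chained vertebrae
#'
#' Composes per-joint rotations down the chain: the pose of vertebra k is the
#' product of all upstream joint transforms, as 4x4 homogeneous matrices.
#'
#' @param chain a `column_chain`.
#' @param angles data frame with columns `segment` (index), `axis`
#'   (`"x"/"y"/"z"`), `angle` (degrees); joints absent from the table stay
#'   neutral.
#' @return A list of 4x4 matrices, one per vertebra (length `n_segments + 1`).
#' @export
chain_poses <- function(chain, angles = NULL) {
  n <- length(chain$segments)
  poses <- vector("list", n + 1L)
  poses[[1L]] <- diag(4)
  for (k in seq_len(n)) {
    seg <- chain$segments[[k]]
    Tk <- diag(4)
    if (!is.null(angles)) {
      rows <- which(angles$segment == k)
      for (r in rows) {
        R <- rotation_matrix(seg$frame[[paste0(angles$axis[r], "_axis")]],
                             angles$angle[r])
        M <- diag(4)
        M[1:3, 1:3] <- R
        M[1:3, 4] <- seg$frame$cor - R %*% seg$frame$cor
        Tk <- Tk %*% M
      }
    }
    poses[[k + 1L]] <- poses[[k]] %*% Tk
  }
  names(poses) <- vapply(seq_len(n + 1L), function(k) {
    if (k <= n) chain$vertebra_ids[[k]][1] else chain$vertebra_ids[[n]][2]
  }, "")
  poses
}

#' Export / import chain poses
#'
#' Poses are stored as JSON: a named list of flattened (row-major) 4x4
#' matrices. Re-reading reproduces the poses exactly.
#'
#' @param poses list of 4x4 matrices as from [chain_poses()].
#' @param path JSON file path.
#' @return `write_chain_poses` returns `path` invisibly; `read_chain_poses`
#'   the list of matrices.
#' @export
write_chain_poses <- function(poses, path) {
  jsonlite::write_json(lapply(poses, function(m) as.numeric(t(m))), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_chain_poses
#' @export
read_chain_poses <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE),
         function(v) matrix(v, 4, 4, byrow = TRUE))
}
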