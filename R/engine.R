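#' Bending configuration
#'
#' Collects the tunable parameters of a digital bending experiment.
#'
#' @param increment probe step in degrees; motion is probed at integer
#'   multiples of this (default 0.5, the half-degree protocol).
#' @param max_angle cap in degrees (default 45); must be a multiple of
#'   `increment`. Directions reaching it unviolated report `max-angle`.
#' @param intersection_threshold permitted boolean overlap, as a fraction of
#'   mean vertebral surface area (default 0.005; 0 forbids any overlap).
#' @param zyg_bounds length-2 strain bounds `(lower, upper)` for the
#'   zygapophyseal pair; motion stops below `lower` (disarticulation, typical
#'   in ventroflexion) or above `upper` (overlap, typical in dorsiflexion).
#'   Default `c(-0.5, 0.5)`, the ~50% strain model.
#' @param centrum_bounds length-2 strain bounds for the four centrum pairs
#'   (compression below `lower`, tension above `upper`). Default `c(-0.5, 0.5)`.
#' @param translation_fraction total translation-relief budget as a fraction
#'   of `sqrt(mean area)`; 0 (default) disables relief. When a probe angle is
#'   stopped only by intersection and budget remains, the posterior vertebra
#'   is shifted once toward the bending side and the same angle re-tested.
#' @param constraints subset of `c("intersection", "zyg", "centrum")` to
#'   enforce; an empty vector runs unconstrained to `max_angle`.
#' @param intersection_measure `"surface_area"` (default) compares the
#'   intersection solid's surface area against `threshold * mean_area`;
#'   `"volume"` compares its volume against `threshold * mean_area^1.5`.
#' @param voxel_pitch optional voxel size for the fallback boolean backend.
#' @param bilateral_zyg evaluate the zygapophyseal strain on both sides if a
#'   right-side pair were supplied; off by default (single left pair).
#' @return An object of class `bending_config`.
#' @export
bending_config <- function(increment = 0.5, max_angle = 45,
                           intersection_threshold = 0.005,
                           zyg_bounds = c(-0.5, 0.5),
                           centrum_bounds = c(-0.5, 0.5),
                           translation_fraction = 0,
                           constraints = c("intersection", "zyg", "centrum"),
                           intersection_measure = c("surface_area", "volume"),
                           voxel_pitch = NULL,
                           bilateral_zyg = FALSE) {
  stopifnot(increment > 0, max_angle > 0, translation_fraction >= 0,
            intersection_threshold >= 0)
  if (abs(max_angle / increment - round(max_angle / increment)) > 1e-9)
    stop("max_angle must be an integer multiple of increment")
  constraints <- as.character(constraints)
  if (length(constraints) &&
      !all(constraints %in% c("intersection", "zyg", "centrum")))
    stop("constraints must be a subset of intersection, zyg, centrum")
  if ("zyg" %in% constraints && !(zyg_bounds[1] < 0 && zyg_bounds[2] > 0))
    stop("zyg_bounds must satisfy lower < 0 < upper")
  if ("centrum" %in% constraints &&
      !(centrum_bounds[1] < 0 && centrum_bounds[2] > 0))
    stop("centrum_bounds must satisfy lower < 0 < upper")
  structure(list(increment = increment, max_angle = max_angle,
                 intersection_threshold = intersection_threshold,
                 zyg_bounds = zyg_bounds, centrum_bounds = centrum_bounds,
                 translation_fraction = translation_fraction,
                 constraints = constraints,
                 intersection_measure = match.arg(intersection_measure),
                 voxel_pitch = voxel_pitch, bilateral_zyg = bilateral_zyg),
            class = "bending_config")
}

#' @export
print.bending_config <- function(x, ...) {
  cat("bending_config\n")
  cat(sprintf("  increment %.3g deg, cap %.3g deg\n", x$increment, x$max_angle))
  cat(sprintf("  constraints: %s\n",
              if (length(x$constraints)) paste(x$constraints, collapse = ", ")
              else "(none)"))
  cat(sprintf("  intersection threshold %.4g of mean area (%s)\n",
              x$intersection_threshold, x$intersection_measure))
  cat(sprintf("  zyg bounds [%.3g, %.3g], centrum bounds [%.3g, %.3g]\n",
              x$zyg_bounds[1], x$zyg_bounds[2],
              x$centrum_bounds[1], x$centrum_bounds[2]))
  cat(sprintf("  translation budget %.4g of sqrt area\n", x$translation_fraction))
  invisible(x)
}

# Bending directions mapped to frame axes and signs. Convention (documented,
# right-handed frame with x caudal, y dorsal, z to the animal's left):
# +z closes the gap dorsally (dorsiflexion); -y closes it on the left side
# (left lateroflexion); +x rolls the dorsal side leftward (left axial).
DIRECTION_TABLE <- data.frame(
  direction = c("dorsiflexion", "ventroflexion", "left-lateral",
                "right-lateral", "left-axial", "right-axial"),
  axis = c("z", "z", "y", "y", "x", "x"),
  sign = c(1, -1, -1, 1, 1, -1),
  stringsAsFactors = FALSE)

#' Bending directions
#'
#' The six bending directions evaluated by [orom()].
#' @export
BENDING_DIRECTIONS <- DIRECTION_TABLE$direction

# Translation-relief unit vector: perpendicular shift toward the bending side
# in the plane of bending; none exists for axial twist.
relief_direction <- function(segment, direction) {
  f <- segment$frame
  switch(direction,
         "dorsiflexion"  = f$y_axis,
         "ventroflexion" = -f$y_axis,
         "left-lateral"  = f$z_axis,
         "right-lateral" = -f$z_axis,
         NULL)
}

# A rigid pose of the posterior body: rotation about the COR plus a world
# translation (the relief shift), composed fresh from neutral.
segment_pose <- function(segment, axis, angle, translation = c(0, 0, 0)) {
  structure(list(rotation = rotation_matrix(segment$frame[[paste0(axis, "_axis")]],
                                            angle),
                 translation = translation, center = segment$frame$cor,
                 axis = axis, angle = angle), class = "rigid_pose")
}

posed_posterior <- function(segment, pose) {
  transform_mesh(segment$posterior, rotation = pose$rotation,
                 translation = pose$translation, center = pose$center)
}

posed_landmarks <- function(segment, pose) {
  lmk <- unclass(segment$landmarks)
  lmk[POSTERIOR_LANDMARKS, ] <-
    apply_rigid(lmk[POSTERIOR_LANDMARKS, , drop = FALSE], pose$rotation,
                pose$translation, center = pose$center)
  lmk
}

constraint_status <- function(violated, labels, measures) {
  structure(list(violated = violated,
                 labels = if (violated) labels else character(0),
                 measures = measures), class = "constraint_status")
}

#' Evaluate the bony-intersection constraint
#'
#' @param segment a `motion_segment`.
#' @param pose a rigid pose of the posterior body (internal class; produced by
#'   the engine).
#' @param threshold permitted overlap fraction of mean vertebral area.
#' @param measure `"surface_area"` or `"volume"` (see [bending_config()]).
#' @param pitch optional voxel pitch for the fallback backend.
#' @return A `constraint_status` with the measured intersection area (and
#'   volume) in `measures`.
#' @export
eval_intersection <- function(segment, pose, threshold,
                              measure = "surface_area", pitch = NULL) {
  post <- posed_posterior(segment, pose)
  bi <- boolean_intersection(segment$anterior, post, pitch = pitch)
  val <- if (measure == "volume") bi$volume else bi$area
  ref <- if (measure == "volume") segment$mean_area^1.5 else segment$mean_area
  constraint_status(val > threshold * ref, "intersection",
                    list(intersection_area = bi$area,
                         intersection_volume = bi$volume,
                         approximate = bi$approximate))
}

#' Evaluate the zygapophyseal strain constraint
#'
#' Strain is the relative change of the craniocaudal (frame-x) component of
#' the zygapophyseal landmark separation against its neutral reference:
#' below `bounds[1]` flags `zyg-disarticulation`, above `bounds[2]`
#' `zyg-overlap`.
#'
#' @inheritParams eval_intersection
#' @param bounds length-2 strain bounds.
#' @return A `constraint_status` with `zyg_strain` in `measures`.
#' @export
eval_zyg_strain <- function(segment, pose, bounds) {
  ref <- segment$reference
  if (!ref$zyg_usable) {
    warning("zygapophyseal reference unusable; constraint skipped")
    return(constraint_status(FALSE, character(0), list(zyg_strain = NA_real_)))
  }
  lmk <- posed_landmarks(segment, pose)
  sep <- lmk["zyg_pre_cranial", ] - lmk["zyg_post_caudal", ]
  d <- abs(sum(sep * segment$frame$x_axis))
  s <- (d - ref$zyg_d0) / ref$zyg_d0
  labels <- c(if (s < bounds[1]) "zyg-disarticulation",
              if (s > bounds[2]) "zyg-overlap")
  constraint_status(length(labels) > 0, labels, list(zyg_strain = s))
}

#' Evaluate the centrum strain constraint
#'
#' Each of the four endplate landmark pairs is compared against its neutral
#' Euclidean reference length; any pair above `bounds[2]` flags
#' `centrum-tension`, below `bounds[1]` `centrum-compression`. All four
#' strains are reported.
#'
#' @inheritParams eval_zyg_strain
#' @return A `constraint_status` with `centrum_strains` (named length-4) in
#'   `measures`.
#' @export
eval_centrum_strain <- function(segment, pose, bounds) {
  ref <- segment$reference$centrum_d0
  lmk <- posed_landmarks(segment, pose)
  pairs <- names(ref)
  d <- vapply(pairs, function(p) {
    sqrt(sum((lmk[paste0("post_", p), ] - lmk[paste0("ant_", p), ])^2))
  }, 1)
  s <- (d - ref) / ref
  labels <- c(if (any(s > bounds[2])) "centrum-tension",
              if (any(s < bounds[1])) "centrum-compression")
  constraint_status(length(labels) > 0, labels, list(centrum_strains = s))
}

# Evaluate every enabled constraint at one pose; returns the union status.
eval_constraints <- function(segment, pose, config) {
  labels <- character(0)
  measures <- list()
  if ("intersection" %in% config$constraints) {
    st <- eval_intersection(segment, pose, config$intersection_threshold,
                            measure = config$intersection_measure,
                            pitch = config$voxel_pitch)
    if (st$violated) labels <- c(labels, st$labels)
    measures <- c(measures, st$measures)
  }
  if ("zyg" %in% config$constraints && segment$reference$zyg_usable) {
    st <- eval_zyg_strain(segment, pose, config$zyg_bounds)
    if (st$violated) labels <- c(labels, st$labels)
    measures <- c(measures, st$measures)
  }
  if ("centrum" %in% config$constraints) {
    st <- eval_centrum_strain(segment, pose, config$centrum_bounds)
    if (st$violated) labels <- c(labels, st$labels)
    measures <- c(measures, st$measures)
  }
  constraint_status(length(labels) > 0, labels, measures)
}

#' Bend a motion segment in one direction
#'
#' Probes rotation angles at integer multiples of the configured increment,
#' composed fresh from the neutral pose, until an enabled constraint is
#' violated or the cap is reached. When the only violation at a probe angle
#' is bony intersection and translation budget remains, one relief
#' translation toward the bending side is applied and the same angle
#' re-tested. The reported `stop_angle` is the last non-violating angle (the
#' pose actually attainable); the violating labels are recorded alongside.
#'
#' @param segment a `motion_segment`.
#' @param direction one of [BENDING_DIRECTIONS].
#' @param config a [bending_config()].
#' @return A list of class `direction_result`: `direction`, `stop_angle`
#'   (degrees), `labels` (character; `"max-angle"` when the cap was reached),
#'   `translation_used` (mm), `neutral_violated` (logical).
#' @export
bend_direction <- function(segment, direction, config = bending_config()) {
  row <- DIRECTION_TABLE[DIRECTION_TABLE$direction == direction, ]
  if (nrow(row) != 1L)
    stop("invalid direction '", direction, "'; expected one of: ",
         paste(BENDING_DIRECTIONS, collapse = ", "))
  probe <- function(angle, shift) {
    eval_constraints(segment,
                     segment_pose(segment, row$axis, row$sign * angle, shift),
                     config)
  }
  shift <- c(0, 0, 0)
  used <- 0
  budget <- config$translation_fraction * segment$sqrt_area
  relief_unit <- relief_direction(segment, direction)
  st0 <- probe(0, shift)
  if (st0$violated)
    return(structure(list(direction = direction, stop_angle = 0,
                          labels = st0$labels, translation_used = 0,
                          neutral_violated = TRUE),
                     class = "direction_result"))
  n_steps <- round(config$max_angle / config$increment)
  stop_labels <- "max-angle"
  stop_angle <- config$max_angle
  for (k in seq_len(n_steps)) {
    theta <- k * config$increment
    st <- probe(theta, shift)
    if (st$violated && identical(st$labels, "intersection") &&
        !is.null(relief_unit) && budget - used > 1e-12) {
      step <- budget - used
      st2 <- probe(theta, shift + relief_unit * step)
      if (!st2$violated) {
        shift <- shift + relief_unit * step
        used <- used + step
        next
      }
      st <- st2
    }
    if (st$violated) {
      stop_angle <- (k - 1L) * config$increment
      stop_labels <- st$labels
      break
    }
  }
  structure(list(direction = direction, stop_angle = stop_angle,
                 labels = stop_labels, translation_used = used,
                 neutral_violated = FALSE), class = "direction_result")
}

#' Estimate osteological range of motion for a motion segment
#'
#' The main fitting function: runs the constrained digital bending experiment
#' in all six directions (dorsiflexion, ventroflexion, left/right
#' lateroflexion, left/right axial rotation) and returns a classed result
#' with the stop angle and triggering constraint per direction. The engine is
#' fully deterministic.
#'
#' @param segment a `motion_segment` (see [build_segment()]).
#' @param config a [bending_config()].
#' @return An object of class `orom_fit` with components `results` (list of
#'   `direction_result`), `table` (result data frame), `aggregated`
#'   (lateral/sagittal/axial totals, see [aggregate_rom()]), `segment_id`,
#'   and `config`. Supported methods: `print`, `summary`, `coef`, `plot`,
#'   `as.data.frame`.
#' @examples
#' seg <- block_segment()$segment
#' fit <- orom(seg, bending_config(constraints = "intersection"))
#' coef(fit)
#' @export
orom <- function(segment, config = bending_config()) {
  stopifnot(inherits(segment, "motion_segment"),
            inherits(config, "bending_config"))
  results <- lapply(BENDING_DIRECTIONS, function(d)
    bend_direction(segment, d, config))
  names(results) <- BENDING_DIRECTIONS
  tab <- data.frame(
    segment_id = segment$segment_id,
    direction = BENDING_DIRECTIONS,
    stop_angle = vapply(results, `[[`, 1, "stop_angle"),
    constraint = vapply(results, function(r) paste(r$labels, collapse = ";"), ""),
    run_variant = "base",
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(results = results, table = tab,
                 aggregated = aggregate_rom(tab),
                 segment_id = segment$segment_id, config = config),
            class = "orom_fit")
}

#' @export
print.orom_fit <- function(x, ...) {
  cat(sprintf("Osteological range of motion, segment '%s'\n", x$segment_id))
  for (r in x$results)
    cat(sprintf("  %-14s %5.1f deg  [%s]\n", r$direction, r$stop_angle,
                paste(r$labels, collapse = ";")))
  a <- x$aggregated
  cat(sprintf("  totals: lateral %.1f, sagittal %.1f, axial %.1f deg\n",
              a["lateral"], a["sagittal"], a["axial"]))
  invisible(x)
}

#' @export
coef.orom_fit <- function(object, ...) {
  stats::setNames(vapply(object$results, `[[`, 1, "stop_angle"),
                  BENDING_DIRECTIONS)
}

#' @export
summary.orom_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.orom_fit")
}

#' @export
print.summary.orom_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nConfiguration:\n")
  print(f$config)
  tu <- vapply(f$results, `[[`, 1, "translation_used")
  if (any(tu > 0))
    cat(sprintf("Translation relief used: %s mm\n",
                paste(sprintf("%s %.3g", names(tu)[tu > 0], tu[tu > 0]),
                      collapse = ", ")))
  invisible(x)
}

#' @export
plot.orom_fit <- function(x, ...) {
  ang <- coef(x)
  graphics::barplot(ang, las = 2, ylab = "stop angle (degrees)",
                    main = sprintf("oROM: %s", x$segment_id),
                    col = "grey70", ...)
  invisible(x)
}

#' @export
as.data.frame.orom_fit <- function(x, ...) x$table
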