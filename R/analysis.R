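#' Aggregate directional results into per-joint totals
#'
#' Left and right measures are averaged to absorb asymmetry and doubled
#' (equivalently, summed) to give total lateral and axial mobility;
#' dorsiflexion and ventroflexion are summed into total sagittal bending.
#'
#' @param x an `orom_fit` or a result data frame with `direction` and
#'   `stop_angle` columns containing all six directions.
#' @return Named numeric vector `c(lateral, sagittal, axial)` in degrees.
#' @export
aggregate_rom <- function(x) {
  tab <- if (inherits(x, "orom_fit")) x$table else x
  need <- BENDING_DIRECTIONS
  miss <- setdiff(need, tab$direction)
  if (length(miss)) stop("missing direction(s): ", paste(miss, collapse = ", "))
  a <- stats::setNames(tab$stop_angle, tab$direction)[need]
  c(lateral = unname(a["left-lateral"] + a["right-lateral"]),
    sagittal = unname(a["dorsiflexion"] + a["ventroflexion"]),
    axial = unname(a["left-axial"] + a["right-axial"]))
}

#' Tally which constraints stop motion
#'
#' For each direction group (lateroflexion, axial, and dorsiflexion and
#' ventroflexion separately, which tend to differ) computes the fraction of
#' runs stopped by each constraint label across all rows (joints x variants).
#' Rows carrying several simultaneous labels are counted once under the
#' highest-priority label.
#'
#' @param results a result data frame (`direction`, `constraint` columns;
#'   multiple labels joined by `";"`).
#' @param priority label order used to resolve ties, highest first.
#' @return Data frame `(group, constraint, n, proportion)`; proportions sum
#'   to 1 within each group.
#' @export
tally_constraints <- function(results,
                              priority = c("intersection",
                                           "zyg-disarticulation",
                                           "zyg-overlap", "centrum-tension",
                                           "centrum-compression",
                                           "max-angle")) {
  if (nrow(results) == 0L) stop("empty result table")
  group <- c("dorsiflexion" = "dorsiflexion", "ventroflexion" = "ventroflexion",
             "left-lateral" = "lateroflexion", "right-lateral" = "lateroflexion",
             "left-axial" = "axial", "right-axial" = "axial")[results$direction]
  pick <- vapply(strsplit(as.character(results$constraint), ";"), function(l) {
    l <- l[l %in% priority]
    if (!length(l)) return(NA_character_)
    priority[min(match(l, priority))]
  }, "")
  out <- do.call(rbind, lapply(split(pick, group), function(v) {
    tt <- table(factor(v, levels = priority))
    tt <- tt[tt > 0]
    data.frame(constraint = names(tt), n = as.integer(tt),
               proportion = as.numeric(tt) / length(v))
  }))
  out <- data.frame(group = sub("\\.\\d+$", "", rownames(out)), out,
                    row.names = NULL)
  out
}

#' Factorial sensitivity analysis
#'
#' Repeats the full six-direction bending experiment over a low/high
#' factorial in three construction parameters: joint spacing (posterior
#' vertebra translated along frame x by a fraction of neutral mean spacing,
#' references rebuilt), intersection threshold, and strain bounds (applied
#' symmetrically to both the zygapophyseal and centrum constraints). The
#' default levels (+/-10% spacing, 0.25%/0.5% intersection, 45%/55% strain)
#' give the standard 2^3 = 8-variant design; passing `NULL` for a parameter
#' drops it from the factorial.
#'
#' @param segment a `motion_segment`.
#' @param base_config a [bending_config()] supplying everything not varied.
#' @param spacing_levels,intersection_levels,strain_levels length-2 numeric
#'   `(low, high)` vectors, or `NULL` to hold the parameter at its base value.
#' @return An object of class `sensitivity_result`: `table` (long result
#'   rows with variant level columns), `design`, `n_variants`. Rows from
#'   variants whose adjusted neutral pose overlaps are flagged in
#'   `neutral_overlap`.
#' @export
run_sensitivity <- function(segment, base_config = bending_config(),
                            spacing_levels = c(-0.10, 0.10),
                            intersection_levels = c(0.0025, 0.005),
                            strain_levels = c(0.45, 0.55)) {
  lev <- function(x) if (is.null(x)) NA_real_ else x
  design <- expand.grid(
    spacing = lev(spacing_levels), intersection = lev(intersection_levels),
    strain = lev(strain_levels), KEEP.OUT.ATTRS = FALSE)
  design <- unique(design)
  label <- function(v, levels) {
    if (all(is.na(v))) rep("base", length(v))
    else c("low", "high")[match(v, sort(levels))]
  }
  design$spacing_level <- label(design$spacing, spacing_levels)
  design$intersection_level <- label(design$intersection, intersection_levels)
  design$strain_level <- label(design$strain, strain_levels)
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    seg_i <- segment
    overlap <- FALSE
    if (!is.na(d$spacing)) {
      seg_i <- withCallingHandlers(
        adjust_spacing(segment, d$spacing),
        warning = function(w) {
          overlap <<- TRUE
          invokeRestart("muffleWarning")
        })
    }
    cfg <- base_config
    if (!is.na(d$intersection)) cfg$intersection_threshold <- d$intersection
    if (!is.na(d$strain)) {
      cfg$zyg_bounds <- c(-d$strain, d$strain)
      cfg$centrum_bounds <- c(-d$strain, d$strain)
    }
    fit <- orom(seg_i, cfg)
    tab <- fit$table
    tab$run_variant <- paste0("spacing=", d$spacing_level,
                              ",intersection=", d$intersection_level,
                              ",strain=", d$strain_level)
    tab$spacing <- d$spacing_level
    tab$intersection <- d$intersection_level
    tab$strain <- d$strain_level
    tab$neutral_overlap <- overlap
    rows[[i]] <- tab
  }
  structure(list(table = do.call(rbind, rows), design = design,
                 n_variants = nrow(design)), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("sensitivity analysis: %d variants x %d directions\n",
              x$n_variants, length(BENDING_DIRECTIONS)))
  agg <- stats::aggregate(stop_angle ~ run_variant, x$table, mean)
  names(agg)[2] <- "mean_stop_angle"
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Variance decomposition of bending results
#'
#' Sequential (type-I) sums of squares on a balanced factorial of bending
#' outcomes: main effects for joint and direction, their interaction, and
#' each sensitivity parameter coded low/high; on balanced designs all
#' classical SS types coincide. Unbalanced tables are rejected. Used as an
#' effect-size comparison of construction error against biological variation;
#' no p-values are reported.
#'
#' @param table long-format data frame (e.g. `sensitivity_result$table`,
#'   possibly row-bound across joints) with the response and factor columns.
#' @param response response column name (default `"stop_angle"`).
#' @param factors candidate factor columns; those absent or single-level are
#'   dropped. The joint x direction interaction is included when both are
#'   present.
#' @return Data frame `(term, df, ss)` including `Residuals`; `sum(ss)`
#'   equals the total sum of squares.
#' @export
variance_decomposition <- function(table, response = "stop_angle",
                                   factors = c("segment_id", "direction",
                                               "spacing", "intersection",
                                               "strain")) {
  stopifnot(response %in% names(table))
  present <- factors[factors %in% names(table)]
  present <- present[vapply(present,
                            function(f) length(unique(table[[f]])) > 1L, TRUE)]
  if (!length(present)) stop("no factor with more than one level")
  cells <- interaction(table[present], drop = FALSE)
  counts <- table(cells)
  if (length(unique(counts)) != 1L) {
    bad <- names(counts)[counts != stats::median(counts)]
    stop("unbalanced design; offending cell(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  terms <- present
  if (all(c("segment_id", "direction") %in% present))
    terms <- c(terms, "segment_id:direction")
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  dat <- table
  for (f in present) dat[[f]] <- factor(dat[[f]])
  # F statistics are not reported, so the perfect-fit warning is irrelevant
  av <- withCallingHandlers(
    stats::anova(stats::lm(fml, data = dat)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(term = rownames(av), df = av$Df, ss = av$`Sum Sq`,
             row.names = NULL)
}

#' Morphometric joint stiffness proxy
#'
#' Estimates relative intervertebral joint stiffness from vertebral
#' morphometrics and range of motion: the resisting force is proxied by
#' centrum cross-sectional area (height x width) raised to the power 3/2, the
#' sagittal moment arm is the distance from mid-disk to the arch top
#' (height/2 + arch height, where the ligamenta flava and joint capsule
#' resist sagittal bending), the lateral arm half the centrum width (annular
#' ligaments), and
#' \deqn{stiffness = force \times arm / oROM}
#' in mm^4 per degree. The metric is comparative; magnitudes are not
#' physical stiffnesses.
#'
#' `mode = "printed"` reproduces display-style arithmetic: the force proxy is
#' rounded to the nearest integer before the division and the result rounded
#' to an integer. The default `"full"` keeps full precision for analysis.
#'
#' @param centrum_height,centrum_width averaged centrum height and width (mm).
#' @param arch_height vertebral arch height (mm).
#' @param rom_sagittal,rom_lateral total sagittal and lateral oROM (degrees,
#'   > 0).
#' @param mode `"full"` or `"printed"`.
#' @return Data frame with columns `force`, `sagittal`, `lateral` (mm^4 per
#'   degree); vectorised over its inputs.
#' @examples
#' estimate_stiffness(8, 10, 3, 15, 12, mode = "printed")  # force 716: 334, 298
#' @export
estimate_stiffness <- function(centrum_height, centrum_width, arch_height,
                               rom_sagittal, rom_lateral,
                               mode = c("full", "printed")) {
  mode <- match.arg(mode)
  stopifnot(all(centrum_height > 0), all(centrum_width > 0),
            all(arch_height >= 0))
  if (any(rom_sagittal <= 0) || any(rom_lateral <= 0))
    stop("oROM must be positive")
  force <- (centrum_height * centrum_width)^1.5
  if (mode == "printed") force <- round(force)
  sagittal <- force * (centrum_height / 2 + arch_height) / rom_sagittal
  lateral <- force * (centrum_width / 2) / rom_lateral
  if (mode == "printed") {
    sagittal <- round(sagittal)
    lateral <- round(lateral)
  }
  out <- data.frame(force = force, sagittal = sagittal, lateral = lateral)
  attr(out, "mode") <- mode
  out
}

#' Normalise stiffness values across species
#'
#' Stiffness proxies are logged (base 10) and scaled by the species' mean
#' centrum length to remove the size difference. The sequencing of the two
#' operations is ambiguous in common usage, so both compositions are
#' available; both preserve within-species rank order.
#'
#' @param values positive stiffness values.
#' @param mean_centrum_length species-level scaling constant (mm, > 0).
#' @param mode `"log-then-divide"` (default): `log10(value) / length`;
#'   `"divide-then-log"`: `log10(value / length)`.
#' @return Numeric vector with attribute `"mode"` recording the composition.
#' @export
normalize_stiffness <- function(values, mean_centrum_length,
                                mode = c("log-then-divide", "divide-then-log")) {
  mode <- match.arg(mode)
  if (any(values <= 0)) stop("stiffness values must be positive")
  if (mean_centrum_length <= 0) stop("mean centrum length must be positive")
  out <- switch(mode,
                "log-then-divide" = log10(values) / mean_centrum_length,
                "divide-then-log" = log10(values / mean_centrum_length))
  attr(out, "mode") <- mode
  out
}
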