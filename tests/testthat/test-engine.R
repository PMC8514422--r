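test_that("constraint evaluators implement the strain arithmetic", {
  # d0 = 2 via a tabless block with gap 2 (zyg reference = gap)
  seg <- block_segment(gap = 2, zyg_tab_length = 0)$segment
  fr <- seg$frame
  # pure translation of the posterior: x-separation becomes d0 + shift
  shift_pose <- function(dx) vertebend:::segment_pose(seg, "z", 0, c(dx, 0, 0))
  st <- eval_zyg_strain(seg, shift_pose(-1.1), c(-0.5, 0.5))   # d = 0.9
  expect_true(st$violated)
  expect_equal(st$labels, "zyg-disarticulation")
  expect_equal(st$measures$zyg_strain, -0.55)
  st <- eval_zyg_strain(seg, shift_pose(1.2), c(-0.5, 0.5))    # d = 3.2
  expect_equal(st$labels, "zyg-overlap")
  expect_equal(st$measures$zyg_strain, 0.6)
  # +0.5 mm along x from gap 2: all centrum strains +0.25, within bounds
  st <- eval_centrum_strain(seg, shift_pose(0.5), c(-0.5, 0.5))
  expect_false(st$violated)
  expect_equal(unname(st$measures$centrum_strains), rep(0.25, 4))
  st <- eval_centrum_strain(seg, shift_pose(1.1), c(-0.5, 0.5))  # +0.55
  expect_equal(st$labels, "centrum-tension")
  st <- eval_centrum_strain(seg, shift_pose(-1.1), c(-0.5, 0.5)) # -0.55
  expect_equal(st$labels, "centrum-compression")
})

test_that("intersection constraint compares area against threshold fraction", {
  a <- box_mesh(c(-1, 0, 0), c(0, 1, 1))
  b <- box_mesh(c(-0.5, 0, 0), c(0.5, 1, 1))   # overlap area 4, each area 6
  lmk <- landmark_set(rbind(
    zyg_post_caudal = c(0, 1, 0.5), zyg_pre_cranial = c(0.5, 1, 0.5),
    ant_dorsal = c(0, 1, 0.5), ant_ventral = c(0, 0, 0.5),
    ant_left = c(0, 0.5, 1), ant_right = c(0, 0.5, 0),
    post_dorsal = c(0.5, 1, 0.5), post_ventral = c(0.5, 0, 0.5),
    post_left = c(0.5, 0.5, 1), post_right = c(0.5, 0.5, 0)))
  seg <- build_segment(a, b, joint_frame(), lmk)   # mean_area 6
  pose <- vertebend:::segment_pose(seg, "z", 0)
  st <- eval_intersection(seg, pose, threshold = 0.5)   # 4 > 3
  expect_true(st$violated)
  expect_equal(st$measures$intersection_area, 4, tolerance = 1e-9)
  expect_false(eval_intersection(seg, pose, threshold = 0.7)$violated)  # 4 < 4.2
})

test_that("a segment violating at neutral reports zero with its labels", {
  seg <- block_segment(gap = 0.4, zyg_tab_length = 0)$segment
  tight <- bending_config(constraints = "centrum",
                          centrum_bounds = c(-1e-9, 1e-9))
  # any rotation violates; neutral itself is exactly zero strain, so probe 1
  # violates and the stop angle is 0 via the last-non-violating rule
  res <- bend_direction(seg, "dorsiflexion", tight)
  expect_equal(res$stop_angle, 0)
  expect_false(res$neutral_violated)
  # overlapping neutral pose: immediate violation flagged at angle 0
  a <- box_mesh(c(-1, 0, 0), c(0.2, 1, 1))
  b <- box_mesh(c(0, 0, 0), c(1.2, 1, 1))
  lmk <- unclass(seg$landmarks)
  seg2 <- build_segment(a, b, joint_frame(), landmark_set(lmk))
  res2 <- bend_direction(seg2, "dorsiflexion",
                         bending_config(constraints = "intersection",
                                        intersection_threshold = 0))
  expect_equal(res2$stop_angle, 0)
  expect_true(res2$neutral_violated)
  expect_equal(res2$labels, "intersection")
})

test_that("disabling all constraints yields the 45-degree cap everywhere", {
  seg <- block_segment()$segment
  fit <- orom(seg, bending_config(constraints = character(0)))
  expect_equal(unname(coef(fit)), rep(45, 6))
  expect_true(all(vapply(fit$results, function(r)
    identical(r$labels, "max-angle"), TRUE)))
})

test_that("stop angles are integer multiples of the increment within the cap", {
  seg <- block_segment(gap = 1)$segment
  for (inc in c(0.5, 1.5)) {
    fit <- orom(seg, bending_config(increment = inc, max_angle = 45))
    k <- coef(fit) / inc
    expect_equal(k, round(k), tolerance = 1e-9)
    expect_true(all(coef(fit) >= 0 & coef(fit) <= 45))
  }
  expect_error(bending_config(increment = 0.7), "multiple")
})

test_that("mirror-symmetric segments bend equally left and right", {
  seg <- block_segment(bilateral_symmetry = TRUE)$segment
  fit <- orom(seg, bending_config(constraints = "intersection",
                                  intersection_threshold = 0))
  ang <- coef(fit)
  expect_equal(ang[["left-lateral"]], ang[["right-lateral"]])
  expect_equal(ang[["left-axial"]], ang[["right-axial"]])
  # dorsal tabs break dorsoventral symmetry: dorsiflexion stops earlier
  expect_lt(ang[["dorsiflexion"]], ang[["ventroflexion"]])
  # a tabless block is dorsoventrally symmetric too
  flat <- block_segment(zyg_tab_length = 0)$segment
  ang2 <- coef(orom(flat, bending_config(constraints = "intersection",
                                         intersection_threshold = 0)))
  expect_equal(ang2[["dorsiflexion"]], ang2[["ventroflexion"]])
})

test_that("the engine is deterministic", {
  seg <- block_segment()$segment
  f1 <- orom(seg)
  f2 <- orom(seg)
  expect_identical(f1$table, f2$table)
})

test_that("widening any constraint never decreases a stop angle", {
  seg <- block_segment(gap = 1.2)$segment
  base <- bending_config(intersection_threshold = 0.001,
                         zyg_bounds = c(-0.3, 0.3),
                         centrum_bounds = c(-0.3, 0.3))
  a0 <- coef(orom(seg, base))
  for (cfg in list(
    bending_config(intersection_threshold = 0.01,
                   zyg_bounds = c(-0.3, 0.3), centrum_bounds = c(-0.3, 0.3)),
    bending_config(intersection_threshold = 0.001,
                   zyg_bounds = c(-0.6, 0.6), centrum_bounds = c(-0.3, 0.3)),
    bending_config(intersection_threshold = 0.001,
                   zyg_bounds = c(-0.3, 0.3), centrum_bounds = c(-0.6, 0.6)))) {
    expect_true(all(coef(orom(seg, cfg)) >= a0 - 1e-12))
  }
})

test_that("strains at the reported stop angle satisfy the configured bounds", {
  seg <- block_segment()$segment
  cfg <- bending_config()
  fit <- orom(seg, cfg)
  for (r in fit$results) {
    row <- vertebend:::DIRECTION_TABLE[
      vertebend:::DIRECTION_TABLE$direction == r$direction, ]
    pose <- vertebend:::segment_pose(seg, row$axis, row$sign * r$stop_angle)
    expect_false(eval_zyg_strain(seg, pose, cfg$zyg_bounds)$violated)
    expect_false(eval_centrum_strain(seg, pose, cfg$centrum_bounds)$violated)
    expect_false(eval_intersection(seg, pose, cfg$intersection_threshold)$violated)
  }
})

test_that("translation relief extends intersection-limited bending", {
  seg <- block_segment(zyg_tab_length = 0, gap = 0.8)$segment
  no_relief <- bending_config(constraints = "intersection",
                              intersection_threshold = 0)
  relief <- bending_config(constraints = "intersection",
                           intersection_threshold = 0,
                           translation_fraction = 0.05)
  r0 <- bend_direction(seg, "dorsiflexion", no_relief)
  r1 <- bend_direction(seg, "dorsiflexion", relief)
  expect_gte(r1$stop_angle, r0$stop_angle)
  expect_gt(r1$translation_used, 0)
  expect_lte(r1$translation_used, 0.05 * seg$sqrt_area + 1e-12)
  # relief only applies when intersection is the sole violation
  r2 <- bend_direction(seg, "dorsiflexion",
                       bending_config(translation_fraction = 0.05,
                                      centrum_bounds = c(-0.01, 0.01)))
  expect_equal(r2$translation_used, 0)
})

test_that("invalid direction labels are rejected", {
  seg <- block_segment()$segment
  expect_error(bend_direction(seg, "sideways", bending_config()), "invalid direction")
})
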