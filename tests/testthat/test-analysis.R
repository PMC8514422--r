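test_that("directional aggregation obeys the sum identities", {
  tab <- data.frame(direction = BENDING_DIRECTIONS,
                    stop_angle = c(5, 7, 10, 12, 3, 4))
  agg <- aggregate_rom(tab)
  expect_identical(agg[["sagittal"]], 12)   # dorsi 5 + ventro 7
  expect_identical(agg[["lateral"]], 22)    # 10 + 12 = mean x 2
  expect_identical(agg[["axial"]], 7)
  zero <- tab; zero$stop_angle <- 0
  expect_equal(unname(aggregate_rom(zero)), c(0, 0, 0))
  expect_error(aggregate_rom(tab[-1, ]), "missing direction")
})

test_that("constraint tallies are proportions summing to one per group", {
  tab <- data.frame(
    direction = rep("left-lateral", 8),
    constraint = c(rep("intersection", 6), rep("centrum-tension", 2)))
  tl <- tally_constraints(tab)
  expect_equal(tl$proportion[tl$constraint == "intersection"], 0.75)
  expect_equal(tl$proportion[tl$constraint == "centrum-tension"], 0.25)
  # ties resolved once under the priority rule, proportions still sum to 1
  tie <- data.frame(direction = c("dorsiflexion", "dorsiflexion"),
                    constraint = c("intersection;zyg-overlap", "zyg-overlap"))
  tt <- tally_constraints(tie)
  expect_equal(sum(tt$proportion), 1)
  expect_equal(tt$proportion[tt$constraint == "intersection"], 0.5)
  allmax <- data.frame(direction = BENDING_DIRECTIONS, constraint = "max-angle")
  tm <- tally_constraints(allmax)
  expect_true(all(tm$proportion == 1))
  expect_error(tally_constraints(allmax[0, ]), "empty")
})

test_that("the default sensitivity design runs exactly eight variants", {
  seg <- block_segment()$segment
  sens <- run_sensitivity(seg)
  expect_equal(sens$n_variants, 8)
  expect_equal(nrow(sens$table), 8 * 6)
  expect_setequal(unique(sens$table$spacing), c("low", "high"))
  # degenerate designs: no varied parameter -> single base variant
  base_only <- run_sensitivity(seg, spacing_levels = NULL,
                               intersection_levels = NULL,
                               strain_levels = NULL)
  expect_equal(base_only$n_variants, 1)
  one <- run_sensitivity(seg, spacing_levels = NULL,
                         intersection_levels = NULL,
                         strain_levels = c(0.45, 0.55))
  expect_equal(one$n_variants, 2)
})

test_that("holding spacing fixed, looser thresholds dominate stricter ones", {
  seg <- block_segment(gap = 1.2)$segment
  sens <- run_sensitivity(seg)
  tab <- sens$table
  for (sp in c("low", "high")) {
    hi <- tab[tab$spacing == sp & tab$intersection == "high" &
                tab$strain == "high", ]
    lo <- tab[tab$spacing == sp & tab$intersection == "low" &
                tab$strain == "low", ]
    hi <- hi[order(hi$direction), ]
    lo <- lo[order(lo$direction), ]
    expect_true(all(hi$stop_angle >= lo$stop_angle - 1e-12))
  }
})

test_that("sequential sums of squares match the projection oracle", {
  # deterministic balanced 2x3x2 factorial with interaction structure
  grid <- expand.grid(segment_id = c("j1", "j2"),
                      direction = c("a", "b", "c"),
                      strain = c("low", "high"),
                      rep = 1:2)
  set.seed(31)
  grid$stop_angle <- 5 +
    2 * (grid$segment_id == "j2") +
    c(a = 0, b = 1.5, c = 4)[as.character(grid$direction)] +
    0.8 * (grid$strain == "high") +
    1.1 * (grid$segment_id == "j2") * (grid$direction == "c") +
    round(rnorm(nrow(grid)), 3)
  got <- variance_decomposition(grid,
                                factors = c("segment_id", "direction", "strain"))
  want <- ss_projection_oracle("stop_angle", grid,
                               c("segment_id", "direction", "strain",
                                 "segment_id:direction"))
  expect_equal(got$ss, want$ss, tolerance = 1e-6)
  expect_true(all(got$ss >= -1e-10))
  # total SS identity
  tot <- sum((grid$stop_angle - mean(grid$stop_angle))^2)
  expect_equal(sum(got$ss), tot, tolerance = 1e-6)
})

test_that("one binary factor has the closed-form n*delta^2/2 sum of squares", {
  df <- data.frame(strain = rep(c("low", "high"), each = 4),
                   stop_angle = c(1, 1, 1, 1, 3, 3, 3, 3))
  got <- variance_decomposition(df, factors = "strain")
  expect_equal(got$ss[got$term == "strain"], 8)   # 4 * 2^2 / 2
  expect_equal(got$ss[got$term == "Residuals"], 0)
  # constant response: zero everywhere
  const <- df; const$stop_angle <- 2
  g2 <- variance_decomposition(const, factors = "strain")
  expect_true(all(abs(g2$ss) < 1e-12))
})

test_that("unbalanced factorials are rejected, naming the imbalance", {
  df <- data.frame(strain = c("low", "low", "high"),
                   stop_angle = c(1, 2, 3))
  expect_error(variance_decomposition(df, factors = "strain"), "unbalanced")
})

test_that("stiffness reproduces the worked printed-arithmetic chain", {
  st <- estimate_stiffness(8, 10, 3, 15, 12, mode = "printed")
  expect_identical(st$force, 716)
  expect_identical(st$sagittal, 334)
  expect_identical(st$lateral, 298)
  # halved sagittal mobility doubles (then rounds) the stiffness
  st2 <- estimate_stiffness(8, 10, 3, 30, 12, mode = "printed")
  expect_identical(st2$sagittal, 167)
  # small analytic case: force 8, unit arms
  st3 <- estimate_stiffness(2, 2, 0, 8, 8, mode = "printed")
  expect_identical(st3$sagittal, 1)
  expect_identical(st3$lateral, 1)
  expect_error(estimate_stiffness(8, 10, 3, 0, 12), "positive")
})

test_that("stiffness is homogeneous of degree four in linear dimensions", {
  base <- estimate_stiffness(8, 10, 3, 15, 12, mode = "full")
  for (c_scale in c(0.5, 2, 3.7)) {
    scaled <- estimate_stiffness(8 * c_scale, 10 * c_scale, 3 * c_scale,
                                 15, 12, mode = "full")
    expect_equal(scaled$sagittal, base$sagittal * c_scale^4, tolerance = 1e-12)
    expect_equal(scaled$lateral, base$lateral * c_scale^4, tolerance = 1e-12)
  }
})

test_that("stiffness normalisation modes behave as documented", {
  expect_equal(as.numeric(normalize_stiffness(1000, 10)), 0.3)
  expect_equal(as.numeric(normalize_stiffness(10, 10, "divide-then-log")), 0)
  vals <- c(320, 87, 1500, 610)
  for (mode in c("log-then-divide", "divide-then-log")) {
    out <- normalize_stiffness(vals, 23.4, mode)
    expect_identical(order(out), order(vals))     # rank order preserved
    expect_identical(attr(out, "mode"), mode)
  }
  expect_error(normalize_stiffness(c(1, -2), 10), "positive")
})
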