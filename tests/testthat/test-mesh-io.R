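test_that("unit cube reads with correct area and triangle count", {
  cube <- box_mesh(c(0, 0, 0), c(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, path)
  m <- read_mesh(path, units_scale = 1)
  expect_equal(nrow(m$faces), 12)
  expect_equal(surface_area(m), 6, tolerance = 1e-9)
  expect_true(attr(m, "watertight"))
})

test_that("units_scale rescales coordinates and rejects degenerate scales", {
  cube <- box_mesh(c(0, 0, 0), c(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, path)
  m2 <- read_mesh(path, units_scale = 2)
  expect_equal(surface_area(m2), 24, tolerance = 1e-9)  # area scales as x^2
  expect_error(read_mesh(path, units_scale = 0), "degenerate scale")
  expect_error(read_mesh(path, units_scale = -1), "degenerate scale")
})

test_that("meshes round-trip through STL, OBJ, and PLY within 1e-6", {
  seg <- block_segment()$segment
  for (ext in c(".stl", ".obj", ".ply")) {
    path <- withr::local_tempfile(fileext = ext)
    write_mesh(seg$anterior, path)
    back <- read_mesh(path)
    expect_equal(surface_area(back), surface_area(seg$anterior),
                 tolerance = 1e-6)
    # identical vertex sets (STL re-expands per facet, so compare as sets)
    orig <- seg$anterior$vertices[seg$anterior$faces[1, ], ]
    expect_equal(back$vertices[back$faces[1, ], ], orig, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("binary STL is read correctly", {
  cube <- box_mesh(c(0, 0, 0), c(2, 1, 1))
  path <- withr::local_tempfile(fileext = ".stl")
  con <- file(path, "wb")
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(cube$faces)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(cube$faces))) {
    writeBin(numeric(3), con, size = 4, endian = "little")  # normal, unused
    for (j in 1:3)
      writeBin(as.numeric(cube$vertices[cube$faces[i, j], ]), con, size = 4,
               endian = "little")
    writeBin(raw(2), con)
  }
  close(con)
  m <- read_mesh(path)
  expect_equal(surface_area(m), 10, tolerance = 1e-5)
  expect_true(attr(m, "watertight"))
})

test_that("written STL agrees with an independent mesh reader", {
  seg <- block_segment()$segment
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(seg$anterior, path)
  code <- sprintf(
    "import trimesh; m = trimesh.load('%s'); print(m.area, abs(m.volume))",
    path)
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  vals <- as.numeric(strsplit(trimws(out[length(out)]), "\\s+")[[1]])
  expect_equal(vals[1], surface_area(seg$anterior), tolerance = 1e-5)
  expect_equal(vals[2], abs(mesh_volume(seg$anterior)), tolerance = 1e-5)
})

test_that("mesh reader rejects unreadable and empty inputs", {
  expect_error(read_mesh(tempfile(fileext = ".stl")), "not found")
  bad <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid empty", "endsolid empty"), bad)
  expect_error(read_mesh(bad), "no triangles")
})

test_that("landmark files round-trip and enforce the closed schema", {
  bs <- block_segment()
  lmk <- bs$segment$landmarks
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_landmarks(lmk, path)
    back <- read_landmarks(path)
    expect_equal(unclass(back), unclass(lmk), tolerance = 1e-9)
  }
  # missing landmark is named in the error
  df <- data.frame(name = rownames(lmk), x = lmk[, 1], y = lmk[, 2],
                   z = lmk[, 3])
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[df$name != "ant_dorsal", ], path, row.names = FALSE)
  expect_error(read_landmarks(path), "ant_dorsal")
  # duplicates rejected
  utils::write.csv(rbind(df, df[1, ]), path, row.names = FALSE)
  expect_error(read_landmarks(path), "duplicate")
  # non-numeric coordinate rejected
  df2 <- df
  df2$x <- as.character(df2$x)
  df2$x[3] <- "oops"
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
  expect_error(read_landmarks(path), "non-numeric|finite")
})

test_that("generated landmark coordinates equal the analytic positions", {
  bs <- block_segment(gap = 2, centrum_height = 10, centrum_width = 10)
  expect_equal(unclass(bs$segment$landmarks), bs$ground_truth$landmarks,
               tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(bs$segment$landmarks, path)
  expect_equal(unclass(read_landmarks(path)), bs$ground_truth$landmarks,
               tolerance = 1e-9)
})

test_that("result tables round-trip losslessly and reject bad labels", {
  tab <- data.frame(segment_id = "s1",
                    direction = BENDING_DIRECTIONS,
                    stop_angle = c(4.5, 5, 6, 6, 45, 45),
                    constraint = c("zyg-overlap", "zyg-disarticulation",
                                   "centrum-tension", "centrum-tension",
                                   "max-angle", "max-angle"),
                    run_variant = "base", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(tab, path)
  expect_equal(read_results(path), tab)
  empty <- tab[0, ]
  write_results(empty, path)
  expect_equal(nrow(read_results(path)), 0)
  bad <- tab
  bad$constraint[1] <- "not-a-label"
  expect_error(write_results(bad, path), "unknown constraint")
})

test_that("scene files round-trip through write_scene/read_scene", {
  bs <- block_segment()
  dir <- withr::local_tempdir()
  scene_path <- write_scene(bs$segment, dir, segment_id = "blk")
  sc <- read_scene(scene_path)
  expect_equal(sc$segment_id, "blk")
  expect_equal(unclass(sc$landmarks), unclass(bs$segment$landmarks),
               tolerance = 1e-6)
  expect_equal(sc$frame$cor, bs$segment$frame$cor)
  expect_equal(surface_area(sc$anterior), surface_area(bs$segment$anterior),
               tolerance = 1e-6)
})
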