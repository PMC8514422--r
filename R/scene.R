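#' Read a motion-segment scene
#'
#' A scene file is JSON describing one articulated motion segment: mesh paths
#' (relative to the scene file), a joint frame, landmarks (inline or a path to
#' a landmark file), and free-text metadata. YAML is accepted when the yaml
#' package is installed.
#'
#' @param path scene file (`.json`, `.yaml`, `.yml`).
#' @param units_scale scale applied to mesh coordinates on read.
#' @return A list of class `scene_description` with elements `segment_id`,
#'   `anterior`, `posterior` (tri_mesh), `frame`, `landmarks`, `species`,
#'   `joint`.
#' @export
read_scene <- function(path, units_scale = 1) {
  if (!file.exists(path)) stop("scene file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  sc <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML scenes require the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  frame <- joint_frame(cor = as.numeric(sc$frame$cor),
                       x_axis = as.numeric(sc$frame$x_axis),
                       y_axis = as.numeric(sc$frame$y_axis),
                       z_axis = as.numeric(sc$frame$z_axis))
  lmk <- if (is.character(sc$landmarks) && length(sc$landmarks) == 1L) {
    read_landmarks(resolve(sc$landmarks))
  } else {
    m <- do.call(rbind, lapply(sc$landmarks, as.numeric))
    rownames(m) <- names(sc$landmarks)
    landmark_set(m)
  }
  structure(list(
    segment_id = as.character(sc$segment_id %||% "segment"),
    anterior = read_mesh(resolve(sc$anterior_mesh), units_scale),
    posterior = read_mesh(resolve(sc$posterior_mesh), units_scale),
    frame = frame, landmarks = lmk,
    species = sc$species %||% NA_character_,
    joint = sc$joint %||% NA_character_), class = "scene_description")
}

#' Write a motion-segment scene
#'
#' Writes meshes (STL), a landmark CSV, and a scene JSON referencing them with
#' relative paths, into `dir`.
#'
#' @param segment a `motion_segment` (or `scene_description`).
#' @param dir output directory, created if needed.
#' @param segment_id identifier recorded in the scene file.
#' @return Invisibly, the scene JSON path.
#' @export
write_scene <- function(segment, dir, segment_id = segment$segment_id %||% "segment") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(segment$anterior, file.path(dir, "anterior.stl"))
  write_mesh(segment$posterior, file.path(dir, "posterior.stl"))
  write_landmarks(segment$landmarks, file.path(dir, "landmarks.csv"))
  sc <- list(segment_id = segment_id,
             anterior_mesh = "anterior.stl", posterior_mesh = "posterior.stl",
             landmarks = "landmarks.csv",
             frame = list(cor = segment$frame$cor,
                          x_axis = segment$frame$x_axis,
                          y_axis = segment$frame$y_axis,
                          z_axis = segment$frame$z_axis),
             species = segment$species %||% NA,
             joint = segment$joint %||% NA)
  out <- file.path(dir, "scene.json")
  jsonlite::write_json(sc, out, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
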