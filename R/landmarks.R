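#' Landmark schema
#'
#' The ten anatomical landmarks of a motion segment: one pair spanning the
#' left zygapophyseal joint (`zyg_post_caudal` on the anterior vertebra's
#' post-zygapophysis, `zyg_pre_cranial` on the posterior vertebra's
#' pre-zygapophysis) and eight at the dorsal, ventral, left, and right
#' extremes of the two facing centrum endplates (`ant_*` on the anterior
#' vertebra, `post_*` on the posterior). The schema is closed: exactly these
#' names, no more, no fewer.
#'
#' @name landmark_schema
#' @export
LANDMARK_NAMES <- c("zyg_post_caudal", "zyg_pre_cranial",
                    "ant_dorsal", "ant_ventral", "ant_left", "ant_right",
                    "post_dorsal", "post_ventral", "post_left", "post_right")

# Landmarks attached to the anterior (fixed) vs posterior (moving) body.
ANTERIOR_LANDMARKS <- c("zyg_post_caudal", "ant_dorsal", "ant_ventral",
                        "ant_left", "ant_right")
POSTERIOR_LANDMARKS <- c("zyg_pre_cranial", "post_dorsal", "post_ventral",
                         "post_left", "post_right")

#' Construct a landmark set
#'
#' @param coords a 10 x 3 numeric matrix with rownames from the landmark
#'   schema (see [LANDMARK_NAMES]), coordinates in mm.
#' @return An object of class `landmark_set` (named 10 x 3 matrix).
#' @export
landmark_set <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  nm <- rownames(coords)
  if (is.null(nm)) stop("landmarks must be named (rownames)")
  dup <- nm[duplicated(nm)]
  if (length(dup)) stop("duplicate landmark name(s): ", paste(dup, collapse = ", "))
  missing <- setdiff(LANDMARK_NAMES, nm)
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(nm, LANDMARK_NAMES)
  if (length(extra))
    stop("unknown landmark name(s): ", paste(extra, collapse = ", "))
  if (ncol(coords) != 3L || !all(is.finite(coords)))
    stop("landmark coordinates must be finite and three-dimensional")
  coords <- coords[LANDMARK_NAMES, , drop = FALSE]
  colnames(coords) <- c("x", "y", "z")
  structure(coords, class = "landmark_set")
}

#' Read landmarks from CSV or JSON
#'
#' CSV must have columns `name,x,y,z`; JSON maps landmark names to coordinate
#' triples. Exactly the ten schema names are required.
#'
#' @param path file path (`.csv` or `.json`).
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(lst)) lst <- as.list(as.data.frame(t(lst)))
    m <- do.call(rbind, lapply(lst, as.numeric))
    rownames(m) <- names(lst)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "x", "y", "z")
    if (!all(need %in% names(df)))
      stop("landmark CSV must have columns name,x,y,z")
    for (col in c("x", "y", "z"))
      if (!is.numeric(df[[col]]))
        stop("non-numeric coordinate in landmark column '", col, "'")
    m <- as.matrix(df[, c("x", "y", "z")])
    rownames(m) <- df$name
  }
  landmark_set(m)
}

#' Write landmarks to CSV or JSON
#'
#' @param landmarks a `landmark_set`.
#' @param path output path (`.csv` or `.json`).
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(landmarks, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    lst <- lapply(seq_len(nrow(landmarks)), function(i) unname(landmarks[i, ]))
    names(lst) <- rownames(landmarks)
    jsonlite::write_json(lst, path, auto_unbox = FALSE, digits = NA)
  } else {
    df <- data.frame(name = rownames(landmarks), x = landmarks[, 1],
                     y = landmarks[, 2], z = landmarks[, 3])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Result tables
#'
#' Bending results are plain data frames with the fixed column set
#' `segment_id, direction, stop_angle, constraint, run_variant`; multiple
#' simultaneous constraint labels are joined with `";"`.
#'
#' @param table a result data frame.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(table, path) {
  cols <- c("segment_id", "direction", "stop_angle", "constraint", "run_variant")
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("result table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unlist(strsplit(as.character(table$constraint), ";")),
                 CONSTRAINT_LABELS)
  if (length(bad)) stop("unknown constraint label(s): ", paste(bad, collapse = ", "))
  utils::write.csv(table[, c(cols, setdiff(names(table), cols))], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Valid constraint labels
#' @export
CONSTRAINT_LABELS <- c("intersection", "zyg-disarticulation", "zyg-overlap",
                       "centrum-tension", "centrum-compression", "max-angle")
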