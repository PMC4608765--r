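## CSV and TPS readers/writers.  All CSVs are RFC-4180 via readr; the
## TPS dialect (LM=, coordinate pairs, ID= records) is parsed by hand.

#' Read a landmark CSV
#'
#' Expects columns `subject_id`, `landmark`, `x_mm`, `y_mm` (UTF-8,
#' header required), one row per digitized landmark.  Unknown landmark
#' names, non-finite coordinates and duplicate subject-landmark pairs
#' are rejected with the offending location.
#'
#' @param path File path.
#' @param invert_y Set `TRUE` for files digitized in image convention
#'   (y increasing downwards); coordinates are flipped on read.
#' @return A validated landmark tibble.
#' @export
read_landmarks <- function(path, invert_y = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    landmark = readr::col_character(),
    x_mm = readr::col_double(),
    y_mm = readr::col_double())))
  prob <- readr::problems(x)
  if (nrow(prob)) {
    stop(sprintf("parse error in %s at line %d: expected %s", path,
                 prob$row[1], prob$expected[1]), call. = FALSE)
  }
  need <- c("subject_id", "landmark", "x_mm", "y_mm")
  if (!all(need %in% names(x))) {
    stop(sprintf("%s must have header columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (anyNA(x[need])) {
    stop(sprintf("truncated or incomplete row in %s at line %d", path,
                 which(!complete.cases(x[need]))[1] + 1L), call. = FALSE)
  }
  if (invert_y) x$y_mm <- -x$y_mm
  bad <- which(!x$landmark %in% CEPH_LANDMARKS)
  if (length(bad)) {
    stop(sprintf("unknown landmark '%s' in %s at line %d", x$landmark[bad[1]],
                 path, bad[1] + 1L), call. = FALSE)
  }
  validate_landmark_tbl(x)
}

#' Write a landmark CSV
#'
#' @param landmarks Landmark tibble.
#' @param path Output path.
#' @export
write_landmarks <- function(landmarks, path) {
  validate_landmark_tbl(landmarks)
  readr::write_csv(landmarks[, c("subject_id", "landmark", "x_mm", "y_mm")],
                   path)
  invisible(path)
}

#' Read a TPS landmark file
#'
#' Minimal TPS dialect: `LM=<n>` followed by n "x y" coordinate lines,
#' then an optional `ID=<subject>` record; `SCALE=` lines are ignored.
#' TPS files carry no landmark names, so points are mapped positionally
#' onto `landmark_order`.
#'
#' @param path File path.
#' @param landmark_order Names assigned to the coordinate lines, in
#'   order (default S, N, A, B, Go, Pg, Me, with Gn derived later).
#' @param invert_y Flip the y-axis for image-convention files.
#' @return A landmark tibble as from [read_landmarks()].
#' @export
read_tps <- function(path, landmark_order = CEPH_REQUIRED, invert_y = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list(); i <- 1L; spec_n <- 0L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^LM=", ln, ignore.case = TRUE)) {
      n <- as.integer(sub("^LM=", "", ln, ignore.case = TRUE))
      if (is.na(n) || n < 1L) {
        stop(sprintf("bad LM= record at line %d of %s", i, path),
             call. = FALSE)
      }
      if (n != length(landmark_order)) {
        stop(sprintf(
          "line %d of %s: LM=%d but %d landmark names supplied",
          i, path, n, length(landmark_order)), call. = FALSE)
      }
      coords <- matrix(NA_real_, n, 2)
      for (j in seq_len(n)) {
        row <- strsplit(trimws(lines[i + j]), "\\s+")[[1]]
        if (length(row) != 2L || anyNA(suppressWarnings(as.numeric(row)))) {
          stop(sprintf("bad coordinate line %d of %s", i + j, path),
               call. = FALSE)
        }
        coords[j, ] <- as.numeric(row)
      }
      i <- i + n + 1L
      id <- sprintf("TPS%03d", length(out) + 1L)
      while (i <= length(lines) &&
             grepl("^(ID|SCALE)=", trimws(lines[i]), ignore.case = TRUE)) {
        if (grepl("^ID=", trimws(lines[i]), ignore.case = TRUE)) {
          id <- sub("^ID=", "", trimws(lines[i]), ignore.case = TRUE)
        }
        i <- i + 1L
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        subject_id = id, landmark = landmark_order,
        x_mm = coords[, 1], y_mm = if (invert_y) -coords[, 2] else coords[, 2])
    } else if (nzchar(ln)) {
      stop(sprintf("unexpected content at line %d of %s: '%s'", i, path, ln),
           call. = FALSE)
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) stop("no LM= records found in ", path, call. = FALSE)
  validate_landmark_tbl(dplyr::bind_rows(out))
}

#' Read a per-condyle feature CSV
#'
#' Columns: `subject_id`, `side`, then one 0/1 column per flag in the
#' fixed order `r paste(TMJ_FEATURES, collapse = ", ")`.
#'
#' @param path File path.
#' @return A validated feature tibble.
#' @export
read_condyle_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    side = readr::col_character(),
    .default = readr::col_integer()))
  if (anyNA(x)) {
    stop(sprintf("truncated or incomplete row in %s at line %d", path,
                 which(!complete.cases(x))[1] + 1L), call. = FALSE)
  }
  validate_feature_tbl(x)
}

#' Write a per-condyle feature CSV
#' @param features Feature tibble.
#' @param path Output path.
#' @export
write_condyle_features <- function(features, path) {
  validate_feature_tbl(features)
  readr::write_csv(features[, c("subject_id", "side", TMJ_FEATURES)], path)
  invisible(path)
}

#' Write a measurement CSV in report column order
#' @param measurements Measurement tibble (from [ceph_measure()]).
#' @param path Output path.
#' @export
write_measurements <- function(measurements, path) {
  keep <- intersect(c("subject_id", "group", CEPH_VARIABLES),
                    names(measurements))
  readr::write_csv(measurements[, keep], path)
  invisible(path)
}

#' Read a group-label CSV (`subject_id`, `group`)
#' @param path File path.
#' @return A tibble with `subject_id` and `group`.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character()))
  if (!all(c("subject_id", "group") %in% names(x)) || anyNA(x)) {
    stop(path, " must have complete columns subject_id, group", call. = FALSE)
  }
  x
}
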