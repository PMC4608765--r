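## Cephalometric measurement of landmark sets.

validate_landmark_tbl <- function(landmarks) {
  need <- c("subject_id", "landmark", "x_mm", "y_mm")
  if (!all(need %in% names(landmarks))) {
    stop("landmark table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(landmarks$landmark), CEPH_LANDMARKS)
  if (length(bad)) {
    rows <- which(landmarks$landmark %in% bad)
    stop(sprintf("unknown landmark name(s) %s (rows %s); expected one of %s",
                 paste(unique(bad), collapse = ", "),
                 paste(head(rows, 5), collapse = ", "),
                 paste(CEPH_LANDMARKS, collapse = ", ")), call. = FALSE)
  }
  if (!all(is.finite(landmarks$x_mm)) || !all(is.finite(landmarks$y_mm))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  dup <- duplicated(landmarks[, c("subject_id", "landmark")])
  if (any(dup)) {
    d <- landmarks[dup, ]
    stop(sprintf("duplicate landmark %s for subject %s",
                 d$landmark[1], d$subject_id[1]), call. = FALSE)
  }
  invisible(landmarks)
}

landmark_points <- function(landmarks_one) {
  pts <- lapply(seq_len(nrow(landmarks_one)), function(i) {
    c(landmarks_one$x_mm[i], landmarks_one$y_mm[i])
  })
  names(pts) <- landmarks_one$landmark
  pts
}

measure_points <- function(pts, subject_id = NA_character_, rotation_deg = 7) {
  missing <- setdiff(CEPH_REQUIRED, names(pts))
  if (length(missing)) {
    stop(sprintf("subject %s: missing landmark(s) %s", subject_id,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!"Gn" %in% names(pts)) {
    pts$Gn <- derive_gnathion(pts$Me, pts$Pg)
  }
  cs <- build_coordinate_system(pts$S, pts$N, inferior = pts$Me,
                                rotation_deg = rotation_deg)
  loc <- function(p) to_local(p, cs)
  SNA <- angle_at_vertex(pts$N, pts$S, pts$A)
  SNB <- angle_at_vertex(pts$N, pts$S, pts$B)
  MP_SN <- line_angle(pts$Go, pts$Gn, pts$S, pts$N)
  A_to_Y <- abs(loc(pts$A)[["x"]])
  Pg_to_Y <- abs(loc(pts$Pg)[["x"]])
  S_Go <- abs(loc(pts$Go)[["y"]])
  N_Me <- abs(loc(pts$N)[["y"]] - loc(pts$Me)[["y"]])
  if (N_Me < 1e-12) {
    stop(sprintf("subject %s: N-Me is zero, the facial height ratio is undefined",
                 subject_id), call. = FALSE)
  }
  tibble::tibble(subject_id = subject_id, SNA = SNA, SNB = SNB,
                 ANB = SNA - SNB, MP_SN = MP_SN, A_to_Y = A_to_Y,
                 Pg_to_Y = Pg_to_Y, S_Go = S_Go, N_Me = N_Me,
                 ratio = 100 * S_Go / N_Me)
}

#' Compute all cephalometric measurements
#'
#' Computes the nine analysis variables for every subject in a landmark
#' table: the angles SNA, SNB, ANB (= SNA - SNB) and MP-SN, the sagittal
#' distances of points A and Pg to the Y-axis, the posterior (S-Go) and
#' anterior (N-Me) facial heights, and the facial height ratio
#' 100 x S-Go / N-Me (percent).  Distances are reported unsigned, in mm;
#' angles in degrees.  Gnathion is derived as the Me-Pg midpoint when it
#' is not supplied.
#'
#' @param landmarks A data frame with columns `subject_id`, `landmark`,
#'   `x_mm`, `y_mm`, one row per digitized landmark.
#' @param rotation_deg Rotation from the SN line to the X-axis (degrees,
#'   default 7).
#' @return A tibble with one row per subject and columns `subject_id`,
#'   `SNA`, `SNB`, `ANB`, `MP_SN`, `A_to_Y`, `Pg_to_Y`, `S_Go`, `N_Me`,
#'   `ratio`.
#' @examples
#' lm <- construct_landmarks(tibble::tibble(
#'   SNA = 82, SNB = 74, MP_SN = 39, A_to_Y = 61.7, Pg_to_Y = 48.6,
#'   N_Me = 122.2, S_Go = 78))
#' ceph_measure(lm)
#' @export
ceph_measure <- function(landmarks, rotation_deg = 7) {
  validate_landmark_tbl(landmarks)
  ids <- unique(landmarks$subject_id)
  out <- purrr::map(ids, function(id) {
    one <- landmarks[landmarks$subject_id == id, ]
    measure_points(landmark_points(one), subject_id = as.character(id),
                   rotation_deg = rotation_deg)
  })
  dplyr::bind_rows(out)
}
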