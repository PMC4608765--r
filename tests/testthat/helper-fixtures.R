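# Shared fixture builders: everything is generated in code at test time.

free_vars <- c("SNA", "SNB", "MP_SN", "A_to_Y", "Pg_to_Y", "N_Me", "S_Go")

# A hand-laid, anatomically shaped landmark configuration (digitizing
# frame: y up, subject facing +x).
fixture_landmarks <- function(subject_id = "demo") {
  pts <- rbind(S = c(0, 0), N = c(66, 4), A = c(62, -42), B = c(54, -92),
               Go = c(-8, -72), Pg = c(53, -105), Me = c(49, -112))
  tibble::tibble(subject_id = subject_id, landmark = rownames(pts),
                 x_mm = pts[, 1], y_mm = pts[, 2])
}

# Random feasible measurement vector spanning the anatomical range.
random_theta <- function() {
  tibble::tibble(SNA = runif(1, 72, 93), SNB = runif(1, 62, 84),
                 MP_SN = runif(1, 22, 68), A_to_Y = runif(1, 50, 72),
                 Pg_to_Y = runif(1, 32, 60), N_Me = runif(1, 100, 140),
                 S_Go = runif(1, 55, 95))
}

rigid_motion <- function(landmarks, angle_deg = 0, dx = 0, dy = 0,
                         reflect = FALSE) {
  a <- angle_deg * pi / 180
  x <- landmarks$x_mm
  if (reflect) x <- -x
  out <- landmarks
  out$x_mm <- cos(a) * x - sin(a) * landmarks$y_mm + dx
  out$y_mm <- sin(a) * x + cos(a) * landmarks$y_mm + dy
  out
}

# One feature record with the named flags on.
feature_row <- function(subject_id, side, on = character(0)) {
  flags <- setNames(as.list(rep(0L, length(cephtmj:::TMJ_FEATURES))),
                    cephtmj:::TMJ_FEATURES)
  flags[on] <- 1L
  tibble::as_tibble(c(list(subject_id = subject_id, side = side), flags))
}

measurement_cols <- c("SNA", "SNB", "ANB", "MP_SN", "A_to_Y", "Pg_to_Y",
                      "S_Go", "N_Me", "ratio")
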