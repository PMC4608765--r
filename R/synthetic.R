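## Synthetic cohort generation: measurement-space sampling from
## group-conditional normal distributions, and exact inverse geometry
## turning a measurement vector into a landmark configuration.

#' Published group-conditional measurement parameters
#'
#' Mean and SD of each cephalometric variable for the three diagnostic
#' groups (bilaterally normal, bilaterally indeterminate, bilateral
#' osteoarthrosis) of the reference cohort, together with the group
#' sizes 17/19/39.  These are the default distributions emulated by the
#' synthetic generator.
#'
#' @return A tibble with columns `group`, `variable`, `mean`, `sd`.
#' @export
tmjoa_group_params <- function() {
  vals <- list(
    normal = c(SNA = 82.40, SNB = 73.94, ANB = 8.45, MP_SN = 39.11,
               A_to_Y = 61.69, Pg_to_Y = 48.60, S_Go = 78.01,
               N_Me = 122.25, ratio = 63.89),
    indeterminate = c(SNA = 82.80, SNB = 73.14, ANB = 9.66, MP_SN = 42.84,
                      A_to_Y = 60.84, Pg_to_Y = 45.12, S_Go = 74.72,
                      N_Me = 123.74, ratio = 60.37),
    osteoarthrosis = c(SNA = 81.94, SNB = 71.89, ANB = 10.05, MP_SN = 47.97,
                       A_to_Y = 59.56, Pg_to_Y = 41.38, S_Go = 68.33,
                       N_Me = 119.81, ratio = 57.13))
  sds <- list(
    normal = c(SNA = 3.63, SNB = 3.52, ANB = 1.50, MP_SN = 6.73,
               A_to_Y = 3.69, Pg_to_Y = 6.46, S_Go = 6.96,
               N_Me = 8.45, ratio = 4.76),
    indeterminate = c(SNA = 2.33, SNB = 2.74, ANB = 2.71, MP_SN = 4.13,
                      A_to_Y = 4.11, Pg_to_Y = 4.16, S_Go = 6.11,
                      N_Me = 5.91, ratio = 3.88),
    osteoarthrosis = c(SNA = 2.87, SNB = 2.56, ANB = 1.96, MP_SN = 6.53,
                       A_to_Y = 4.71, Pg_to_Y = 5.78, S_Go = 4.63,
                       N_Me = 5.45, ratio = 4.48))
  dplyr::bind_rows(lapply(TMJ_CATEGORIES, function(gr) {
    tibble::tibble(group = gr, variable = names(vals[[gr]]),
                   mean = unname(vals[[gr]]), sd = unname(sds[[gr]]))
  }))
}

default_nuisance <- function() {
  list(sn_mm = NULL,      # sella-nasion distance; NULL = auto-feasible
       nb_mm = 100,       # nasion-to-B distance along the SNB ray
       me_x_mm = 46,      # menton abscissa in the rotated frame
       pg_rise_mm = 8)    # pogonion height above menton (local frame)
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles the group sizes, the per-group measurement distributions, the
#' nuisance geometry parameters, an optional correlation matrix among
#' the seven free measurements, and the sampling mode for the facial
#' height ratio.
#'
#' In `ratio_mode = "derived"` (default) the seven free measurements
#' (SNA, SNB, MP-SN, A-to-Y, Pg-to-Y, N-Me, S-Go) are sampled and the
#' ratio emerges as 100 x S-Go / N-Me; in `"direct"` the ratio is
#' sampled from its own distribution and S-Go is derived as
#' ratio x N-Me / 100.  ANB is always derived as SNA - SNB, never
#' sampled.
#'
#' @param group_sizes Named integer vector of subjects per group
#'   (default the reference sizes 17/19/39).
#' @param params Distribution table as from [tmjoa_group_params()].
#' @param nuisance List of nuisance geometry parameters: `sn_mm`
#'   (sella-nasion distance, `NULL` = auto-feasible, see
#'   [construct_landmarks()]), `nb_mm`, `me_x_mm`, `pg_rise_mm`.
#' @param correlation Optional correlation matrix (default identity)
#'   over the sampled variables, in the order they are sampled.
#' @param ratio_mode `"derived"` or `"direct"` (see above).
#' @param truncate_sd Draws with any |z| beyond this many SDs are
#'   rejected and resampled (default 5), protecting the geometry from
#'   extreme tails.
#' @param rotation_deg X-axis rotation used when building landmarks.
#' @return A list of class `tmj_synth_config`.
#' @export
synthetic_config <- function(group_sizes = c(normal = 17, indeterminate = 19,
                                             osteoarthrosis = 39),
                             params = tmjoa_group_params(),
                             nuisance = default_nuisance(),
                             correlation = NULL,
                             ratio_mode = c("derived", "direct"),
                             truncate_sd = 5,
                             rotation_deg = 7) {
  ratio_mode <- match.arg(ratio_mode)
  if (length(group_sizes) < 2L || any(group_sizes < 2L)) {
    stop("need at least two groups with n >= 2 each", call. = FALSE)
  }
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop("group_sizes must be named", call. = FALSE)
  }
  need <- if (ratio_mode == "derived") CEPH_FREE_VARIABLES else
    c(setdiff(CEPH_FREE_VARIABLES, "S_Go"), "ratio")
  for (gr in names(group_sizes)) {
    sub <- params[params$group == gr, ]
    miss <- setdiff(need, sub$variable)
    if (length(miss)) {
      stop(sprintf("params lack variable(s) %s for group %s",
                   paste(miss, collapse = ", "), gr), call. = FALSE)
    }
    if (any(sub$sd[sub$variable %in% need] <= 0)) {
      stop("all SDs must be > 0", call. = FALSE)
    }
  }
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (nrow(correlation) != length(need) ||
        any(abs(correlation - t(correlation)) > 1e-8) ||
        any(eigen(correlation, symmetric = TRUE,
                  only.values = TRUE)$values < -1e-8)) {
      stop(sprintf(
        "correlation must be a symmetric positive semidefinite %dx%d matrix",
        length(need), length(need)), call. = FALSE)
    }
  }
  nd <- default_nuisance()
  nd[names(nuisance)] <- nuisance
  structure(list(group_sizes = group_sizes, params = params,
                 nuisance = nd, correlation = correlation,
                 ratio_mode = ratio_mode, sampled_vars = need,
                 truncate_sd = truncate_sd, rotation_deg = rotation_deg),
            class = "tmj_synth_config")
}

feasible_row <- function(m, truncate = TRUE, rotation_deg = 7) {
  m$S_Go > 0 && m$N_Me > 0 && m$A_to_Y > 0 && m$Pg_to_Y > 0 &&
    m$MP_SN > 0 && m$MP_SN < 90 &&
    abs(m$MP_SN - rotation_deg) > 1e-4 &&
    m$SNA > rotation_deg + 0.1 && m$SNA < 180 - rotation_deg - 0.1 &&
    m$SNB > 0 && m$SNB < 180
}

#' Sample measurement vectors for one group
#'
#' Draws measurement vectors from the group's (optionally correlated)
#' normal distributions and derives ANB = SNA - SNB and the facial
#' height ratio.  Draws outside the truncation band or violating basic
#' positivity are rejected and resampled; the number of rejections is
#' attached as attribute `"rejected"`.
#'
#' @param config A [synthetic_config()].
#' @param group Group label (must appear in `config`).
#' @param n Number of draws (defaults to the configured group size).
#' @param seed Optional integer seed (local to this call).
#' @return A tibble of `n` draws with the nine measurement columns.
#' @export
sample_measurements <- function(config, group, n = NULL, seed = NULL) {
  stopifnot(inherits(config, "tmj_synth_config"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed, sample_measurements(config, group, n)))
  }
  if (is.null(n)) {
    if (!group %in% names(config$group_sizes)) {
      stop(sprintf("unknown group '%s'", group), call. = FALSE)
    }
    n <- config$group_sizes[[group]]
  }
  vars <- config$sampled_vars
  sub <- config$params[config$params$group == group, ]
  mu <- setNames(sub$mean, sub$variable)[vars]
  sigma <- setNames(sub$sd, sub$variable)[vars]
  L <- if (is.null(config$correlation)) diag(length(vars)) else
    chol(config$correlation + diag(1e-12, length(vars)))

  draw <- function(k) {
    z <- matrix(rnorm(k * length(vars)), k) %*% L
    m <- sweep(sweep(z, 2, sigma, "*"), 2, mu, "+")
    colnames(m) <- vars
    tibble::as_tibble(m)
  }
  finalize <- function(m) {
    if (config$ratio_mode == "direct") {
      m$S_Go <- m$ratio * m$N_Me / 100
    } else {
      m$ratio <- 100 * m$S_Go / m$N_Me
    }
    m$ANB <- m$SNA - m$SNB
    m[, CEPH_VARIABLES]
  }
  ok_row <- function(m, z_ok) {
    full <- finalize(m)
    z_ok & vapply(seq_len(nrow(full)), function(i) {
      feasible_row(full[i, ], rotation_deg = config$rotation_deg)
    }, logical(1))
  }

  out <- NULL; rejected <- 0L; tries <- 0L; need_n <- n
  while (need_n > 0L) {
    tries <- tries + 1L
    if (tries > 200L) {
      stop("sampling rejection rate too high; check the configuration",
           call. = FALSE)
    }
    m <- draw(need_n)
    z <- abs(sweep(sweep(as.matrix(m), 2, mu, "-"), 2, sigma, "/"))
    keep <- ok_row(m, apply(z <= config$truncate_sd, 1, all))
    rejected <- rejected + sum(!keep)
    out <- dplyr::bind_rows(out, finalize(m[keep, , drop = FALSE]))
    need_n <- n - nrow(out)
  }
  attr(out, "rejected") <- rejected
  out
}

## Solve the A point: on the line parallel to the Y-axis at abscissa
## a_to_y, below nasion, such that angle S-N-A equals sna (degrees).
solve_a_point <- function(sna, a_to_y, s, n, x_hat, y_hat, rotation_deg) {
  ceiling_deg <- 90 - rotation_deg
  gap <- a_to_y - sum((n - s) * x_hat)
  if (abs(sna - ceiling_deg) < 1e-4) {
    stop(sprintf(
      "infeasible configuration: SNA = %.4f lies at the geometric ceiling %g deg (A-line parallel asymptote)",
      sna, ceiling_deg), call. = FALSE)
  }
  if (sign(gap) != sign(sna - ceiling_deg)) {
    stop(sprintf(
      "infeasible configuration: SNA = %.2f requires the A-line (A_to_Y = %.2f) on the %s side of nasion's Y-parallel",
      sna, a_to_y, if (sna > ceiling_deg) "anterior" else "posterior"),
      call. = FALSE)
  }
  t_n <- sum((n - s) * y_hat)  # nasion's local ordinate
  a_at <- function(depth) s + a_to_y * x_hat + (t_n - depth) * y_hat
  f <- function(depth) angle_at_vertex(n, s, a_at(depth)) - sna
  lo <- 1e-9; hi <- 10
  while (f(hi) * f(lo) > 0 && hi < 1e8) hi <- hi * 10
  if (f(hi) * f(lo) > 0) {
    stop("infeasible configuration: no A-point depth satisfies SNA",
         call. = FALSE)
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  a <- a_at(root)
  if (abs(angle_at_vertex(n, s, a) - sna) > 1e-9) {
    stop("A-point solve did not converge to tolerance", call. = FALSE)
  }
  a
}

construct_one <- function(m, nuisance, rotation_deg, subject_id) {
  for (v in CEPH_FREE_VARIABLES) {
    if (!is.finite(m[[v]])) {
      stop(sprintf("non-finite measurement %s", v), call. = FALSE)
    }
  }
  if (!feasible_row(m, rotation_deg = rotation_deg)) {
    stop(sprintf(
      "infeasible measurement vector for subject %s (positivity/angle-range constraints)",
      subject_id), call. = FALSE)
  }
  r <- rotation_deg * DEG
  c7 <- cos(r); s7 <- sin(r)
  x_hat <- c(c7, -s7); y_hat <- c(s7, c7)  # inferior rotation, y up

  d <- nuisance$sn_mm
  a <- NULL
  if (is.null(d)) {
    # Auto S-N distance: on the Y-parallel line at A_to_Y, the angle
    # S-N-A only approaches (90 - rotation) deg asymptotically, so a
    # fixed d makes near-ceiling SNA values unreachable (or absurdly
    # deep).  Instead place A at a fixed anatomical depth below nasion's
    # level and solve the posterior/anterior offset of the A-line in
    # closed form; d follows.  All seven measurements remain exact.
    depth <- 45  # mm below nasion's local ordinate, mid-anatomical
    ct <- cos(m$SNA * DEG); st <- sin(m$SNA * DEG)
    denom <- ct^2 - c7^2
    if (abs(denom) < 1e-10) {
      stop(sprintf(
        "infeasible configuration: SNA = %.2f coincides with the axis rotation",
        m$SNA), call. = FALSE)
    }
    offset <- depth * (c7 * s7 - ct * st) / denom  # nasion-line gap, mm
    d <- (m$A_to_Y + offset) / c7
    if (d <= 5) {
      stop("infeasible configuration: no positive S-N distance places A at depth",
           call. = FALSE)
    }
    s <- c(0, 0); n <- c(d, 0)
    a <- m$A_to_Y * x_hat + (d * s7 - depth) * y_hat
    if (abs(angle_at_vertex(n, s, a) - m$SNA) > 1e-9) {
      stop("A-point closed-form placement did not reach tolerance",
           call. = FALSE)
    }
  } else {
    s <- c(0, 0); n <- c(d, 0)
    a <- solve_a_point(m$SNA, m$A_to_Y, s, n, x_hat, y_hat, rotation_deg)
  }
  u_b <- c(-cos(m$SNB * DEG), -sin(m$SNB * DEG))
  b <- n + nuisance$nb_mm * u_b
  y_n <- d * s7
  me <- nuisance$me_x_mm * x_hat + (y_n - m$N_Me) * y_hat
  pg <- m$Pg_to_Y * x_hat + (y_n - m$N_Me + nuisance$pg_rise_mm) * y_hat
  gn <- derive_gnathion(me, pg)
  w <- c(-cos(m$MP_SN * DEG), sin(m$MP_SN * DEG))  # posterior-superior
  denom <- sum(w * y_hat)  # sin(MP_SN - rotation)
  if (abs(denom) < 1e-8) {
    stop("infeasible configuration: mandibular plane parallel to the X-axis",
         call. = FALSE)
  }
  t_go <- (-m$S_Go - sum(gn * y_hat)) / denom
  go <- gn + t_go * w
  if (vnorm(go - gn) < 1e-9) {
    stop("degenerate configuration: Go coincides with Gn", call. = FALSE)
  }
  pts <- rbind(S = s, N = n, A = a, B = b, Go = go, Pg = pg, Me = me, Gn = gn)
  tibble::tibble(subject_id = subject_id, landmark = rownames(pts),
                 x_mm = unname(pts[, 1]), y_mm = unname(pts[, 2]))
}

#' Construct landmark configurations from measurement vectors
#'
#' Inverse of [ceph_measure()]: places sella at the origin and nasion on
#' the +x axis, builds the 7-degree rotated frame, and solves landmark
#' positions so that re-measuring reproduces the seven free measurements
#' (SNA, SNB, MP-SN, A-to-Y, Pg-to-Y, N-Me, S-Go) to within 1e-9.
#' Nuisance parameters (sella-nasion distance, N-B distance, menton
#' abscissa, pogonion rise) fix the remaining degrees of freedom and
#' affect no reported measurement.
#'
#' With `sn_mm = NULL` (default) the sella-nasion distance is chosen in
#' closed form so that point A sits 45 mm below nasion's level on the
#' Y-axis-parallel line at A-to-Y: with a fixed S-N distance the angle
#' S-N-A can only approach `90 - rotation_deg` degrees asymptotically
#' along that line, so near-ceiling SNA values would be unreachable or
#' require an anatomically absurd depth.  A user-supplied `sn_mm` is
#' honored and raises an infeasibility error when unreachable.
#'
#' @param measurements Data frame with the seven free measurement
#'   columns (extra columns ignored); optional `subject_id`.
#' @param nuisance Nuisance geometry list (see [synthetic_config()]).
#' @param rotation_deg X-axis rotation (degrees, default 7).
#' @return A landmark tibble (`subject_id`, `landmark`, `x_mm`, `y_mm`)
#'   suitable for [ceph_measure()].
#' @export
construct_landmarks <- function(measurements, nuisance = default_nuisance(),
                                rotation_deg = 7) {
  measurements <- tibble::as_tibble(measurements)
  miss <- setdiff(CEPH_FREE_VARIABLES, names(measurements))
  if (length(miss)) {
    stop("measurements lack column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  nd <- default_nuisance()
  nd[names(nuisance)] <- nuisance
  ids <- if ("subject_id" %in% names(measurements)) {
    as.character(measurements$subject_id)
  } else {
    sprintf("S%03d", seq_len(nrow(measurements)))
  }
  dplyr::bind_rows(purrr::map(seq_len(nrow(measurements)), function(i) {
    construct_one(measurements[i, ], nd, rotation_deg, ids[i])
  }))
}

#' Generate a full synthetic cohort
#'
#' Draws measurement vectors for every group, constructs a landmark
#' configuration per subject (redrawing a subject's vector if its
#' geometry is infeasible), and returns the landmark table, group
#' labels, and the measurement table.  Fully deterministic under
#' `seed`.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed (local to this call).
#' @return A list of class `tmj_cohort` with tibbles `landmarks`
#'   (long format), `groups` (`subject_id`, `group`) and `measurements`
#'   (subject_id, group, nine variables); attribute `"rejected"` counts
#'   resampled draws.
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "tmj_synth_config"))
  if (!is.null(seed)) return(withr::with_seed(seed, generate_cohort(config)))
  idx <- 0L
  rejected <- 0L
  landmarks <- list(); meas <- list()
  for (gr in names(config$group_sizes)) {
    n <- config$group_sizes[[gr]]
    m <- sample_measurements(config, gr, n)
    rejected <- rejected + attr(m, "rejected")
    rows <- list()
    for (i in seq_len(n)) {
      idx <- idx + 1L
      id <- sprintf("S%03d", idx)
      mi <- m[i, ]
      lm <- NULL
      for (try in seq_len(100L)) {
        lm <- tryCatch(
          construct_one(mi, config$nuisance, config$rotation_deg, id),
          error = function(e) NULL)
        if (!is.null(lm)) break
        rejected <- rejected + 1L
        mi <- sample_measurements(config, gr, 1L)
      }
      if (is.null(lm)) {
        stop(sprintf("could not construct a feasible geometry for %s", id),
             call. = FALSE)
      }
      mi$subject_id <- id
      rows[[i]] <- list(lm = lm, m = mi)
    }
    landmarks[[gr]] <- dplyr::bind_rows(purrr::map(rows, "lm"))
    mm <- dplyr::bind_rows(purrr::map(rows, "m"))
    mm$group <- gr
    meas[[gr]] <- mm
  }
  measurements <- dplyr::bind_rows(meas)
  measurements <- dplyr::select(measurements, "subject_id", "group",
                                dplyr::all_of(CEPH_VARIABLES))
  out <- list(landmarks = dplyr::bind_rows(landmarks),
              groups = measurements[, c("subject_id", "group")],
              measurements = measurements)
  attr(out, "rejected") <- rejected
  structure(out, class = "tmj_cohort")
}

#' @export
print.tmj_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s)\n",
              nrow(x$groups),
              paste(sprintf("%s n=%d", names(table(x$groups$group)),
                            as.integer(table(x$groups$group))),
                    collapse = ", ")))
  invisible(x)
}
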