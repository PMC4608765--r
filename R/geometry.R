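## Planar geometry primitives for cephalometric measurement.  All
## coordinates are in mm in the digitizing plane; by convention y
## increases superiorly and the subject faces the +x direction, but the
## frame construction only assumes that menton marks the inferior side.

DEG <- pi / 180

as_point <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 2L || !all(is.finite(p))) {
    stop(sprintf("%s must be a finite 2-D coordinate", what), call. = FALSE)
  }
  p
}

rotate2 <- function(v, angle_deg) {
  a <- angle_deg * DEG
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

vnorm <- function(v) sqrt(sum(v^2))

#' Construct the rotated cranial-base coordinate system
#'
#' Builds the reference frame used for all linear cephalometric
#' measurements: the X-axis is the sella-nasion (SN) line rotated by
#' `rotation_deg` (7 degrees by default) towards the inferior field, with
#' its origin at sella; the Y-axis is the perpendicular through sella.
#'
#' The inferior side is identified from the `inferior` point (normally
#' menton) so that the construction is invariant under rigid motions and
#' reflections of the digitized tracing.  When `inferior` is `NULL` the
#' conventional orientation (y up, subject facing +x) is assumed and the
#' rotation is clockwise.
#'
#' @param s,n Sella and nasion coordinates (numeric length-2, mm).
#' @param inferior Optional point on the inferior side of the SN line
#'   (typically menton), used to orient the rotation.
#' @param rotation_deg Magnitude of the rotation from SN to the X-axis,
#'   in degrees.
#' @return An object of class `ceph_cs`: a list with `origin`, `x_hat`,
#'   `y_hat` and `rotation_deg`.
#' @examples
#' cs <- build_coordinate_system(c(0, 0), c(100, 0))
#' cs$x_hat  # (cos 7, -sin 7)
#' @export
build_coordinate_system <- function(s, n, inferior = NULL, rotation_deg = 7) {
  s <- as_point(s, "S")
  n <- as_point(n, "N")
  u <- n - s
  if (vnorm(u) < 1e-12) {
    stop("degenerate geometry: S and N coincide, the SN line is undefined",
         call. = FALSE)
  }
  u <- u / vnorm(u)
  sign <- -1  # clockwise = inferior under the y-up, face-+x convention
  if (!is.null(inferior)) {
    p <- as_point(inferior, "inferior")
    cross <- u[1] * (p[2] - s[2]) - u[2] * (p[1] - s[1])
    if (abs(cross) < 1e-9) {
      stop("degenerate geometry: the inferior reference point lies on the SN line",
           call. = FALSE)
    }
    sign <- if (cross < 0) -1 else 1
  }
  x_hat <- rotate2(u, sign * rotation_deg)
  y_hat <- c(-x_hat[2], x_hat[1])
  structure(list(origin = s, x_hat = x_hat, y_hat = y_hat,
                 rotation_deg = rotation_deg, rotation_sign = sign),
            class = "ceph_cs")
}

#' Project points into the cranial-base frame
#'
#' Expresses digitized points in the rotated frame of
#' [build_coordinate_system()].  The map is an isometry: distances are
#' preserved.
#'
#' @param p A length-2 point or an n-by-2 matrix of points (mm).
#' @param cs A `ceph_cs` coordinate system.
#' @return Coordinates in the local frame, same shape as the input.
#' @export
to_local <- function(p, cs) {
  stopifnot(inherits(cs, "ceph_cs"))
  if (is.matrix(p)) {
    d <- sweep(p, 2, cs$origin)
    return(cbind(x = d %*% cs$x_hat, y = d %*% cs$y_hat))
  }
  d <- as_point(p) - cs$origin
  c(x = sum(d * cs$x_hat), y = sum(d * cs$y_hat))
}

#' Unsigned angle at a vertex
#'
#' Interior angle, in degrees, between the rays `vertex -> p1` and
#' `vertex -> p2`.  This is the primitive behind SNA (angle S-N-A) and
#' SNB (angle S-N-B).
#'
#' @param vertex,p1,p2 Points (numeric length-2, mm).
#' @return Angle in degrees, in \[0, 180\].
#' @examples
#' angle_at_vertex(c(0, 0), c(1, 0), c(0, 1))  # 90
#' @export
angle_at_vertex <- function(vertex, p1, p2) {
  vertex <- as_point(vertex, "vertex")
  u1 <- as_point(p1, "p1") - vertex
  u2 <- as_point(p2, "p2") - vertex
  if (vnorm(u1) < 1e-12 || vnorm(u2) < 1e-12) {
    stop("degenerate geometry: ray endpoint coincides with the vertex",
         call. = FALSE)
  }
  cosang <- sum(u1 * u2) / (vnorm(u1) * vnorm(u2))
  acos(min(1, max(-1, cosang))) / DEG
}

#' Angle between two lines
#'
#' Unsigned angle between two undirected lines, each given by a pair of
#' points, as used for the mandibular plane angle MP-SN (mandibular
#' plane Go-Gn against the SN line).
#'
#' @param a1,a2 Two points on the first line.
#' @param b1,b2 Two points on the second line.
#' @param directed If `TRUE`, treat the inputs as directed vectors
#'   `a1 -> a2` and `b1 -> b2` and return the angle in \[0, 180).
#' @return Angle in degrees: \[0, 90\] for undirected lines (default).
#' @examples
#' line_angle(c(0, 0), c(1, 0), c(0, 0), c(1, -1))  # 45
#' @export
line_angle <- function(a1, a2, b1, b2, directed = FALSE) {
  u <- as_point(a2, "a2") - as_point(a1, "a1")
  v <- as_point(b2, "b2") - as_point(b1, "b1")
  if (vnorm(u) < 1e-12 || vnorm(v) < 1e-12) {
    stop("degenerate geometry: line defined by coincident points",
         call. = FALSE)
  }
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  ang <- acos(min(1, max(-1, cosang))) / DEG
  if (directed) ang else min(ang, 180 - ang)
}

#' Derive gnathion from menton and pogonion
#'
#' Gnathion is taken as the midpoint of the menton-pogonion segment.
#'
#' @param me,pg Menton and pogonion coordinates (mm).
#' @return The gnathion coordinate (numeric length-2).
#' @export
derive_gnathion <- function(me, pg) {
  me <- as_point(me, "Me")
  pg <- as_point(pg, "Pg")
  if (vnorm(me - pg) < 1e-12) {
    stop("degenerate geometry: Me and Pg coincide, Gn is undefined",
         call. = FALSE)
  }
  (me + pg) / 2
}

line_intersection <- function(p1, d1, p2, d2) {
  # p1 + t d1 = p2 + s d2; returns NULL when (near) parallel
  det <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(det) < 1e-12) return(NULL)
  rhs <- p2 - p1
  t <- (rhs[1] * d2[2] - rhs[2] * d2[1]) / det
  p1 + t * d1
}

#' Construct gonion from tangent lines and the mandibular contour
#'
#' Gonion is located by bisecting the angle formed by the tangent to the
#' posterior ramus and the tangent to the inferior mandibular border,
#' and taking the contour point closest to the interior bisector ray
#' (the bisector opening towards the contour).  This is an auxiliary
#' construction: the main pipeline accepts a directly digitized Go.
#'
#' @param ramus_tangent,border_tangent Each a list or matrix of two
#'   points defining a tangent line.
#' @param contour A matrix (n x 2) of contour points (mm).
#' @return The selected contour point (numeric length-2).
#' @export
construct_gonion <- function(ramus_tangent, border_tangent, contour) {
  pair <- function(x, what) {
    if (is.list(x)) x <- rbind(as_point(x[[1]], what), as_point(x[[2]], what))
    x <- as.matrix(x)
    if (!all(dim(x) == c(2L, 2L))) {
      stop(sprintf("%s must be two 2-D points", what), call. = FALSE)
    }
    x
  }
  rt <- pair(ramus_tangent, "ramus_tangent")
  bt <- pair(border_tangent, "border_tangent")
  contour <- as.matrix(contour)
  if (nrow(contour) < 1L) stop("empty mandibular contour", call. = FALSE)

  d1 <- rt[2, ] - rt[1, ]; d1 <- d1 / vnorm(d1)
  d2 <- bt[2, ] - bt[1, ]; d2 <- d2 / vnorm(d2)
  apex <- line_intersection(rt[1, ], d1, bt[1, ], d2)
  if (is.null(apex)) {
    stop("parallel tangent lines: the gonial angle has no apex", call. = FALSE)
  }
  # Four candidate bisector directions; pick the one opening towards the
  # contour (largest mean alignment with apex -> contour directions).
  cand <- list(d1 + d2, d1 - d2, -d1 + d2, -d1 - d2)
  cand <- lapply(cand, function(v) v / vnorm(v))
  rel <- sweep(contour, 2, apex)
  rel_n <- rel / pmax(sqrt(rowSums(rel^2)), 1e-12)
  score <- vapply(cand, function(v) mean(rel_n %*% v), numeric(1))
  bis <- cand[[which.max(score)]]

  t_proj <- as.numeric(rel %*% bis)
  if (all(t_proj <= 0)) {
    warning("mandibular contour lies entirely behind the bisector ray; ",
            "returning the contour point nearest the apex")
    return(contour[which.min(rowSums(rel^2)), ])
  }
  t_clamp <- pmax(t_proj, 0)
  foot <- outer(t_clamp, bis)
  dist2 <- rowSums((rel - foot)^2)
  # penalize points behind the ray so ties resolve to the ray proper
  dist2[t_proj <= 0] <- dist2[t_proj <= 0] + rowSums(rel[t_proj <= 0, , drop = FALSE]^2)
  contour[which.min(dist2), ]
}
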