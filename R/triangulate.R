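#' Infer the knee position by triangulation
#'
#' Locates the knee as the intersection of two circles: radius
#' `femur_cm` around the hip and radius `tibia_cm` around the ankle.
#' Of the two intersection points the one on the rostral side of the
#' hip-to-ankle chord is taken by default (the mouse knee lies rostral
#' to that chord). When the circles do not intersect (marker noise
#' stretching or compressing the chain), the knee is placed on the
#' hip-ankle segment with the two distances rescaled proportionally and
#' the frame is flagged degraded rather than failing.
#'
#' @param hip,ankle numeric `c(x, y)` positions in cm.
#' @param segs a [segment_lengths()] object.
#' @param side which circle-intersection branch to take relative to the
#'   hip-to-ankle chord; `"rostral"` (default) or `"caudal"`.
#' @return list with `point` (numeric xy, cm) and `degraded` (logical).
#' @examples
#' infer_knee(c(0, 0), c(5, 0), segment_lengths(3, 4))$point  # (1.8, 2.4)
#' @export
infer_knee <- function(hip, ankle, segs, side = c("rostral", "caudal")) {
  side <- match.arg(side)
  stopifnot(inherits(segs, "segment_lengths"))
  f <- segs$femur_cm; tb <- segs$tibia_cm
  dxy <- ankle - hip
  d2 <- sum(dxy^2)
  d <- sqrt(d2)
  if (!is.finite(d) || d < 1e-12) stop("degenerate triangulation")
  u <- dxy / d
  a <- (f^2 - tb^2 + d2) / (2 * d)
  h2 <- f^2 - a^2
  if (h2 < 0) {
    # circles do not intersect: project onto the chord proportionally
    return(list(point = hip + u * (d * f / (f + tb)), degraded = TRUE))
  }
  h <- sqrt(h2)
  nrm <- c(-u[2], u[1])              # +90 deg rotation of the chord
  if (side == "caudal") nrm <- -nrm
  list(point = hip + a * u + h * nrm, degraded = FALSE)
}

# Vectorized triangulation over n frames; hip/ankle are n x 2 matrices.
triangulate_knee <- function(hip, ankle, segs, side = "rostral") {
  f <- segs$femur_cm; tb <- segs$tibia_cm
  dx <- ankle[, 1] - hip[, 1]
  dy <- ankle[, 2] - hip[, 2]
  d2 <- dx^2 + dy^2
  d <- sqrt(d2)
  bad <- !is.finite(d) | d < 1e-12
  ux <- dx / d; uy <- dy / d
  a <- (f^2 - tb^2 + d2) / (2 * d)
  h2 <- f^2 - a^2
  degraded <- h2 < 0 & !bad
  h <- sqrt(pmax(h2, 0))
  sgn <- if (identical(side, "caudal")) -1 else 1
  kx <- hip[, 1] + a * ux + sgn * h * (-uy)
  ky <- hip[, 2] + a * uy + sgn * h * ux
  prop <- d * f / (f + tb)
  kx[degraded] <- hip[degraded, 1] + ux[degraded] * prop[degraded]
  ky[degraded] <- hip[degraded, 2] + uy[degraded] * prop[degraded]
  kx[bad] <- NA_real_; ky[bad] <- NA_real_
  list(knee = cbind(x = kx, y = ky), degraded = degraded, invalid = bad)
}

# Included angle (degrees) at a vertex between rays toward p1 and p2;
# all arguments are n x 2 matrices.
included_angle <- function(vertex, p1, p2) {
  v1x <- p1[, 1] - vertex[, 1]; v1y <- p1[, 2] - vertex[, 2]
  v2x <- p2[, 1] - vertex[, 1]; v2y <- p2[, 2] - vertex[, 2]
  dot <- v1x * v2x + v1y * v2y
  nn <- sqrt(v1x^2 + v1y^2) * sqrt(v2x^2 + v2y^2)
  acos(pmin(1, pmax(-1, dot / nn))) * 180 / pi
}

#' Compute hindlimb joint angles from marker coordinates
#'
#' Hip angle is the included angle at the hip between the rays toward
#' the iliac crest and the knee; knee angle between the rays toward hip
#' and ankle; ankle angle between the rays toward knee and toe. The
#' knee is inferred by triangulation ([infer_knee()]) whenever a knee
#' marker is absent or missing in a frame. Marker gaps of at most
#' `max_gap` frames are filled by linear interpolation; frames that
#' remain incomplete are flagged missing and excluded downstream.
#'
#' @param markers a [marker_series()].
#' @param segs a [segment_lengths()] object (required when the knee must
#'   be inferred).
#' @param max_gap longest interpolable marker gap, in frames.
#' @param knee_side triangulation branch, see [infer_knee()].
#' @return an object of class `joint_angles` with per-frame `hip_deg`,
#'   `knee_deg`, `ankle_deg`, a `missing` flag and a `degraded` flag.
#' @export
compute_joint_angles <- function(markers, segs = NULL, max_gap = 4L,
                                 knee_side = "rostral") {
  stopifnot(inherits(markers, "marker_series"))
  co <- markers$coords
  for (nm in names(co)) co[[nm]] <- fill_gaps(co[[nm]], max_gap = max_gap)
  get <- function(m) cbind(co[[paste0(m, "_x")]], co[[paste0(m, "_y")]])
  iliac <- get("iliac_crest"); hip <- get("hip")
  ankle <- get("ankle"); toe <- get("toe")
  degraded <- rep(FALSE, nrow(co))
  if (markers$has_knee) {
    knee <- get("knee")
    gap <- is.na(knee[, 1]) | is.na(knee[, 2])
    if (any(gap)) {
      if (is.null(segs)) {
        stop("knee marker has unfillable gaps and no segment lengths given")
      }
      tri <- triangulate_knee(hip[gap, , drop = FALSE],
                              ankle[gap, , drop = FALSE], segs,
                              side = knee_side)
      knee[gap, ] <- tri$knee
      degraded[gap] <- tri$degraded
    }
  } else {
    if (is.null(segs)) stop("segment lengths required to infer the knee")
    tri <- triangulate_knee(hip, ankle, segs, side = knee_side)
    knee <- tri$knee
    degraded <- tri$degraded
  }
  hip_deg <- included_angle(hip, iliac, knee)
  knee_deg <- included_angle(knee, hip, ankle)
  ankle_deg <- included_angle(ankle, knee, toe)
  miss <- is.na(hip_deg) | is.na(knee_deg) | is.na(ankle_deg)
  structure(
    list(frame_rate = markers$frame_rate, time_s = markers$time_s,
         hip_deg = hip_deg, knee_deg = knee_deg, ankle_deg = ankle_deg,
         missing = miss, degraded = degraded),
    class = "joint_angles"
  )
}

#' @export
print.joint_angles <- function(x, ...) {
  cat(sprintf("<joint_angles> %d frames at %g frames/s, %d missing, %d degraded\n",
              length(x$hip_deg), x$frame_rate, sum(x$missing), sum(x$degraded)))
  invisible(x)
}

#' Forward kinematics: markers from a joint-angle pose
#'
#' Builds a consistent sagittal marker set (iliac crest, hip, knee,
#' ankle, toe) from included joint angles and segment lengths. The limb
#' hangs from a fixed hip with the iliac crest at a fixed rostro-dorsal
#' offset; successive segments zig-zag (femur rotated clockwise from
#' the hip-to-iliac-crest ray, tibia counter-clockwise from the
#' knee-to-hip ray, foot clockwise from the ankle-to-knee ray), which is
#' the anatomical flexion pattern. Used by the synthetic generator and
#' as the round-trip oracle for angle recovery.
#'
#' @param hip_deg,knee_deg,ankle_deg included joint angles in degrees,
#'   scalars or equal-length vectors; must lie in (0, 180].
#' @param segs a [segment_lengths()] object.
#' @param hip_pos hip position(s), a length-2 vector or n x 2 matrix.
#' @param crest_cm iliac-crest offset length from the hip, cm.
#' @param crest_angle_deg direction of the hip-to-iliac-crest ray from
#'   the +x (rostral) axis.
#' @param foot_cm ankle-to-toe segment length, cm.
#' @return data frame of marker coordinates (`<marker>_x`, `<marker>_y`).
#' @export
pose_markers <- function(hip_deg, knee_deg, ankle_deg, segs,
                         hip_pos = c(0, 3), crest_cm = 1.2,
                         crest_angle_deg = 60, foot_cm = 0.9) {
  n <- max(length(hip_deg), length(knee_deg), length(ankle_deg))
  hip_deg <- rep_len(hip_deg, n)
  knee_deg <- rep_len(knee_deg, n)
  ankle_deg <- rep_len(ankle_deg, n)
  if (is.null(dim(hip_pos))) hip_pos <- matrix(hip_pos, n, 2, byrow = TRUE)
  rad <- pi / 180
  a0 <- crest_angle_deg * rad
  iliac <- cbind(hip_pos[, 1] + crest_cm * cos(a0),
                 hip_pos[, 2] + crest_cm * sin(a0))
  # femur ray: clockwise rotation of the iliac ray by the hip angle
  a_f <- a0 - hip_deg * rad
  knee <- hip_pos + segs$femur_cm * cbind(cos(a_f), sin(a_f))
  # tibia ray: counter-clockwise from the knee-to-hip ray
  a_kh <- a_f + pi
  a_t <- a_kh + knee_deg * rad
  ankle <- knee + segs$tibia_cm * cbind(cos(a_t), sin(a_t))
  # foot ray: clockwise from the ankle-to-knee ray
  a_ak <- a_t + pi
  a_ft <- a_ak - ankle_deg * rad
  toe <- ankle + foot_cm * cbind(cos(a_ft), sin(a_ft))
  data.frame(
    iliac_crest_x = iliac[, 1], iliac_crest_y = iliac[, 2],
    hip_x = hip_pos[, 1], hip_y = hip_pos[, 2],
    knee_x = knee[, 1], knee_y = knee[, 2],
    ankle_x = ankle[, 1], ankle_y = ankle[, 2],
    toe_x = toe[, 1], toe_y = toe[, 2]
  )
}
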