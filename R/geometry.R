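# Canonical compass directions in the mathematical angle convention:
# 0 = East (right), counterclockwise positive, degrees in [0, 360).
.canonical_angles <- c(E = 0, NE = 45, N = 90, NW = 135,
                       W = 180, SW = 225, S = 270, SE = 315)

# Column order used by the displacement table and throughout reports.
.compass_order <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")

#' Canonical compass directions of the visual field
#'
#' The eight cardinal and intercardinal directions used to place targets on
#' an isoeccentric ring, with their polar angles in the mathematical
#' convention (0 = East/right, counterclockwise positive).
#'
#' @return Named numeric vector of angles in degrees.
#' @export
#' @examples
#' canonical_angles()[["N"]]  # 90
canonical_angles <- function() .canonical_angles

#' Round half away from zero
#'
#' Decimal rounding with ties going up (half-up), matching how printed
#' tables of eccentricities are rounded. Base [round()] rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' A position in the two-dimensional visual field
#'
#' A `field_location` is a point given by a compass label, a polar angle and
#' an eccentricity (radial distance) in degrees of visual angle.  Canonical
#' labels fix the angle exactly (`E` = 0, `NE` = 45, ..., `SE` = 315);
#' any other point carries the label `"custom"`.
#'
#' @param label one of `"N"`, `"NE"`, `"E"`, `"SE"`, `"S"`, `"SW"`, `"W"`,
#'   `"NW"`, or `"custom"`; may be omitted when `angle_deg` is given.
#' @param angle_deg polar angle in degrees (0 = East, counterclockwise
#'   positive); ignored when a canonical `label` is given.
#' @param eccentricity_deg radial distance from the origin in degrees of
#'   visual angle, non-negative.
#' @return An object of class `field_location` with fields `label`,
#'   `angle_deg` (in `[0, 360)`) and `eccentricity_deg`.
#' @export
#' @examples
#' field_location("NE", eccentricity_deg = 6)
#' field_location(angle_deg = 30, eccentricity_deg = 2)
field_location <- function(label = NULL, angle_deg = NULL, eccentricity_deg) {
  if (!is.numeric(eccentricity_deg) || length(eccentricity_deg) != 1L ||
      !is.finite(eccentricity_deg) || eccentricity_deg < 0) {
    stop("'eccentricity_deg' must be a single finite number >= 0")
  }
  if (!is.null(label) && label %in% names(.canonical_angles)) {
    angle <- unname(.canonical_angles[[label]])
  } else if (!is.null(angle_deg)) {
    angle <- angle_deg %% 360
    lab <- .match_canonical(angle)
    label <- if (is.null(label) || label != "custom") {
      if (is.na(lab)) "custom" else lab
    } else "custom"
  } else {
    stop("give either a canonical 'label' or an 'angle_deg'")
  }
  structure(
    list(label = label, angle_deg = angle, eccentricity_deg = eccentricity_deg),
    class = "field_location"
  )
}

# Canonical tag whose angle matches `angle` to within `tol`, else NA.
.match_canonical <- function(angle, tol = 1e-6) {
  d <- abs(((.canonical_angles - angle + 180) %% 360) - 180)
  i <- which(d < tol)
  if (length(i)) names(.canonical_angles)[i[1L]] else NA_character_
}

#' @export
print.field_location <- function(x, ...) {
  cat(sprintf("<field_location> %s: angle %.4g deg, eccentricity %.4g deg\n",
              x$label, x$angle_deg, x$eccentricity_deg))
  invisible(x)
}

#' A planar point in degrees of visual angle
#'
#' Cartesian backbone for all frame transforms: `x` positive toward East
#' (right), `y` positive toward North (up).  The origin is whichever point
#' the caller treats as reference (screen/head center or current fixation).
#'
#' @param x,y offsets in degrees of visual angle.
#' @return An object of class `planar_point` (named numeric of length 2).
#' @export
planar_point <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1L, length(y) == 1L,
            is.finite(x), is.finite(y))
  structure(c(x = x, y = y), class = "planar_point")
}

#' @export
print.planar_point <- function(x, ...) {
  cat(sprintf("<planar_point> (%.4g, %.4g) deg\n", x[["x"]], x[["y"]]))
  invisible(x)
}

#' Convert a field location to Cartesian coordinates
#'
#' @param loc a [field_location()].
#' @return A [planar_point()] with `x = ecc * cos(angle)`,
#'   `y = ecc * sin(angle)`.
#' @export
#' @examples
#' to_cartesian(field_location("NE", eccentricity_deg = 6))
to_cartesian <- function(loc) {
  stopifnot(inherits(loc, "field_location"))
  a <- loc$angle_deg * pi / 180
  planar_point(loc$eccentricity_deg * cos(a), loc$eccentricity_deg * sin(a))
}

#' Convert Cartesian coordinates to a field location
#'
#' Inverse of [to_cartesian()].  The label is set to the canonical compass
#' tag when the angle matches a multiple of 45 degrees to within `tol`,
#' otherwise `"custom"`.  The zero vector maps to angle 0 with label
#' `"custom"`.
#'
#' @param p a [planar_point()] or numeric vector `c(x, y)`.
#' @param tol angular tolerance (degrees) for canonical labelling.
#' @return A [field_location()].
#' @export
from_cartesian <- function(p, tol = 1e-6) {
  stopifnot(is.numeric(p), length(p) == 2L, all(is.finite(p)))
  ecc <- sqrt(sum(p^2))
  if (ecc == 0) {
    return(structure(list(label = "custom", angle_deg = 0,
                          eccentricity_deg = 0),
                     class = "field_location"))
  }
  angle <- (atan2(p[[2L]], p[[1L]]) * 180 / pi) %% 360
  lab <- .match_canonical(angle, tol)
  structure(list(label = if (is.na(lab)) "custom" else lab,
                 angle_deg = angle, eccentricity_deg = ecc),
            class = "field_location")
}

#' Screen position of a retina-fixed direction under head roll
#'
#' Rolling the head about the line of sight by `head_roll_deg`
#' (counterclockwise positive as seen by the observer facing the screen)
#' carries a direction fixed on the retina to a rotated screen direction.
#' In the tilted posture used here (`head_roll_deg = 45`) retinal East maps
#' to screen North-East and retinal South to screen South-East, so the
#' horizontal meridian of the rotated field runs through NE and SW.
#'
#' @param loc_retinal a [field_location()] in retinal coordinates.
#' @param head_roll_deg signed roll in degrees, in `(-180, 180]`.
#' @return The corresponding screen [field_location()].
#' @export
#' @examples
#' apply_head_roll(field_location("E", eccentricity_deg = 6), 45)  # NE
apply_head_roll <- function(loc_retinal, head_roll_deg) {
  stopifnot(inherits(loc_retinal, "field_location"),
            is.numeric(head_roll_deg), length(head_roll_deg) == 1L,
            is.finite(head_roll_deg))
  roll <- ((head_roll_deg + 180) %% 360) - 180  # normalize to (-180, 180]
  if (roll == -180) roll <- 180
  angle <- (loc_retinal$angle_deg + roll) %% 360
  lab <- .match_canonical(angle)
  structure(list(label = if (is.na(lab)) "custom" else lab,
                 angle_deg = angle,
                 eccentricity_deg = loc_retinal$eccentricity_deg),
            class = "field_location")
}

#' Retinal displacement of a target under a fixation shift
#'
#' Vector from the (possibly displaced) fixation point to a target given in
#' screen/head-centered coordinates: its length is the target's retinal
#' eccentricity, its direction the retinal polar angle.
#'
#' @param target a [field_location()] in screen coordinates.
#' @param fixation_offset a [planar_point()] (or `c(x, y)`) giving the
#'   fixation dot's offset from the screen/head center, in degrees.
#' @return A list with `eccentricity_deg` and `angle_deg` (degrees, in
#'   `[0, 360)`; 0 for a zero-length displacement).
#' @export
#' @examples
#' # Target 6 deg West, fixation shifted 4 deg East: 10 deg displacement.
#' retinal_displacement(field_location("W", eccentricity_deg = 6),
#'                      planar_point(4, 0))
retinal_displacement <- function(target, fixation_offset = planar_point(0, 0)) {
  stopifnot(inherits(target, "field_location"),
            is.numeric(fixation_offset), length(fixation_offset) == 2L)
  p <- to_cartesian(target)
  dx <- p[["x"]] - fixation_offset[[1L]]
  dy <- p[["y"]] - fixation_offset[[2L]]
  ecc <- sqrt(dx^2 + dy^2)
  angle <- if (ecc == 0) 0 else (atan2(dy, dx) * 180 / pi) %% 360
  list(eccentricity_deg = ecc, angle_deg = angle)
}

#' Snap an angle to the nearest canonical compass direction
#'
#' Returns, for each angle, the canonical direction (E, NE, N, NW, W, SW,
#' S, SE) whose angle is nearest modulo 360.  Exact midpoints (22.5 degrees
#' from two canonicals) break ties counterclockwise, i.e. toward the larger
#' angle.  This is the default rule for assigning shifted-fixation cells to
#' baseline ring directions; see [build_prediction_maps()] for the
#' alternative keep-original-label strategy.
#'
#' @param angle_deg numeric vector of angles in degrees.
#' @return Character vector of compass tags.
#' @export
#' @examples
#' snap_to_canonical(c(86.73, 0, 67.5))  # "N" "E" "N"
snap_to_canonical <- function(angle_deg) {
  stopifnot(is.numeric(angle_deg), all(is.finite(angle_deg)))
  vapply(angle_deg, function(a) {
    d <- ((.canonical_angles - a + 180) %% 360) - 180  # signed, in (-180, 180]
    ad <- abs(d)
    i <- which(ad - min(ad) < 1e-9)
    if (length(i) > 1L) i <- i[d[i] > 0]  # tie: counterclockwise wins
    names(.canonical_angles)[i[1L]]
  }, character(1L))
}

#' Fixation offset for a cardinal fixation shift
#'
#' @param shift one of `"N"`, `"S"`, `"E"`, `"W"` or `"none"`.
#' @param dist_deg shift magnitude in degrees of visual angle (default 4).
#' @return A [planar_point()].
#' @export
fixation_offset <- function(shift = c("none", "N", "S", "E", "W"),
                            dist_deg = 4) {
  shift <- match.arg(shift)
  dir <- list(none = c(0, 0), N = c(0, 1), S = c(0, -1),
              E = c(1, 0), W = c(-1, 0))[[shift]]
  planar_point(dir[1L] * dist_deg, dir[2L] * dist_deg)
}

#' Retinal eccentricities of ring targets under cardinal fixation shifts
#'
#' Computes, from first principles, the retinal eccentricity of each of the
#' eight canonical targets on a ring when the fixation dot is displaced by
#' a cardinal shift: the Euclidean distance from the shifted fixation point
#' to each target, rounded half-up to two decimals.  With the default 6
#' degree ring and 4 degree shifts every row is a permutation of
#' \{2, 4.25, 4.25, 7.21, 7.21, 9.27, 9.27, 10\}.
#'
#' @param ring_ecc_deg radius of the target ring (degrees; default 6).
#' @param shift_deg magnitude of the fixation shift (degrees; default 4).
#' @param digits decimals kept (half-up rounding; default 2).
#' @return A 4 x 8 numeric matrix; rows `East`, `West`, `North`, `South`
#'   (fixation shifts), columns `N, NE, E, SE, S, SW, W, NW` (targets).
#' @export
#' @examples
#' table1()["East", ]  # 7.21 4.25 2 4.25 7.21 9.27 10 9.27
table1 <- function(ring_ecc_deg = 6, shift_deg = 4, digits = 2) {
  shifts <- c(East = "E", West = "W", North = "N", South = "S")
  out <- matrix(NA_real_, nrow = 4L, ncol = 8L,
                dimnames = list(names(shifts), .compass_order))
  for (s in names(shifts)) {
    off <- fixation_offset(shifts[[s]], shift_deg)
    for (loc in .compass_order) {
      tgt <- field_location(loc, eccentricity_deg = ring_ecc_deg)
      out[s, loc] <- retinal_displacement(tgt, off)$eccentricity_deg
    }
  }
  round_half_up(out, digits)
}
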