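#' Generative parameters of a synthetic observer
#'
#' Defines a performance field anchored to a reference frame.  Accuracy in
#' the 2AFC tilt task is generated as
#' `p = chance + (1 - chance - lapse) * (1 - exp(-(contrast * s / alpha0)^beta))`
#' where the sensitivity scale `s` is the product of an angular modulation
#' (the HVA/VMA shape, see [angular_modulation()]), an eccentricity gain
#' ([eccentricity_gain()]), and an oblique-effect decrement applied when the
#' distractor array is tilted.  The target's angle and eccentricity are
#' taken in the observer's anchoring frame: fixation-relative with rolled
#' axes (retinotopic), head/screen-centered with rolled axes (head-centric),
#' or screen-centered with unrolled axes (allocentric).
#'
#' @param chance guessing rate (0.5 for the two-alternative tilt task).
#' @param lapse asymptotic error rate, in `[0, 0.1]`.
#' @param hva HVA amplitude: fractional accuracy-scale loss at the vertical
#'   meridian relative to horizontal (>= 0).
#' @param vma VMA amplitude: additional loss at the upper vertical meridian
#'   (>= 0); `hva + vma < 1`.
#' @param e2 eccentricity half-saturation constant in degrees (> 0).
#' @param alpha0 Weibull contrast threshold scale at the best location and
#'   the 6 degree reference ring.
#' @param beta Weibull slope (> 0).
#' @param oblique_drop sensitivity-scale decrement when distractors are
#'   tilted, in `[0, 1)`.
#' @param frame anchoring reference frame: `"retinotopic"`,
#'   `"head_centric"` or `"allocentric"`.
#' @param seed integer RNG seed associated with this observer.
#' @return An object of class `observer_params`.
#' @export
#' @examples
#' observer_params(hva = 0.2, vma = 0.07)
observer_params <- function(chance = 0.5, lapse = 0.01,
                            hva = 0.2, vma = 0.07, e2 = 8,
                            alpha0 = 0.05, beta = 3.5,
                            oblique_drop = 0.05,
                            frame = c("retinotopic", "head_centric",
                                      "allocentric"),
                            seed = 1L) {
  frame <- match.arg(frame)
  if (!(chance > 0 && chance < 1)) stop("'chance' must be in (0, 1)")
  if (!(lapse >= 0 && lapse <= 0.1)) stop("'lapse' must be in [0, 0.1]")
  if (hva < 0 || vma < 0) stop("'hva' and 'vma' must be >= 0")
  if (hva + vma >= 1) stop("'hva' + 'vma' must be < 1")
  if (!(e2 > 0)) stop("'e2' must be > 0")
  if (!(alpha0 > 0)) stop("'alpha0' must be > 0")
  if (!(beta > 0)) stop("'beta' must be > 0")
  if (oblique_drop < 0 || oblique_drop >= 1) {
    stop("'oblique_drop' must be in [0, 1)")
  }
  structure(list(chance = chance, lapse = lapse, hva = hva, vma = vma,
                 e2 = e2, alpha0 = alpha0, beta = beta,
                 oblique_drop = oblique_drop, frame = frame,
                 seed = as.integer(seed)),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(paste0("<observer_params> frame=%s hva=%.3g vma=%.3g e2=%.3g ",
                     "alpha0=%.3g beta=%.3g lapse=%.3g oblique_drop=%.3g ",
                     "seed=%d\n"),
              x$frame, x$hva, x$vma, x$e2, x$alpha0, x$beta, x$lapse,
              x$oblique_drop, x$seed))
  invisible(x)
}

#' Angular modulation of the performance field
#'
#' The accuracy-scale profile over retinal polar angle:
#' `m(theta) = 1 - hva * |sin(theta)| - vma * max(sin(theta), 0)`.
#' It equals 1 on the horizontal meridian, `1 - hva` at the lower vertical
#' meridian, `1 - hva - vma` at the upper vertical meridian, and takes
#' strictly intermediate values at intercardinal angles when both
#' amplitudes are positive -- the canonical HVA/VMA field shape.
#'
#' @param params an [observer_params()].
#' @param angle_deg retinal polar angle(s) in degrees.
#' @return Numeric vector of modulation values in `(0, 1]`.
#' @export
#' @examples
#' p <- observer_params(hva = 0.2, vma = 0.1)
#' angular_modulation(p, c(0, 90, 270))  # 1.0 0.7 0.8
angular_modulation <- function(params, angle_deg) {
  stopifnot(inherits(params, "observer_params"))
  if (params$hva + params$vma >= 1) stop("'hva' + 'vma' must be < 1")
  s <- sin(angle_deg * pi / 180)
  1 - params$hva * abs(s) - params$vma * pmax(s, 0)
}

#' Eccentricity gain of the performance field
#'
#' Hyperbolic decline of the sensitivity scale with retinal eccentricity,
#' normalized to 1 at the reference ring:
#' `E(e) = (1 + ref/e2) / (1 + e/e2)`.  Strictly decreasing in `e`.
#'
#' @param params an [observer_params()].
#' @param ecc_deg retinal eccentricity(ies), degrees, >= 0.
#' @param ref_ecc_deg reference eccentricity at which the gain is 1
#'   (default 6, the main target ring).
#' @return Numeric vector of gains.
#' @export
#' @examples
#' eccentricity_gain(observer_params(e2 = 10), c(0, 6))  # 1.6 1.0
eccentricity_gain <- function(params, ecc_deg, ref_ecc_deg = 6) {
  stopifnot(inherits(params, "observer_params"), all(ecc_deg >= 0))
  (1 + ref_ecc_deg / params$e2) / (1 + ecc_deg / params$e2)
}

#' A stimulus specification for one trial
#'
#' @param target_location a [field_location()] in screen coordinates.
#' @param contrast Michelson contrast in `(0, 1]`.
#' @param head_roll_deg signed head roll in degrees (0 = upright).
#' @param fixation_offset a [planar_point()]: fixation dot offset from the
#'   screen/head center.
#' @param distractor_tilt_deg orientation of the distractor array's
#'   reference orientation (0 = upright distractors).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(target_location, contrast, head_roll_deg = 0,
                          fixation_offset = planar_point(0, 0),
                          distractor_tilt_deg = 0) {
  stopifnot(inherits(target_location, "field_location"))
  if (!is.numeric(contrast) || length(contrast) != 1L ||
      !is.finite(contrast) || contrast <= 0 || contrast > 1) {
    stop("'contrast' must be a single value in (0, 1]")
  }
  structure(list(target_location = target_location, contrast = contrast,
                 head_roll_deg = head_roll_deg,
                 fixation_offset = fixation_offset,
                 distractor_tilt_deg = distractor_tilt_deg),
            class = "stimulus_spec")
}

# Target angle/eccentricity in the observer's anchoring frame.  Vectorized
# over target coordinates; tx/ty in screen coordinates (degrees).
.frame_coords <- function(frame, tx, ty, head_roll_deg, fx, fy) {
  if (frame == "retinotopic") {
    dx <- tx - fx
    dy <- ty - fy
    rot <- head_roll_deg
  } else if (frame == "head_centric") {
    dx <- tx
    dy <- ty
    rot <- head_roll_deg
  } else {  # allocentric: screen axes, no roll
    dx <- tx
    dy <- ty
    rot <- 0
  }
  ecc <- sqrt(dx^2 + dy^2)
  angle <- ifelse(ecc == 0, 0, (atan2(dy, dx) * 180 / pi - rot) %% 360)
  list(angle_deg = angle, ecc_deg = ecc)
}

# Vectorized accuracy kernel shared by p_correct() and simulate_trials().
.p_correct_vec <- function(params, tx, ty, contrast, head_roll_deg = 0,
                           fx = 0, fy = 0, tilted = FALSE) {
  if (any(!is.finite(contrast)) || any(contrast <= 0)) {
    stop("contrast must be positive")
  }
  fc <- .frame_coords(params$frame, tx, ty, head_roll_deg, fx, fy)
  s <- angular_modulation(params, fc$angle_deg) *
    eccentricity_gain(params, fc$ecc_deg) *
    (1 - params$oblique_drop * as.numeric(tilted))
  g <- params$chance
  g + (1 - g - params$lapse) *
    (1 - exp(-(contrast * s / params$alpha0)^params$beta))
}

#' Probability of a correct response
#'
#' Evaluates the generative model for one stimulus: the target is expressed
#' in the observer's anchoring frame, the sensitivity scale is the product
#' of the angular modulation, the eccentricity gain and the oblique-effect
#' decrement, and accuracy follows the Weibull psychometric function.  The
#' result lies in `[chance, 1 - lapse]`.
#'
#' @param params an [observer_params()].
#' @param stim a [stimulus_spec()].
#' @return Probability of a correct response.
#' @export
#' @examples
#' obs <- observer_params()
#' p_correct(obs, stimulus_spec(field_location("E", eccentricity_deg = 6),
#'                              contrast = 0.05))
p_correct <- function(params, stim) {
  stopifnot(inherits(params, "observer_params"),
            inherits(stim, "stimulus_spec"))
  p <- to_cartesian(stim$target_location)
  .p_correct_vec(params, p[["x"]], p[["y"]], stim$contrast,
                 stim$head_roll_deg,
                 stim$fixation_offset[[1L]], stim$fixation_offset[[2L]],
                 stim$distractor_tilt_deg != 0)
}

#' Simulate one behavioral trial
#'
#' Draws the correctness of a single trial as a Bernoulli outcome with
#' success probability [p_correct()], together with a gaze deviation from a
#' truncated half-normal noise model.  Uses and advances the R RNG stream;
#' set a seed beforehand for reproducibility.
#'
#' @inheritParams p_correct
#' @param gaze_sd standard deviation of the half-normal gaze deviation
#'   model, degrees.
#' @param gaze_max truncation bound of the gaze deviation, degrees.  The
#'   default (0.3) keeps every simulated trial far below the 1 degree
#'   exclusion criterion, mirroring well-trained fixators.
#' @return A one-row data.frame with `contrast`, `correct` (logical) and
#'   `gaze_dev_deg`.
#' @export
simulate_trial <- function(params, stim, gaze_sd = 0.1, gaze_max = 0.3) {
  p <- p_correct(params, stim)
  data.frame(contrast = stim$contrast,
             correct = stats::runif(1L) < p,
             gaze_dev_deg = min(abs(stats::rnorm(1L, 0, gaze_sd)), gaze_max))
}

#' Simulate responses for a whole design
#'
#' Vectorized trial simulation over a design table (one row per planned
#' trial, as produced by [generate_design()]).  Correctness is Bernoulli
#' with the generative probability of [p_correct()] evaluated per row;
#' gaze deviations come from a truncated half-normal model.
#'
#' @param params an [observer_params()].
#' @param design data.frame with columns `target_location`,
#'   `ring_eccentricity_deg`, `fixation_shift`, `head_roll_deg`,
#'   `distractor_orientation_deg` and `contrast`.
#' @param seed integer seed; when `NULL` the current RNG stream is used.
#' @param gaze_sd,gaze_max gaze-noise model, see [simulate_trial()].
#' @param fixation_dist_deg magnitude of cardinal fixation shifts, degrees.
#' @return The design with `correct` and `gaze_dev_deg` columns appended.
#' @export
simulate_trials <- function(params, design, seed = NULL,
                            gaze_sd = 0.1, gaze_max = 0.3,
                            fixation_dist_deg = 4) {
  stopifnot(inherits(params, "observer_params"), is.data.frame(design))
  need <- c("target_location", "ring_eccentricity_deg", "fixation_shift",
            "head_roll_deg", "distractor_orientation_deg", "contrast")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design lacks columns: ", paste(miss, collapse = ", "))
  if (!is.null(seed)) set.seed(as.integer(seed))

  ang <- .canonical_angles[design$target_location] * pi / 180
  tx <- design$ring_eccentricity_deg * cos(ang)
  ty <- design$ring_eccentricity_deg * sin(ang)
  fx <- ifelse(design$fixation_shift == "E", fixation_dist_deg,
               ifelse(design$fixation_shift == "W", -fixation_dist_deg, 0))
  fy <- ifelse(design$fixation_shift == "N", fixation_dist_deg,
               ifelse(design$fixation_shift == "S", -fixation_dist_deg, 0))
  p <- .p_correct_vec(params, tx, ty, design$contrast,
                      design$head_roll_deg, fx, fy,
                      design$distractor_orientation_deg != 0)
  n <- nrow(design)
  design$correct <- stats::runif(n) < p
  design$gaze_dev_deg <- pmin(abs(stats::rnorm(n, 0, gaze_sd)), gaze_max)
  design
}
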