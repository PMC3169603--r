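#' Describe a session design
#'
#' Builds the structural description of one experimental session, from
#' which [generate_design()] produces a randomized trial list.
#' Three designs are supported:
#' \describe{
#'   \item{exp1}{head-tilt session: 8 blocks of 112 trials; each of the 8
#'     canonical locations appears 14 times per block (112 trials per
#'     location per session); distractor orientation (0 or -45 degrees) is
#'     fixed within a block, 4 blocks each.}
#'   \item{exp2}{fixation-shift session: 4 blocks of 400 trials, 50 trials
#'     of each of the 32 fixation-shift x target-location combinations,
#'     head upright throughout.}
#'   \item{baseline_ring}{one 400-trial block per ring (8 locations x 50
#'     trials), central fixation, head upright; with the default six rings
#'     this is 2,400 trials.}
#' }
#'
#' @param experiment `"exp1"`, `"exp2"` or `"baseline_ring"`.
#' @param head_posture for exp1: `"upright"` or `"tilted"`.
#' @param tilt_roll_deg head roll (degrees) of the tilted posture
#'   (default 45: the roll that carries retinal East to screen North-East).
#' @param ring_ecc_deg target ring radius for exp1/exp2 (default 6).
#' @param rings ring radii for baseline_ring sessions (default the six
#'   rings 2, 4.25, 6, 7.21, 9.27, 10).
#' @param n_blocks number of blocks per session (default 8 for exp1,
#'   4 for exp2; one block per ring for baseline sessions).
#' @param reps_per_block exp1 target appearances per location per block
#'   (default 14).
#' @param n_per_cell exp2 / baseline trials per cell (default 50).
#' @param distractor_levels exp1 distractor orientations in degrees.
#' @param session session index recorded on every trial.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(experiment = c("exp1", "exp2", "baseline_ring"),
                        head_posture = c("upright", "tilted"),
                        tilt_roll_deg = 45,
                        ring_ecc_deg = 6,
                        rings = c(2, 4.25, 6, 7.21, 9.27, 10),
                        n_blocks = NULL, reps_per_block = 14L,
                        n_per_cell = 50L,
                        distractor_levels = c(0, -45),
                        session = 1L) {
  experiment <- match.arg(experiment)
  head_posture <- match.arg(head_posture)
  if (experiment != "exp1") head_posture <- "upright"
  if (is.null(n_blocks)) {
    n_blocks <- if (experiment == "exp2") 4L else 8L
  }
  structure(list(experiment = experiment, head_posture = head_posture,
                 tilt_roll_deg = tilt_roll_deg, ring_ecc_deg = ring_ecc_deg,
                 rings = rings, n_blocks = as.integer(n_blocks),
                 reps_per_block = as.integer(reps_per_block),
                 n_per_cell = as.integer(n_per_cell),
                 distractor_levels = distractor_levels,
                 session = as.integer(session)),
            class = "design_spec")
}

# Balanced CW/CCW tilt assignment for one cell of `n` trials; an odd
# residual trial gets a random direction.
.balanced_tilt <- function(n) {
  half <- n %/% 2L
  tilt <- c(rep("CW", half), rep("CCW", half))
  if (n %% 2L) tilt <- c(tilt, sample(c("CW", "CCW"), 1L))
  sample(tilt)
}

#' Generate a randomized trial list from a design
#'
#' Expands a [design_spec()] into an ordered trial table with exact
#' per-cell counts, block structure, per-cell balanced target tilt
#' directions, and seed-determined randomization of trial order.
#'
#' @param spec a [design_spec()].
#' @param seed integer seed controlling all randomization.
#' @param observer_id identifier written to every row.
#' @return data.frame with one row per planned trial: `observer_id`,
#'   `experiment`, `session`, `block`, `trial`, `head_posture`,
#'   `head_roll_deg`, `distractor_orientation_deg`, `fixation_shift`,
#'   `ring_eccentricity_deg`, `target_location`, `target_tilt_direction`
#'   and `contrast` (NA until assigned).
#' @export
#' @examples
#' d <- generate_design(design_spec("exp2"), seed = 1)
#' nrow(d)  # 1600
generate_design <- function(spec, seed = 1L, observer_id = "obs1") {
  stopifnot(inherits(spec, "design_spec"))
  set.seed(as.integer(seed))
  locs <- .compass_order

  if (spec$experiment == "exp1") {
    if (length(spec$distractor_levels) != 2L) {
      stop("exp1 needs exactly two distractor orientations")
    }
    if (spec$n_blocks %% 2L != 0L) {
      stop("exp1 block count must split evenly over the two distractor ",
           "orientations")
    }
    roll <- if (spec$head_posture == "tilted") spec$tilt_roll_deg else 0
    # distractor orientation fixed within block, alternating
    block_distractor <- rep(spec$distractor_levels,
                            length.out = spec$n_blocks)
    blocks <- lapply(seq_len(spec$n_blocks), function(b) {
      df <- expand.grid(target_location = locs,
                        rep = seq_len(spec$reps_per_block),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      df$target_tilt_direction <- NA_character_
      for (l in locs) {
        df$target_tilt_direction[df$target_location == l] <-
          .balanced_tilt(spec$reps_per_block)
      }
      df <- df[sample.int(nrow(df)), c("target_location",
                                       "target_tilt_direction")]
      df$block <- b
      df$distractor_orientation_deg <- block_distractor[b]
      df
    })
    out <- do.call(rbind, blocks)
    out$fixation_shift <- "none"
    out$ring_eccentricity_deg <- spec$ring_ecc_deg
    out$head_posture <- spec$head_posture
    out$head_roll_deg <- roll
  } else if (spec$experiment == "exp2") {
    shifts <- c("N", "S", "E", "W")
    cells <- expand.grid(fixation_shift = shifts, target_location = locs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n_total <- nrow(cells) * spec$n_per_cell
    if (n_total %% spec$n_blocks != 0L) {
      stop("total exp2 trials (", n_total, ") do not divide evenly into ",
           spec$n_blocks, " blocks")
    }
    out <- cells[rep(seq_len(nrow(cells)), each = spec$n_per_cell), ]
    out$target_tilt_direction <- unlist(
      replicate(nrow(cells), .balanced_tilt(spec$n_per_cell),
                simplify = FALSE))
    out <- out[sample.int(nrow(out)), ]
    out$block <- rep(seq_len(spec$n_blocks),
                     each = n_total / spec$n_blocks)
    out$distractor_orientation_deg <- 0
    out$ring_eccentricity_deg <- spec$ring_ecc_deg
    out$head_posture <- "upright"
    out$head_roll_deg <- 0
  } else {  # baseline_ring
    blocks <- lapply(seq_along(spec$rings), function(b) {
      df <- data.frame(
        target_location = rep(locs, each = spec$n_per_cell),
        stringsAsFactors = FALSE
      )
      df$target_tilt_direction <- unlist(
        replicate(length(locs), .balanced_tilt(spec$n_per_cell),
                  simplify = FALSE))
      df <- df[sample.int(nrow(df)), ]
      df$block <- b
      df$ring_eccentricity_deg <- spec$rings[b]
      df
    })
    out <- do.call(rbind, blocks)
    out$fixation_shift <- "none"
    out$distractor_orientation_deg <- 0
    out$head_posture <- "upright"
    out$head_roll_deg <- 0
  }

  out$observer_id <- observer_id
  out$experiment <- spec$experiment
  out$session <- spec$session
  out$trial <- seq_len(nrow(out))
  out$contrast <- NA_real_
  rownames(out) <- NULL
  out[, c("observer_id", "experiment", "session", "block", "trial",
          "head_posture", "head_roll_deg", "distractor_orientation_deg",
          "fixation_shift", "ring_eccentricity_deg", "target_location",
          "target_tilt_direction", "contrast")]
}

#' Exclude trials with broken fixation
#'
#' Removes trials whose recorded gaze deviation exceeds the criterion
#' (strictly greater than; a deviation of exactly the criterion is kept).
#'
#' @param trials trial table with a `gaze_dev_deg` column.
#' @param max_dev_deg exclusion criterion in degrees (default 1).
#' @return A list: `trials` (kept rows), `n_excluded`, and `by_condition`
#'   (exclusion counts per design condition).
#' @export
filter_fixation <- function(trials, max_dev_deg = 1.0) {
  stopifnot(is.data.frame(trials))
  if (!"gaze_dev_deg" %in% names(trials)) {
    stop("trials lack the 'gaze_dev_deg' column")
  }
  drop <- trials$gaze_dev_deg > max_dev_deg
  cond_keys <- intersect(c("observer_id", "experiment", "head_posture",
                           "distractor_orientation_deg", "fixation_shift"),
                         names(trials))
  by_condition <- if (length(cond_keys)) {
    stats::aggregate(
      data.frame(n_excluded = as.integer(drop), n_total = 1L),
      by = trials[cond_keys], FUN = sum)
  } else NULL
  list(trials = trials[!drop, , drop = FALSE],
       n_excluded = sum(drop),
       by_condition = by_condition)
}

#' Aggregate trials into accuracy cells
#'
#' Counts, proportion correct and the arcsine-square-root transform per
#' cell of the grouping keys.  Cells with zero trials are absent from the
#' result rather than zero-filled.
#'
#' @param trials non-empty trial table with a logical/0-1 `correct` column.
#' @param keys character vector (length >= 1) of grouping columns.
#' @return data.frame with the key columns plus `n_trials`, `n_correct`,
#'   `prop` and `transformed`.
#' @export
#' @examples
#' tr <- data.frame(g = c("a", "a", "a", "a"), correct = c(TRUE, TRUE,
#'                  TRUE, FALSE))
#' aggregate_cells(tr, "g")  # prop 0.75
aggregate_cells <- function(trials, keys) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0L) stop("empty trial table")
  if (length(keys) < 1L) stop("at least one grouping key is required")
  miss <- setdiff(c(keys, "correct"), names(trials))
  if (length(miss)) stop("trials lack columns: ", paste(miss, collapse = ", "))
  n <- stats::aggregate(trials$correct, by = trials[keys], FUN = length)
  s <- stats::aggregate(as.numeric(trials$correct), by = trials[keys],
                        FUN = sum)
  out <- n
  names(out)[ncol(out)] <- "n_trials"
  out$n_correct <- s$x
  out$prop <- out$n_correct / out$n_trials
  out$transformed <- arcsine_transform(out$prop)
  out
}

#' Estimate a condition's contrast threshold on a synthetic observer
#'
#' Runs a QUEST staircase against the generative observer model with
#' targets drawn uniformly over the eight canonical locations of a ring,
#' mirroring thresholding "across all locations" within a condition, and
#' returns the recommended contrast for criterion accuracy.
#'
#' @param params an [observer_params()].
#' @param head_roll_deg,distractor_tilt_deg condition under which the
#'   threshold is estimated.
#' @param ring_ecc_deg target ring radius (default 6).
#' @param n_trials staircase length (default 150).
#' @param prior_mean,prior_sd QUEST prior over log10 threshold.
#' @param criterion target accuracy (default 0.75).
#' @param seed integer seed.
#' @return A list: `contrast` (linear Michelson contrast, capped at 1),
#'   `log_threshold` (posterior mode) and the final `state`.
#' @export
estimate_threshold <- function(params, head_roll_deg = 0,
                               distractor_tilt_deg = 0, ring_ecc_deg = 6,
                               n_trials = 150L,
                               prior_mean = log10(0.05), prior_sd = 0.5,
                               criterion = 0.75, seed = 1L) {
  stopifnot(inherits(params, "observer_params"))
  q <- quest_init(prior_mean, prior_sd, beta = 3.5,
                  gamma = params$chance, delta = params$lapse,
                  criterion = criterion)
  locs <- names(.canonical_angles)
  respond <- function(log_contrast) {
    loc <- sample(locs, 1L)
    ang <- .canonical_angles[[loc]] * pi / 180
    p <- .p_correct_vec(params, ring_ecc_deg * cos(ang),
                        ring_ecc_deg * sin(ang),
                        min(1, 10^log_contrast), head_roll_deg, 0, 0,
                        distractor_tilt_deg != 0)
    stats::runif(1L) < p
  }
  q <- quest_run(q, respond, n_trials, seed = seed)
  list(contrast = min(1, 10^quest_recommend(q)),
       log_threshold = quest_mode(q), state = q)
}

# Draw n reproducible sub-seeds from a master seed without disturbing the
# caller's RNG stream.
.derive_seeds <- function(seed, n) {
  .substream_seeds(seed, n)
}

#' Default pipeline configuration
#'
#' The resolved settings used by [run_exp1()] and [run_exp2()] when a key
#' is not overridden: observer-model parameters (see [observer_params()]),
#' the master `seed`, the tilted-posture roll, ring radii, the contrast
#' policy (`"quest"` for per-condition staircase thresholds, or a fixed
#' numeric contrast), staircase settings, the gaze-noise and exclusion
#' parameters, the direction-matching `snap_rule`, and the bootstrap
#' settings `n_iter` and `k`.
#'
#' @return Named list of defaults.
#' @export
#' @examples
#' names(default_config())
default_config <- function() {
  list(
    n_observers = 4L,
    frame = "retinotopic",
    chance = 0.5, lapse = 0.01,
    hva = 0.2, vma = 0.07, e2 = 8,
    alpha0 = 0.05, beta = 3.5, oblique_drop = 0.05,
    seed = 1L,
    tilt_roll_deg = 45,
    ring_ecc_deg = 6,
    rings = c(2, 4.25, 6, 7.21, 9.27, 10),
    contrast = "quest",        # "quest" or a fixed numeric contrast
    quest_trials = 150L,
    quest_prior_mean = log10(0.05),
    quest_prior_sd = 0.5,
    criterion = 0.75,
    max_gaze_dev = 1.0,
    gaze_sd = 0.1, gaze_max = 0.3,
    snap_rule = "nearest",
    n_iter = 10000L,
    k = 10L
  )
}

# Build the observer list described by a config.
.config_observers <- function(cfg) {
  seeds <- .derive_seeds(cfg$seed, cfg$n_observers)
  lapply(seq_len(cfg$n_observers), function(i) {
    observer_params(chance = cfg$chance, lapse = cfg$lapse, hva = cfg$hva,
                    vma = cfg$vma, e2 = cfg$e2, alpha0 = cfg$alpha0,
                    beta = cfg$beta, oblique_drop = cfg$oblique_drop,
                    frame = cfg$frame, seed = seeds[i])
  })
}

.merge_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  cfg
}

# Contrast for a condition: the staircase recommendation, or the fixed
# value from the config.
.condition_contrast <- function(cfg, params, head_roll_deg,
                                distractor_tilt_deg, seed) {
  if (identical(cfg$contrast, "quest")) {
    estimate_threshold(params, head_roll_deg, distractor_tilt_deg,
                       ring_ecc_deg = cfg$ring_ecc_deg,
                       n_trials = cfg$quest_trials,
                       prior_mean = cfg$quest_prior_mean,
                       prior_sd = cfg$quest_prior_sd,
                       criterion = cfg$criterion, seed = seed)$contrast
  } else {
    as.numeric(cfg$contrast)
  }
}

#' Run the head-tilt experiment end to end on synthetic observers
#'
#' Simulates the full two-session head-tilt design for each synthetic
#' observer (per-condition QUEST thresholding, trial generation, response
#' simulation), applies the gaze-deviation exclusion, aggregates and
#' transforms accuracy, and computes the omnibus 2 x 2 x 8 within-subject
#' ANOVA and the four meridian contrasts for each posture in both the
#' upright and the tilted analysis frame.  Contrast units pool the two
#' distractor orientations (observer x distractor), giving 8 paired units
#' with 4 observers.
#'
#' @param config named list overriding [default_config()] entries.
#' @param out_dir optional directory; when given, the trial table, the
#'   cell table, the report (JSON) and a run manifest are written there.
#' @return A list of class `exp1_report`: `anova`, `contrasts` (named list
#'   of `contrast_result`s), `cells`, `thresholds`, `exclusions` and
#'   `manifest`.
#' @export
run_exp1 <- function(config = list(), out_dir = NULL) {
  cfg <- .merge_config(config)
  observers <- .config_observers(cfg)
  seeds <- .derive_seeds(cfg$seed + 1L, cfg$n_observers * 8L)
  si <- 0L

  all_trials <- list()
  thresholds <- list()
  for (i in seq_along(observers)) {
    obs <- observers[[i]]
    oid <- sprintf("obs%02d", i)
    for (posture in c("upright", "tilted")) {
      roll <- if (posture == "tilted") cfg$tilt_roll_deg else 0
      spec <- design_spec("exp1", head_posture = posture,
                          tilt_roll_deg = cfg$tilt_roll_deg,
                          ring_ecc_deg = cfg$ring_ecc_deg,
                          session = if (posture == "upright") 1L else 2L)
      si <- si + 1L
      des <- generate_design(spec, seed = seeds[si], observer_id = oid)
      for (dist in unique(des$distractor_orientation_deg)) {
        si <- si + 1L
        ctr <- .condition_contrast(cfg, obs, roll, dist, seeds[si])
        des$contrast[des$distractor_orientation_deg == dist] <- ctr
        thresholds[[paste(oid, posture, dist, sep = "|")]] <- ctr
      }
      si <- si + 1L
      all_trials[[paste(oid, posture)]] <-
        simulate_trials(obs, des, seed = seeds[si],
                        gaze_sd = cfg$gaze_sd, gaze_max = cfg$gaze_max)
    }
  }
  trials <- do.call(rbind, all_trials)
  rownames(trials) <- NULL

  filt <- filter_fixation(trials, cfg$max_gaze_dev)
  cells <- aggregate_cells(
    filt$trials,
    c("observer_id", "head_posture", "distractor_orientation_deg",
      "target_location"))

  anova_cells <- data.frame(
    observer = cells$observer_id,
    head_posture = cells$head_posture,
    distractor_orientation = cells$distractor_orientation_deg,
    target_location = cells$target_location,
    transformed = cells$transformed
  )
  anova <- rm_anova_2x2x8(anova_cells)

  contrasts <- list()
  for (posture in c("upright", "tilted")) {
    sub <- cells[cells$head_posture == posture, ]
    unit_cells <- data.frame(
      unit = paste(sub$observer_id, sub$distractor_orientation_deg,
                   sep = "|"),
      target_location = sub$target_location,
      transformed = sub$transformed
    )
    for (roll in c(0, cfg$tilt_roll_deg)) {
      for (axis in names(.contrast_axes)) {
        nm <- sprintf("%s|roll%g|%s", posture, roll, axis)
        contrasts[[nm]] <- meridian_contrast(unit_cells, roll, axis)
      }
    }
  }

  report <- structure(
    list(anova = anova, contrasts = contrasts, cells = cells,
         thresholds = thresholds,
         exclusions = list(n_excluded = filt$n_excluded,
                           by_condition = filt$by_condition),
         manifest = run_manifest(cfg)),
    class = "exp1_report")
  if (!is.null(out_dir)) .write_exp1_outputs(report, trials, out_dir)
  report
}

#' Run the fixation-shift experiment end to end on synthetic observers
#'
#' Simulates, for each synthetic observer, the shifted-fixation session
#' (1,600 trials: 50 per shift x location cell) and the baseline sessions
#' (2,400 trials: 50 per location on each of six rings), applies the
#' gaze-deviation exclusion, bootstraps transformed accuracy per cell,
#' builds the retinotopic and head-centric prediction maps, and compares
#' the two models against the observed shifted performance.
#'
#' @inheritParams run_exp1
#' @return A list of class `exp2_report`: `maps`, `observed` and
#'   `baseline` bootstrap results, `comparison`
#'   (a `model_comparison_result`), `thresholds`, `exclusions` and
#'   `manifest`.
#' @export
run_exp2 <- function(config = list(), out_dir = NULL) {
  cfg <- .merge_config(config)
  observers <- .config_observers(cfg)
  seeds <- .derive_seeds(cfg$seed + 2L, cfg$n_observers * 5L)
  si <- 0L

  all_trials <- list()
  thresholds <- list()
  for (i in seq_along(observers)) {
    obs <- observers[[i]]
    oid <- sprintf("obs%02d", i)
    si <- si + 1L
    ctr <- .condition_contrast(cfg, obs, 0, 0, seeds[si])
    thresholds[[oid]] <- ctr

    si <- si + 1L
    shifted <- generate_design(design_spec("exp2",
                                           ring_ecc_deg = cfg$ring_ecc_deg),
                               seed = seeds[si], observer_id = oid)
    shifted$contrast <- ctr
    si <- si + 1L
    shifted <- simulate_trials(obs, shifted, seed = seeds[si],
                               gaze_sd = cfg$gaze_sd,
                               gaze_max = cfg$gaze_max)

    si <- si + 1L
    base <- generate_design(design_spec("baseline_ring", rings = cfg$rings),
                            seed = seeds[si], observer_id = oid)
    base$contrast <- ctr
    si <- si + 1L
    base <- simulate_trials(obs, base, seed = seeds[si],
                            gaze_sd = cfg$gaze_sd, gaze_max = cfg$gaze_max)
    all_trials[[oid]] <- rbind(shifted, base)
  }
  trials <- do.call(rbind, all_trials)
  rownames(trials) <- NULL

  filt <- filter_fixation(trials, cfg$max_gaze_dev)
  kept <- filt$trials

  observed <- bootstrap_cells(kept[kept$experiment == "exp2", ],
                              by = c("fixation_shift", "target_location"),
                              n_iter = cfg$n_iter, k = cfg$k,
                              seed = cfg$seed + 3L)
  baseline <- bootstrap_cells(kept[kept$experiment == "baseline_ring", ],
                              by = c("ring_eccentricity_deg",
                                     "target_location"),
                              n_iter = cfg$n_iter, k = cfg$k,
                              seed = cfg$seed + 4L)
  maps <- build_prediction_maps(ring_ecc_deg = cfg$ring_ecc_deg,
                                snap_rule = cfg$snap_rule)
  comparison <- compare_models(observed, maps, baseline)

  report <- structure(
    list(maps = maps, observed = observed, baseline = baseline,
         comparison = comparison, thresholds = thresholds,
         exclusions = list(n_excluded = filt$n_excluded,
                           by_condition = filt$by_condition),
         manifest = run_manifest(cfg)),
    class = "exp2_report")
  if (!is.null(out_dir)) .write_exp2_outputs(report, trials, out_dir)
  report
}

#' @export
print.exp1_report <- function(x, ...) {
  cat("== Head-tilt experiment (synthetic) ==\n")
  print(x$anova)
  cat("\nKey contrasts:\n")
  for (nm in c("upright|roll0|horizontal_vs_vertical",
               sprintf("tilted|roll%g|horizontal_vs_vertical",
                       x$manifest$config$tilt_roll_deg))) {
    if (!is.null(x$contrasts[[nm]])) {
      cat(" ", nm, ": ")
      print(x$contrasts[[nm]])
    }
  }
  invisible(x)
}

#' @export
print.exp2_report <- function(x, ...) {
  cat("== Fixation-shift experiment (synthetic) ==\n")
  print(x$comparison)
  invisible(x)
}
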