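#' Prediction maps for the fixation-shift experiment
#'
#' For each of the 32 shifted-fixation cells (4 cardinal fixation shifts x
#' 8 target locations on the ring), determines which baseline ring cell
#' predicts its performance under each hypothesis:
#' \describe{
#'   \item{retinotopic}{the baseline ring whose eccentricity equals the
#'     target's retinal displacement from the shifted fixation dot (the
#'     [table1()] value) at the retinal direction of that displacement.}
#'   \item{head-centric}{the unchanged 6 degree ring cell at the same
#'     screen location, regardless of the shift.}
#' }
#' The retinal direction rarely falls exactly on a canonical compass
#' direction; by default it is snapped to the nearest one
#' ([snap_to_canonical()]).  The alternative `"label"` rule keeps the
#' target's original screen label instead.
#'
#' @param ring_ecc_deg radius of the screen target ring (default 6).
#' @param shift_deg magnitude of the cardinal fixation shifts (default 4).
#' @param snap_rule `"nearest"` (default) or `"label"`; direction-matching
#'   strategy for the retinotopic map.
#' @return An object of class `prediction_maps`: a list with data.frames
#'   `retinotopic` and `head_centric` (columns `fixation_shift`,
#'   `target_location`, `ring_eccentricity_deg`, `direction`), plus the
#'   `snap_rule` used.
#' @export
#' @examples
#' m <- build_prediction_maps()
#' subset(m$retinotopic, fixation_shift == "E" & target_location == "W")
build_prediction_maps <- function(ring_ecc_deg = 6, shift_deg = 4,
                                  snap_rule = c("nearest", "label")) {
  snap_rule <- match.arg(snap_rule)
  shifts <- c("N", "S", "E", "W")
  locs <- .compass_order
  grid <- expand.grid(fixation_shift = shifts, target_location = locs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ring <- numeric(nrow(grid))
  dir <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    off <- fixation_offset(grid$fixation_shift[i], shift_deg)
    tgt <- field_location(grid$target_location[i],
                          eccentricity_deg = ring_ecc_deg)
    rd <- retinal_displacement(tgt, off)
    ring[i] <- round_half_up(rd$eccentricity_deg, 2)
    dir[i] <- if (snap_rule == "nearest") {
      snap_to_canonical(rd$angle_deg)
    } else {
      grid$target_location[i]
    }
  }
  retino <- cbind(grid, ring_eccentricity_deg = ring, direction = dir)
  headc <- cbind(grid, ring_eccentricity_deg = ring_ecc_deg,
                 direction = grid$target_location)
  structure(list(retinotopic = retino, head_centric = headc,
                 snap_rule = snap_rule),
            class = "prediction_maps")
}

#' @export
print.prediction_maps <- function(x, ...) {
  cat(sprintf("<prediction_maps> %d cells, snap_rule = '%s'\n",
              nrow(x$retinotopic), x$snap_rule))
  cat("retinotopic rings:",
      paste(sort(unique(x$retinotopic$ring_eccentricity_deg)),
            collapse = ", "), "\n")
  invisible(x)
}

# Deterministic per-(observer, cell) substream seeds: depend only on the
# master seed and the sorted identities, never on input row order.
.substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Bootstrap transformed accuracy per design cell
#'
#' For every observer and cell (a unique combination of the `by` columns),
#' draws `k` trial outcomes with replacement `n_iter` times and records the
#' arcsine-square-root transform of each draw's mean correctness.  The
#' per-observer iterate arrays are then averaged across observers per
#' iteration.  Substream seeds for each observer x cell are derived
#' deterministically from the master seed over the *sorted* cell
#' identities, so input row order cannot change the result.
#'
#' @param trials trial table with columns `observer_id`, `correct`, and
#'   the `by` columns.
#' @param by character vector of grouping columns defining the cells, e.g.
#'   `c("fixation_shift", "target_location")` or
#'   `c("ring_eccentricity_deg", "target_location")`.
#' @param n_iter number of bootstrap iterations (default 10000).
#' @param k samples drawn per iteration (default 10).
#' @param seed master integer seed.
#' @return An object of class `bootstrap_result`:
#' \describe{
#'   \item{cells}{data.frame of the cell keys with a `cell_id` column.}
#'   \item{iterates}{numeric array `[n_iter, n_cells, n_observers]` of
#'     transformed mean accuracies (values in `[0, pi]`).}
#'   \item{averaged}{matrix `[n_iter, n_cells]`, the per-iteration mean
#'     over observers.}
#'   \item{summary}{data.frame per observer x cell: bootstrap `mean` and
#'     2.5/97.5 percentile interval.}
#'   \item{n_iter, k, seed}{the resampling settings.}
#' }
#' @export
bootstrap_cells <- function(trials, by, n_iter = 10000L, k = 10L, seed = 1L) {
  stopifnot(is.data.frame(trials), length(by) >= 1L, k >= 1L, n_iter >= 1L)
  need <- c("observer_id", "correct", by)
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials lack columns: ", paste(miss, collapse = ", "))

  cell_id <- do.call(paste, c(lapply(trials[by], as.character), sep = "|"))
  observers <- sort(unique(as.character(trials$observer_id)))
  cells <- sort(unique(cell_id))
  n_obs <- length(observers)
  n_cells <- length(cells)

  key <- paste(rep(observers, each = n_cells), rep(cells, n_obs), sep = "@")
  seeds <- .substream_seeds(seed, n_obs * n_cells)
  names(seeds) <- key

  idx <- split(seq_len(nrow(trials)),
               paste(as.character(trials$observer_id), cell_id, sep = "@"))
  missing_cells <- setdiff(key, names(idx))
  if (length(missing_cells)) {
    stop("no trials for cell(s): ",
         paste(utils::head(missing_cells, 5L), collapse = "; "),
         if (length(missing_cells) > 5L) " ..." else "")
  }

  iter <- array(NA_real_, dim = c(n_iter, n_cells, n_obs),
                dimnames = list(NULL, cells, observers))
  for (o in seq_len(n_obs)) {
    for (ci in seq_len(n_cells)) {
      kk <- paste(observers[o], cells[ci], sep = "@")
      # canonical outcome order: the result depends on the cell's outcome
      # multiset, never on trial-table row order
      outc <- sort(as.numeric(trials$correct[idx[[kk]]]), decreasing = TRUE)
      set.seed(seeds[[kk]])
      draws <- matrix(outc[sample.int(length(outc), n_iter * k,
                                      replace = TRUE)],
                      nrow = n_iter)
      iter[, ci, o] <- 2 * asin(sqrt(rowMeans(draws)))
    }
  }
  averaged <- apply(iter, c(1L, 2L), mean)

  means <- apply(iter, c(2L, 3L), mean)
  q_lo <- apply(iter, c(2L, 3L), stats::quantile, probs = 0.025)
  q_hi <- apply(iter, c(2L, 3L), stats::quantile, probs = 0.975)
  summ <- data.frame(
    observer_id = rep(observers, each = n_cells),
    cell_id = rep(cells, n_obs),
    mean = as.vector(means),
    lower = as.vector(q_lo),
    upper = as.vector(q_hi),
    stringsAsFactors = FALSE
  )

  key_df <- unique(data.frame(trials[by], cell_id = cell_id,
                              stringsAsFactors = FALSE))
  key_df <- key_df[match(cells, key_df$cell_id), , drop = FALSE]
  rownames(key_df) <- NULL

  structure(list(cells = key_df, by = by, iterates = iter,
                 averaged = averaged, summary = summ,
                 n_iter = as.integer(n_iter), k = as.integer(k),
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(paste0("<bootstrap_result> %d cells x %d observers, ",
                     "n_iter = %d, k = %d, seed = %d\n"),
              nrow(x$cells), dim(x$iterates)[3L], x$n_iter, x$k, x$seed))
  invisible(x)
}

# Internal: cell_id string for a (ring, direction) baseline cell, matching
# bootstrap_cells() keyed by c("ring_eccentricity_deg", "target_location").
.ring_cell_id <- function(ring, direction) {
  paste(as.character(ring), direction, sep = "|")
}

#' Compare retinotopic and head-centric accounts of shifted performance
#'
#' Pairs every observer x shifted-cell bootstrap summary with the summary
#' of its mapped baseline cell under each model, then scores each model
#' with (1) a paired t test over all observer x cell points
#' (`df = n_observers * 32 - 1`) -- a *non*-significant difference means
#' the model's predictions are statistically indistinguishable from the
#' observations -- and (2) an ordinary least-squares regression of observed
#' on predicted values, whose R squared measures the variance in shifted
#' performance the model explains.  The winner is the model with the
#' higher R squared; `winner_nonsig` flags whether the winner's paired
#' difference is also non-significant at the 0.05 level.
#'
#' @param observed a [bootstrap_cells()] result keyed by
#'   `c("fixation_shift", "target_location")` covering all 32 cells per
#'   observer.
#' @param maps a [build_prediction_maps()] result.
#' @param baseline a [bootstrap_cells()] result keyed by
#'   `c("ring_eccentricity_deg", "target_location")` covering every mapped
#'   ring cell per observer.
#' @return An object of class `model_comparison_result`: per model a list
#'   with the paired test (`statistic`, `df`, `sem`, `p`, `mean_diff`) and
#'   the regression (`r_squared`, `slope`, `intercept`, `F`, `df1`, `df2`,
#'   `p`), plus `winner`, `winner_nonsig` and the per-point pairing table
#'   `points`.
#' @export
compare_models <- function(observed, maps, baseline) {
  stopifnot(inherits(observed, "bootstrap_result"),
            inherits(maps, "prediction_maps"),
            inherits(baseline, "bootstrap_result"))
  if (!identical(observed$by, c("fixation_shift", "target_location"))) {
    stop("'observed' must be keyed by fixation_shift, target_location")
  }
  if (!identical(baseline$by,
                 c("ring_eccentricity_deg", "target_location"))) {
    stop("'baseline' must be keyed by ring_eccentricity_deg, ",
         "target_location")
  }

  obs_sum <- observed$summary
  base_sum <- baseline$summary
  models <- list(retinotopic = maps$retinotopic,
                 head_centric = maps$head_centric)
  out <- list()
  points <- list()
  for (m in names(models)) {
    map <- models[[m]]
    map_key <- paste(map$fixation_shift, map$target_location, sep = "|")
    pred_cell <- .ring_cell_id(map$ring_eccentricity_deg, map$direction)
    pred_for_obs <- pred_cell[match(obs_sum$cell_id, map_key)]
    if (anyNA(pred_for_obs)) {
      stop("internal consistency error: observed cell without a mapping")
    }
    j <- match(paste(obs_sum$observer_id, pred_for_obs, sep = "@"),
               paste(base_sum$observer_id, base_sum$cell_id, sep = "@"))
    if (anyNA(j)) {
      stop("unmapped baseline cell(s) for model '", m,
           "': baseline bootstrap does not cover all mapped ring cells")
    }
    x_obs <- obs_sum$mean
    y_pred <- base_sum$mean[j]

    tt <- paired_t(x_obs, y_pred)
    fit <- stats::lm(x_obs ~ y_pred)
    sf <- summary(fit)
    fstat <- sf$fstatistic
    reg <- if (is.null(fstat)) {
      # constant predictor or response: the regression is undefined
      list(r_squared = NA_real_, slope = NA_real_,
           intercept = unname(stats::coef(fit)[1L]),
           F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
           p = NA_real_)
    } else {
      list(
        r_squared = sf$r.squared,
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        F = unname(fstat[1L]),
        df1 = unname(fstat[2L]),
        df2 = unname(fstat[3L]),
        p = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                             lower.tail = FALSE))
      )
    }
    out[[m]] <- list(paired = tt, regression = reg)
    points[[m]] <- data.frame(
      model = m, observer_id = obs_sum$observer_id,
      cell_id = obs_sum$cell_id, observed = x_obs, predicted = y_pred,
      stringsAsFactors = FALSE
    )
  }
  r2 <- vapply(out, function(z) z$regression$r_squared, numeric(1L))
  if (all(is.na(r2))) {
    winner <- NA_character_
    nonsig <- NA
  } else {
    winner <- names(out)[which.max(r2)]
    nonsig <- out[[winner]]$paired$p > 0.05
  }
  structure(list(models = out, winner = winner, winner_nonsig = nonsig,
                 points = do.call(rbind, points)),
            class = "model_comparison_result")
}

#' @export
print.model_comparison_result <- function(x, ...) {
  cat("<model_comparison_result>\n")
  for (m in names(x$models)) {
    z <- x$models[[m]]
    cat(sprintf(
      "  %-12s t(%d) = %6.3f, p = %.4g | R^2 = %.3f, F(%d,%d) = %.2f\n",
      m, z$paired$df, z$paired$statistic, z$paired$p,
      z$regression$r_squared, z$regression$df1, z$regression$df2,
      z$regression$F))
  }
  cat(sprintf("  winner: %s (paired difference %ssignificant at 0.05)\n",
              x$winner, if (x$winner_nonsig) "non-" else ""))
  invisible(x)
}
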