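#' Arcsine square-root transform of a proportion
#'
#' The variance-stabilizing transform `2 * asin(sqrt(p))` applied to
#' accuracy proportions before all inferential statistics, countering the
#' compression of binomial accuracies against their ceiling of 1.  Maps
#' `[0, 1]` bijectively onto `[0, pi]`.
#'
#' @param prop proportion(s) in `[0, 1]`.
#' @return Transformed value(s) in `[0, pi]`.
#' @seealso [arcsine_inverse()]
#' @export
#' @examples
#' arcsine_transform(c(0, 0.5, 1))  # 0, pi/2, pi
arcsine_transform <- function(prop) {
  if (any(!is.finite(prop)) || any(prop < 0) || any(prop > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  2 * asin(sqrt(prop))
}

#' Inverse of the arcsine square-root transform
#'
#' @param x transformed value(s) in `[0, pi]`.
#' @return Proportion(s) in `[0, 1]`.
#' @export
arcsine_inverse <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > pi)) {
    stop("transformed values must lie in [0, pi]")
  }
  sin(x / 2)^2
}

#' Paired t test over matched units
#'
#' Classical paired t statistic with `df = n - 1` and a two-sided p value,
#' the workhorse behind [meridian_contrast()] and the model comparison.
#' Degenerate zero-variance differences are handled explicitly: all-equal
#' pairs give `t = 0, p = 1`; a constant nonzero difference gives the
#' infinite-t limit with `p = 0`.
#'
#' @param x,y numeric vectors of equal length (>= 2), no missing values.
#' @return An object of class `contrast_result`: `statistic`, `df`, `sem`
#'   (standard error of the mean difference), `p` (two-sided) and
#'   `mean_diff`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3, 4), c(0.5, 1.8, 2.9, 3.4))
paired_t <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  d <- x - y
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd < 1e-12) {
    if (abs(md) < 1e-12) {
      res <- list(statistic = 0, df = n - 1L, sem = 0, p = 1, mean_diff = 0)
    } else {
      res <- list(statistic = sign(md) * Inf, df = n - 1L, sem = 0, p = 0,
                  mean_diff = md)
    }
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    res <- list(statistic = unname(tt$statistic), df = n - 1L,
                sem = sdd / sqrt(n), p = tt$p.value, mean_diff = md)
  }
  structure(res, class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, SEM = %.4f, p = %.4g, mean diff = %.4f\n",
              x$df, x$statistic, x$sem, x$p, x$mean_diff))
  if (!is.null(x$axis)) {
    cat(sprintf("  axis: %s; set A {%s} vs set B {%s}\n", x$axis,
                paste(x$set_a, collapse = ","),
                paste(x$set_b, collapse = ",")))
  }
  invisible(x)
}

# Axis definitions in upright (unrolled) angles; rotated by frame_roll_deg
# and snapped to canonical labels at call time.
.contrast_axes <- list(
  horizontal_vs_vertical      = list(a = c(0, 180),        b = c(90, 270)),
  lower_vs_upper              = list(a = 270,               b = 90),
  intercardinal_vs_horizontal = list(a = c(45, 135, 225, 315), b = c(0, 180)),
  intercardinal_vs_vertical   = list(a = c(45, 135, 225, 315), b = c(90, 270))
)

#' Performance-field meridian contrast
#'
#' Paired comparison of mean transformed accuracy between two sets of
#' isoeccentric locations, with the axes optionally rotated into a tilted
#' head's frame.  With `frame_roll_deg = 0` the horizontal-vs-vertical
#' contrast compares \{E, W\} against \{N, S\} (the HVA); with the 45
#' degree tilt used in the tilted posture it compares \{NE, SW\} against
#' \{NW, SE\}.  The lower-vs-upper contrast is the VMA.  Units (e.g.
#' observer by distractor-condition) are paired across the two sets.
#'
#' @param cells data.frame with columns `unit`, `target_location` and
#'   `transformed`; one row per unit x location (all 8 canonical locations
#'   required for every unit).
#' @param frame_roll_deg rotation of the analysis axes in degrees
#'   (0 = upright; 45 = the tilted posture used here).
#' @param axis which contrast to compute; see Details.
#' @return A `contrast_result` (see [paired_t()]) with the `axis` and the
#'   resolved location sets attached.
#' @export
meridian_contrast <- function(cells, frame_roll_deg = 0,
                              axis = c("horizontal_vs_vertical",
                                       "lower_vs_upper",
                                       "intercardinal_vs_horizontal",
                                       "intercardinal_vs_vertical")) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(cells))
  need <- c("unit", "target_location", "transformed")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cells lack columns: ", paste(miss, collapse = ", "))

  units <- sort(unique(as.character(cells$unit)))
  locs <- names(.canonical_angles)
  for (u in units) {
    have <- cells$target_location[cells$unit == u]
    if (!all(locs %in% have)) {
      stop("unit '", u, "' is missing locations: ",
           paste(setdiff(locs, have), collapse = ", "))
    }
  }
  ax <- .contrast_axes[[axis]]
  set_a <- snap_to_canonical((ax$a + frame_roll_deg) %% 360)
  set_b <- snap_to_canonical((ax$b + frame_roll_deg) %% 360)

  mean_set <- function(u, set) {
    sub <- cells[cells$unit == u & cells$target_location %in% set, ]
    mean(sub$transformed)
  }
  a_means <- vapply(units, mean_set, numeric(1L), set = set_a)
  b_means <- vapply(units, mean_set, numeric(1L), set = set_b)
  res <- paired_t(a_means, b_means)
  res$axis <- axis
  res$frame_roll_deg <- frame_roll_deg
  res$set_a <- set_a
  res$set_b <- set_b
  res
}

#' Fully within-subject 2 x 2 x 8 ANOVA on transformed accuracy
#'
#' The omnibus repeated-measures ANOVA over head posture (2), distractor
#' orientation (2) and target location (8), with every effect tested
#' against its own effect-by-subject interaction (classical univariate
#' partitioning via [stats::aov()] error strata).  No sphericity
#' correction is applied; this is recorded in the result's metadata.
#'
#' @param cells data.frame with columns `observer`, `head_posture`,
#'   `distractor_orientation`, `target_location` and `transformed`; exactly
#'   one value per observer x posture x distractor x location cell.
#' @return An object of class `anova_table`: a data.frame with one row per
#'   effect (`effect`, `df1`, `df2`, `ss`, `mse` of the error term, `F`,
#'   `p`, `eta_p2` partial eta squared), plus attributes `degenerate`
#'   (TRUE when the data carry no variance at all, in which case all F are
#'   reported as 0) and `sphericity_correction = "none"`.
#' @export
rm_anova_2x2x8 <- function(cells) {
  stopifnot(is.data.frame(cells))
  need <- c("observer", "head_posture", "distractor_orientation",
            "target_location", "transformed")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cells lack columns: ", paste(miss, collapse = ", "))

  d <- data.frame(
    observer = factor(cells$observer),
    posture = factor(cells$head_posture),
    distractor = factor(cells$distractor_orientation),
    location = factor(cells$target_location),
    y = cells$transformed
  )
  if (nlevels(d$posture) != 2L || nlevels(d$distractor) != 2L ||
      nlevels(d$location) != 8L) {
    stop("design must be 2 postures x 2 distractor orientations x 8 locations")
  }
  tab <- table(d$observer, d$posture, d$distractor, d$location)
  if (any(tab != 1L)) {
    stop("unbalanced design: need exactly one value per observer x cell ",
         "(no imputation is performed)")
  }

  degenerate <- stats::var(d$y) < 1e-24
  effects <- c("posture", "distractor", "location",
               "posture:distractor", "posture:location",
               "distractor:location", "posture:distractor:location")

  if (degenerate) {
    out <- data.frame(effect = effects, df1 = NA_integer_, df2 = NA_integer_,
                      ss = 0, mse = 0, F = 0, p = NA_real_, eta_p2 = 0)
  } else {
    fit <- stats::aov(
      y ~ posture * distractor * location +
        Error(observer / (posture * distractor * location)),
      data = d
    )
    sm <- summary(fit)
    rows <- list()
    for (stratum in sm) {
      st <- stratum[[1L]]
      terms <- trimws(rownames(st))
      eff <- setdiff(terms, "Residuals")
      if (!length(eff)) next
      for (e in eff) {
        i <- match(e, terms)
        r <- match("Residuals", terms)
        ss_e <- st[i, "Sum Sq"]
        ss_r <- st[r, "Sum Sq"]
        rows[[e]] <- data.frame(
          effect = e, df1 = st[i, "Df"], df2 = st[r, "Df"],
          ss = ss_e, mse = st[r, "Mean Sq"],
          F = st[i, "F value"], p = st[i, "Pr(>F)"],
          eta_p2 = if (ss_e + ss_r > 0) ss_e / (ss_e + ss_r) else 0
        )
      }
    }
    out <- do.call(rbind, rows[effects[effects %in% names(rows)]])
    rownames(out) <- NULL
  }
  structure(out, class = c("anova_table", "data.frame"),
            degenerate = degenerate, sphericity_correction = "none")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Within-subject ANOVA (no sphericity correction)\n")
  if (isTRUE(attr(x, "degenerate"))) {
    cat("  [degenerate: data carry no variance; all F reported as 0]\n")
  }
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
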