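test_that("prediction maps implement both hypotheses over all 32 cells", {
  maps <- build_prediction_maps()
  expect_equal(nrow(maps$retinotopic), 32)
  expect_equal(nrow(maps$head_centric), 32)

  pick <- function(map, shift, loc) {
    map[map$fixation_shift == shift & map$target_location == loc, ]
  }
  # target 6 deg West under an East shift: 10 deg retinal displacement
  ew <- pick(maps$retinotopic, "E", "W")
  expect_equal(ew$ring_eccentricity_deg, 10)
  expect_equal(ew$direction, "W")
  # the head-centric account ignores the shift entirely
  expect_equal(pick(maps$head_centric, "E", "W")$ring_eccentricity_deg, 6)
  expect_equal(pick(maps$head_centric, "E", "W")$direction, "W")
  # NE target under an East shift snaps to the North direction
  ene <- pick(maps$retinotopic, "E", "NE")
  expect_equal(ene$ring_eccentricity_deg, 4.25)
  expect_equal(ene$direction, "N")

  # retinotopic rings agree with the displacement table cell by cell
  tb <- table1()
  row_of <- c(E = "East", W = "West", N = "North", S = "South")
  for (i in seq_len(nrow(maps$retinotopic))) {
    r <- maps$retinotopic[i, ]
    expect_equal(r$ring_eccentricity_deg,
                 tb[row_of[[r$fixation_shift]], r$target_location])
  }

  # head-centric map is constant in fixation shift; retinotopic is not
  hc <- maps$head_centric
  for (loc in unique(hc$target_location)) {
    expect_equal(length(unique(
      hc$ring_eccentricity_deg[hc$target_location == loc])), 1L)
  }
  rt <- maps$retinotopic
  expect_gt(length(unique(
    rt$ring_eccentricity_deg[rt$target_location == "N"])), 1L)

  # keep-label strategy preserves the screen label
  lab <- build_prediction_maps(snap_rule = "label")
  expect_equal(lab$retinotopic$direction, lab$retinotopic$target_location)
})

test_that("bootstrap iterates are valid, consistent and reproducible", {
  # degenerate all-correct cell: every iterate equals pi
  tr <- make_cell_trials(rep(1, 20))
  b <- bootstrap_cells(tr, by = c("fixation_shift", "target_location"),
                       n_iter = 50, k = 10, seed = 1)
  expect_true(all(b$iterates == pi))

  # mixed cell: values in [0, pi], mean within 3 bootstrap SE of the
  # directly transformed proportion (bootstrap SE = sd of the iterates)
  set.seed(51)
  tr <- make_cell_trials(runif(60) < 0.75)
  b <- bootstrap_cells(tr, by = c("fixation_shift", "target_location"),
                       n_iter = 2000, k = 10, seed = 2)
  expect_true(all(b$iterates >= 0 & b$iterates <= pi))
  direct <- arcsine_transform(mean(tr$correct))
  expect_lt(abs(mean(b$iterates) - direct), 3 * sd(b$iterates))

  # same seed, bit-identical result; different seed differs
  b2 <- bootstrap_cells(tr, by = c("fixation_shift", "target_location"),
                        n_iter = 2000, k = 10, seed = 2)
  expect_identical(b, b2)
  b3 <- bootstrap_cells(tr, by = c("fixation_shift", "target_location"),
                        n_iter = 2000, k = 10, seed = 3)
  expect_false(identical(b$iterates, b3$iterates))

  # row order of the trial table cannot change the result
  tr2 <- rbind(make_cell_trials(runif(30) < 0.6, target_location = "S"),
               tr)
  shuffled <- tr2[rev(seq_len(nrow(tr2))), ]
  ba <- bootstrap_cells(tr2, by = c("fixation_shift", "target_location"),
                        n_iter = 200, k = 10, seed = 4)
  bb <- bootstrap_cells(shuffled,
                        by = c("fixation_shift", "target_location"),
                        n_iter = 200, k = 10, seed = 4)
  expect_equal(ba$summary, bb$summary)

  # an empty referenced cell is a data-completeness error: one observer
  # lacks a cell the other has
  bad <- rbind(tr,
               make_cell_trials(c(1, 0, 1), observer = "obs02",
                                target_location = "S"))
  expect_error(bootstrap_cells(bad,
                               by = c("fixation_shift",
                                      "target_location"),
                               n_iter = 10, k = 5, seed = 1),
               "no trials")
})

test_that("self-comparison gives a perfect fit and a null paired test", {
  maps <- build_prediction_maps()
  observers <- c("obs01", "obs02")
  # observed summaries over the 32 shifted cells
  set.seed(52)
  obs_cells <- expand.grid(fixation_shift = c("E", "N", "S", "W"),
                           target_location = names(canonical_angles()),
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
  obs_cells <- obs_cells[order(obs_cells$fixation_shift,
                               obs_cells$target_location), ]
  cell_id <- paste(obs_cells$fixation_shift, obs_cells$target_location,
                   sep = "|")
  # assign one value per unique baseline ring cell (the retinotopic map
  # is many-to-one) and make the observed cells reproduce their mapped
  # value exactly
  map <- maps$retinotopic
  map_key <- paste(map$fixation_shift, map$target_location, sep = "|")
  base_cell <- paste(map$ring_eccentricity_deg, map$direction, sep = "|")
  ring6_cells <- paste(6, names(canonical_angles()), sep = "|")
  all_base <- unique(c(base_cell, ring6_cells))
  base_vals <- lapply(observers, function(o) {
    setNames(runif(length(all_base), 1.5, 2.5), all_base)
  })
  names(base_vals) <- observers

  obs_summary <- do.call(rbind, lapply(observers, function(o) {
    data.frame(observer_id = o, cell_id = cell_id,
               mean = unname(base_vals[[o]][base_cell[match(cell_id,
                                                            map_key)]]))
  }))
  fake_observed <- structure(
    list(by = c("fixation_shift", "target_location"),
         summary = obs_summary),
    class = "bootstrap_result")
  fake_baseline <- structure(
    list(by = c("ring_eccentricity_deg", "target_location"),
         summary = do.call(rbind, lapply(observers, function(o) {
           data.frame(observer_id = o, cell_id = all_base,
                      mean = unname(base_vals[[o]]))
         }))),
    class = "bootstrap_result")

  # lm warns about the (intended) perfect fit
  res <- suppressWarnings(compare_models(fake_observed, maps,
                                         fake_baseline))
  expect_equal(res$models$retinotopic$paired$statistic, 0)
  expect_equal(res$models$retinotopic$paired$p, 1)
  expect_equal(res$models$retinotopic$regression$r_squared, 1,
               tolerance = 1e-9)
  expect_equal(res$winner, "retinotopic")
  expect_equal(res$models$retinotopic$paired$df, 2 * 32 - 1)
})

test_that("the comparison recovers the generating reference frame", {
  for (frame in c("retinotopic", "head_centric")) {
    trials <- make_exp2_trials(frame = frame, n_obs = 2, seed = 60,
                               n_per_cell = 40)
    observed <- bootstrap_cells(
      trials[trials$experiment == "exp2", ],
      by = c("fixation_shift", "target_location"),
      n_iter = 400, k = 10, seed = 61)
    baseline <- bootstrap_cells(
      trials[trials$experiment == "baseline_ring", ],
      by = c("ring_eccentricity_deg", "target_location"),
      n_iter = 400, k = 10, seed = 62)
    res <- compare_models(observed, build_prediction_maps(), baseline)
    expect_equal(res$winner, frame)
    r2 <- vapply(res$models, function(z) z$regression$r_squared,
                 numeric(1))
    expect_gt(r2[[frame]], max(r2[names(r2) != frame]))
  }
})

test_that("an unmapped baseline cell is an internal consistency error", {
  trials <- make_exp2_trials(n_obs = 1, seed = 70, n_per_cell = 10)
  observed <- bootstrap_cells(
    trials[trials$experiment == "exp2", ],
    by = c("fixation_shift", "target_location"),
    n_iter = 20, k = 5, seed = 1)
  # baseline missing the 10-degree ring
  incomplete <- trials[trials$experiment == "baseline_ring" &
                         trials$ring_eccentricity_deg != 10, ]
  baseline <- bootstrap_cells(
    incomplete, by = c("ring_eccentricity_deg", "target_location"),
    n_iter = 20, k = 5, seed = 2)
  expect_error(compare_models(observed, build_prediction_maps(), baseline),
               "unmapped")
})
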