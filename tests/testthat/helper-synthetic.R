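# Small fixture builders shared across tests.

# Per-unit x location transformed-accuracy cells for meridian contrasts.
make_unit_cells <- function(values_by_location, units = paste0("u", 1:4),
                            noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  locs <- names(values_by_location)
  out <- expand.grid(unit = units, target_location = locs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$transformed <- values_by_location[out$target_location] +
    stats::rnorm(nrow(out), 0, noise_sd)
  out
}

# Fully crossed 2 x 2 x 8 within-subject cell table with random values.
make_anova_cells <- function(n_obs = 4, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(
    observer = paste0("s", seq_len(n_obs)),
    head_posture = c("upright", "tilted"),
    distractor_orientation = c(0, -45),
    target_location = names(canonical_angles()),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  cells$transformed <- stats::runif(nrow(cells), 1.5, 2.5)
  cells
}

# Minimal trial table: one observer, one cell, given outcome vector.
make_cell_trials <- function(outcomes, observer = "obs01",
                             fixation_shift = "E", target_location = "N") {
  data.frame(observer_id = observer, fixation_shift = fixation_shift,
             target_location = target_location,
             ring_eccentricity_deg = 6,
             correct = as.logical(outcomes),
             stringsAsFactors = FALSE)
}

# Trial tables covering all shifted and baseline cells for n observers,
# generated from the observer model at a fixed contrast (no staircase),
# for fast model-comparison tests.
make_exp2_trials <- function(frame = "retinotopic", n_obs = 2, seed = 1,
                             n_per_cell = 30, contrast = 0.05) {
  seeds <- seed + seq_len(2 * n_obs)
  out <- list()
  for (i in seq_len(n_obs)) {
    obs <- observer_params(frame = frame, seed = seed + i)
    oid <- sprintf("obs%02d", i)
    sh <- generate_design(design_spec("exp2", n_per_cell = n_per_cell,
                                      n_blocks = 1L),
                          seed = seeds[2 * i - 1], observer_id = oid)
    sh$contrast <- contrast
    sh <- simulate_trials(obs, sh, seed = seeds[2 * i - 1])
    ba <- generate_design(design_spec("baseline_ring",
                                      n_per_cell = n_per_cell),
                          seed = seeds[2 * i], observer_id = oid)
    ba$contrast <- contrast
    ba <- simulate_trials(obs, ba, seed = seeds[2 * i])
    out[[oid]] <- rbind(sh, ba)
  }
  do.call(rbind, out)
}
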