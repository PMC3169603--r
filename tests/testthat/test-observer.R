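test_that("angular modulation has the HVA/VMA field shape", {
  p <- observer_params(hva = 0.2, vma = 0.1)
  expect_equal(angular_modulation(p, 0), 1.0)
  expect_equal(angular_modulation(p, 180), 1.0)
  expect_equal(angular_modulation(p, 90), 0.7)
  expect_equal(angular_modulation(p, 270), 0.8)
  # intercardinals strictly between the meridian values
  inter <- angular_modulation(p, c(45, 135, 225, 315))
  expect_true(all(inter < 1 & inter > 0.7))
  # uniform field
  u <- observer_params(hva = 0, vma = 0)
  expect_equal(angular_modulation(u, seq(0, 350, by = 10)),
               rep(1, 36))
  # amplitude domain is enforced
  expect_error(observer_params(hva = 0.8, vma = 0.3), "< 1")
  bad <- observer_params(hva = 0.2, vma = 0.1)
  bad$hva <- 0.95; bad$vma <- 0.2
  expect_error(angular_modulation(bad, 90), "< 1")
})

test_that("eccentricity gain is normalized at the reference ring and
           decreases monotonically", {
  p <- observer_params(e2 = 10)
  expect_equal(eccentricity_gain(p, 6), 1.0)
  expect_equal(eccentricity_gain(p, 0), 1.6)
  for (e2 in c(2, 8, 50)) {
    g <- eccentricity_gain(observer_params(e2 = e2),
                           c(2, 4.25, 7.21, 9.27, 10))
    expect_true(all(diff(g) < 0))
  }
})

test_that("p_correct respects its asymptotes, orderings and frame", {
  obs <- observer_params(hva = 0.2, vma = 0.1, lapse = 0.05,
                         alpha0 = 0.005)
  # saturating contrast at the best location approaches 1 - lapse
  hi <- p_correct(obs, stimulus_spec(field_location("E",
                                                    eccentricity_deg = 6),
                                     contrast = 1))
  expect_equal(hi, 1 - obs$lapse, tolerance = 1e-6)
  expect_error(stimulus_spec(field_location("E", eccentricity_deg = 6),
                             contrast = 0), "contrast")

  # upright retinotopic observer: N < S < E ordering at threshold contrast
  obs <- observer_params(hva = 0.2, vma = 0.1)
  pv <- vapply(c("N", "S", "E"), function(l) {
    p_correct(obs, stimulus_spec(field_location(l, eccentricity_deg = 6),
                                 contrast = 0.05))
  }, numeric(1))
  expect_true(pv[["N"]] < pv[["S"]])
  expect_true(pv[["S"]] < pv[["E"]])

  # under the 45-degree head roll the best screen locations move from
  # {E, W} to {NE, SW}
  locs <- names(canonical_angles())
  p_at <- function(roll) {
    vapply(locs, function(l) {
      p_correct(obs, stimulus_spec(field_location(l, eccentricity_deg = 6),
                                   contrast = 0.05, head_roll_deg = roll))
    }, numeric(1))
  }
  expect_setequal(names(sort(p_at(0), decreasing = TRUE))[1:2],
                  c("E", "W"))
  expect_setequal(names(sort(p_at(45), decreasing = TRUE))[1:2],
                  c("NE", "SW"))
})

test_that("accuracy is anchored to the observer's reference frame", {
  grid <- expand.grid(loc = names(canonical_angles()),
                      roll = c(0, 30, 45), fx = c(0, 4), fy = c(0, -4),
                      stringsAsFactors = FALSE)
  p_of <- function(frame, loc, roll, fx, fy) {
    obs <- observer_params(frame = frame)
    p_correct(obs, stimulus_spec(field_location(loc, eccentricity_deg = 6),
                                 contrast = 0.05, head_roll_deg = roll,
                                 fixation_offset = planar_point(fx, fy)))
  }
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    # allocentric: invariant to head roll
    expect_equal(p_of("allocentric", g$loc, g$roll, g$fx, g$fy),
                 p_of("allocentric", g$loc, 0, g$fx, g$fy))
    # head-centric: invariant to fixation offset
    expect_equal(p_of("head_centric", g$loc, g$roll, g$fx, g$fy),
                 p_of("head_centric", g$loc, g$roll, 0, 0))
  }
  # retinotopic: depends on the target only through its fixation-relative,
  # head-rolled coordinates -- equal retinal coordinates, equal accuracy
  p1 <- p_of("retinotopic", "E", 0, 4, 0)   # retinal (2, 0 deg)
  obs <- observer_params(frame = "retinotopic")
  p2 <- p_correct(obs, stimulus_spec(
    field_location(angle_deg = 0, eccentricity_deg = 2), contrast = 0.05))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("p_correct is non-decreasing in contrast and flat for a
           uniform field", {
  obs <- observer_params()
  cs <- seq(0.005, 0.5, length.out = 30)
  ps <- vapply(cs, function(cc) {
    p_correct(obs, stimulus_spec(field_location("NW",
                                                eccentricity_deg = 6),
                                 contrast = cc))
  }, numeric(1))
  expect_true(all(diff(ps) >= 0))

  flat <- observer_params(hva = 0, vma = 0, oblique_drop = 0)
  pv <- vapply(names(canonical_angles()), function(l) {
    p_correct(flat, stimulus_spec(field_location(l, eccentricity_deg = 6),
                                  contrast = 0.04))
  }, numeric(1))
  expect_equal(max(pv) - min(pv), 0, tolerance = 1e-12)
})

test_that("trial simulation is Bernoulli-consistent and deterministic", {
  # ceiling construct: zero lapse, saturating contrast -> always correct
  sure <- observer_params(lapse = 0, alpha0 = 1e-4)
  des <- data.frame(target_location = "E", ring_eccentricity_deg = 6,
                    fixation_shift = "none", head_roll_deg = 0,
                    distractor_orientation_deg = 0, contrast = 1)
  des <- des[rep(1, 200), ]
  out <- simulate_trials(sure, des, seed = 4)
  expect_true(all(out$correct))

  # determinism: same seed, same trial sequence
  obs <- observer_params()
  des$contrast <- 0.05
  a <- simulate_trials(obs, des, seed = 9)
  b <- simulate_trials(obs, des, seed = 9)
  expect_identical(a, b)

  # empirical accuracy within 3 binomial SE of the generative probability
  n <- 10000
  des10k <- des[rep(1, n), ]
  sim <- simulate_trials(obs, des10k, seed = 21)
  p <- p_correct(obs, stimulus_spec(field_location("E",
                                                   eccentricity_deg = 6),
                                    contrast = 0.05))
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(sim$correct) - p), 3 * se)

  # gaze deviations respect the truncation bound
  expect_true(all(sim$gaze_dev_deg >= 0 & sim$gaze_dev_deg <= 0.3))
})
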