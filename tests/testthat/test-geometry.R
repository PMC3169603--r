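test_that("canonical labels carry exact angles and Cartesian axis cases", {
  expect_equal(canonical_angles(),
               c(E = 0, NE = 45, N = 90, NW = 135,
                 W = 180, SW = 225, S = 270, SE = 315))
  expect_equal(unclass(to_cartesian(field_location("E", eccentricity_deg = 6))),
               c(x = 6, y = 0), tolerance = 1e-12)
  expect_equal(unclass(to_cartesian(field_location("N", eccentricity_deg = 6))),
               c(x = 0, y = 6), tolerance = 1e-12)
  ne <- to_cartesian(field_location("NE", eccentricity_deg = 6))
  expect_equal(unname(ne[["x"]]), 6 / sqrt(2), tolerance = 1e-9)
  expect_equal(unname(ne[["y"]]), 6 / sqrt(2), tolerance = 1e-9)
})

test_that("from_cartesian inverts to_cartesian, labels canonical points", {
  s <- from_cartesian(planar_point(0, -6))
  expect_equal(s$label, "S")
  expect_equal(s$angle_deg, 270)
  expect_equal(s$eccentricity_deg, 6)

  ne <- from_cartesian(planar_point(4.2426, 4.2426))
  expect_equal(ne$label, "NE")
  expect_equal(ne$angle_deg, 45, tolerance = 1e-4)

  origin <- from_cartesian(planar_point(0, 0))
  expect_equal(origin$label, "custom")
  expect_equal(origin$angle_deg, 0)
  expect_equal(origin$eccentricity_deg, 0)
})

test_that("polar round trip preserves angle and eccentricity", {
  set.seed(11)
  for (i in 1:50) {
    ang <- runif(1, 0, 360)
    ecc <- runif(1, 0.1, 12)
    loc <- field_location(angle_deg = ang, eccentricity_deg = ecc)
    back <- from_cartesian(to_cartesian(loc))
    expect_equal(back$angle_deg %% 360, ang %% 360, tolerance = 1e-9)
    expect_equal(back$eccentricity_deg, ecc, tolerance = 1e-9)
  }
})

test_that("head roll carries retinal directions to the reported screen
           locations and preserves eccentricity", {
  e6 <- field_location("E", eccentricity_deg = 6)
  expect_equal(apply_head_roll(e6, 45)$label, "NE")
  expect_equal(apply_head_roll(field_location("W", eccentricity_deg = 6),
                               45)$label, "SW")
  expect_equal(apply_head_roll(field_location("S", eccentricity_deg = 6),
                               45)$label, "SE")
  # roll 0 is the identity
  id <- apply_head_roll(field_location("NW", eccentricity_deg = 3), 0)
  expect_equal(id$label, "NW")
  expect_equal(id$angle_deg, 135)

  set.seed(12)
  for (i in 1:20) {
    loc <- field_location(angle_deg = runif(1, 0, 360),
                          eccentricity_deg = runif(1, 0, 10))
    rho <- runif(1, -180, 180)
    expect_equal(apply_head_roll(loc, rho)$eccentricity_deg,
                 loc$eccentricity_deg, tolerance = 1e-9)
    # composition of rolls
    r1 <- runif(1, -90, 90); r2 <- runif(1, -90, 90)
    a12 <- apply_head_roll(apply_head_roll(loc, r1), r2)$angle_deg
    a_sum <- apply_head_roll(loc, r1 + r2)$angle_deg
    expect_equal(a12 %% 360, a_sum %% 360, tolerance = 1e-9)
  }
})

test_that("retinal displacement reproduces the fixation-shift distances", {
  w6 <- field_location("W", eccentricity_deg = 6)
  e6 <- field_location("E", eccentricity_deg = 6)
  ne6 <- field_location("NE", eccentricity_deg = 6)
  east <- planar_point(4, 0)

  expect_equal(retinal_displacement(w6, east)$eccentricity_deg, 10,
               tolerance = 1e-9)
  expect_equal(retinal_displacement(e6, east)$eccentricity_deg, 2,
               tolerance = 1e-9)
  rd <- retinal_displacement(ne6, east)
  expect_equal(rd$eccentricity_deg, 4.25, tolerance = 0.005)
  # independently: atan2(6/sqrt(2), 6/sqrt(2) - 4) = 86.727 degrees
  expect_equal(rd$angle_deg, atan2(6 / sqrt(2), 6 / sqrt(2) - 4) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(rd$angle_deg, 86.73, tolerance = 0.005)

  # zero offset returns the target's own polar coordinates
  rd0 <- retinal_displacement(ne6, planar_point(0, 0))
  expect_equal(rd0$eccentricity_deg, 6, tolerance = 1e-12)
  expect_equal(rd0$angle_deg, 45, tolerance = 1e-12)
})

test_that("snapping picks the nearest canonical direction, ties go
           counterclockwise", {
  expect_equal(snap_to_canonical(86.73), "N")
  expect_equal(snap_to_canonical(0), "E")
  expect_equal(snap_to_canonical(67.5), "N")   # midpoint NE/N -> CCW
  expect_equal(snap_to_canonical(c(359, 46, 224.9)), c("E", "NE", "SW"))
  # brute-force nearest over a sweep (off the midpoints)
  set.seed(13)
  a <- runif(200, 0, 360)
  a <- a[pmin(abs((a %% 45) - 22.5), 45 - abs((a %% 45) - 22.5)) > 1e-3]
  expected <- vapply(a, function(x) {
    cand <- canonical_angles()
    d <- pmin(abs(cand - x) %% 360, (360 - abs(cand - x)) %% 360)
    names(cand)[which.min(d)]
  }, character(1))
  expect_equal(snap_to_canonical(a), expected)
})

test_that("the displacement table matches brute-force recomputation and
           its symmetries", {
  tb <- table1()
  # brute force: Euclidean norm via to_cartesian on all 32 pairs
  offs <- list(East = c(4, 0), West = c(-4, 0),
               North = c(0, 4), South = c(0, -4))
  for (s in names(offs)) {
    for (loc in colnames(tb)) {
      p <- to_cartesian(field_location(loc, eccentricity_deg = 6))
      d <- sqrt((p[["x"]] - offs[[s]][1])^2 + (p[["y"]] - offs[[s]][2])^2)
      expect_equal(tb[s, loc], round_half_up(d, 2))
    }
  }
  # every row is a permutation of the same multiset
  ms <- c(2, 4.25, 4.25, 7.21, 7.21, 9.27, 9.27, 10)
  for (s in rownames(tb)) expect_equal(sort(unname(tb[s, ])), ms)
  # mirror symmetry across the N-S axis: East and West rows swap E/W pairs
  swap_ew <- c(N = "N", NE = "NW", E = "W", SE = "SW",
               S = "S", SW = "SE", W = "E", NW = "NE")
  expect_equal(unname(tb["East", ]), unname(tb["West", swap_ew]))
  swap_ns <- c(N = "S", NE = "SE", E = "E", SE = "NE",
               S = "N", SW = "NW", W = "W", NW = "SW")
  expect_equal(unname(tb["North", ]), unname(tb["South", swap_ns]))
})
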