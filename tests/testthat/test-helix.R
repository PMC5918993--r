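test_that("the axis of an ideal helix is recovered to within 1 degree", {
  h <- build_ideal_helix(13)
  ax <- fit_helix_axis(h, "name CA")
  expect_lt(acos(min(1, ax$direction[3])) * 180 / pi, 1)
  expect_equal(sqrt(sum(ax$direction^2)), 1, tolerance = 1e-9)
  expect_equal(ax$fit_rms, 2.3, tolerance = 0.05)  # perpendicular scatter = radius
  # short helix too
  ax8 <- fit_helix_axis(build_ideal_helix(8), "name CA")
  expect_lt(acos(min(1, ax8$direction[3])) * 180 / pi, 1)
})

test_that("the fitted axis is equivariant under rigid rotations", {
  h <- build_ideal_helix(13)
  R <- rot3(c(1, -1, 2), 53)
  h2 <- h
  h2$xyz <- sweep(h$xyz %*% t(R), 2, c(4, 5, -6), "+")
  ax2 <- fit_helix_axis(h2, "name CA")
  expect_lt(acos(min(1, sum(ax2$direction * (R %*% c(0, 0, 1))))) *
              180 / pi, 1)
})

test_that("coordinate noise of 0.3 A perturbs the axis by < 2 degrees on average", {
  h <- build_ideal_helix(13)
  set.seed(50)
  devs <- replicate(50, {
    hn <- h
    hn$xyz <- h$xyz + matrix(rnorm(length(h$xyz), 0, 0.3), ncol = 3)
    ax <- fit_helix_axis(hn, "name CA")
    acos(min(1, ax$direction[3])) * 180 / pi
  })
  expect_lt(mean(devs), 2)
})

test_that("pair angles follow the constructed geometry and sign convention", {
  h1 <- build_ideal_helix(13)
  expect_equal(helix_pair_angle(fit_helix_axis(h1, "all"),
                                fit_helix_axis(h1, "all"))$angle, 0,
               tolerance = 0.5)
  hx <- build_ideal_helix(13, direction = c(1, 0, 0), origin = c(25, 0, 0))
  expect_equal(helix_pair_angle(fit_helix_axis(h1, "all"),
                                fit_helix_axis(hx, "all"))$angle, 90,
               tolerance = 0.5)
  for (theta in c(26, 30, 44)) {
    ht <- build_ideal_helix(13,
                            direction = c(sin(theta * pi / 180), 0,
                                          cos(theta * pi / 180)),
                            origin = c(25, 0, 0))
    a <- fit_helix_axis(h1, "all")
    b <- fit_helix_axis(ht, "all")
    expect_equal(helix_pair_angle(a, b)$angle, theta, tolerance = 0.5)
    # swapping arguments changes nothing
    expect_equal(helix_pair_angle(b, a)$angle,
                 helix_pair_angle(a, b)$angle, tolerance = 1e-9)
  }
})

test_that("reversing one helix N->C orientation maps theta to 180 - theta", {
  h1 <- build_ideal_helix(13)
  h2 <- build_ideal_helix(13, direction = c(sin(0.5), 0, cos(0.5)),
                          origin = c(25, 0, 0))
  a <- fit_helix_axis(h1, "all")
  b <- fit_helix_axis(h2, "all")
  b_rev <- b
  b_rev$direction <- -b$direction
  expect_equal(helix_pair_angle(a, b_rev)$angle,
               180 - helix_pair_angle(a, b)$angle, tolerance = 1e-9)
})

test_that("angles are invariant under a global rigid transform", {
  sys <- build_two_domain_system()
  la <- attr(sys, "layout")
  ang <- function(s) helix_pair_angle(fit_helix_axis(s, la$indices$a1),
                                      fit_helix_axis(s, la$indices$a2))$angle
  base <- ang(sys)
  R <- rot3(c(2, 1, 1), 111)
  sys2 <- sys
  sys2$xyz <- sweep(sys$xyz %*% t(R), 2, c(10, -4, 2), "+")
  expect_equal(ang(sys2), base, tolerance = 1e-6)
})

test_that("an equal-dwell 26/44-degree hinge averages to ~35 degrees", {
  sys <- build_two_domain_system()
  la <- attr(sys, "layout")
  cfg <- generator_config(seed = 3, n_frames = 60, noise_sigma = 0.05,
                          hinge = list(helix = "a2", angles = c(26, 44)))
  st <- generate_trajectory(sys, cfg)
  as <- angle_series(st$trajectory, la$indices$a1, la$indices$a2)
  expect_equal(as$mean, 35, tolerance = 1)
  expect_equal(as$n_excluded, 0)
  expect_gt(as$sd, 5)   # bimodal, not smeared
  # the per-frame series follows the generator's schedule
  expect_equal(mean(as$angle[1:30]), 26, tolerance = 1)
  expect_equal(mean(as$angle[31:60]), 44, tolerance = 1)
})

test_that("a rigid trajectory has zero angle spread; one frame is its own mean", {
  sys <- build_two_domain_system()
  la <- attr(sys, "layout")
  tr <- traj_from_frames(sys, list(sys$xyz, sys$xyz, sys$xyz))
  as <- angle_series(tr, la$indices$a3, la$indices$a4)
  expect_equal(as$sd, 0)
  expect_equal(as$mean, 44, tolerance = 0.5)
  tr1 <- traj_from_frames(sys, list(sys$xyz))
  as1 <- angle_series(tr1, la$indices$a3, la$indices$a4)
  expect_equal(as1$mean, as1$angle[1])
  expect_equal(as1$sd, 0)
})

test_that("non-helical frames are excluded and degenerate fits rejected", {
  h <- build_ideal_helix(6)
  expect_error(fit_helix_axis(h, "resid 1-4"), ">= 5 C-alpha")
  # scrambled coordinates exceed the fit_rms threshold
  sys <- build_two_domain_system()
  la <- attr(sys, "layout")
  bad <- sys$xyz
  set.seed(60)
  bad[la$indices$a2, ] <- matrix(rnorm(length(la$indices$a2) * 3, 0, 6),
                                 ncol = 3)
  tr <- traj_from_frames(sys, list(sys$xyz, bad))
  as <- angle_series(tr, la$indices$a1, la$indices$a2)
  expect_equal(as$n_excluded, 1)
  expect_equal(as$mean, 26, tolerance = 0.5)
})
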