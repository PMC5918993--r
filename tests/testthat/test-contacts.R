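test_that("the distance criterion is boundary-inclusive and counts exactly", {
  s <- atoms_structure(c("C", "C"), rbind(c(0, 0, 0), c(4, 0, 0)))
  tr <- traj_from_frames(s, list(s$xyz))
  oc <- contact_occupancy(tr, contact_spec(1, 2, "distance", cutoff = 4))
  expect_true(oc$formed[1])          # exactly at the cutoff counts
  expect_equal(oc$occupancy, 1)
  # 70 of 100 frames within cutoff -> occupancy 0.70 exactly
  frames <- lapply(1:100, function(i) {
    x <- s$xyz
    x[2, 1] <- if (i <= 70) 3.5 else 6.0
    x
  })
  tr100 <- traj_from_frames(s, frames)
  oc100 <- contact_occupancy(tr100, contact_spec(1, 2, "distance",
                                                 cutoff = 4))
  expect_equal(oc100$occupancy, 0.70)
  expect_equal(oc100$min_dist[1], 3.5, tolerance = 1e-9)
})

test_that("the hydrogen-bond angle criterion separates 165 from 90 degrees", {
  build_hb <- function(angle_deg) {
    # donor N at origin, H at 1.0 A along x; acceptor O 1.9 A from H,
    # placed so the N-H...O angle at the hydrogen is angle_deg
    phi <- pi - angle_deg * pi / 180
    h <- c(1, 0, 0)
    o <- h + 1.9 * c(cos(phi), sin(phi), 0)
    atoms_structure(c("N", "H", "O"), rbind(c(0, 0, 0), h, o),
                    elety = c("N", "H1", "O"))
  }
  good <- build_hb(165)
  bad <- build_hb(90)
  spec <- contact_spec("name N", "name O", "hbond", cutoff = 3.5,
                       angle_min = 120)
  oc_good <- contact_occupancy(traj_from_frames(good, list(good$xyz)), spec)
  oc_bad <- contact_occupancy(traj_from_frames(bad, list(bad$xyz)), spec)
  expect_equal(oc_good$occupancy, 1)
  expect_equal(oc_bad$occupancy, 0)
  expect_false(oc_good$fallback)
})

test_that("hbond without any donor is a spec error; without H it falls back", {
  s <- atoms_structure(c("C", "C"), rbind(c(0, 0, 0), c(3, 0, 0)))
  tr <- traj_from_frames(s, list(s$xyz))
  expect_error(contact_occupancy(tr, contact_spec(1, 2, "hbond")),
               "spec error")
  s2 <- atoms_structure(c("N", "O"), rbind(c(0, 0, 0), c(2.9, 0, 0)))
  tr2 <- traj_from_frames(s2, list(s2$xyz))
  expect_warning(oc <- contact_occupancy(tr2, contact_spec(1, 2, "hbond")),
                 "distance-only")
  expect_true(oc$fallback)
  expect_equal(oc$occupancy, 1)
})

test_that("ion coordination uses O/N partners within its cutoff", {
  s <- atoms_structure(c("MG", "O", "C"),
                       rbind(c(0, 0, 0), c(2.1, 0, 0), c(2.1, 0, 0.5)),
                       elety = c("MG", "O1", "C1"))
  tr <- traj_from_frames(s, list(s$xyz))
  oc <- contact_occupancy(tr, contact_spec("name MG", "name O1,C1",
                                           "coordination"))
  expect_equal(oc$occupancy, 1)
  expect_equal(oc$min_dist[1], 2.1, tolerance = 1e-9)
  far <- s; far$xyz[2, 1] <- 3.5
  oc2 <- contact_occupancy(traj_from_frames(far, list(far$xyz)),
                           contact_spec("name MG", "name O1,C1",
                                        "coordination"))
  expect_equal(oc2$occupancy, 0)
})

test_that("occupancy is invariant under global rigid transforms", {
  mkframes <- function(transform) lapply(1:20, function(i) {
    x <- rand_structure(8, seed = 80)$xyz
    x[2, 1] <- x[1, 1] + ifelse(i %% 2 == 0, 3, 8)
    transform(x, i)
  })
  s <- rand_structure(8, seed = 80)
  plain <- traj_from_frames(s, mkframes(function(x, i) x))
  set.seed(81)
  Rs <- lapply(1:20, function(i) rot3(rnorm(3), runif(1, 0, 360)))
  moved <- traj_from_frames(s, mkframes(function(x, i)
    sweep(x %*% t(Rs[[i]]), 2, rnorm(3, 0, 5), "+")))
  spec <- contact_spec(1, 2, "distance", cutoff = 4)
  expect_equal(contact_occupancy(plain, spec)$occupancy,
               contact_occupancy(moved, spec)$occupancy)
})

test_that("a co-moving ligand has zero positional mobility", {
  sys <- build_two_domain_system()
  frames <- lapply(1:10, function(i)
    sweep(sys$xyz %*% t(rot3(c(0, 0, 1), i * 5)), 2, c(i, 0, 0), "+"))
  tr <- traj_from_frames(sys, frames)
  lm <- ligand_mobility(tr, "chain A,B", "resname LIG")
  expect_lt(lm$positional$mean, 1e-6)
  expect_lt(lm$internal$mean, 1e-6)
})

test_that("an isotropically jittered rigid ligand shows positional but no internal mobility", {
  sys <- build_two_domain_system()
  lig <- resolve_selection(sys, "resname LIG")$indices
  sigma <- 0.2
  set.seed(82)
  frames <- lapply(1:400, function(i) {
    x <- sys$xyz
    x[lig, ] <- sweep(x[lig, ], 2, rnorm(3, 0, sigma), "+")
    x
  })
  tr <- traj_from_frames(sys, frames)
  lm <- ligand_mobility(tr, "chain A,B", "resname LIG")
  # a rigid frame-wise offset d ~ N(0, sigma^2 I3) gives per-frame RMSD
  # |d|, whose mean is the 3-d chi mean 2*sigma*sqrt(2/pi)
  expect_equal(lm$positional$mean, 2 * sigma * sqrt(2 / pi),
               tolerance = 0.1)
  expect_lt(lm$internal$mean, 1e-5)
})

test_that("a two-pose rigid ligand is internally rigid but positionally bimodal", {
  sys <- build_two_domain_system()
  lig <- resolve_selection(sys, "resname LIG")$indices
  shifted <- sys$xyz
  shifted[lig, 1] <- shifted[lig, 1] + 2
  tr <- traj_from_frames(sys, list(sys$xyz, shifted, sys$xyz, shifted))
  lm <- ligand_mobility(tr, "chain A,B", "resname LIG")
  expect_lt(lm$internal$mean, 1e-8)
  expect_equal(lm$positional$rmsd, rep(1, 4), tolerance = 1e-6)
})
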