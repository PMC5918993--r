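two_mode_traj <- function(n_frames = 2000, vars = c(4, 1), seed = 11,
                          noise = 0.02) {
  sys <- build_two_domain_system()
  cfg <- generator_config(seed = seed, n_frames = n_frames,
                          noise_sigma = noise, mode_variances = vars)
  generate_trajectory(sys, cfg)
}

test_that("a single oscillating atom yields exactly one mode on that atom", {
  s <- rand_structure(10, seed = 40)
  up <- s$xyz; up[5, 1] <- up[5, 1] + 1
  dn <- s$xyz; dn[5, 1] <- dn[5, 1] - 1
  tr <- traj_from_frames(s, list(up, dn, up, dn))
  # fit on the static body so the localized motion is not redistributed
  m <- fit_pca(tr, selection = NULL, weighting = "uniform",
               fit_selection = c(1:4, 6:10))
  expect_gt(m$values[1], 0.9)
  expect_lt(m$values[2] / m$values[1], 1e-6)
  v <- matrix(m$vectors[, 1], ncol = 3)
  expect_gt(abs(v[5, 1]), 0.99)      # support concentrated on atom 5, x
})

test_that("a two-mode generator's eigenvalue ratio and spectrum are recovered", {
  st <- two_mode_traj()
  m <- fit_pca(st$trajectory, selection = NULL, weighting = "uniform")
  expect_equal(m$values[1] / m$values[2], 4, tolerance = 0.1)
  expect_lt(m$values[3] / m$values[1], 0.01)
  # trace identity: sum of eigenvalues = total weighted variance
  Xw <- trajkit:::.pca_frame_matrix(st$trajectory, m)
  total_var <- sum(Xw^2) / nrow(Xw)
  expect_equal(sum(m$values), total_var, tolerance = 1e-6)
})

test_that("projections carry the eigenvalue variance and are uncorrelated", {
  st <- two_mode_traj(n_frames = 1500, seed = 13)
  m <- fit_pca(st$trajectory, selection = NULL, weighting = "uniform")
  n <- n_frames(st$trajectory)
  p1 <- project(st$trajectory, m, 1)
  p2 <- project(st$trajectory, m, 2)
  v1 <- mean((p1$coord - mean(p1$coord))^2)
  expect_equal(v1, m$values[1], tolerance = 1e-6)
  expect_lt(abs(cor(p1$coord, p2$coord)), 0.05)
  expect_error(project(st$trajectory, m, 10000), "out of range")
})

test_that("filtering over all modes reconstructs the aligned trajectory", {
  st <- two_mode_traj(n_frames = 50, seed = 17)
  m <- fit_pca(st$trajectory, selection = "name N,CA,C")
  full <- filter_trajectory(st$trajectory, m, seq_along(m$values))
  aligned <- trajkit:::.fit_frames(st$trajectory, m$reference$xyz,
                                   m$selection)[m$selection, , ,
                                                drop = FALSE]
  expect_lt(max(abs(full$frames - aligned)), 1e-6)
  # empty mode set freezes every frame at the mean
  frozen <- filter_trajectory(st$trajectory, m, integer(0))
  spread <- apply(frozen$frames, c(1, 2), sd)
  expect_lt(max(spread), 1e-10)
})

test_that("mode-wise filtering obeys the variance bookkeeping", {
  st <- two_mode_traj(n_frames = 2000, seed = 19, noise = 0.002)
  m <- fit_pca(st$trajectory, selection = NULL, weighting = "uniform")
  # residual variance after keeping only mode 1 carries mode 2's eigenvalue
  Xw <- trajkit:::.pca_frame_matrix(st$trajectory, m)
  p1 <- Xw %*% m$vectors[, 1]
  resid_var <- sum(Xw^2) / nrow(Xw) - mean(p1^2)
  expect_equal(resid_var, sum(m$values[-1]), tolerance = 1e-6)
  expect_equal(resid_var, m$values[2], tolerance = 0.05)
})

test_that("the top eigenpair matches a power-iteration oracle", {
  st <- two_mode_traj(n_frames = 300, seed = 23)
  tr <- st$trajectory
  small <- md_trajectory(
    md_structure(tr$topology$atom[1:25, ], tr$topology$xyz[1:25, ]),
    tr$frames[1:25, , , drop = FALSE])
  m <- fit_pca(small, selection = NULL, weighting = "uniform")
  Xw <- trajkit:::.pca_frame_matrix(small, m)
  C <- crossprod(Xw) / nrow(Xw)
  v <- rep(1 / sqrt(ncol(C)), ncol(C))
  for (i in 1:500) { v <- C %*% v; v <- v / sqrt(sum(v^2)) }
  lam <- as.numeric(t(v) %*% C %*% v)
  expect_equal(m$values[1], lam, tolerance = 1e-6)
  expect_gt(abs(sum(v * m$vectors[, 1])), 1 - 1e-6)
})

test_that("eigenvalues are invariant under a rigid transform of the input", {
  st <- two_mode_traj(n_frames = 400, seed = 29)
  tr <- st$trajectory
  R <- rot3(c(1, 3, -2), 67)
  moved <- tr
  for (f in seq_len(n_frames(tr)))
    moved$frames[, , f] <- sweep(tr$frames[, , f] %*% t(R), 2,
                                 c(5, 5, 5), "+")
  m1 <- fit_pca(tr)
  m2 <- fit_pca(moved)
  top <- 1:5
  expect_equal(m2$values[top], m1$values[top], tolerance = 0.01)
})

test_that("uniform and mass weighting coincide for equal masses", {
  s <- rand_structure(12, seed = 44)       # all carbon
  set.seed(45)
  frames <- lapply(1:60, function(i)
    s$xyz + matrix(rnorm(length(s$xyz), 0, 0.3), ncol = 3))
  tr <- traj_from_frames(s, frames)
  mu <- fit_pca(tr, selection = NULL, weighting = "uniform")
  mm <- fit_pca(tr, selection = NULL, weighting = "mass")
  expect_equal(mm$values / mm$masses[1], mu$values, tolerance = 1e-8)
})

test_that("mode reports give monotone fractions and localized involvement", {
  st <- two_mode_traj(n_frames = 800, seed = 31)
  m <- fit_pca(st$trajectory, selection = NULL, weighting = "uniform")
  rep5 <- mode_report(m, 5)
  expect_true(all(diff(rep5$fraction) <= 1e-12))
  expect_lte(sum(rep5$fraction), 1 + 1e-9)
  expect_equal(colSums(rep5$involvement), rep(1, 5), tolerance = 1e-9)
  # hinge trajectory: the moving helix dominates mode 1
  sys <- build_two_domain_system()
  la <- attr(sys, "layout")
  cfgh <- generator_config(seed = 37, n_frames = 120, noise_sigma = 0.02,
                           hinge = list(helix = "a2", angles = c(26, 44)))
  sth <- generate_trajectory(sys, cfgh)
  mh <- fit_pca(sth$trajectory, selection = NULL, weighting = "uniform")
  rp <- mode_report(mh, 1)
  res_a2 <- paste(sys$atom$chain[la$indices$a2],
                  sys$atom$resno[la$indices$a2], sep = ":")
  moving <- rownames(rp$involvement) %in% res_a2
  expect_gt(sum(rp$involvement[moving, 1]), 0.8)
})
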