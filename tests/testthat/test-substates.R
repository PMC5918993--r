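markov_traj <- function(n_frames = 400, displacement = 3, seed = 5,
                        noise = 0.1, tm = NULL) {
  if (is.null(tm))
    tm <- matrix(c(.90, .05, .05,
                   .05, .90, .05,
                   .05, .05, .90), 3, 3, byrow = TRUE)
  sys <- build_two_domain_system()
  cfg <- generator_config(seed = seed, n_frames = n_frames,
                          noise_sigma = noise,
                          substates = list(n = nrow(tm),
                                           displacement = displacement,
                                           transition = tm,
                                           selection = NULL))
  list(sys = sys, st = generate_trajectory(sys, cfg))
}

label_accuracy <- function(truth, labels) {
  tab <- table(truth, labels)
  sum(apply(tab, 1, max)) / sum(tab)   # best per-state matching
}

test_that("identical frames collapse into a single cluster", {
  s <- rand_structure(10, seed = 70)
  tr <- traj_from_frames(s, list(s$xyz, s$xyz, s$xyz, s$xyz))
  sa <- cluster_substates(tr, cutoff = 0.5)
  expect_equal(length(sa$sizes), 1)
  expect_equal(sa$sizes, 4L)
  expect_true(all(sa$labels == 1))
})

test_that("two well-separated conformations cluster perfectly", {
  s <- rand_structure(10, seed = 71)
  b <- s$xyz
  b[6:10, 1] <- b[6:10, 1] + 6
  tr <- traj_from_frames(s, list(s$xyz, b, s$xyz, b, s$xyz, b))
  sa <- cluster_substates(tr, fit_selection = 1:5,
                          measure_selection = 6:10, cutoff = 1.0)
  expect_equal(length(sa$sizes), 2)
  expect_equal(sort(unique(sa$labels[c(1, 3, 5)])),
               sort(unique(sa$labels[c(1, 3, 5)])))
  expect_equal(label_accuracy(rep(1:2, 3), sa$labels), 1)
})

test_that("a 3-state Markov generator is recovered at >= 95% accuracy", {
  mk <- markov_traj()
  la <- attr(mk$sys, "layout")
  sa <- cluster_substates(mk$st$trajectory, fit_selection = "chain A",
                          measure_selection = la$indices$a4, cutoff = 0.8)
  expect_equal(length(sa$sizes), 3)
  acc <- label_accuracy(mk$st$ground_truth$states, sa$labels)
  expect_gte(acc, 0.95)
  # clusters are ordered by size, sizes sum to the frame count
  expect_true(all(diff(sa$sizes) <= 0))
  expect_equal(sum(sa$sizes), n_frames(mk$st$trajectory))
})

test_that("clustering is deterministic and medoids minimize summed RMSD", {
  mk <- markov_traj(n_frames = 120, seed = 9)
  la <- attr(mk$sys, "layout")
  run <- function() cluster_substates(mk$st$trajectory,
                                      fit_selection = "chain A",
                                      measure_selection = la$indices$a4,
                                      cutoff = 0.8)
  a <- run(); b <- run()
  expect_identical(a$labels, b$labels)
  expect_identical(a$medoids, b$medoids)
  # medoid property, checked exhaustively per cluster
  idx_fit <- a$fit_selection
  avg <- average_structure(mk$st$trajectory, idx_fit)
  fitted <- trajkit:::.fit_frames(mk$st$trajectory, avg$xyz, idx_fit)
  X <- t(apply(fitted[a$measure_selection, , , drop = FALSE], 3,
               as.vector))
  D <- as.matrix(dist(X)) / sqrt(length(a$measure_selection))
  for (k in seq_along(a$sizes)) {
    mem <- which(a$labels == k)
    sums <- rowSums(D[mem, mem, drop = FALSE])
    expect_equal(sum(D[a$medoids[k], mem]), min(sums), tolerance = 1e-12)
  }
})

test_that("per-cluster averages sit near the generating state centers", {
  mk <- markov_traj(n_frames = 600, seed = 12, noise = 0.08)
  la <- attr(mk$sys, "layout")
  gt <- mk$st$ground_truth
  sa <- cluster_substates(mk$st$trajectory, fit_selection = "chain A",
                          measure_selection = la$indices$a4, cutoff = 0.8)
  # match clusters to states by majority vote
  for (k in seq_along(sa$sizes)) {
    state <- as.integer(names(which.max(
      table(gt$states[sa$labels == k]))))
    expected <- mk$sys$xyz[gt$substate_indices, , drop = FALSE]
    expected <- sweep(expected, 2, gt$state_centers[[state]], "+")
    got <- sa$averages[[k]]$xyz[gt$substate_indices, , drop = FALSE]
    nk <- sa$sizes[k]
    expect_lt(max(abs(got - expected)), 3 * 0.08 / sqrt(nk) * 8)
  }
})

test_that("the labeled RMSD series tracks the state sequence", {
  mk <- markov_traj(n_frames = 200, seed = 21)
  la <- attr(mk$sys, "layout")
  sa <- cluster_substates(mk$st$trajectory, fit_selection = "chain A",
                          measure_selection = la$indices$a4, cutoff = 0.8)
  ser <- substate_series(sa, mk$st$trajectory,
                         average_structure(mk$st$trajectory, "chain A"))
  expect_named(ser, c("frame", "rmsd", "substate"))
  expect_identical(ser$substate, sa$labels)
  expect_gte(label_accuracy(mk$st$ground_truth$states, ser$substate), 0.95)
})

test_that("oversized trajectories are told to stride", {
  s <- rand_structure(5, seed = 73)
  tr <- traj_from_frames(s, rep(list(s$xyz), 30))
  expect_error(cluster_substates(tr, cutoff = 1, max_frames = 10),
               "stride")
})
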