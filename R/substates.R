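# Conformational-substate clustering (neighbor-counting / GROMOS-style)
# and labeled RMSD series with per-substate average structures.

#' Cluster trajectory frames into conformational substates
#'
#' Frames are superposed onto the converged average structure over
#' `fit_selection`; pairwise RMSD between frames is then measured on
#' `measure_selection` (no per-pair refit). Clustering is
#' neighbor-counting: the frame with the most neighbors within `cutoff`
#' becomes a cluster center, that cluster is removed, and the process
#' repeats. Ties are broken toward the lowest frame index, so the result is
#' fully deterministic. Clusters are relabeled by size, largest first.
#'
#' @param traj a `md_trajectory` (>= 2 frames).
#' @param fit_selection selection for superposition.
#' @param measure_selection selection on which RMSD is measured (default:
#'   `fit_selection`).
#' @param cutoff neighbor RMSD cutoff (A, inclusive); default 1.5.
#' @param max_frames cap on the pairwise-matrix size; more frames is an
#'   error instructing the caller to stride the trajectory first.
#' @return list of class `substate_assignment`: `labels` (per-frame,
#'   1..K, largest cluster = 1), `sizes`, `medoids` (frame index of each
#'   cluster's central structure), `averages` (list of `md_structure`),
#'   `cutoff`, `fit_selection`, `measure_selection`.
#' @export
cluster_substates <- function(traj, fit_selection = NULL,
                              measure_selection = fit_selection,
                              cutoff = 1.5, max_frames = 4000) {
  stopifnot(inherits(traj, "md_trajectory"), cutoff > 0)
  nf <- n_frames(traj)
  if (nf < 2) stop("clustering needs >= 2 frames", call. = FALSE)
  if (nf > max_frames)
    stop("pairwise RMSD matrix infeasible for ", nf, " frames ",
         "(cap ", max_frames, "); stride the trajectory first",
         call. = FALSE)
  idx_fit <- .sel_idx(traj, fit_selection)
  idx_meas <- .sel_idx(traj, measure_selection)
  avg <- average_structure(traj, idx_fit)
  fitted <- .fit_frames(traj, avg$xyz, idx_fit)
  X <- t(apply(fitted[idx_meas, , , drop = FALSE], 3, as.vector))
  D <- as.matrix(dist(X)) / sqrt(length(idx_meas))
  adj <- D <= cutoff            # inclusive boundary, as all cutoffs here
  labels <- rep(NA_integer_, nf)
  k <- 0L
  remaining <- rep(TRUE, nf)
  centers <- integer(0)
  while (any(remaining)) {
    counts <- rowSums(adj[, remaining, drop = FALSE]) * remaining
    center <- which.max(counts)      # ties -> lowest index (which.max)
    members <- which(adj[center, ] & remaining)
    k <- k + 1L
    labels[members] <- k
    centers[k] <- center
    remaining[members] <- FALSE
  }
  # relabel by size descending (stable: earlier cluster wins ties)
  sizes <- tabulate(labels, k)
  ord <- order(-sizes, seq_len(k))
  relab <- match(labels, ord)
  sizes <- sizes[ord]
  medoids <- vapply(seq_len(k), function(c) {
    mem <- which(relab == c)
    mem[which.min(rowSums(D[mem, mem, drop = FALSE]))]
  }, integer(1))
  averages <- lapply(seq_len(k), function(c) {
    mem <- which(relab == c)
    md_structure(traj$topology$atom,
                 apply(fitted[, , mem, drop = FALSE], c(1, 2), mean))
  })
  structure(list(labels = relab, sizes = sizes, medoids = medoids,
                 averages = averages, cutoff = cutoff,
                 fit_selection = idx_fit, measure_selection = idx_meas),
            class = "substate_assignment")
}

#' @export
print.substate_assignment <- function(x, ...) {
  cat("substate_assignment:", length(x$sizes), "substates, sizes",
      paste(x$sizes, collapse = "/"), "at cutoff", x$cutoff, "A\n")
  invisible(x)
}

#' Substate-labeled RMSD time series
#'
#' Per-frame RMSD to a reference structure (fit on the assignment's fit
#' selection, measured on its measure selection) annotated with each
#' frame's substate label — the standard way to display which substate a
#' trajectory occupies over time.
#'
#' @param assignment a `substate_assignment` computed on `traj`.
#' @param traj the same `md_trajectory`.
#' @param reference a `md_structure` (e.g. the overall average).
#' @return data.frame with columns `frame`, `rmsd`, `substate`.
#' @export
substate_series <- function(assignment, traj, reference) {
  stopifnot(inherits(assignment, "substate_assignment"))
  if (length(assignment$labels) != n_frames(traj))
    stop("assignment does not match this trajectory", call. = FALSE)
  rs <- rmsd_series(traj, reference,
                    fit_selection = assignment$fit_selection,
                    measure_selection = assignment$measure_selection)
  data.frame(frame = seq_len(n_frames(traj)), rmsd = rs$rmsd,
             substate = assignment$labels)
}
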