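# Principal component analysis of collective motion ("essential dynamics"):
# mass-weighted covariance of superposed backbone coordinates,
# eigen-decomposition, mode projections and per-mode filtered trajectories.

#' Principal component analysis of a trajectory
#'
#' Frames are superposed onto the iteratively converged average structure
#' over `selection` (a deterministic reference), centred, optionally
#' mass-weighted (coordinates scaled by sqrt(m)), and the covariance matrix
#' (1/n normalisation, so the projection-variance identity is exact) is
#' eigen-decomposed. Eigenvalues are reported in descending order; tiny
#' negative values from finite precision are clipped to zero.
#'
#' @param traj a `md_trajectory` with >= 2 frames.
#' @param selection atoms entering the analysis; the conventional choice is
#'   the backbone heavy atoms, `"name N,CA,C"` (the default).
#' @param weighting `"mass"` (default) or `"uniform"`.
#' @param fit_selection atoms used for the superposition (default: the
#'   analysis selection itself; a rigid core may be chosen instead so that
#'   localized motion is not partially absorbed into the fit).
#' @return list of class `pca_model`: `mean` (3N aligned mean, A),
#'   `values` (eigenvalues; amu A^2 under mass weighting), `vectors`
#'   (orthonormal columns), `selection`, `masses`, `weighting`,
#'   `atom` (atom table of the selection).
#' @export
fit_pca <- function(traj, selection = "name N,CA,C",
                    weighting = c("mass", "uniform"),
                    fit_selection = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(traj, "md_trajectory"))
  if (n_frames(traj) < 2)
    stop("data error: PCA needs >= 2 frames", call. = FALSE)
  idx <- .sel_idx(traj, selection)
  fit_idx <- if (is.null(fit_selection)) idx else
    .sel_idx(traj, fit_selection)
  avg <- average_structure(traj, fit_idx)
  fitted <- .fit_frames(traj, avg$xyz, fit_idx)
  nf <- n_frames(traj)
  X <- t(apply(fitted[idx, , , drop = FALSE], 3, as.vector))  # F x 3m
  m <- if (weighting == "mass") traj$topology$atom$mass[idx] else
    rep(1, length(idx))
  sw <- sqrt(rep(m, times = 3))       # column order: all x..., y..., z...
  mu <- colMeans(X)
  Xw <- sweep(sweep(X, 2, mu), 2, sw, "*")
  C <- crossprod(Xw) / nf
  e <- eigen(C, symmetric = TRUE)
  if (any(e$values < -1e-8 * max(abs(e$values))))
    stop("covariance eigenvalues unexpectedly negative", call. = FALSE)
  e$values[e$values < 0] <- 0
  structure(list(mean = mu, values = e$values, vectors = e$vectors,
                 selection = idx, fit_selection = fit_idx,
                 masses = m, weighting = weighting,
                 atom = traj$topology$atom[idx, ],
                 reference = avg),
            class = "pca_model")
}

# Aligned, centred, weighted frame matrix for a trajectory under a model.
.pca_frame_matrix <- function(traj, model) {
  idx <- model$selection
  fitted <- .fit_frames(traj, model$reference$xyz, model$fit_selection)
  X <- t(apply(fitted[idx, , , drop = FALSE], 3, as.vector))
  sw <- sqrt(rep(model$masses, times = 3))
  sweep(sweep(X, 2, model$mean), 2, sw, "*")
}

#' Project a trajectory onto one PCA mode
#'
#' @param traj a `md_trajectory` (typically the one the model was fitted
#'   on, but any trajectory sharing the topology works).
#' @param model a `pca_model`.
#' @param mode 1-based mode index.
#' @return list of class `mode_projection`: `coord` (per-frame scalar,
#'   A amu^1/2 under mass weighting), `mode`.
#' @export
project <- function(traj, model, mode) {
  stopifnot(inherits(model, "pca_model"))
  if (mode < 1 || mode > ncol(model$vectors))
    stop("index error: mode ", mode, " out of range", call. = FALSE)
  Xw <- .pca_frame_matrix(traj, model)
  structure(list(coord = as.vector(Xw %*% model$vectors[, mode]),
                 mode = mode),
            class = "mode_projection")
}

#' Reconstruct a trajectory from a subset of PCA modes
#'
#' Frames are rebuilt as `mean + sum_k p_k(t) v_k` in the weighted space and
#' back-transformed to plain coordinates — the per-eigenvector filtered
#' trajectory used to visualise individual collective motions. `modes =
#' integer(0)` yields the mean structure in every frame; the full mode set
#' reproduces the aligned trajectory exactly.
#'
#' @param traj a `md_trajectory`.
#' @param model a `pca_model`.
#' @param modes integer vector of 1-based mode indices.
#' @return a `md_trajectory` over the model's atom selection.
#' @export
filter_trajectory <- function(traj, model, modes) {
  stopifnot(inherits(model, "pca_model"))
  modes <- as.integer(modes)
  if (length(modes) && (min(modes) < 1 || max(modes) > ncol(model$vectors)))
    stop("index error: mode index out of range", call. = FALSE)
  Xw <- .pca_frame_matrix(traj, model)
  V <- model$vectors[, modes, drop = FALSE]
  Rw <- if (length(modes)) (Xw %*% V) %*% t(V) else
    matrix(0, nrow(Xw), ncol(Xw))
  sw <- sqrt(rep(model$masses, times = 3))
  Xr <- sweep(sweep(Rw, 2, sw, "/"), 2, model$mean, "+")
  nf <- nrow(Xr)
  na <- length(model$selection)
  frames <- array(t(Xr), dim = c(na, 3, nf))
  topo <- md_structure(model$atom, model$reference$xyz[model$selection, ])
  md_trajectory(topo, frames, frame_period = traj$frame_period)
}

#' Summarize the leading PCA modes
#'
#' @param model a `pca_model`.
#' @param n_modes number of leading modes to report (default 5, the usual
#'   number of eigenvectors carrying the global motions).
#' @return list of class `mode_report`: `fraction` (eigenvalue fraction of
#'   the total variance per mode) and `involvement` (per-residue share of
#'   each mode's eigenvector norm; columns are modes, rows residues, each
#'   column sums to 1).
#' @export
mode_report <- function(model, n_modes = 5) {
  stopifnot(inherits(model, "pca_model"))
  n_modes <- min(n_modes, sum(model$values > 0))
  if (n_modes < 1) stop("no modes with positive variance", call. = FALSE)
  frac <- model$values[seq_len(n_modes)] / sum(model$values)
  res <- paste(model$atom$chain, model$atom$resno, sep = ":")
  lev <- unique(res)
  inv <- sapply(seq_len(n_modes), function(k) {
    v <- model$vectors[, k]
    percomp <- matrix(v, ncol = 3)       # rows atoms, cols x/y/z
    a2 <- rowSums(percomp^2)
    w <- tapply(a2, factor(res, levels = lev), sum)
    as.vector(w / sum(w))
  })
  rownames(inv) <- lev
  structure(list(fraction = frac, involvement = inv), class = "mode_report")
}
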