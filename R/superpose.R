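# Optimal rigid-body superposition (Kabsch), average structures, RMSD/RMSF
# and per-residue difference maps.

# Kabsch: rotation R (acting on row vectors, y ~ x %*% R) and translation
# minimizing the weighted least-squares deviation of mobile onto reference.
.kabsch <- function(P, Q, w = NULL) {
  n <- nrow(P)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  cp <- colSums(P * w)
  cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  # degenerate sets: < 3 atoms, or (near-)collinear reference/mobile
  if (n < 3)
    stop("geometry error: superposition needs >= 3 atoms", call. = FALSE)
  sv_p <- svd(Pc * sqrt(w))$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1))
    stop("geometry error: collinear atom set, rotation underdetermined",
         call. = FALSE)
  H <- crossprod(Pc * w, Qc)
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  list(R = R, t = cq - as.vector(cp %*% R))
}

.apply_rt <- function(X, rt) sweep(X %*% rt$R, 2, rt$t, "+")

.rmsd_xyz <- function(X, Y, w = NULL) {
  d2 <- rowSums((X - Y)^2)
  if (is.null(w)) sqrt(mean(d2)) else sqrt(sum(w * d2) / sum(w))
}

#' Optimal least-squares superposition of two coordinate sets
#'
#' Computes the weighted Kabsch rigid transform (proper rotation only; the
#' determinant correction guarantees no reflection is ever returned) fitting
#' `mobile` onto `reference` over `fit_selection`, and the post-fit RMSD over
#' that selection.
#'
#' @param mobile,reference `md_structure` objects or plain `n x 3` coordinate
#'   matrices sharing atom correspondence.
#' @param fit_selection selection (object, expression or indices) resolved on
#'   both inputs; `NULL` means all atoms.
#' @param weights `"uniform"` (default) or `"mass"` (requires structures).
#' @return list of class `superposition` with `rotation` (3x3), `translation`
#'   (length 3, for `x %*% rotation + translation`), `rmsd` (A), and
#'   `coords` — all mobile atoms after the transform.
#' @export
superpose <- function(mobile, reference, fit_selection = NULL,
                      weights = c("uniform", "mass")) {
  weights <- match.arg(weights)
  Xall <- if (inherits(mobile, "md_structure")) mobile$xyz else
    as.matrix(mobile)
  Yall <- if (inherits(reference, "md_structure")) reference$xyz else
    as.matrix(reference)
  idx <- .sel_idx(if (inherits(mobile, "md_structure")) mobile else Xall,
                  fit_selection)
  if (length(.sel_idx(if (inherits(reference, "md_structure")) reference
                      else Yall, fit_selection)) != length(idx))
    stop("topology error: fit selection sizes differ", call. = FALSE)
  w <- NULL
  if (weights == "mass") {
    if (!inherits(mobile, "md_structure"))
      stop("mass weighting needs a md_structure mobile", call. = FALSE)
    w <- mobile$atom$mass[idx]
  }
  rt <- .kabsch(Xall[idx, , drop = FALSE], Yall[idx, , drop = FALSE], w)
  fit <- .apply_rt(Xall, rt)
  structure(list(rotation = rt$R, translation = rt$t,
                 rmsd = .rmsd_xyz(fit[idx, , drop = FALSE],
                                  Yall[idx, , drop = FALSE], w),
                 coords = fit),
            class = "superposition")
}

#' Pairwise RMSD after optimal superposition
#'
#' @inheritParams superpose
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(mobile, reference, fit_selection = NULL,
                 weights = c("uniform", "mass")) {
  superpose(mobile, reference, fit_selection, weights)$rmsd
}

# Superpose every frame of a trajectory onto reference coords over idx;
# returns n x 3 x F array of fitted full coordinates.
.fit_frames <- function(traj, ref_xyz, idx, w = NULL) {
  out <- traj$frames
  for (f in seq_len(n_frames(traj))) {
    X <- out[, , f]
    rt <- .kabsch(X[idx, , drop = FALSE], ref_xyz[idx, , drop = FALSE], w)
    out[, , f] <- .apply_rt(X, rt)
  }
  out
}

#' Iteratively converged average structure of a trajectory
#'
#' All frames are superposed onto the current average over `fit_selection`,
#' the mean coordinates are recomputed, and the cycle repeats until the mean
#' per-atom shift of the average falls below `tol`.
#'
#' @param traj a `md_trajectory` with at least 2 frames.
#' @param fit_selection selection used for the fit (default: all atoms).
#' @param tol convergence threshold on the mean per-atom shift (A).
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   last shift.
#' @return a `md_structure` holding the converged mean coordinates.
#' @export
average_structure <- function(traj, fit_selection = NULL, tol = 1e-4,
                              max_iter = 100) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (n_frames(traj) < 2)
    stop("average_structure needs >= 2 frames", call. = FALSE)
  idx <- .sel_idx(traj, fit_selection)
  avg <- frame_coords(traj, 1)
  for (it in seq_len(max_iter)) {
    fitted <- .fit_frames(traj, avg, idx)
    new_avg <- apply(fitted, c(1, 2), mean)
    shift <- mean(sqrt(rowSums((new_avg - avg)^2)))
    avg <- new_avg
    if (shift < tol)
      return(md_structure(traj$topology$atom, avg))
  }
  stop("convergence error: average structure did not converge in ",
       max_iter, " iterations (last mean shift ", signif(shift, 3), " A)",
       call. = FALSE)
}

#' Per-frame RMSD series with normalized histogram
#'
#' Each frame is fitted on `fit_selection` onto the reference, and the RMSD
#' is then measured on `measure_selection` (which may differ — e.g. fit on
#' the receptor, measure on the ligand).
#'
#' @param traj a `md_trajectory`.
#' @param reference a `md_structure` (e.g. the [average_structure()]).
#' @param fit_selection,measure_selection selections; `measure_selection`
#'   defaults to `fit_selection`, which defaults to all atoms.
#' @param breaks histogram bin width in Angstrom (default 0.1).
#' @return list of class `rmsd_series`: `rmsd` (per-frame, A), `hist`
#'   (density-normalized `hist` object), `mean`, `sd`.
#' @export
rmsd_series <- function(traj, reference, fit_selection = NULL,
                        measure_selection = fit_selection, breaks = 0.1) {
  idx_fit <- .sel_idx(traj, fit_selection)
  idx_meas <- .sel_idx(traj, measure_selection)
  if (length(.sel_idx(reference, fit_selection)) != length(idx_fit))
    stop("topology error: selection sizes differ between trajectory and ",
         "reference", call. = FALSE)
  ref <- reference$xyz
  fitted <- .fit_frames(traj, ref, idx_fit)
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    .rmsd_xyz(fitted[idx_meas, , f], ref[idx_meas, , drop = FALSE]),
    numeric(1))
  brk <- seq(0, max(vals) + breaks, by = breaks)
  h <- graphics::hist(vals, breaks = brk, plot = FALSE)
  structure(list(rmsd = vals, hist = h, mean = mean(vals), sd = sd(vals)),
            class = "rmsd_series")
}

#' Root-mean-square fluctuation profile
#'
#' Fluctuations are measured about the converged [average_structure()] after
#' per-frame superposition on `fit_selection`. With `aggregate = "residue"`,
#' the profile is the root-mean-square of the per-atom values over each
#' residue's selected atoms.
#'
#' @param traj a `md_trajectory` (>= 2 frames).
#' @param fit_selection selection used for the per-frame superposition.
#' @param measure_selection atoms profiled (default: all atoms, so a fit on
#'   a rigid core still reports the fluctuation of everything else).
#' @param aggregate `"atom"` or `"residue"`.
#' @return list of class `rmsf_profile`: `value` (A), `label` (atom index or
#'   `chain:resno`), `selection`, `reference` (the average structure).
#' @export
rmsf <- function(traj, fit_selection = NULL, measure_selection = NULL,
                 aggregate = c("atom", "residue")) {
  aggregate <- match.arg(aggregate)
  fit_idx <- .sel_idx(traj, fit_selection)
  idx <- .sel_idx(traj, measure_selection)
  avg <- average_structure(traj, fit_selection)
  fitted <- .fit_frames(traj, avg$xyz, fit_idx)
  msf <- rowMeans(apply(fitted, 3, function(F)
    rowSums((F - avg$xyz)^2))[idx, , drop = FALSE])
  at <- traj$topology$atom[idx, ]
  if (aggregate == "atom") {
    val <- sqrt(msf)
    lab <- as.character(idx)
  } else {
    res <- paste(at$chain, at$resno, sep = ":")
    val <- sqrt(as.vector(tapply(msf, factor(res, levels = unique(res)),
                                 mean)))
    lab <- unique(res)
  }
  structure(list(value = unname(val), label = lab,
                 selection = fit_selection, reference = avg,
                 aggregate = aggregate),
            class = "rmsf_profile")
}

#' Per-residue difference maps between two systems
#'
#' Two variants, following the two standard comparison figures of trajectory
#' studies:
#' \describe{
#'   \item{displacement}{per-residue RMS distance between the two average
#'     structures after superposing `b`'s average onto `a`'s over
#'     `fit_selection`; non-negative, display scale 0 -> 4 A.}
#'   \item{drmsf}{per-residue RMSF(b) - RMSF(a); signed, display scale
#'     -1.2 -> +1.2 A.}
#' }
#' Residues are matched by `chain:resno`.
#'
#' @param a,b `md_trajectory` objects (displacement variant) or
#'   `rmsf_profile` objects (drmsf variant).
#' @param fit_selection selection for the superposition (displacement
#'   variant), resolvable on both trajectories.
#' @param measure_selection atoms entering the per-residue RMS (displacement
#'   variant); defaults to all atoms.
#' @param type `"displacement"` or `"drmsf"`; inferred from the inputs when
#'   missing.
#' @return list of class `difference_map`: `residue`, `value` (A), `type`,
#'   `scale_bounds`.
#' @export
difference_map <- function(a, b, fit_selection = NULL,
                           measure_selection = NULL, type = NULL) {
  if (is.null(type))
    type <- if (inherits(a, "rmsf_profile")) "drmsf" else "displacement"
  if (type == "drmsf") {
    stopifnot(inherits(a, "rmsf_profile"), inherits(b, "rmsf_profile"))
    if (a$aggregate != "residue" || b$aggregate != "residue")
      stop("drmsf maps need residue-aggregated profiles", call. = FALSE)
    m <- match(a$label, b$label)
    if (anyNA(m))
      stop("mapping error: residues not alignable: ",
           paste(head(a$label[is.na(m)], 5), collapse = " "), call. = FALSE)
    return(structure(list(residue = a$label, value = b$value[m] - a$value,
                          type = "drmsf", scale_bounds = c(-1.2, 1.2)),
                     class = "difference_map"))
  }
  stopifnot(inherits(a, "md_trajectory"), inherits(b, "md_trajectory"))
  avg_a <- average_structure(a, fit_selection)
  avg_b <- average_structure(b, fit_selection)
  fit <- superpose(avg_b, avg_a, fit_selection)
  at_a <- avg_a$atom
  at_b <- avg_b$atom
  ia <- .sel_idx(avg_a, measure_selection)
  key_a <- paste(at_a$chain[ia], at_a$resno[ia], at_a$elety[ia])
  key_b <- paste(at_b$chain, at_b$resno, at_b$elety)
  m <- match(key_a, key_b)
  if (anyNA(m))
    stop("mapping error: atoms not alignable: ",
         paste(head(key_a[is.na(m)], 5), collapse = ", "), call. = FALSE)
  d2 <- rowSums((avg_a$xyz[ia, , drop = FALSE] -
                 fit$coords[m, , drop = FALSE])^2)
  res <- paste(at_a$chain[ia], at_a$resno[ia], sep = ":")
  val <- sqrt(as.vector(tapply(d2, factor(res, levels = unique(res)),
                               mean)))
  structure(list(residue = unique(res), value = unname(val),
                 type = "displacement", scale_bounds = c(0, 4)),
            class = "difference_map")
}

#' Write a per-frame or per-residue series as CSV
#'
#' @param x an `rmsd_series`, `rmsf_profile` or `difference_map`.
#' @param path output CSV path.
#' @export
write_series_csv <- function(x, path) {
  df <- if (inherits(x, "rmsd_series"))
    data.frame(frame = seq_along(x$rmsd), value = x$rmsd)
  else if (inherits(x, "rmsf_profile"))
    data.frame(label = x$label, value = x$value)
  else if (inherits(x, "difference_map"))
    data.frame(residue = x$residue, value = x$value)
  else stop("unsupported object for CSV export", call. = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a difference map as a B-factor-stuffed PDB for visualisation
#'
#' @param map a `difference_map`.
#' @param structure the `md_structure` whose residues the map indexes.
#' @param path output PDB path.
#' @export
write_map_pdb <- function(map, structure, path) {
  res <- paste(structure$atom$chain, structure$atom$resno, sep = ":")
  b <- map$value[match(res, map$residue)]
  b[is.na(b)] <- 0
  write_pdb(structure, path, b = b)
}
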