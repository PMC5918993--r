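# Helix-axis fitting and inter-helix angles.

#' Fit a helical axis to a residue range
#'
#' The C-alpha trace is first reduced to a chain of local helix origins:
#' at each interior residue the bisector of the two chain bonds points
#' toward the axis, the local twist angle follows from consecutive
#' bisectors, and the local radius from the radial component of the chain
#' bond, placing one on-axis origin per interior residue (this
#' construction is exact for an ideal helix, so no winding bias remains).
#' A total-least-squares line (first principal direction) is then fitted
#' to the origin chain. The direction is signed to point from the
#' N-terminal toward the C-terminal end, so angles between two axes are
#' orientation-aware.
#'
#' @param structure a `md_structure`.
#' @param range selection containing >= 5 C-alpha atoms (non-CA atoms in
#'   the selection are ignored).
#' @return list of class `helix_axis`: `origin` (centroid), `direction`
#'   (unit, N->C), `fit_rms` (perpendicular RMS scatter of the C-alphas
#'   about the axis, A), `n_ca`.
#' @export
fit_helix_axis <- function(structure, range) {
  idx <- .sel_idx(structure, range)
  idx <- idx[toupper(structure$atom$elety[idx]) == "CA"]
  if (length(idx) < 5)
    stop("geometry error: helix fit needs >= 5 C-alpha atoms, got ",
         length(idx), call. = FALSE)
  ca <- structure$xyz[idx, , drop = FALSE]
  # order along the chain
  ord <- order(structure$atom$resno[idx])
  ca <- ca[ord, , drop = FALSE]
  n <- nrow(ca)
  # unit bisectors at interior residues (point from CA toward the axis)
  v1 <- ca[1:(n - 2), , drop = FALSE] - ca[2:(n - 1), , drop = FALSE]
  v2 <- ca[3:n, , drop = FALSE] - ca[2:(n - 1), , drop = FALSE]
  bis <- v1 + v2
  bn <- sqrt(rowSums(bis^2))
  if (any(bn < 1e-8))
    stop("geometry error: degenerate (zero-variance) helix coordinates",
         call. = FALSE)
  bis <- bis / bn
  # local twist from consecutive bisectors, local radius from the radial
  # component of the chain bond: R (1 - cos t) = (CA_{i+1}-CA_i) . b_i
  nb <- nrow(bis)
  ct <- rowSums(bis[-nb, , drop = FALSE] * bis[-1, , drop = FALSE])
  cos_t <- mean(pmax(-1, pmin(1, ct)))
  bond <- ca[3:n, , drop = FALSE] - ca[2:(n - 1), , drop = FALSE]
  R_loc <- mean(rowSums(bond * bis)) / (1 - cos_t)
  org <- ca[2:(n - 1), , drop = FALSE] + R_loc * bis
  ctr <- colMeans(org)
  M <- sweep(org, 2, ctr)
  sv <- svd(M)
  if (sv$d[1] < 1e-8)
    stop("geometry error: degenerate (zero-variance) helix coordinates",
         call. = FALSE)
  dir <- sv$v[, 1]
  if (sum((org[nrow(org), ] - org[1, ]) * dir) < 0) dir <- -dir
  perp <- sweep(ca, 2, ctr)
  perp <- perp - outer(as.vector(perp %*% dir), dir)
  structure(list(origin = ctr, direction = dir / sqrt(sum(dir^2)),
                 fit_rms = sqrt(mean(rowSums(perp^2))),
                 n_ca = length(idx)),
            class = "helix_axis")
}

#' Angle between two helix axes
#'
#' `acos` of the dot product of the two signed (N->C) directions, in
#' degrees on `[0, 180]`. Because directions are signed, an opening hinge
#' is distinguished from its supplementary closing geometry.
#'
#' @param a,b `helix_axis` objects.
#' @param label optional pair label (e.g. `"alpha_C1"`).
#' @return list of class `helix_pair_angle` with `angle` (degrees) and
#'   `label`.
#' @export
helix_pair_angle <- function(a, b, label = NULL) {
  stopifnot(inherits(a, "helix_axis"), inherits(b, "helix_axis"))
  d <- sum(a$direction * b$direction)
  structure(list(angle = acos(max(-1, min(1, d))) * 180 / pi,
                 label = label),
            class = "helix_pair_angle")
}

#' Per-frame inter-helix angle series
#'
#' Fits both helix axes in every frame and reports the angle time series
#' with mean and standard deviation. Frames in which either range's
#' perpendicular scatter exceeds `max_fit_rms` are flagged non-helical and
#' excluded from the summary (with a count). A warning is issued if any
#' retained angle lies within 5 degrees of the 0/180 wrap, where the plain
#' mean is no longer circular-safe.
#'
#' @param traj a `md_trajectory`.
#' @param range_a,range_b selections for the two helices.
#' @param max_fit_rms non-helicity threshold on `fit_rms` (A, default 2.5).
#' @param label optional pair label.
#' @return list of class `angle_series`: `angle` (per-frame degrees, NA for
#'   excluded frames), `mean`, `sd`, `n_excluded`, `label`.
#' @export
angle_series <- function(traj, range_a, range_b, max_fit_rms = 2.5,
                         label = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  ang <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    s <- frame_structure(traj, f)
    ax_a <- tryCatch(fit_helix_axis(s, range_a), error = function(e) NULL)
    ax_b <- tryCatch(fit_helix_axis(s, range_b), error = function(e) NULL)
    if (is.null(ax_a) || is.null(ax_b)) next
    if (ax_a$fit_rms > max_fit_rms || ax_b$fit_rms > max_fit_rms) next
    ang[f] <- helix_pair_angle(ax_a, ax_b)$angle
  }
  ok <- !is.na(ang)
  if (any(ok) && any(ang[ok] < 5 | ang[ok] > 175))
    warning("angles within 5 degrees of the 0/180 wrap; ",
            "plain mean may be biased")
  structure(list(angle = ang,
                 mean = if (any(ok)) mean(ang[ok]) else NA_real_,
                 sd = if (sum(ok) > 1) sd(ang[ok]) else
                   if (any(ok)) 0 else NA_real_,
                 n_excluded = sum(!ok), label = label),
            class = "angle_series")
}
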