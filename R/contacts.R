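# Interaction occupancy (distance / hydrogen-bond / ion-coordination
# criteria) and ligand mobility.

#' Specify an interaction criterion between two atom groups
#'
#' @param group_a,group_b selection expressions or objects. For `hbond`,
#'   donors are sought in `group_a` and acceptors in `group_b`; for
#'   `coordination`, `group_a` is the ion (or ions) and `group_b` the
#'   coordinating O/N pool.
#' @param criterion `"distance"`, `"hbond"` or `"coordination"`.
#' @param cutoff distance cutoff in A, compared inclusively (`<=`).
#'   Defaults: 4.0 (distance), 3.5 donor-acceptor (hbond), 2.6 ion-O/N
#'   (coordination).
#' @param angle_min minimum donor-H...acceptor angle in degrees (hbond
#'   only; default 120). Ignored when no hydrogens are present, in which
#'   case the criterion degrades to distance-only and the result is
#'   flagged.
#' @return list of class `contact_spec`.
#' @export
contact_spec <- function(group_a, group_b,
                         criterion = c("distance", "hbond", "coordination"),
                         cutoff = NULL, angle_min = 120) {
  criterion <- match.arg(criterion)
  if (is.null(cutoff))
    cutoff <- switch(criterion, distance = 4.0, hbond = 3.5,
                     coordination = 2.6)
  stopifnot(cutoff > 0)
  structure(list(group_a = group_a, group_b = group_b,
                 criterion = criterion, cutoff = cutoff,
                 angle_min = angle_min),
            class = "contact_spec")
}

.min_cross_dist <- function(X, Y) {
  # min distance between two coordinate sets
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  sqrt(max(0, min(d2)))
}

.angle_deg <- function(a, b, c) {
  # angle at vertex b, degrees
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

#' Interaction occupancy over a trajectory
#'
#' Evaluates a [contact_spec()] in every frame and reports the per-frame
#' formed/broken state, the per-frame minimum relevant distance, and the
#' occupancy (fraction of frames formed). All cutoffs are inclusive.
#'
#' @param traj a `md_trajectory`.
#' @param spec a `contact_spec`.
#' @return list of class `occupancy_series`: `formed` (logical), `min_dist`
#'   (A), `occupancy`, `fallback` (`TRUE` when an hbond criterion had to
#'   drop its angle term for lack of hydrogens).
#' @export
contact_occupancy <- function(traj, spec) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(spec, "contact_spec"))
  at <- traj$topology$atom
  ia <- .sel_idx(traj, spec$group_a)
  ib <- .sel_idx(traj, spec$group_b)
  nf <- n_frames(traj)
  fallback <- FALSE

  if (spec$criterion == "hbond") {
    don <- ia[at$elesy[ia] %in% c("N", "O")]
    acc <- ib[at$elesy[ib] %in% c("N", "O")]
    if (!length(don) || !length(acc))
      stop("spec error: hbond criterion needs N/O donors in group_a and ",
           "acceptors in group_b", call. = FALSE)
    hyd <- which(at$elesy == "H")
    # attach hydrogens to donors by covalent proximity in the topology frame
    ref <- traj$topology$xyz
    don_h <- lapply(don, function(d) {
      if (!length(hyd)) return(integer(0))
      hd <- hyd[sqrt(rowSums(sweep(ref[hyd, , drop = FALSE], 2,
                                   ref[d, ])^2)) <= 1.25]
      hd
    })
    if (!any(lengths(don_h) > 0)) fallback <- TRUE
    formed <- logical(nf)
    mind <- numeric(nf)
    for (f in seq_len(nf)) {
      X <- frame_coords(traj, f)
      ok <- FALSE
      best <- Inf
      for (di in seq_along(don)) {
        d <- don[di]
        dd <- sqrt(rowSums(sweep(X[acc, , drop = FALSE], 2, X[d, ])^2))
        best <- min(best, dd)
        cand <- acc[dd <= spec$cutoff]
        if (!length(cand)) next
        hs <- don_h[[di]]
        if (!length(hs)) { if (fallback) ok <- TRUE; next }
        for (a in cand) {
          angs <- vapply(hs, function(h)
            .angle_deg(X[d, ], X[h, ], X[a, ]), numeric(1))
          if (any(angs >= spec$angle_min)) { ok <- TRUE; break }
        }
        if (ok) break
      }
      formed[f] <- ok
      mind[f] <- best
    }
    if (fallback)
      warning("no hydrogens present; hbond criterion degraded to ",
              "distance-only")
  } else {
    if (spec$criterion == "coordination")
      ib <- ib[at$elesy[ib] %in% c("N", "O")]
    if (!length(ia) || !length(ib))
      stop("spec error: empty group after role filtering", call. = FALSE)
    mind <- vapply(seq_len(nf), function(f) {
      X <- frame_coords(traj, f)
      .min_cross_dist(X[ia, , drop = FALSE], X[ib, , drop = FALSE])
    }, numeric(1))
    formed <- mind <= spec$cutoff
  }
  structure(list(formed = formed, min_dist = mind,
                 occupancy = mean(formed), fallback = fallback,
                 spec = spec),
            class = "occupancy_series")
}

#' Ligand mobility within a binding site
#'
#' Two complementary measures, both summarized as mean and standard
#' deviation over frames:
#' \describe{
#'   \item{positional}{per-frame RMSD of the ligand atoms to the ligand's
#'     average pose, after superposing each frame on `receptor_fit` —
#'     rattling of the whole ligand inside the site.}
#'   \item{internal}{same, but each frame's ligand is first superposed onto
#'     the average ligand on the ligand atoms themselves — pure
#'     conformational flexibility, zero for a rigid ligand.}
#' }
#'
#' @param traj a `md_trajectory`.
#' @param receptor_fit selection for the receptor superposition.
#' @param ligand ligand selection.
#' @return list of class `ligand_mobility`: `positional` and `internal`,
#'   each `list(rmsd, mean, sd)`.
#' @export
ligand_mobility <- function(traj, receptor_fit, ligand) {
  idx_fit <- .sel_idx(traj, receptor_fit)
  idx_lig <- .sel_idx(traj, ligand)
  if (!length(idx_lig)) stop("empty ligand selection", call. = FALSE)
  avg <- average_structure(traj, idx_fit)
  fitted <- .fit_frames(traj, avg$xyz, idx_fit)
  nf <- n_frames(traj)
  lig_mean <- apply(fitted[idx_lig, , , drop = FALSE], c(1, 2), mean)
  pos <- vapply(seq_len(nf), function(f)
    .rmsd_xyz(matrix(fitted[idx_lig, , f], ncol = 3), lig_mean),
    numeric(1))
  int <- vapply(seq_len(nf), function(f) {
    L <- matrix(fitted[idx_lig, , f], ncol = 3)
    rt <- .kabsch(L, lig_mean)
    .rmsd_xyz(.apply_rt(L, rt), lig_mean)
  }, numeric(1))
  structure(list(
    positional = list(rmsd = pos, mean = mean(pos), sd = sd(pos)),
    internal = list(rmsd = int, mean = mean(int), sd = sd(int))),
    class = "ligand_mobility")
}
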