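#' Structure and trajectory containers
#'
#' A `md_structure` holds an atom table plus one coordinate set; a
#' `md_trajectory` holds the same atom table plus an ordered stack of
#' coordinate frames. Coordinates are in Angstrom throughout; no unit
#' conversion is ever applied internally.
#'
#' @param atom data.frame with columns `eleno` (serial), `elety` (atom
#'   name), `elesy` (element symbol), `resid` (3-letter residue name),
#'   `resno` (residue id), `chain`, `mass` (Da), `radius` (A).
#' @param xyz numeric matrix, one row per atom, columns x/y/z (A).
#' @return an object of class `md_structure`.
#' @export
md_structure <- function(atom, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L)
    stop("xyz must have 3 columns", call. = FALSE)
  if (nrow(xyz) != nrow(atom))
    stop("coords length (", nrow(xyz), ") != atom count (", nrow(atom), ")",
         call. = FALSE)
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates", call. = FALSE)
  need <- c("eleno", "elety", "elesy", "resid", "resno", "chain",
            "mass", "radius")
  miss <- setdiff(need, names(atom))
  if (length(miss))
    stop("atom table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(atom$mass <= 0) || any(atom$radius <= 0))
    stop("masses and radii must be positive", call. = FALSE)
  key <- paste(atom$chain, atom$resno, atom$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom name) in atom table: ",
         key[anyDuplicated(key)], call. = FALSE)
  rownames(xyz) <- NULL
  structure(list(atom = as.data.frame(atom, stringsAsFactors = FALSE),
                 xyz = xyz),
            class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat("md_structure:", nrow(x$atom), "atoms,",
      length(unique(paste(x$atom$chain, x$atom$resno))), "residues,",
      "chains:", paste(unique(x$atom$chain), collapse = " "), "\n")
  invisible(x)
}

n_atoms <- function(x) {
  if (inherits(x, "md_trajectory")) nrow(x$topology$atom)
  else if (inherits(x, "md_structure")) nrow(x$atom)
  else nrow(as.matrix(x))
}

#' Build a trajectory from a topology and coordinate frames
#'
#' @param topology a `md_structure`; its coordinates serve as the reference
#'   frame and its atom table is shared by every frame.
#' @param frames numeric array `n_atoms x 3 x n_frames`, or a list of
#'   `n_atoms x 3` matrices.
#' @param frame_period time per frame in ns (metadata only; default 1).
#' @param discarded number of equilibration frames already removed
#'   (metadata; default 0).
#' @return an object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, frames, frame_period = 1,
                          discarded = 0L) {
  stopifnot(inherits(topology, "md_structure"))
  if (is.list(frames))
    frames <- array(unlist(frames),
                    dim = c(nrow(frames[[1]]), 3L, length(frames)))
  if (length(dim(frames)) != 3L || dim(frames)[2] != 3L)
    stop("frames must be an n_atoms x 3 x n_frames array", call. = FALSE)
  if (dim(frames)[1] != nrow(topology$atom))
    stop("frame atom count (", dim(frames)[1],
         ") != topology atom count (", nrow(topology$atom), ")",
         call. = FALSE)
  if (dim(frames)[3] < 1L)
    stop("trajectory needs at least one frame", call. = FALSE)
  storage.mode(frames) <- "double"
  structure(list(topology = topology, frames = frames,
                 frame_period = frame_period,
                 discarded = as.integer(discarded)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", dim(x$frames)[3], "frames x",
      dim(x$frames)[1], "atoms",
      sprintf("(period %g ns, %d equilibration frames discarded)\n",
              x$frame_period, x$discarded))
  invisible(x)
}

n_frames <- function(traj) dim(traj$frames)[3]

frame_coords <- function(traj, i) traj$frames[, , i, drop = TRUE]

#' Drop the equilibration segment of a trajectory
#'
#' Removes the leading frames of a trajectory and returns the trailing
#' production segment, mirroring the standard convention of analysing only
#' the post-equilibration window of a simulation. The number of discarded
#' frames is recorded in the result's metadata.
#'
#' @param traj a `md_trajectory`.
#' @param fraction_or_frames either an integer number of frames (>= 1) or a
#'   fraction in (0, 1) of the total frame count.
#' @return a `md_trajectory` holding the remaining frames (topology shared).
#' @examples
#' s <- build_ideal_helix(6)
#' tr <- md_trajectory(s, array(rep(s$xyz, 10), c(nrow(s$xyz), 3, 10)))
#' n_frames(discard_equilibration(tr, 4))      # 6
#' n_frames(discard_equilibration(tr, 0.5))    # 5
#' @export
discard_equilibration <- function(traj, fraction_or_frames) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  n <- if (fraction_or_frames > 0 && fraction_or_frames < 1)
    floor(fraction_or_frames * nf) else as.integer(fraction_or_frames)
  if (n < 0) stop("discard must be >= 0", call. = FALSE)
  if (n >= nf)
    stop("range error: cannot discard ", n, " of ", nf, " frames",
         call. = FALSE)
  if (n == 0) return(traj)
  md_trajectory(traj$topology,
                traj$frames[, , (n + 1L):nf, drop = FALSE],
                frame_period = traj$frame_period,
                discarded = traj$discarded + n)
}

#' Extract one frame of a trajectory as a structure
#' @param traj a `md_trajectory`.
#' @param i frame index.
#' @export
frame_structure <- function(traj, i) {
  md_structure(traj$topology$atom, frame_coords(traj, i))
}
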