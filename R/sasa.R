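# Solvent-accessible surface area by deterministic sphere-point sampling
# (Shrake-Rupley) and the interface buried-area statistic
# delta-ASA = (ASA_A + ASA_B - ASA_AB) / 2.

#' Surface and gap-volume parameters
#'
#' @param probe_radius solvent probe radius (A); 1.4 corresponds to water.
#' @param sample_points points per atom for the accessible-surface sampling.
#' @param grid_spacing lattice spacing for the gap-volume integration (A).
#' @param min_gap_sphere,max_gap_sphere radius window (A) for gap spheres:
#'   spheres smaller than the minimum (thin creases) or larger than the
#'   maximum (bulk solvent) are not counted as interface gap.
#' @param include_h include hydrogens in surface/gap computations (default
#'   `FALSE`: heavy atoms only, the convention of united-atom radii sets).
#' @return list of class `surface_params`.
#' @export
surface_params <- function(probe_radius = 1.4, sample_points = 960,
                           grid_spacing = 0.75, min_gap_sphere = 1.0,
                           max_gap_sphere = 5.0, include_h = FALSE) {
  stopifnot(probe_radius > 0, sample_points >= 16, grid_spacing > 0,
            min_gap_sphere < max_gap_sphere, min_gap_sphere >= 0)
  structure(list(probe_radius = probe_radius,
                 sample_points = sample_points,
                 grid_spacing = grid_spacing,
                 min_gap_sphere = min_gap_sphere,
                 max_gap_sphere = max_gap_sphere,
                 include_h = include_h),
            class = "surface_params")
}

# Deterministic quasi-uniform unit-sphere point set (Fibonacci lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.drop_h_idx <- function(structure, idx, params) {
  if (params$include_h) return(idx)
  idx[toupper(structure$atom$elesy[idx]) != "H"]
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' The accessible surface of each selected atom is sampled with a
#' deterministic Fibonacci point lattice on its probe-inflated sphere;
#' points occluded by any other selected atom are discarded. Only the
#' selected atoms act as occluders, so the ASA of a part "in isolation" is
#' obtained simply by selecting that part. Hydrogens are excluded unless
#' `params$include_h`.
#'
#' @param structure a `md_structure`.
#' @param selection selection (default: all atoms).
#' @param params a [surface_params()] list.
#' @return list of class `sasa_result`: `total` (A^2), `per_atom` (named by
#'   atom index; sums to `total`), `params`.
#' @export
sasa <- function(structure, selection = NULL, params = surface_params()) {
  idx <- .drop_h_idx(structure, .sel_idx(structure, selection), params)
  if (!length(idx))
    stop("selection error: no heavy atoms selected for sasa", call. = FALSE)
  xyz <- structure$xyz[idx, , drop = FALSE]
  rad <- structure$atom$radius[idx] + params$probe_radius
  n <- length(idx)
  pts <- .sphere_points(params$sample_points)
  area <- numeric(n)
  # neighbor pruning: atoms can only occlude within the sum of inflated radii
  maxr <- max(rad)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    P <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(P))
    for (j in nb) {
      if (!any(acc)) break
      acc[acc] <- rowSums(sweep(P[acc, , drop = FALSE], 2,
                                xyz[j, ])^2) > rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / nrow(P)
  }
  structure(list(total = sum(area), per_atom = setNames(area, idx),
                 params = params),
            class = "sasa_result")
}

#' Buried surface area on complex formation (delta-ASA)
#'
#' `delta_asa = (ASA_A + ASA_B - ASA_AB) / 2`, where the monomeric-state
#' terms are computed on each part in the conformation it adopts within the
#' complex (rigid-body convention: no relaxation), and `ASA_AB` on the
#' union of the two parts.
#'
#' @param complex a `md_structure` containing both parts.
#' @param part_A,part_B disjoint selections.
#' @param params a [surface_params()] list.
#' @return delta-ASA in A^2 (attributes `asa_A`, `asa_B`, `asa_AB`).
#' @export
delta_asa <- function(complex, part_A, part_B, params = surface_params()) {
  ia <- .sel_idx(complex, part_A)
  ib <- .sel_idx(complex, part_B)
  if (length(intersect(ia, ib)))
    stop("selection error: part_A and part_B overlap", call. = FALSE)
  aA <- sasa(complex, ia, params)$total
  aB <- sasa(complex, ib, params)$total
  aAB <- sasa(complex, sort(c(ia, ib)), params)$total
  out <- (aA + aB - aAB) / 2
  attr(out, "asa_A") <- aA
  attr(out, "asa_B") <- aB
  attr(out, "asa_AB") <- aAB
  out
}
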