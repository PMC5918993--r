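# Interface gap volume and gap index.
#
# The gap region between two molecular parts is modelled as the union of
# "gap spheres": for every facing atom pair (one atom per part) a sphere is
# seeded midway between the two van der Waals surfaces and shrunk to the
# largest radius that penetrates no atom; spheres with radius inside
# [min_gap_sphere, max_gap_sphere] are kept. This is a reproducible,
# grid-integrated variant of the classic sphere-packing procedure for
# inter-molecular gap volumes; it is documented as this package's own
# operational definition, not a bit-level replica of any prior program.

# Gap-sphere placement. Returns centers (m x 3) and radii (length m).
.gap_spheres <- function(xyz, rad, ia, ib, params) {
  min_r <- params$min_gap_sphere
  max_r <- params$max_gap_sphere
  centers <- NULL
  radii <- numeric(0)
  xa <- xyz[ia, , drop = FALSE]
  xb <- xyz[ib, , drop = FALSE]
  ra <- rad[ia]
  rb <- rad[ib]
  for (i in seq_along(ia)) {
    dv <- sweep(xb, 2, xa[i, ], "-")
    d <- sqrt(rowSums(dv^2))
    g <- d - ra[i] - rb                     # surface-to-surface gap
    cand <- which(g > 0 & g <= 2 * max_r)
    if (!length(cand)) next
    u <- dv[cand, , drop = FALSE] / d[cand]
    cc <- sweep(u * (ra[i] + g[cand] / 2), 2, xa[i, ], "+")
    centers <- rbind(centers, cc)
  }
  if (is.null(centers)) return(list(centers = NULL, radii = radii))
  # shrink each seed to the largest non-penetrating radius over ALL atoms
  # r <= g/2 <= max_r by construction (the seeding pair caps the radius),
  # so only the lower bound filters spheres here
  r <- apply(centers, 1, function(c0)
    min(sqrt(rowSums(sweep(xyz, 2, c0)^2)) - rad))
  keep <- r >= min_r
  list(centers = centers[keep, , drop = FALSE], radii = r[keep])
}

# Membership of arbitrary points in the union of spheres.
.in_sphere_union <- function(P, centers, radii) {
  inside <- rep(FALSE, nrow(P))
  for (k in seq_along(radii)) {
    todo <- !inside
    if (!any(todo)) break
    inside[todo] <- rowSums(sweep(P[todo, , drop = FALSE], 2,
                                  centers[k, ])^2) <= radii[k]^2
  }
  inside
}

#' Inter-molecular gap volume
#'
#' Volume of the empty region enclosed between two parts of a complex,
#' defined as the union of all gap spheres (see the module notes in the
#' source) and integrated on a deterministic cubic lattice of spacing
#' `params$grid_spacing`. `method = "mc"` integrates the identical region
#' with uniform random points instead — the discretization cross-check used
#' by the test suite.
#'
#' @param complex a `md_structure`.
#' @param part_A,part_B disjoint, non-empty selections.
#' @param params a [surface_params()] list.
#' @param method `"grid"` (default, deterministic) or `"mc"`.
#' @param mc_points number of random points for `method = "mc"`.
#' @return gap volume in A^3 (0, with a warning, when no gap sphere fits).
#' @export
gap_volume <- function(complex, part_A, part_B, params = surface_params(),
                       method = c("grid", "mc"), mc_points = 1e6) {
  method <- match.arg(method)
  ia <- .drop_h_idx(complex, .sel_idx(complex, part_A), params)
  ib <- .drop_h_idx(complex, .sel_idx(complex, part_B), params)
  if (!length(ia) || !length(ib))
    stop("selection error: empty part", call. = FALSE)
  if (length(intersect(ia, ib)))
    stop("selection error: parts overlap", call. = FALSE)
  both <- sort(c(ia, ib))
  xyz <- complex$xyz[both, , drop = FALSE]
  rad <- complex$atom$radius[both]
  sp <- .gap_spheres(xyz, rad, match(ia, both), match(ib, both), params)
  if (is.null(sp$centers) || length(sp$radii) == 0L) {
    warning("no gap region between the parts; gap volume 0")
    return(0)
  }
  lo <- apply(sp$centers - sp$radii, 2, min)
  hi <- apply(sp$centers + sp$radii, 2, max)
  if (method == "grid") {
    h <- params$grid_spacing
    ax <- lapply(1:3, function(k)
      seq(floor(lo[k] / h) * h, ceiling(hi[k] / h) * h, by = h))
    P <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
    sum(.in_sphere_union(P, sp$centers, sp$radii)) * h^3
  } else {
    P <- cbind(runif(mc_points, lo[1], hi[1]),
               runif(mc_points, lo[2], hi[2]),
               runif(mc_points, lo[3], hi[3]))
    mean(.in_sphere_union(P, sp$centers, sp$radii)) * prod(hi - lo)
  }
}

#' Interface complementarity metrics (gap index)
#'
#' Fills the full interface-metrics record: part and complex accessible
#' surface areas, buried area `delta_asa`, gap volume, and
#' `gap_index = gap_volume / delta_asa` (units A). Low gap-index values
#' indicate geometrically complementary, tight interfaces; typical
#' protein-protein values span roughly 1 to 5, with obligate/homodimeric
#' interfaces at the low end.
#'
#' @param complex a `md_structure`.
#' @param part_A,part_B disjoint selections.
#' @param params a [surface_params()] list.
#' @param min_delta_asa definedness threshold (A^2): below it the gap index
#'   is an undefined-division error.
#' @return list of class `interface_metrics`: `asa_A`, `asa_B`, `asa_AB`,
#'   `delta_asa`, `gap_volume`, `gap_index`, `band` (`"tight"` if
#'   gap_index < 2.5, `"intermediate"` < 5, else `"loose"`).
#' @export
gap_index <- function(complex, part_A, part_B, params = surface_params(),
                      min_delta_asa = 1) {
  da <- delta_asa(complex, part_A, part_B, params)
  if (da < min_delta_asa)
    stop("undefined gap index: delta-ASA (", signif(da, 3),
         " A^2) below threshold ", min_delta_asa, " A^2", call. = FALSE)
  gv <- gap_volume(complex, part_A, part_B, params)
  gi <- gv / as.numeric(da)
  structure(list(asa_A = attr(da, "asa_A"), asa_B = attr(da, "asa_B"),
                 asa_AB = attr(da, "asa_AB"), delta_asa = as.numeric(da),
                 gap_volume = gv, gap_index = gi,
                 band = if (gi < 2.5) "tight" else if (gi < 5)
                   "intermediate" else "loose"),
            class = "interface_metrics")
}

#' @export
print.interface_metrics <- function(x, ...) {
  cat(sprintf(paste0("interface: dASA %.1f A^2, gap volume %.1f A^3, ",
                     "gap index %.2f A (%s)\n"),
              x$delta_asa, x$gap_volume, x$gap_index, x$band))
  invisible(x)
}

#' Per-frame interface metrics over a trajectory
#'
#' Evaluates [gap_index()] on every `stride`-th frame and summarizes each
#' metric as mean and standard deviation. Frames whose gap index is
#' undefined (buried area below threshold) are excluded from the summary
#' and counted.
#'
#' @param traj a `md_trajectory`.
#' @param part_A,part_B disjoint selections on the topology.
#' @param params a [surface_params()] list.
#' @param stride evaluate every stride-th frame (default 1).
#' @param min_delta_asa passed to [gap_index()].
#' @return list of class `interface_series`: `frames` (indices evaluated),
#'   `table` (per-frame data.frame), `summary` (mean/sd per metric),
#'   `n_defined`, `n_undefined`, `params`.
#' @export
interface_series <- function(traj, part_A, part_B,
                             params = surface_params(), stride = 1L,
                             min_delta_asa = 1) {
  stopifnot(inherits(traj, "md_trajectory"), stride >= 1)
  fr <- seq(1L, n_frames(traj), by = as.integer(stride))
  rows <- vector("list", length(fr))
  und <- 0L
  for (k in seq_along(fr)) {
    s <- frame_structure(traj, fr[k])
    m <- tryCatch(gap_index(s, part_A, part_B, params, min_delta_asa),
                  error = function(e) NULL)
    if (is.null(m)) { und <- und + 1L; next }
    rows[[k]] <- data.frame(frame = fr[k], delta_asa = m$delta_asa,
                            gap_volume = m$gap_volume,
                            gap_index = m$gap_index,
                            asa_A = m$asa_A, asa_B = m$asa_B,
                            asa_AB = m$asa_AB)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  summ <- if (!is.null(tab) && nrow(tab) > 0)
    lapply(tab[-1], function(v) c(mean = mean(v), sd = sd(v))) else list()
  structure(list(frames = fr, table = tab, summary = summ,
                 n_defined = length(fr) - und, n_undefined = und,
                 params = params),
            class = "interface_series")
}

#' Write an interface series as CSV plus a JSON summary
#' @param x an `interface_series`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_interface_series <- function(x, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(x$table, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(summary = x$summary, n_defined = x$n_defined,
           n_undefined = x$n_undefined,
           params = unclass(x$params)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}
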