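# Synthetic structures and trajectories with recorded ground truth.
#
# The generator emulates the statistical features the analysis stages
# assume: a two-domain architecture with a planar interface of controllable
# separation, helix pairs at prescribed mutual angles, an interfacial
# ligand with ions, Markov-switched conformational substates, low-rank
# collective modes plus isotropic noise, and an optional hinge schedule.
# Every stochastic element is drawn from one explicitly seeded RNG and the
# drawn ground truth is returned alongside the trajectory.

.rot_about <- function(axis, theta_deg) {
  # Rodrigues rotation matrix (acting on row vectors via x %*% t(R))
  k <- axis / sqrt(sum(axis^2))
  th <- theta_deg * pi / 180
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.rot_z_to <- function(d) {
  # minimal rotation taking the z axis onto unit vector d
  d <- d / sqrt(sum(d^2))
  z <- c(0, 0, 1)
  v <- c(-d[2], d[1], 0)                 # z x d
  s2 <- sum(v^2)
  co <- d[3]                             # z . d
  if (s2 < 1e-24)
    return(if (co > 0) diag(3) else diag(c(1, -1, -1)))
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - co) / s2)
}

#' Build an ideal alpha-helix with backbone stubs
#'
#' C-alpha atoms are placed on a canonical helix (defaults: rise 1.5
#' A/residue, twist 100 degrees/residue, radius 2.3 A, giving the canonical
#' 3.8 A consecutive-CA spacing); N and C atoms are placed at fixed offsets
#' along the same helical path so that backbone selections
#' (`"name N,CA,C"`) resolve.
#'
#' @param n number of residues (>= 5).
#' @param rise,twist,radius helix parameters (A, degrees/residue, A).
#' @param direction unit 3-vector for the helix axis.
#' @param origin 3-vector added to all coordinates.
#' @param chain,resno_start,resid atom-table metadata.
#' @return a `md_structure` with 3 backbone atoms per residue.
#' @export
build_ideal_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3,
                              direction = c(0, 0, 1), origin = c(0, 0, 0),
                              chain = "A", resno_start = 1L,
                              resid = "ALA") {
  if (n < 5) stop("parameter error: helix needs n >= 5 residues",
                  call. = FALSE)
  place <- function(t, r) {
    a <- t * twist * pi / 180
    cbind(r * cos(a), r * sin(a), t * rise)
  }
  t_ca <- seq_len(n) - 1
  xyz <- matrix(NA_real_, 3 * n, 3)
  xyz[seq(2, 3 * n, 3), ] <- place(t_ca, radius)           # CA
  xyz[seq(1, 3 * n, 3), ] <- place(t_ca - 0.33, radius * 0.92)  # N
  xyz[seq(3, 3 * n, 3), ] <- place(t_ca + 0.33, radius * 0.92)  # C
  R <- .rot_z_to(direction)
  xyz <- sweep(xyz %*% t(R), 2, origin, "+")
  atom <- data.frame(
    eleno = seq_len(3 * n),
    elety = rep(c("N", "CA", "C"), n),
    elesy = rep(c("N", "C", "C"), n),
    resid = resid,
    resno = rep(resno_start + t_ca, each = 3),
    chain = chain,
    stringsAsFactors = FALSE)
  atom$mass <- lookup_mass(atom$elesy)
  atom$radius <- lookup_radius(atom$elesy)
  md_structure(atom, xyz)
}

#' Configuration for the synthetic two-domain generator
#'
#' Defaults describe the reference study conditions of the package's
#' validation suite: two domains whose helix pairs sit at 26 degrees
#' (domain 1, the closed apo-like state) and 44 degrees (domain 2), a
#' planar interface at 1.6 A surface separation (close enough for the
#' water probe to be excluded, so interface area is buried, the gap index
#' is defined and sits in the typical 1-5 A band), a 10-atom ring ligand with
#' two divalent ions, 300 frames, 0.1 A isotropic coordinate noise, and no
#' substate or collective-mode motion unless requested.
#'
#' @param seed RNG seed (integer).
#' @param n_frames number of trajectory frames.
#' @param noise_sigma isotropic Gaussian coordinate noise per frame (A).
#' @param interface_separation surface-to-surface distance between the two
#'   filler planes (A).
#' @param angle_c1,angle_c2 helix-pair angles of the two domains (degrees).
#' @param helix list of `rise`, `twist`, `radius` shared by all helices.
#' @param ranges named list of residue ranges for the four helices
#'   (defaults `a1` 408-420, `a2` 468-475, `a3` 910-918, `a4` 978-988).
#' @param grid_n,grid_spacing filler plane: `grid_n x grid_n` atoms at this
#'   spacing (A).
#' @param ligand list: `present`, `n_atoms`, `ions` (add two Mg ions),
#'   `jitter` (rigid random ligand displacement sd per frame, A).
#' @param mode_variances variances (A^2) of orthonormal internal collective
#'   modes added to the trajectory.
#' @param mode_selection atoms carrying the modes (default all).
#' @param substates list: `n` states, `displacement` step between adjacent
#'   state centers (A), `transition` (n x n row-stochastic matrix),
#'   `selection` (atoms displaced; default helix a4).
#' @param hinge `NULL`, or list: `helix` (`"a2"` or `"a4"`), `angles`
#'   (per-frame degrees, or 2 values for equal-dwell alternation).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_frames = 300L, noise_sigma = 0.1,
                             interface_separation = 1.6,
                             angle_c1 = 26, angle_c2 = 44,
                             helix = list(rise = 1.5, twist = 100,
                                          radius = 2.3),
                             ranges = list(a1 = c(408L, 420L),
                                           a2 = c(468L, 475L),
                                           a3 = c(910L, 918L),
                                           a4 = c(978L, 988L)),
                             grid_n = 7L, grid_spacing = 4,
                             ligand = list(present = TRUE, n_atoms = 10L,
                                           ions = TRUE, jitter = 0),
                             mode_variances = numeric(0),
                             mode_selection = NULL,
                             substates = list(n = 1L, displacement = 0,
                                              transition = matrix(1, 1, 1),
                                              selection = NULL),
                             hinge = NULL) {
  stopifnot(noise_sigma >= 0, interface_separation > 0, n_frames >= 1)
  if (!is.null(substates$transition)) {
    tm <- substates$transition
    if (nrow(tm) != substates$n || any(abs(rowSums(tm) - 1) > 1e-9))
      stop("config error: transition matrix rows must sum to 1 and match ",
           "the state count", call. = FALSE)
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Build the synthetic two-domain complex
#'
#' Two pseudo-domains (chains A and B), each a pair of ideal helices at the
#' configured mutual angle plus a planar grid of filler atoms; the two
#' filler planes face each other across the configured surface separation,
#' with an optional ring ligand (chain L) and two ions in a pocket at the
#' interface. Construction fails if any two atoms come closer than 1.5 A.
#'
#' The returned structure carries a `layout` attribute recording component
#' atom indices, helix anchors and base directions — the metadata
#' [generate_trajectory()] needs for hinge motion.
#'
#' @param config a [generator_config()].
#' @return a `md_structure` with attribute `layout`.
#' @export
build_two_domain_system <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  hx <- config$helix
  rg <- config$ranges
  sep <- config$interface_separation
  z_b <- -(sep + 2 * 1.7)        # plane B z; plane A at z = 0; radii 1.7

  nres <- function(r) r[2] - r[1] + 1L
  mk <- function(range, dir, origin, chain)
    build_ideal_helix(nres(range), hx$rise, hx$twist, hx$radius,
                      direction = dir, origin = origin, chain = chain,
                      resno_start = range[1])
  u_a1 <- c(0, 0, 1)
  u_a2 <- c(sin(config$angle_c1 * pi / 180), 0,
            cos(config$angle_c1 * pi / 180))
  u_a3 <- c(0, 0, -1)
  u_a4 <- c(sin(config$angle_c2 * pi / 180), 0,
            -cos(config$angle_c2 * pi / 180))
  anch <- list(a1 = c(-11, 0, 5), a2 = c(11, 0, 5),
               a3 = c(-11, 0, z_b - 5), a4 = c(11, 0, z_b - 5))
  helices <- list(
    a1 = mk(rg$a1, u_a1, anch$a1, "A"), a2 = mk(rg$a2, u_a2, anch$a2, "A"),
    a3 = mk(rg$a3, u_a3, anch$a3, "B"), a4 = mk(rg$a4, u_a4, anch$a4, "B"))

  # filler planes with a central pocket when a ligand is present
  g <- (seq_len(config$grid_n) - (config$grid_n + 1) / 2) *
    config$grid_spacing
  gxy <- as.matrix(expand.grid(x = g, y = g))
  lig_r <- if (isTRUE(config$ligand$present))
    max(2, 1.5 / (2 * sin(pi / config$ligand$n_atoms))) else 0
  hole <- if (lig_r > 0) lig_r + 3.8 else -1
  gxy <- gxy[sqrt(rowSums(gxy^2)) > hole, , drop = FALSE]
  mkplane <- function(z, chain) {
    n <- nrow(gxy)
    atom <- data.frame(
      eleno = seq_len(n), elety = "C", elesy = "C", resid = "FIL",
      resno = seq_len(n), chain = chain, stringsAsFactors = FALSE)
    atom$mass <- lookup_mass(atom$elesy)
    atom$radius <- lookup_radius(atom$elesy)
    md_structure(atom, cbind(gxy, z))
  }
  planes <- list(A = mkplane(0, "A"), B = mkplane(z_b, "B"))

  parts <- list(helices$a1, helices$a2, planes$A,
                helices$a3, helices$a4, planes$B)
  nm <- c("a1", "a2", "planeA", "a3", "a4", "planeB")

  if (isTRUE(config$ligand$present)) {
    na <- config$ligand$n_atoms
    zmid <- z_b / 2
    ang <- 2 * pi * (seq_len(na) - 1) / na
    lxyz <- cbind(lig_r * cos(ang), lig_r * sin(ang), zmid)
    # carbon ring with an oxygen every third atom, so coordination and
    # hydrogen-bond criteria have polar partners to find
    el <- ifelse(seq_len(na) %% 3 == 1, "O", "C")
    atom <- data.frame(
      eleno = seq_len(na), elety = paste0(el, seq_len(na)), elesy = el,
      resid = "LIG", resno = 1L, chain = "L", stringsAsFactors = FALSE)
    atom$mass <- lookup_mass(atom$elesy)
    atom$radius <- lookup_radius(atom$elesy)
    parts <- c(parts, list(md_structure(atom, lxyz)))
    nm <- c(nm, "ligand")
    if (isTRUE(config$ligand$ions)) {
      ixyz <- rbind(c(lig_r + 1.8, 0, zmid), c(-(lig_r + 1.8), 0, zmid))
      iat <- data.frame(eleno = 1:2, elety = "MG", elesy = "MG",
                        resid = "MG", resno = 2:3, chain = "L",
                        stringsAsFactors = FALSE)
      iat$mass <- lookup_mass(iat$elesy)
      iat$radius <- lookup_radius(iat$elesy)
      parts <- c(parts, list(md_structure(iat, ixyz)))
      nm <- c(nm, "ions")
    }
  }

  atom <- do.call(rbind, lapply(parts, function(p) p$atom))
  xyz <- do.call(rbind, lapply(parts, function(p) p$xyz))
  atom$eleno <- seq_len(nrow(atom))
  # placement check: no two atoms from DIFFERENT components may come
  # closer than 1.5 A (within a rigid component, bonded backbone stubs
  # are closer by construction)
  comp <- rep(seq_along(parts),
              vapply(parts, function(p) nrow(p$atom), integer(1)))
  D <- as.matrix(dist(xyz))
  D[outer(comp, comp, "==")] <- Inf
  if (min(D) < 1.5)
    stop("construction error: components closer than 1.5 A (min ",
         signif(min(D), 3), " A)", call. = FALSE)
  s <- md_structure(atom, xyz)
  sizes <- vapply(parts, function(p) nrow(p$atom), integer(1))
  ends <- cumsum(sizes)
  idx <- Map(function(a, b) seq(a, b), ends - sizes + 1L, ends)
  names(idx) <- nm
  attr(s, "layout") <- list(
    indices = idx,
    anchors = anch,
    base_dirs = list(a1 = u_a1, a2 = u_a2, a3 = u_a3, a4 = u_a4),
    base_angles = c(c1 = config$angle_c1, c2 = config$angle_c2),
    hinge_axis = c(0, 1, 0))
  s
}

# Orthonormal internal modes over the selected atoms: seeded Gaussian
# vectors with the 6 rigid-body modes projected out, then QR-orthonormalized.
.internal_modes <- function(xyz, idx, k) {
  n <- length(idx)
  ctr <- sweep(xyz[idx, , drop = FALSE], 2, colMeans(xyz[idx, , drop = FALSE]))
  rig <- cbind(
    rep(c(1, 0, 0), each = n), rep(c(0, 1, 0), each = n),
    rep(c(0, 0, 1), each = n),
    c(rep(0, n), -ctr[, 3], ctr[, 2]),
    c(ctr[, 3], rep(0, n), -ctr[, 1]),
    c(-ctr[, 2], ctr[, 1], rep(0, n)))
  Qr <- qr.Q(qr(rig))
  V <- matrix(rnorm(3 * n * k), 3 * n, k)
  V <- V - Qr %*% crossprod(Qr, V)
  qr.Q(qr(V))[, seq_len(k), drop = FALSE]
}

#' Generate a synthetic trajectory with recorded ground truth
#'
#' Each frame is assembled as: hinge-rotated base structure (if a hinge
#' schedule is configured) + the Markov-chain substate displacement + the
#' sum of collective-mode displacements with Gaussian amplitudes + a rigid
#' random ligand jitter (if configured) + isotropic Gaussian noise. The
#' returned object carries everything needed to score downstream recovery:
#' the state sequence, the mode matrix and per-frame coefficients, and the
#' hinge schedule.
#'
#' @param base a structure from [build_two_domain_system()] (or any
#'   `md_structure`; hinge motion then requires a `layout` attribute).
#' @param config a [generator_config()].
#' @return list of class `synthetic_trajectory`: `trajectory`
#'   (`md_trajectory`) and `ground_truth` (list: `states`, `state_centers`
#'   — per-state displacement of the substate selection, `mode_matrix`,
#'   `mode_coeffs`, `mode_selection`, `hinge_angles`, `seed`).
#' @export
generate_trajectory <- function(base, config = generator_config()) {
  stopifnot(inherits(base, "md_structure"),
            inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  nf <- config$n_frames
  na <- nrow(base$atom)
  layout <- attr(base, "layout")

  # hinge schedule (per-frame target angle for the chosen helix pair)
  hinge_angles <- NULL
  if (!is.null(config$hinge)) {
    if (is.null(layout))
      stop("config error: hinge motion needs a layout-carrying base",
           call. = FALSE)
    a <- config$hinge$angles
    hinge_angles <- if (length(a) == 2)
      a[1 + (seq_len(nf) > nf / 2)]      # equal-dwell halves
    else a
    if (length(hinge_angles) != nf)
      stop("config error: hinge angle schedule length != n_frames",
           call. = FALSE)
  }

  # substate machinery
  ss <- config$substates
  nstate <- if (is.null(ss$n)) 1L else ss$n
  states <- integer(nf)
  state_disp <- NULL
  ss_idx <- integer(0)
  if (nstate > 1) {
    sel <- if (is.null(ss$selection)) {
      if (is.null(layout)) stop("config error: substate selection needed",
                                call. = FALSE)
      layout$indices$a4
    } else .sel_idx(base, ss$selection)
    ss_idx <- sel
    # state j displaces the selection by (j-1)*displacement along +x
    state_disp <- lapply(seq_len(nstate), function(j)
      c((j - 1) * ss$displacement, 0, 0))
    states[1] <- 1L
    if (nf > 1) for (f in 2:nf)
      states[f] <- sample.int(nstate, 1, prob = ss$transition[states[f - 1], ])
  } else states[] <- 1L

  # collective modes
  kmode <- length(config$mode_variances)
  mode_idx <- if (is.null(config$mode_selection)) seq_len(na) else
    .sel_idx(base, config$mode_selection)
  modes <- NULL
  coeffs <- NULL
  if (kmode > 0) {
    modes <- .internal_modes(base$xyz, mode_idx, kmode)
    coeffs <- sapply(seq_len(kmode), function(k)
      rnorm(nf, 0, sqrt(config$mode_variances[k])))
    if (nf == 1) coeffs <- matrix(coeffs, 1)
  }

  lig_idx <- if (!is.null(layout) && !is.null(layout$indices$ligand))
    layout$indices$ligand else integer(0)
  jit <- if (isTRUE(config$ligand$present)) config$ligand$jitter else 0

  frames <- array(NA_real_, c(na, 3, nf))
  for (f in seq_len(nf)) {
    X <- base$xyz
    if (!is.null(hinge_angles)) {
      hname <- config$hinge$helix
      pair <- if (hname == "a2") "c1" else "c2"
      delta <- hinge_angles[f] - layout$base_angles[[pair]]
      # a2 opens about +y; a4's partner a3 points -z, so the same +y
      # rotation closes the pair: flip the sense for a4
      if (hname == "a4") delta <- -delta
      R <- .rot_about(layout$hinge_axis, delta)
      hidx <- layout$indices[[hname]]
      anc <- layout$anchors[[hname]]
      X[hidx, ] <- sweep(sweep(X[hidx, , drop = FALSE], 2, anc) %*% t(R),
                         2, anc, "+")
    }
    if (nstate > 1)
      X[ss_idx, ] <- sweep(X[ss_idx, , drop = FALSE], 2,
                           state_disp[[states[f]]], "+")
    if (kmode > 0) {
      dx <- matrix(modes %*% coeffs[f, ], ncol = 3)
      X[mode_idx, ] <- X[mode_idx, ] + dx
    }
    if (length(lig_idx) && jit > 0)
      X[lig_idx, ] <- sweep(X[lig_idx, , drop = FALSE], 2,
                            rnorm(3, 0, jit), "+")
    if (config$noise_sigma > 0)
      X <- X + matrix(rnorm(3 * na, 0, config$noise_sigma), na, 3)
    frames[, , f] <- X
  }
  traj <- md_trajectory(base, frames)
  structure(list(
    trajectory = traj,
    ground_truth = list(states = states, state_centers = state_disp,
                        substate_indices = ss_idx,
                        mode_matrix = modes, mode_coeffs = coeffs,
                        mode_selection = mode_idx,
                        hinge_angles = hinge_angles, seed = config$seed)),
    class = "synthetic_trajectory")
}

#' Write ground truth as JSON
#' @param x a `synthetic_trajectory`.
#' @param path output path.
#' @export
write_ground_truth <- function(x, path) {
  gt <- x$ground_truth
  gt$mode_matrix <- NULL   # bulky; coefficients + seed regenerate it
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
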