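# Shared fixtures and independent oracles for the test suite.

# Random non-degenerate structure of n carbon atoms.
rand_structure <- function(n, seed = 1, spread = 5) {
  set.seed(seed)
  xyz <- matrix(rnorm(3 * n, 0, spread), n, 3)
  atom <- data.frame(eleno = seq_len(n), elety = paste0("C", seq_len(n)),
                     elesy = "C", resid = "UNK", resno = seq_len(n),
                     chain = "A", mass = 12.011, radius = 1.7,
                     stringsAsFactors = FALSE)
  md_structure(atom, xyz)
}

# Structure with arbitrary atoms: el = element vector, xyz matrix.
atoms_structure <- function(el, xyz, elety = NULL, radius = NULL) {
  n <- length(el)
  atom <- data.frame(eleno = seq_len(n),
                     elety = if (is.null(elety)) paste0(el, seq_len(n))
                       else elety,
                     elesy = el, resid = "UNK", resno = seq_len(n),
                     chain = "A", stringsAsFactors = FALSE)
  atom$mass <- trajkit:::lookup_mass(atom$elesy)
  atom$radius <- if (is.null(radius)) trajkit:::lookup_radius(atom$elesy)
    else radius
  md_structure(atom, as.matrix(xyz))
}

# Trajectory from a list of coordinate matrices over one topology.
traj_from_frames <- function(topo, frames)
  md_trajectory(topo, array(unlist(frames),
                            c(nrow(topo$xyz), 3, length(frames))))

rot3 <- function(axis, deg) trajkit:::.rot_about(axis, deg)

# --- brute-force rotation oracle for minimal RMSD --------------------------
# Coarse Euler-angle grid followed by Nelder-Mead refinement from the best
# grid points; independent of the Kabsch path.
brute_min_rmsd <- function(P, Q, coarse = 20) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  euler_R <- function(a) rot3(c(0, 0, 1), a[1]) %*%
    rot3(c(0, 1, 0), a[2]) %*% rot3(c(0, 0, 1), a[3])
  f <- function(a) sqrt(mean(rowSums((Pc %*% t(euler_R(a)) - Qc)^2)))
  grid <- expand.grid(a = seq(0, 360 - coarse, by = coarse),
                      b = seq(0, 180, by = coarse),
                      c = seq(0, 360 - coarse, by = coarse))
  vals <- apply(grid, 1, f)
  best <- order(vals)[1:4]
  refined <- vapply(best, function(i)
    optim(as.numeric(grid[i, ]), f, method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-12))$value,
    numeric(1))
  min(refined)
}

# --- two-sphere spherical-cap closed form ----------------------------------
# Accessible areas of two probe-inflated spheres (radii R1, R2, centers d
# apart): each loses a cap of height h_i = R_i - x_i.
two_sphere_area <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(c(4 * pi * R1^2, 4 * pi * R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  c(4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1),
    4 * pi * R2^2 - 2 * pi * R2 * (R2 - x2))
}

# Two parallel square slabs of carbon atoms facing each other across a
# surface-to-surface separation (A), for the gap-volume family.
make_slabs <- function(separation, n = 6, spacing = 2.5, radius = 1.7) {
  g <- (seq_len(n) - (n + 1) / 2) * spacing
  gxy <- as.matrix(expand.grid(g, g))
  m <- nrow(gxy)
  xyz <- rbind(cbind(gxy, 0), cbind(gxy, -(separation + 2 * radius)))
  atom <- data.frame(eleno = seq_len(2 * m), elety = "C", elesy = "C",
                     resid = "SLB", resno = seq_len(2 * m),
                     chain = rep(c("A", "B"), each = m),
                     mass = 12.011, radius = radius,
                     stringsAsFactors = FALSE)
  md_structure(atom, xyz)
}

# Standard four-system synthetic comparison set: apo / +ligand (tighter
# interface, opened C1 hinge, stiller ligand region) / +partner (looser
# interface) / +both. Small frame counts keep the full pipeline fast.
demo_run_config <- function(label, traj, stride = 12) {
  run_config(
    label, traj, discard = 10,
    domains = list(C1 = "chain A", C2 = "chain B"),
    helix_pairs = list(
      alpha_C1 = list("chain A and resid 408-420",
                      "chain A and resid 468-475"),
      alpha_C2 = list("chain B and resid 910-918",
                      "chain B and resid 978-988")),
    interface = list(part_A = "chain A", part_B = "chain B"),
    ligand = "resname LIG", receptor_fit = "chain A,B",
    cluster_cutoff = 1.0, stride = stride)
}
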