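# Orchestration: run every analysis stage on one system and compare
# systems pairwise (difference maps + deltas of all scalar summaries).

#' Configuration for a full single-system analysis run
#'
#' @param label system label (e.g. `"apo"`, `"plus_ligand"`).
#' @param trajectory a `md_trajectory`, or the path of a multi-MODEL PDB.
#' @param discard equilibration discard (frames, or fraction in (0,1)).
#' @param domains named list of selection expressions, one per domain
#'   (RMSD/RMSF are reported per domain).
#' @param helix_pairs named list; each element is a length-2 list/vector of
#'   selection expressions for the two helices of the pair.
#' @param interface list with `part_A`, `part_B` selection expressions, or
#'   `NULL` to skip the interface stage.
#' @param ligand ligand selection expression or `NULL`.
#' @param receptor_fit selection used to fit frames for ligand mobility and
#'   as the global fit/PCA default region.
#' @param contacts named list of [contact_spec()] objects, or `NULL`.
#' @param pca_selection selection for the PCA stage (default backbone
#'   `"name N,CA,C"`).
#' @param surface a [surface_params()] list.
#' @param cluster_cutoff substate clustering cutoff (A).
#' @param cluster_selection selection clustered (default: first domain).
#' @param stride frame stride for the interface series.
#' @param outdir output directory for CSV/JSON artifacts, or `NULL`.
#' @return list of class `run_config`.
#' @export
run_config <- function(label, trajectory, discard = 0,
                       domains = list(), helix_pairs = list(),
                       interface = NULL, ligand = NULL,
                       receptor_fit = NULL, contacts = NULL,
                       pca_selection = "name N,CA,C",
                       surface = surface_params(),
                       cluster_cutoff = 1.5, cluster_selection = NULL,
                       stride = 1L, outdir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

.load_traj <- function(x) {
  if (inherits(x, "md_trajectory")) return(x)
  if (is.character(x)) return(read_pdb(x, model_policy = "all"))
  stop("validation error: trajectory must be a md_trajectory or a PDB path",
       call. = FALSE)
}

#' Run every analysis stage on one system
#'
#' Stage order is fixed: equilibration discard; per-domain average
#' structure, RMSD series and residue RMSF; interface series; helix-pair
#' angle series; substate clustering; contact occupancy and ligand
#' mobility/exposure; PCA with a five-mode report. All referenced
#' selections are resolved up front, so a bad configuration fails before
#' any computation starts. Reruns with identical inputs are bit-identical
#' (no stage draws random numbers).
#'
#' @param config a [run_config()].
#' @return list of class `system_bundle` holding each stage's result plus
#'   the post-discard trajectory and all parameters used.
#' @export
run_system <- function(config) {
  stopifnot(inherits(config, "run_config"))
  traj <- .load_traj(config$trajectory)

  # fail-fast: resolve every referenced selection before any stage runs
  all_exprs <- c(unlist(config$domains), unlist(config$helix_pairs),
                 unlist(config$interface), config$ligand,
                 config$receptor_fit, config$pca_selection,
                 config$cluster_selection)
  for (e in all_exprs)
    if (is.character(e)) resolve_selection(traj, e)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(err)
      stop("stage '", name, "' failed for system '", config$label, "': ",
           conditionMessage(err), call. = FALSE))
  }

  traj <- stage("discard",
                if (config$discard > 0)
                  discard_equilibration(traj, config$discard) else traj)

  fit_sel <- if (!is.null(config$receptor_fit)) config$receptor_fit else
    NULL

  domains <- stage("flexibility", lapply(config$domains, function(ds) {
    avg <- average_structure(traj, ds)
    rs <- rmsd_series(traj, avg, fit_selection = ds)
    prof <- rmsf(traj, ds, ds, aggregate = "residue")
    list(average = avg, rmsd = rs, rmsf = prof,
         summary = c(rmsd_mean = rs$mean, rmsd_sd = rs$sd))
  }))

  interface <- if (!is.null(config$interface))
    stage("interface",
          interface_series(traj, config$interface$part_A,
                           config$interface$part_B, config$surface,
                           stride = config$stride)) else NULL

  angles <- stage("angles", lapply(config$helix_pairs, function(hp)
    angle_series(traj, hp[[1]], hp[[2]])))

  substates <- stage("substates", {
    cs <- if (!is.null(config$cluster_selection)) config$cluster_selection
      else if (length(config$domains)) config$domains[[1]] else NULL
    nf <- n_frames(traj)
    st <- if (nf > 4000) unique(round(seq(1, nf, length.out = 4000)))
      else seq_len(nf)
    cluster_substates(md_trajectory(traj$topology,
                                    traj$frames[, , st, drop = FALSE]),
                      fit_selection = cs, cutoff = config$cluster_cutoff)
  })

  contacts <- if (!is.null(config$contacts))
    stage("contacts", lapply(config$contacts, function(sp)
      contact_occupancy(traj, sp))) else NULL

  ligand <- if (!is.null(config$ligand)) stage("ligand", {
    mob <- ligand_mobility(traj, fit_sel, config$ligand)
    fr <- seq(1L, n_frames(traj), by = as.integer(config$stride))
    lig_idx <- .sel_idx(traj, config$ligand)
    expo <- vapply(fr, function(f) {
      s <- frame_structure(traj, f)
      pa <- sasa(s, NULL, config$surface)$per_atom   # whole complex occludes
      sum(pa[as.character(lig_idx)], na.rm = TRUE)
    }, numeric(1))
    iso <- vapply(fr, function(f) {
      s <- frame_structure(traj, f)
      sasa(s, lig_idx, config$surface)$total         # ligand in isolation
    }, numeric(1))
    list(mobility = mob,
         exposure = c(mean = mean(expo), sd = sd(expo)),
         exposure_isolated = c(mean = mean(iso), sd = sd(iso)))
  }) else NULL

  pca <- stage("pca", {
    model <- fit_pca(traj, config$pca_selection)
    list(model = model, report = mode_report(model, 5))
  })

  bundle <- structure(list(
    label = config$label, n_frames = n_frames(traj), trajectory = traj,
    domains = domains, interface = interface, angles = angles,
    substates = substates, contacts = contacts, ligand = ligand,
    pca = pca, config = config),
    class = "system_bundle")
  if (!is.null(config$outdir)) .write_bundle(bundle, config$outdir)
  bundle
}

.write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pre <- file.path(outdir, bundle$label)
  for (d in names(bundle$domains)) {
    write_series_csv(bundle$domains[[d]]$rmsd,
                     paste0(pre, "_rmsd_", d, ".csv"))
    write_series_csv(bundle$domains[[d]]$rmsf,
                     paste0(pre, "_rmsf_", d, ".csv"))
  }
  if (!is.null(bundle$interface))
    write_interface_series(bundle$interface,
                           paste0(pre, "_interface.csv"),
                           paste0(pre, "_interface.json"))
  for (a in names(bundle$angles))
    write.csv(data.frame(frame = seq_along(bundle$angles[[a]]$angle),
                         angle = bundle$angles[[a]]$angle),
              paste0(pre, "_angle_", a, ".csv"), row.names = FALSE)
  jsonlite::write_json(summary_table(bundle), paste0(pre, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(bundle)
}

#' Scalar summary of a system bundle
#'
#' One flat named list: per-domain RMSD mean/sd, per-pair angle mean/sd,
#' interface metrics mean/sd, ligand mobility and exposure, substate
#' populations, leading PCA mode fractions.
#'
#' @param bundle a `system_bundle`.
#' @return named list of numbers (and small vectors).
#' @export
summary_table <- function(bundle) {
  out <- list(label = bundle$label, n_frames = bundle$n_frames)
  for (d in names(bundle$domains)) {
    out[[paste0("rmsd_mean_", d)]] <- bundle$domains[[d]]$rmsd$mean
    out[[paste0("rmsd_sd_", d)]] <- bundle$domains[[d]]$rmsd$sd
  }
  for (a in names(bundle$angles)) {
    out[[paste0("angle_mean_", a)]] <- bundle$angles[[a]]$mean
    out[[paste0("angle_sd_", a)]] <- bundle$angles[[a]]$sd
  }
  if (!is.null(bundle$interface)) for (m in names(bundle$interface$summary)) {
    out[[paste0(m, "_mean")]] <- unname(bundle$interface$summary[[m]]["mean"])
    out[[paste0(m, "_sd")]] <- unname(bundle$interface$summary[[m]]["sd"])
  }
  if (!is.null(bundle$ligand)) {
    out$ligand_rmsd_mean <- bundle$ligand$mobility$positional$mean
    out$ligand_rmsd_sd <- bundle$ligand$mobility$positional$sd
    out$ligand_internal_rmsd_mean <- bundle$ligand$mobility$internal$mean
    out$ligand_asa_mean <- unname(bundle$ligand$exposure["mean"])
    out$ligand_asa_isolated_mean <-
      unname(bundle$ligand$exposure_isolated["mean"])
  }
  if (!is.null(bundle$contacts))
    for (cn in names(bundle$contacts))
      out[[paste0("occupancy_", cn)]] <- bundle$contacts[[cn]]$occupancy
  out$n_substates <- length(bundle$substates$sizes)
  out$substate_populations <- bundle$substates$sizes /
    sum(bundle$substates$sizes)
  out$pca_mode_fractions <- bundle$pca$report$fraction
  out
}

#' Pairwise comparison of analyzed systems
#'
#' For each requested pair `(a, b)` computes the per-residue displacement
#' map between average structures, the per-residue RMSF difference map,
#' and the deltas (b minus a) of every shared scalar summary — the
#' comparative tables of a multi-system trajectory study.
#'
#' @param bundles list of `system_bundle` objects (named or not; labels
#'   are taken from the bundles).
#' @param pairs list of length-2 character vectors of system labels.
#' @param map_selection selection used to fit and measure the displacement
#'   map (default: the first domain of system `a`).
#' @return list of class `comparison_report`, one element per pair:
#'   `displacement_map`, `drmsf_maps` (per domain), `deltas` (named
#'   numeric), `labels`.
#' @export
compare_systems <- function(bundles, pairs, map_selection = NULL) {
  labs <- vapply(bundles, function(b) b$label, character(1))
  out <- lapply(pairs, function(p) {
    ia <- match(p[1], labs)
    ib <- match(p[2], labs)
    if (anyNA(c(ia, ib)))
      stop("unknown system label in pair: ", paste(p, collapse = ", "),
           call. = FALSE)
    a <- bundles[[ia]]
    b <- bundles[[ib]]
    msel <- if (!is.null(map_selection)) map_selection else
      a$config$domains[[1]]
    disp <- difference_map(a$trajectory, b$trajectory,
                           fit_selection = msel)
    drmsf <- lapply(intersect(names(a$domains), names(b$domains)),
                    function(d) difference_map(a$domains[[d]]$rmsf,
                                               b$domains[[d]]$rmsf))
    names(drmsf) <- intersect(names(a$domains), names(b$domains))
    sa <- summary_table(a)
    sb <- summary_table(b)
    shared <- intersect(names(sa), names(sb))
    shared <- shared[vapply(shared, function(k)
      is.numeric(sa[[k]]) && length(sa[[k]]) == 1 &&
        is.numeric(sb[[k]]) && length(sb[[k]]) == 1, logical(1))]
    deltas <- setNames(vapply(shared, function(k) sb[[k]] - sa[[k]],
                              numeric(1)), paste0("d_", shared))
    list(labels = p, displacement_map = disp, drmsf_maps = drmsf,
         deltas = deltas)
  })
  structure(out, class = "comparison_report")
}
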