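#' Read a PDB file into a structure or trajectory
#'
#' Parsing is delegated to [bio3d::read.pdb()]; the atom table is then
#' annotated with per-atom masses and van der Waals radii from an
#' element-keyed lookup (atom-name overrides take precedence). Alternate
#' locations are reduced to the highest-occupancy conformer (tie: first
#' encountered). Hydrogens are kept in the atom table; surface and gap
#' computations ignore them by default (see [sasa()]).
#'
#' @param path PDB file path.
#' @param model_policy `"first"` returns a `md_structure` from the first
#'   MODEL; `"all"` returns a `md_trajectory` with one frame per MODEL
#'   (all MODEL blocks must share the same atom table).
#' @param radius_override,mass_override optional named numeric vectors keyed
#'   by atom name.
#' @param drop_h drop hydrogen atoms on read (default `FALSE`).
#' @return `md_structure` or `md_trajectory`.
#' @export
read_pdb <- function(path, model_policy = c("first", "all"),
                     radius_override = NULL, mass_override = NULL,
                     drop_h = FALSE) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  # validate fixed-column coordinate fields up front (the delegate parser
  # silently truncates malformed numbers like "1.0x0")
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)", lines)
  if (!length(rec))
    stop("parse error: no ATOM/HETATM records in ", path, call. = FALSE)
  num_re <- "^\\s*-?[0-9]*\\.?[0-9]+\\s*$"
  for (i in rec) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (!all(grepl(num_re, fields)))
      stop("parse error: malformed coordinate field at line ", i,
           " of ", path, call. = FALSE)
  }
  if (model_policy == "all") {
    starts <- grep("^MODEL", lines)
    if (length(starts) > 1) {
      ends <- grep("^ENDMDL", lines)
      cnt <- mapply(function(a, b)
        sum(grepl("^(ATOM|HETATM)", lines[a:b])), starts, ends)
      if (length(unique(cnt)) > 1)
        stop("topology error: MODEL blocks differ in atom count (",
             paste(unique(cnt), collapse = " vs "), ")", call. = FALSE)
    }
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = (model_policy == "all"),
                    rm.alt = FALSE, verbose = FALSE),
    error = function(e)
      stop("parse error reading '", path, "': ", conditionMessage(e),
           call. = FALSE))
  if (nrow(pdb$atom) == 0L)
    stop("parse error: no ATOM/HETATM records in ", path, call. = FALSE)

  at <- pdb$atom
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  nmod <- nrow(pdb$xyz)

  # altloc: keep the highest-occupancy conformer per atom site, tie -> first
  keep <- rep(TRUE, nrow(at))
  if (any(!is.na(at$alt))) {
    site <- paste(at$chain, at$resno, at$insert, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    for (s in unique(site[duplicated(site)])) {
      i <- which(site == s)
      best <- i[which.max(occ[i])]
      keep[setdiff(i, best)] <- FALSE
    }
  }

  elesy <- if ("elesy" %in% names(at)) trimws(at$elesy) else
    rep(NA_character_, nrow(at))
  elesy[is.na(elesy) | elesy == ""] <-
    .element_from_name(at$elety[is.na(elesy) | elesy == ""])
  if (anyNA(elesy))
    stop("lookup error: cannot infer element for atom(s) ",
         paste(unique(at$elety[is.na(elesy)]), collapse = ", "),
         call. = FALSE)
  if (drop_h) keep <- keep & toupper(elesy) != "H"

  atom <- data.frame(
    eleno = at$eleno[keep],
    elety = at$elety[keep],
    elesy = toupper(elesy[keep]),
    resid = at$resid[keep],
    resno = at$resno[keep],
    chain = ifelse(is.na(at$chain[keep]), " ", at$chain[keep]),
    stringsAsFactors = FALSE)
  atom$mass <- lookup_mass(atom$elesy, atom$elety, mass_override)
  atom$radius <- lookup_radius(atom$elesy, atom$elety, radius_override)
  xyz <- xyz[keep, , drop = FALSE]

  topo <- md_structure(atom, xyz)
  if (model_policy == "first") return(topo)

  frames <- array(NA_real_, c(nrow(atom), 3L, nmod))
  for (m in seq_len(nmod)) {
    fx <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    if (nrow(fx) != length(keep))
      stop("topology error: MODEL ", m, " atom count differs", call. = FALSE)
    frames[, , m] <- fx[keep, , drop = FALSE]
  }
  if (any(!is.finite(frames)))
    stop("topology error: MODEL blocks have mismatched atom tables",
         call. = FALSE)
  md_trajectory(topo, frames)
}

#' Write a structure or trajectory as (multi-MODEL) PDB
#'
#' @param x a `md_structure` or `md_trajectory`.
#' @param path output file.
#' @param b optional per-atom numeric vector stored in the B-factor column
#'   (used by the difference-map writer for visualisation).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, b = NULL) {
  if (inherits(x, "md_trajectory")) {
    at <- x$topology$atom
    xyz <- t(apply(x$frames, 3, function(f) as.vector(t(f))))
  } else {
    at <- x$atom
    xyz <- matrix(as.vector(t(x$xyz)), nrow = 1)
  }
  is_het <- !(at$resid %in% bio3d::aa.table$aa3)
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(is_het, "HETATM", "ATOM"),
                   eleno = at$eleno, elety = at$elety, resid = at$resid,
                   resno = at$resno, chain = ifelse(at$chain == " ",
                                                    "", at$chain),
                   elesy = at$elesy,
                   b = if (is.null(b)) rep(0, nrow(at)) else b)
  invisible(path)
}
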