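#' Resolve an atom selection expression
#'
#' The selection language is a conjunction of predicates joined by `and`:
#' \describe{
#'   \item{`chain A,B`}{chain identifiers (comma list)}
#'   \item{`resid 408-420,468-475`}{residue-id ranges and single ids}
#'   \item{`name N,CA,C`}{atom names}
#'   \item{`resname ATP,MG`}{residue names}
#'   \item{`elem C,N,O`}{element symbols}
#'   \item{`all`}{every atom}
#' }
#' e.g. `"chain A and resid 408-420 and name CA"`. Matching atom indices
#' are returned in topology order.
#'
#' @param structure a `md_structure` (or `md_trajectory`, whose topology is
#'   used).
#' @param expression selection string.
#' @param allow_empty if `FALSE` (default) an empty result is an error.
#' @return an object of class `md_selection` with fields `expression` and
#'   `indices` (strictly increasing integer vector).
#' @examples
#' h <- build_ideal_helix(13, resno_start = 408)
#' length(resolve_selection(h, "resid 408-420 and name CA")$indices)  # 13
#' @export
resolve_selection <- function(structure, expression, allow_empty = FALSE) {
  atom <- if (inherits(structure, "md_trajectory"))
    structure$topology$atom else structure$atom
  keep <- rep(TRUE, nrow(atom))
  expr <- trimws(expression)
  if (!nzchar(expr))
    stop("selection syntax error: empty expression", call. = FALSE)
  clauses <- trimws(strsplit(expr, "\\band\\b")[[1]])
  for (cl in clauses) {
    if (!nzchar(cl))
      stop("selection syntax error: empty clause in '", expression, "'",
           call. = FALSE)
    toks <- strsplit(cl, "\\s+")[[1]]
    key <- tolower(toks[1])
    if (key == "all") next
    if (length(toks) < 2)
      stop("selection syntax error: predicate '", cl, "' has no arguments",
           call. = FALSE)
    args <- strsplit(paste(toks[-1], collapse = ""), ",")[[1]]
    keep <- keep & switch(key,
      chain   = atom$chain %in% args,
      name    = toupper(atom$elety) %in% toupper(args),
      resname = toupper(atom$resid) %in% toupper(args),
      elem    = toupper(atom$elesy) %in% toupper(args),
      resid   = atom$resno %in% .expand_ranges(args, cl),
      stop("selection syntax error: unknown predicate '", toks[1],
           "' in '", cl, "'", call. = FALSE)
    )
  }
  idx <- which(keep)
  if (length(idx) == 0L && !allow_empty)
    stop("selection error: '", expression, "' matched no atoms",
         call. = FALSE)
  structure(list(expression = expression, indices = idx),
            class = "md_selection")
}

.expand_ranges <- function(args, clause) {
  out <- integer(0)
  for (a in args) {
    if (grepl("^-?[0-9]+--?[0-9]+$", a)) {
      ab <- as.integer(strsplit(sub("^(-?[0-9]+)-", "\\1 ", a), " ")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", a)) {
      out <- c(out, as.integer(a))
    } else {
      stop("selection syntax error: bad residue range token '", a,
           "' in '", clause, "'", call. = FALSE)
    }
  }
  out
}

#' @export
print.md_selection <- function(x, ...) {
  cat("md_selection:", length(x$indices), "atoms <-", x$expression, "\n")
  invisible(x)
}

# Accept either a selection object, a raw index vector, or an expression
# string; always return a validated strictly-increasing index vector.
.sel_idx <- function(structure, sel) {
  n <- n_atoms(structure)
  if (inherits(sel, "md_selection")) idx <- sel$indices
  else if (is.character(sel)) idx <- resolve_selection(structure, sel)$indices
  else if (is.numeric(sel)) idx <- as.integer(sel)
  else if (is.null(sel)) idx <- seq_len(n)
  else stop("cannot interpret selection of class ", class(sel)[1],
            call. = FALSE)
  if (length(idx) && (min(idx) < 1L || max(idx) > n))
    stop("selection indices out of range for this structure", call. = FALSE)
  if (is.unsorted(idx, strictly = TRUE))
    stop("selection indices must be strictly increasing", call. = FALSE)
  idx
}
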