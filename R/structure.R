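#' Construct a single-conformation structure
#'
#' A `cc_structure` holds one conformation of a (typically hexameric)
#' coiled-coil assembly: an atom table plus an `n x 3` coordinate matrix in
#' Angstrom. It is the unit that all geometry, packing and RMSD operations
#' consume.
#'
#' @param atom data frame with columns `serial`, `name` (atom name, e.g.
#'   `"CA"`), `resname` (3-letter residue code), `chain` (single character),
#'   `resno` (1-based residue number), `occ` (occupancy in `[0, 1]`) and
#'   `element`.
#' @param xyz numeric matrix, `nrow(atom)` rows and 3 columns, coordinates in
#'   Angstrom.
#' @param model_id integer model identifier (PDB MODEL number).
#' @return An object of class `cc_structure`.
#' @export
cc_structure <- function(atom, xyz, model_id = 1L) {
  atom <- as.data.frame(atom)
  required <- c("serial", "name", "resname", "chain", "resno", "occ", "element")
  missing_cols <- setdiff(required, names(atom))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L || nrow(xyz) != nrow(atom)) {
    stop("xyz must be a numeric matrix with 3 columns and one row per atom")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (any(!nzchar(atom$chain))) stop("empty chain identifiers")
  structure(
    list(atom = atom, xyz = unname(xyz), model_id = as.integer(model_id)),
    class = "cc_structure"
  )
}

#' @export
print.cc_structure <- function(x, ...) {
  cat(sprintf(
    "cc_structure: %d atoms, %d chain(s) [%s], residues %d-%d, model %d\n",
    nrow(x$atom), length(chains(x)), paste(chains(x), collapse = ""),
    min(x$atom$resno), max(x$atom$resno), x$model_id
  ))
  invisible(x)
}

#' Chains of a structure
#'
#' @param x a `cc_structure`.
#' @return Character vector of chain identifiers in order of first appearance.
#' @export
chains <- function(x) unique(x$atom$chain)

#' Number of atoms
#' @param x a `cc_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atom)

#' Construct a conformational ensemble
#'
#' A `cc_ensemble` is an ordered set of conformations sharing one topology
#' (identical atom table); coordinates are stored as an
#' `n_atoms x 3 x n_frames` array. It stands in for a set of MD trajectory
#' frames.
#'
#' @param atom shared atom table (see [cc_structure()]).
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)`.
#' @param provenance named list recording where the frames came from
#'   (source path, generator seed, per-frame metadata, ...).
#' @return An object of class `cc_ensemble`.
#' @export
cc_ensemble <- function(atom, coords, provenance = list()) {
  atom <- as.data.frame(atom)
  coords <- as.array(coords)
  if (length(dim(coords)) != 3L || dim(coords)[1] != nrow(atom) ||
      dim(coords)[2] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  structure(
    list(atom = atom, coords = coords, provenance = provenance),
    class = "cc_ensemble"
  )
}

#' @export
print.cc_ensemble <- function(x, ...) {
  cat(sprintf(
    "cc_ensemble: %d frame(s) x %d atoms, chains [%s]\n",
    n_frames(x), nrow(x$atom), paste(unique(x$atom$chain), collapse = "")
  ))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x a `cc_ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) dim(x$coords)[3]

#' Extract one frame of an ensemble as a structure
#'
#' @param ensemble a `cc_ensemble`.
#' @param i frame index (1-based).
#' @return A `cc_structure`.
#' @export
get_frame <- function(ensemble, i) {
  i <- as.integer(i)
  if (i < 1L || i > n_frames(ensemble)) stop("frame index out of range")
  cc_structure(ensemble$atom, ensemble$coords[, , i], model_id = i)
}

#' Bundle structures into an ensemble
#'
#' All structures must share an identical topology (chains, residue layout and
#' atom ordering).
#'
#' @param structures list of `cc_structure` objects.
#' @param provenance optional provenance list.
#' @return A `cc_ensemble`.
#' @export
as_ensemble <- function(structures, provenance = list()) {
  if (length(structures) == 0L) stop("empty structure list")
  ref <- structures[[1L]]
  key <- function(s) paste(s$atom$chain, s$atom$resno, s$atom$name, sep = "|")
  ref_key <- key(ref)
  for (s in structures[-1L]) {
    if (!identical(key(s), ref_key)) {
      stop("inconsistent chain/residue/atom layout across models")
    }
  }
  coords <- array(
    unlist(lapply(structures, function(s) s$xyz), use.names = FALSE),
    dim = c(nrow(ref$atom), 3L, length(structures))
  )
  cc_ensemble(ref$atom, coords, provenance)
}
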