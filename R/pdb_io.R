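#' Read a (multi-model) PDB file into an ensemble
#'
#' Parsing is delegated to [bio3d::read.pdb()]; this wrapper adds the
#' conventions used throughout the package: only `ATOM` records are kept
#' (`HETATM`, e.g. solvent, is dropped), alternate locations are reduced to
#' the highest-occupancy conformer (ties broken by first occurrence), residue
#' numbers are taken verbatim from the PDB columns, and every model becomes
#' one frame of a [cc_ensemble()].
#'
#' Zero-occupancy atoms (used by crystallographers for side chains without
#' map density) are retained; downstream selections can exclude them with the
#' `occ > 0` predicate of [select_atoms()].
#'
#' @param path path to a PDB v3.3 file.
#' @param models `"all"` (every MODEL becomes a frame) or `"single"` (first
#'   model only).
#' @return A `cc_ensemble` with provenance recording the source path.
#' @export
read_pdb <- function(path, models = c("all", "single")) {
  models <- match.arg(models)
  if (!file.exists(path)) stop("file not found: ", path)
  validate_pdb_lines(path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = (models == "all"),
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) {
      stop("topology error reading '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  keep <- pdb$atom$type == "ATOM"
  atom <- pdb$atom[keep, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz_idx <- which(keep)

  # altloc reduction: highest occupancy wins, ties go to the first conformer
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  akey <- paste(atom$chain, atom$resno, atom$elety, sep = "|")
  keep2 <- rep(TRUE, nrow(atom))
  for (k in unique(akey[alt != ""])) {
    idx <- which(akey == k)
    if (length(idx) > 1L) {
      occ <- atom$o[idx]
      occ[is.na(occ)] <- 0
      best <- idx[which.max(occ)]
      keep2[setdiff(idx, best)] <- FALSE
    }
  }
  atom <- atom[keep2, , drop = FALSE]
  xyz_idx <- xyz_idx[keep2]

  cols <- as.vector(rbind(3 * (xyz_idx - 1) + 1, 3 * (xyz_idx - 1) + 2,
                          3 * xyz_idx))
  n_model <- if (models == "single") 1L else nrow(xyz)
  atom_df <- data.frame(
    serial = atom$eleno,
    name = atom$elety,
    resname = atom$resid,
    chain = atom$chain,
    resno = atom$resno,
    occ = ifelse(is.na(atom$o), 1, atom$o),
    element = trimws(ifelse(is.na(atom$elesy) | atom$elesy == "",
                            substr(trimws(atom$elety), 1L, 1L), atom$elesy)),
    stringsAsFactors = FALSE
  )
  frames <- lapply(seq_len(n_model), function(m) {
    m_xyz <- matrix(xyz[m, cols], ncol = 3L, byrow = TRUE)
    cc_structure(atom_df, m_xyz, model_id = m)
  })
  as_ensemble(frames, provenance = list(source = normalizePath(path)))
}

# Cheap structural validation so that malformed ATOM lines are reported with
# their line number (the backend parser reports neither).
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atom_like <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(atom_like)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed ATOM line ", i, " in '", path, "': too short")
    }
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      stop("malformed ATOM line ", i, " in '", path,
           "': non-numeric coordinates")
    }
    if (is.na(suppressWarnings(as.integer(substr(ln, 23, 26))))) {
      stop("malformed ATOM line ", i, " in '", path,
           "': non-numeric residue number")
    }
  }
  invisible(TRUE)
}

#' Write a structure or ensemble as PDB v3.3
#'
#' Multi-frame ensembles are written with `MODEL`/`ENDMDL` records (one pair
#' per frame); a single frame is written as one implicit model. A `TER`
#' record follows each chain. Coordinates are written at the format's 3
#' decimal places.
#'
#' @param x a `cc_structure` or `cc_ensemble`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "cc_structure")) x <- as_ensemble(list(x))
  if (!inherits(x, "cc_ensemble")) stop("x must be a cc_structure or cc_ensemble")
  nf <- n_frames(x)
  if (nf < 1L) stop("empty ensemble")
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to '", path, "'"))
  on.exit(close(con))
  for (m in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(format_pdb_model(x$atom, x$coords[, , m]), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

format_pdb_model <- function(atom, xyz) {
  name4 <- ifelse(nchar(atom$name) < 4L,
                  sprintf(" %-3s", atom$name),
                  substr(atom$name, 1L, 4L))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atom$serial %% 100000L, name4, atom$resname, atom$chain, atom$resno,
    xyz[, 1], xyz[, 2], xyz[, 3], atom$occ, 0, atom$element
  )
  # insert TER after each chain block
  out <- character(0)
  for (ch in unique(atom$chain)) {
    idx <- which(atom$chain == ch)
    out <- c(out, lines[idx], "TER")
  }
  out
}
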