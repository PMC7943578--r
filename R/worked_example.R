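# Worked example against the deposited crystal structure of the switchable
# hexamer (PDB 6ZT1): its asymmetric unit contains both the open barrel and
# the collapsed sandwich. These helpers split the two assemblies and compute
# the geometric observables discussed for that structure. They require the
# PDB file (see fetch_rcsb_structure()); nothing here is needed for the
# synthetic analyses.

#' Split a two-hexamer crystal structure into its assemblies
#'
#' Groups the chains into two six-chain assemblies by k-means clustering of
#' the chain centroids (the two hexamers of the asymmetric unit are
#' spatially separate), and identifies which is the open barrel: the one
#' with the smaller spread of helix-triad angles (all ~120 degrees in a C6
#' barrel, 90-150 degrees in the collapsed sandwich).
#'
#' @param structure a `cc_structure` containing twelve chains.
#' @return A list with elements `open` and `closed` (each a six-chain
#'   `cc_structure`).
#' @export
split_hexamers <- function(structure) {
  ch <- chains(structure)
  if (length(ch) < 4L) stop("expected a multi-assembly structure")
  cent <- t(vapply(ch, function(cc) {
    colMeans(structure$xyz[structure$atom$chain == cc, , drop = FALSE])
  }, numeric(3)))
  km <- stats::kmeans(cent, centers = 2L, nstart = 10L)
  grp <- split(ch, km$cluster)
  assemblies <- lapply(grp, function(g) {
    select_atoms(structure, paste("chain", paste(g, collapse = " ")))
  })
  spread <- vapply(assemblies, function(a) {
    diff(range(helix_triad_angles(a)))
  }, numeric(1))
  list(open = assemblies[[which.min(spread)]],
       closed = assemblies[[which.max(spread)]])
}

#' Geometric observables of the crystal-structure worked example
#'
#' Computes, for a two-hexamer crystal structure (e.g. PDB 6ZT1): the mean
#' CA spacing of the reporter residue between neighbouring helices in each
#' state; the triad-angle range of each state; the knobs-into-holes count
#' difference between the states; the backbone RMSD of the best-matching
#' open/closed helix pair (the central helices align closely); and the
#' per-helix centroid translations between the states after superposing the
#' best-matching three-helix sheets.
#'
#' @param path path to the PDB file.
#' @param resno reporter residue number (default 13).
#' @param cutoff knobs-into-holes cutoff (A).
#' @param exclude_zero_occ drop zero-occupancy (unmodelled-density) atoms
#'   from RMSD selections (default TRUE, so terminal residues without map
#'   density do not distort the comparison).
#' @return A list of the observables described above.
#' @export
reference_structure_report <- function(path, resno = 13L, cutoff = 7.0,
                                       exclude_zero_occ = TRUE) {
  s <- get_frame(read_pdb(path, "single"), 1L)
  hx <- split_hexamers(s)
  open <- hx$open
  closed <- hx$closed

  spacing_open <- neighbour_ca_distances(open, resno)$mean
  spacing_closed <- neighbour_ca_distances(closed, resno)$mean
  triads_open <- helix_triad_angles(open)
  triads_closed <- helix_triad_angles(closed)
  kih <- compare_kih_counts(open, closed, cutoff)

  # best-matching single-helix pair (any open helix vs a central closed one)
  pair_rmsd <- Inf
  for (co in chains(open)) {
    a <- select_atoms(open, paste("chain", co,
                                  if (exclude_zero_occ) "and occ > 0" else ""))
    for (cc in chains(closed)) {
      b <- select_atoms(closed, paste("chain", cc,
                                      if (exclude_zero_occ) "and occ > 0" else ""))
      r <- tryCatch(single_chain_rmsd(a, b), error = function(e) Inf)
      pair_rmsd <- min(pair_rmsd, r)
    }
  }

  # per-helix translations: superpose each contiguous closed three-helix
  # sheet onto each open three-helix arc, keep the best, then measure how
  # far the remaining closed helix centroids sit from their open partners
  translations <- sheet_alignment_translations(open, closed, exclude_zero_occ)

  list(
    spacing_open = spacing_open, spacing_closed = spacing_closed,
    triads_open = triads_open, triads_closed = triads_closed,
    kih_count_open = kih$count_a, kih_count_closed = kih$count_b,
    kih_percent_difference = kih$percent_difference,
    helix_pair_rmsd = pair_rmsd,
    helix_translations = translations
  )
}

# Backbone RMSD between two single chains on their common residue numbers.
single_chain_rmsd <- function(a, b) {
  common <- intersect(unique(a$atom$resno[a$atom$name == "CA"]),
                      unique(b$atom$resno[b$atom$name == "CA"]))
  if (length(common) < 7L) stop("too few common residues")
  sel <- paste("backbone and resno", paste(range(common), collapse = ":"))
  aa <- select_atoms(a, sel)
  bb <- select_atoms(b, sel)
  keep_a <- paste(aa$atom$resno, aa$atom$name) %in%
    paste(bb$atom$resno, bb$atom$name)
  keep_b <- paste(bb$atom$resno, bb$atom$name) %in%
    paste(aa$atom$resno, aa$atom$name)
  kabsch_superpose(aa$xyz[keep_a, , drop = FALSE],
                   bb$xyz[keep_b, , drop = FALSE])$rmsd
}

# Superpose the best-matching closed three-helix sheet onto an open arc and
# return the sorted per-helix centroid displacements of the non-superposed
# chains.
sheet_alignment_translations <- function(open, closed, exclude_zero_occ) {
  ord_o <- cyclic_chain_order(open)
  ord_c <- cyclic_chain_order(closed)
  best <- NULL
  best_rmsd <- Inf
  bb_sel <- function(s, chs) {
    sel <- paste("backbone and chain", paste(chs, collapse = " "),
                 if (exclude_zero_occ) "and occ > 0" else "")
    select_atoms(s, sel)
  }
  for (i in seq_along(ord_o)) {
    tri_o <- ord_o[((i - 1L + 0:2) %% 6L) + 1L]
    for (j in seq_along(ord_c)) {
      for (dir in list(0:2, 2:0)) {
        tri_c <- ord_c[((j - 1L + dir) %% 6L) + 1L]
        map <- stats::setNames(tri_c, tri_o)
        r <- tryCatch(backbone_rmsd(open, closed, chain_map = c(map)),
                      error = function(e) Inf)
        # chain_map above superposes only the mapped chains
        if (r < best_rmsd) {
          best_rmsd <- r
          best <- list(tri_o = tri_o, tri_c = tri_c)
        }
      }
    }
  }
  if (is.null(best)) stop("no sheet alignment found")
  # superpose closed onto open over the best sheet, then measure remaining
  # chain-centroid displacements under the induced cyclic pairing
  sel_o <- bb_sel(open, best$tri_o)
  sel_c <- bb_sel(closed, best$tri_c)
  n <- min(n_atoms(sel_o), n_atoms(sel_c))
  sup <- kabsch_superpose(sel_c$xyz[seq_len(n), , drop = FALSE],
                          sel_o$xyz[seq_len(n), , drop = FALSE])
  closed_xyz <- sweep(closed$xyz %*% sup$rotation, 2L, -sup$translation)
  ord_o <- cyclic_chain_order(open)
  ord_c <- cyclic_chain_order(closed)
  i0 <- match(best$tri_o[2], ord_o)
  j0 <- match(best$tri_c[2], ord_c)
  shifts <- vapply(0:5, function(k) {
    co <- ord_o[((i0 - 1L + k) %% 6L) + 1L]
    cc <- ord_c[((j0 - 1L + k) %% 6L) + 1L]
    po <- colMeans(open$xyz[open$atom$chain == co, , drop = FALSE])
    pc <- colMeans(closed_xyz[closed$atom$chain == cc, , drop = FALSE])
    vec_norm(pc - po)
  }, numeric(1))
  names(shifts) <- paste0("helix", 1:6)
  shifts
}
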