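# Knobs-into-holes packing detection and SASA burial analysis. KIH detection
# follows the SOCKET-style count rule: a residue is a knob when its
# side-chain centroid lies within a cutoff of the side-chain centroids of at
# least four residues on a single other helix; those four nearest residues
# form the hole. No angular complementarity test is applied.

#' Side-chain centroids of every residue
#'
#' The centroid is the mean of the residue's non-backbone heavy atoms (for
#' builder structures: CB plus the idealized `SC` pseudo-centroid); glycine,
#' which has no side chain, is represented by its CA so it can line a hole
#' but never be a knob.
#'
#' @param structure a `cc_structure`.
#' @return Data frame with `chain`, `resno`, `resname`, `x`, `y`, `z` and
#'   `has_side_chain`.
#' @export
side_chain_centroids <- function(structure) {
  atom <- structure$atom
  sc <- !(atom$name %in% c(BACKBONE_ATOMS)) & atom$element != "H"
  res <- unique(atom[, c("chain", "resno", "resname")])
  res <- res[order(match(res$chain, chains(structure)), res$resno), ]
  rownames(res) <- NULL
  cen <- matrix(NA_real_, nrow(res), 3L)
  has <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    rows <- which(atom$chain == res$chain[i] & atom$resno == res$resno[i] & sc)
    if (length(rows) > 0L) {
      cen[i, ] <- colMeans(structure$xyz[rows, , drop = FALSE])
      has[i] <- TRUE
    } else {
      ca <- which(atom$chain == res$chain[i] & atom$resno == res$resno[i] &
                    atom$name == "CA")
      cen[i, ] <- structure$xyz[ca[1], ]
      has[i] <- FALSE
    }
  }
  cbind(res, data.frame(x = cen[, 1], y = cen[, 2], z = cen[, 3],
                        has_side_chain = has))
}

#' Detect knobs-into-holes interactions
#'
#' @param structure a `cc_structure` with at least two chains and side-chain
#'   atoms or pseudo-centroids (builder structures carry `CB`/`SC` atoms; see
#'   [build_open_barrel()]).
#' @param cutoff knob-to-hole centroid distance cutoff (Angstrom, default
#'   7.0, the SOCKET convention).
#' @param register_offset optional heptad offset (see [assign_register()]);
#'   when given, each knob is annotated with its register letter, which
#'   [classify_kih()] requires.
#' @return Data frame of class `kih_table`: `knob_chain`, `knob_resno`,
#'   `knob_resname`, `knob_register`, `hole_chain`, `hole_resno1..4` and
#'   `mean_distance`, deterministically ordered.
#' @export
detect_kih <- function(structure, cutoff = 7.0, register_offset = NULL) {
  if (length(chains(structure)) < 2L) {
    return(empty_kih_table())
  }
  cen <- side_chain_centroids(structure)
  if (!any(cen$has_side_chain)) {
    stop("no side-chain representation found; build structures with ",
         "side-chain pseudo-centroids (see build_open_barrel) or supply ",
         "side-chain atoms")
  }
  reg <- if (!is.null(register_offset)) {
    assign_register(structure, register_offset)
  } else NULL
  xyz <- as.matrix(cen[, c("x", "y", "z")])
  out <- list()
  for (i in which(cen$has_side_chain)) {
    d <- dist_to_point(xyz, xyz[i, ])
    for (ch in setdiff(chains(structure), cen$chain[i])) {
      cand <- which(cen$chain == ch & d <= cutoff)
      if (length(cand) >= 4L) {
        hole <- cand[order(d[cand], cen$resno[cand])][1:4]
        hole <- hole[order(cen$resno[hole])]
        out[[length(out) + 1L]] <- data.frame(
          knob_chain = cen$chain[i], knob_resno = cen$resno[i],
          knob_resname = cen$resname[i],
          knob_register = if (is.null(reg)) NA_character_ else
            register_of(reg, cen$chain[i], cen$resno[i]),
          hole_chain = ch,
          hole_resno1 = cen$resno[hole[1]], hole_resno2 = cen$resno[hole[2]],
          hole_resno3 = cen$resno[hole[3]], hole_resno4 = cen$resno[hole[4]],
          mean_distance = mean(d[hole]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(empty_kih_table())
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$knob_chain, tab$knob_resno, tab$hole_chain), ]
  rownames(tab) <- NULL
  class(tab) <- c("kih_table", class(tab))
  tab
}

empty_kih_table <- function() {
  tab <- data.frame(
    knob_chain = character(0), knob_resno = integer(0),
    knob_resname = character(0), knob_register = character(0),
    hole_chain = character(0), hole_resno1 = integer(0),
    hole_resno2 = integer(0), hole_resno3 = integer(0),
    hole_resno4 = integer(0), mean_distance = numeric(0),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("kih_table", class(tab))
  tab
}

#' Classify knobs-into-holes interactions
#'
#' Three classes: `cyclic` — an a/d-position knob docking into the
#' cyclically adjacent chain, with all such interactions following one
#' rotational direction consistently around the bundle; `inter-sheet` — knob
#' and hole chains in different three-helix sheets and not cyclically
#' adjacent; `non-cyclic` — the remainder (e.g. knobs from b, c, e or g
#' positions between adjacent chains).
#'
#' @param interactions a `kih_table` from [detect_kih()] with register
#'   annotations.
#' @param sheets list of two chain vectors partitioning the chains into the
#'   two three-helix sheets.
#' @param cyclic_order chain identifiers in cyclic order around the bundle;
#'   computed from `structure` when supplied, otherwise required.
#' @param structure optional `cc_structure` from which the cyclic order is
#'   derived (angular order of helix axes).
#' @return The `kih_table` with an added `class` column.
#' @export
classify_kih <- function(interactions, sheets, cyclic_order = NULL,
                         structure = NULL) {
  if (nrow(interactions) == 0L) {
    interactions$class <- character(0)
    return(interactions)
  }
  if (anyNA(interactions$knob_register)) {
    stop("interactions lack register annotation; run detect_kih with ",
         "register_offset")
  }
  all_chains <- unique(c(interactions$knob_chain, interactions$hole_chain))
  sheet_chains <- unlist(sheets)
  if (!all(all_chains %in% sheet_chains)) {
    stop("sheet partition does not cover chain(s): ",
         paste(setdiff(all_chains, sheet_chains), collapse = ", "))
  }
  if (is.null(cyclic_order)) {
    if (is.null(structure)) stop("supply cyclic_order or structure")
    cyclic_order <- cyclic_chain_order(structure)
  }
  n <- length(cyclic_order)
  pos <- match(interactions$knob_chain, cyclic_order)
  pos_h <- match(interactions$hole_chain, cyclic_order)
  step <- (pos_h - pos) %% n
  adjacent <- step == 1L | step == (n - 1L)
  ad_knob <- interactions$knob_register %in% c("a", "d")
  sheet_of <- function(ch) {
    which(vapply(sheets, function(s) ch %in% s, logical(1)))[1]
  }
  same_sheet <- vapply(seq_len(nrow(interactions)), function(i) {
    sheet_of(interactions$knob_chain[i]) == sheet_of(interactions$hole_chain[i])
  }, logical(1))

  # consistent rotational direction: the majority direction among a/d knobs
  # into adjacent chains
  cand <- ad_knob & adjacent
  cls <- rep("non-cyclic", nrow(interactions))
  if (any(cand)) {
    dir_major <- if (sum(step[cand] == 1L) >= sum(step[cand] == (n - 1L)))
      1L else (n - 1L)
    cls[cand & step == dir_major] <- "cyclic"
  }
  inter <- !same_sheet & !adjacent & cls != "cyclic"
  cls[inter] <- "inter-sheet"
  interactions$class <- cls
  interactions
}

#' Compare knobs-into-holes counts between two structures
#'
#' @param a,b `cc_structure`s (e.g. the open and closed states).
#' @param cutoff distance cutoff (A), see [detect_kih()].
#' @return A list with `count_a`, `count_b` and `percent_difference`
#'   (`100 * (count_b - count_a) / count_a`).
#' @export
compare_kih_counts <- function(a, b, cutoff = 7.0) {
  na_ <- nrow(detect_kih(a, cutoff))
  nb_ <- nrow(detect_kih(b, cutoff))
  if (na_ == 0L) stop("no interactions in the first structure; ",
                      "percent difference undefined")
  list(count_a = na_, count_b = nb_,
       percent_difference = 100 * (nb_ - na_) / na_)
}

#' Write a KIH table as TSV
#'
#' @param interactions a `kih_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_kih <- function(interactions, path) {
  utils::write.table(interactions, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Standard sphere-point sampling: each atom's solvent-accessible sphere
#' (van der Waals radius + probe) is covered with `n_points` quasi-uniform
#' points; the accessible area is the fraction of points not buried inside
#' any neighbouring atom's accessible sphere.
#'
#' @param structure a `cc_structure`.
#' @param probe probe radius (Angstrom, default 1.4, a water molecule).
#' @param n_points sample points per atom (default 960).
#' @param atoms optional integer indices: compute SASA only for these atoms
#'   (in the context of the whole structure).
#' @return Numeric vector of per-atom areas (Angstrom^2), one per requested
#'   atom.
#' @export
shrake_rupley_sasa <- function(structure, probe = 1.4, n_points = 960L,
                               atoms = NULL) {
  radii <- vdw_radii(structure) + probe
  xyz <- structure$xyz
  if (is.null(atoms)) atoms <- seq_len(nrow(xyz))
  pts <- sphere_points(n_points)
  vapply(atoms, function(i) {
    ri <- radii[i]
    d <- dist_to_point(xyz, xyz[i, ])
    nb <- which(d < ri + radii & seq_along(d) != i)
    if (length(nb) == 0L) return(4 * pi * ri^2)
    surf <- sweep(pts * ri, 2L, -xyz[i, ])
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- dist_to_point(surf, xyz[j, ])
      free <- free & (dj >= radii[j])
      if (!any(free)) break
    }
    4 * pi * ri^2 * mean(free)
  }, numeric(1))
}

#' Population-weighted burial analysis of a reporter residue's CB
#'
#' For representative conformations of every core state, the SASA of the
#' reporter residue's CB atom is computed per chain and classified buried
#' (`SASA < threshold`, boundary values counted as buried) or exposed.
#' Per-state fractions are then weighted by state populations to give the
#' ensemble-averaged occupancies of the two environments.
#'
#' @param states a `cc_states`.
#' @param ensemble the source `cc_ensemble`.
#' @param resno reporter residue number (default 13, the interface Ala).
#' @param threshold burial threshold (Angstrom^2, default 10).
#' @param probe,n_points see [shrake_rupley_sasa()].
#' @param n_rep representative conformations per state (default 1000).
#' @param seed integer seed for the per-state sampling.
#' @return A list of class `burial_summary`: `per_state` (data frame with
#'   per-state buried/exposed fractions), `weighted_buried`,
#'   `weighted_exposed`, `threshold`.
#' @export
burial_occupancy <- function(states, ensemble, resno = 13L, threshold = 10,
                             probe = 1.4, n_points = 960L, n_rep = 1000L,
                             seed = 1L) {
  cb_rows <- which(ensemble$atom$resno == resno & ensemble$atom$name == "CB")
  if (length(cb_rows) == 0L) {
    stop("residue ", resno, " has no CB atom in this topology")
  }
  per_state <- lapply(states, function(st) {
    reps <- sample_state_conformations(st, ensemble, n = n_rep,
                                       seed = seed + st$id)
    buried <- 0L
    total <- 0L
    for (f in seq_len(n_frames(reps))) {
      sasa <- shrake_rupley_sasa(get_frame(reps, f), probe = probe,
                                 n_points = n_points, atoms = cb_rows)
      buried <- buried + sum(sasa <= threshold)
      total <- total + length(sasa)
    }
    data.frame(state = st$id, population = st$population,
               buried_fraction = buried / total,
               exposed_fraction = 1 - buried / total)
  })
  per_state <- do.call(rbind, per_state)
  wb <- sum(per_state$population * per_state$buried_fraction)
  structure(
    list(per_state = per_state, weighted_buried = wb,
         weighted_exposed = 1 - wb, threshold = threshold, resno = resno),
    class = "burial_summary"
  )
}

#' @export
print.burial_summary <- function(x, ...) {
  cat(sprintf(
    "burial of residue %d CB (threshold %.0f A^2): %.0f%% buried / %.0f%% exposed (population-weighted)\n",
    x$resno, x$threshold, 100 * x$weighted_buried, 100 * x$weighted_exposed))
  invisible(x)
}
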