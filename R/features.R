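# Per-frame 2-D conformational coordinates: backbone RMSD to the closed and
# open reference structures, each minimised over the six cyclic chain-name
# topologies of the hexamer. This symmetry-aware featurization removes the
# chain-labelling artefact that otherwise inflates RMSDs between frames and
# references whose chain names are rotated relative to each other.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `mobile %*% R + t` onto `reference` (row-vector convention). Reflections
#' are excluded by the determinant correction, so the returned rotation
#' always has determinant +1.
#'
#' @param mobile,reference numeric `n x 3` coordinate matrices, equal `n >= 3`.
#' @return A list with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd` (Angstrom, the global minimum over rigid motions).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("point count mismatch")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  mc <- colMeans(mobile)
  rc <- colMeans(reference)
  P <- sweep(mobile, 2L, mc)
  Q <- sweep(reference, 2L, rc)
  if (max(svd(P, nu = 0, nv = 0)$d) < 1e-9) stop("degenerate point set")
  C <- crossprod(P, Q)
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  ssd <- sum(P * P) + sum(Q * Q) - 2 * sum(sv$d * c(1, 1, d))
  rmsd <- sqrt(max(0, ssd) / nrow(P))
  list(rotation = R, translation = rc - as.vector(mc %*% R), rmsd = rmsd)
}

# Backbone atom row indices of `structure`, ordered chain-by-chain (in the
# order of `chain_order`), by residue number, atoms in N, CA, C, O order.
# Errors listing residues whose backbone is incomplete.
backbone_indices <- function(structure, chain_order = chains(structure),
                             exclude_zero_occ = FALSE) {
  atom <- structure$atom
  ok <- atom$name %in% BACKBONE_ATOMS
  if (exclude_zero_occ) ok <- ok & atom$occ > 0
  idx_all <- integer(0)
  bad <- character(0)
  for (ch in chain_order) {
    rows <- which(ok & atom$chain == ch)
    sub <- atom[rows, ]
    counts <- table(sub$resno)
    resnos <- sort(unique(sub$resno))
    incomplete <- resnos[counts[as.character(resnos)] != 4L]
    if (length(incomplete) > 0L) {
      bad <- c(bad, paste0(ch, ":", incomplete))
      next
    }
    ord <- order(sub$resno, match(sub$name, BACKBONE_ATOMS))
    idx_all <- c(idx_all, rows[ord])
  }
  if (length(bad) > 0L) {
    stop("incomplete backbone for residue(s): ", paste(bad, collapse = ", "))
  }
  idx_all
}

#' Backbone RMSD between two structures under a chain mapping
#'
#' All mapped backbone atoms (N, CA, C, O) are superposed jointly with one
#' Kabsch fit, and the RMSD of that single superposition is returned.
#'
#' @param a,b `cc_structure`s.
#' @param chain_map named character vector mapping chains of `a` to chains of
#'   `b`; default is the identity over the chains of `a`.
#' @param exclude_zero_occ drop zero-occupancy atoms from the comparison
#'   (atoms must then be dropped consistently in both structures).
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(a, b, chain_map = NULL, exclude_zero_occ = FALSE) {
  ch_a <- chains(a)
  if (is.null(chain_map)) chain_map <- stats::setNames(ch_a, ch_a)
  if (!all(names(chain_map) %in% ch_a) || !all(chain_map %in% chains(b))) {
    stop("chain_map must map chains of a onto chains of b")
  }
  ia <- backbone_indices(a, names(chain_map), exclude_zero_occ)
  ib <- backbone_indices(b, unname(chain_map), exclude_zero_occ)
  if (length(ia) != length(ib)) {
    stop("mapped chains have different backbone atom counts")
  }
  kabsch_superpose(a$xyz[ia, , drop = FALSE], b$xyz[ib, , drop = FALSE])$rmsd
}

# The six cyclic chain-name topologies of a hexamer: topology k (0-based)
# maps frame chain i onto reference chain i+k (cyclically), e.g. for k = 1
# the reference trimers (A B C)(D E F) are read as (B C D)(E F A).
cyclic_chain_maps <- function(frame_chains, ref_chains) {
  n <- length(ref_chains)
  lapply(0:(n - 1L), function(k) {
    stats::setNames(ref_chains[((seq_len(n) - 1L + k) %% n) + 1L],
                    frame_chains)
  })
}

#' Minimum backbone RMSD over the six cyclic chain-name topologies
#'
#' Computes the backbone RMSD of `frame` against `reference` under each of
#' the six cyclic rotations of the reference chain names and returns the
#' smallest, together with the 0-based index of the topology achieving it
#' (ties resolved to the lowest index). Anti-parallel or reflected matchings
#' are deliberately not considered.
#'
#' @param frame,reference `cc_structure`s with six chains of equal lengths.
#' @param exclude_zero_occ see [backbone_rmsd()].
#' @return A list with `rmsd` (Angstrom) and `topology` (0-5).
#' @export
min_rmsd_over_cyclic_topologies <- function(frame, reference,
                                            exclude_zero_occ = FALSE) {
  if (length(chains(frame)) != 6L || length(chains(reference)) != 6L) {
    stop("cyclic-topology RMSD requires six chains in both structures")
  }
  maps <- cyclic_chain_maps(chains(frame), chains(reference))
  rmsds <- vapply(maps, function(m) {
    backbone_rmsd(frame, reference, chain_map = m,
                  exclude_zero_occ = exclude_zero_occ)
  }, numeric(1))
  k <- which.min(rmsds)
  list(rmsd = rmsds[k], topology = k - 1L)
}

#' Featurize an ensemble against the closed and open references
#'
#' For every frame, computes the pair of conformational coordinates
#' (backbone RMSD to the closed reference, backbone RMSD to the open
#' reference), each independently minimised over the six cyclic chain-name
#' topologies of the respective reference.
#'
#' @param ensemble a `cc_ensemble` of hexamer conformations.
#' @param open_ref,closed_ref reference `cc_structure`s (six chains).
#' @param exclude_zero_occ see [backbone_rmsd()].
#' @return A data frame with columns `frame`, `rmsd_to_closed`,
#'   `rmsd_to_open`, `topology_closed`, `topology_open` (topologies 0-5).
#' @export
featurize_ensemble <- function(ensemble, open_ref, closed_ref,
                               exclude_zero_occ = FALSE) {
  frame1 <- get_frame(ensemble, 1L)
  if (length(chains(frame1)) != 6L) stop("ensemble frames must have 6 chains")
  fr_idx <- backbone_indices(frame1, exclude_zero_occ = exclude_zero_occ)

  prep_reference <- function(ref) {
    maps <- cyclic_chain_maps(chains(frame1), chains(ref))
    lapply(maps, function(m) {
      idx <- backbone_indices(ref, unname(m), exclude_zero_occ)
      Q <- ref$xyz[idx, , drop = FALSE]
      Q <- sweep(Q, 2L, colMeans(Q))
      list(Q = Q, q2 = sum(Q * Q))
    })
  }
  refs <- list(closed = prep_reference(closed_ref),
               open = prep_reference(open_ref))
  n_bb <- length(fr_idx)
  if (any(vapply(refs$closed, function(r) nrow(r$Q), integer(1)) != n_bb) ||
      any(vapply(refs$open, function(r) nrow(r$Q), integer(1)) != n_bb)) {
    stop("reference/frame backbone atom counts differ")
  }

  nf <- n_frames(ensemble)
  out <- data.frame(frame = seq_len(nf), rmsd_to_closed = NA_real_,
                    rmsd_to_open = NA_real_, topology_closed = NA_integer_,
                    topology_open = NA_integer_)
  for (f in seq_len(nf)) {
    P <- ensemble$coords[fr_idx, , f]
    P <- sweep(P, 2L, colMeans(P))
    p2 <- sum(P * P)
    for (which_ref in c("closed", "open")) {
      best <- Inf
      best_k <- 0L
      for (k in seq_along(refs[[which_ref]])) {
        r <- refs[[which_ref]][[k]]
        sv <- svd(crossprod(P, r$Q))
        d <- sign(det(sv$u %*% t(sv$v)))
        ssd <- p2 + r$q2 - 2 * sum(sv$d * c(1, 1, d))
        rmsd <- sqrt(max(0, ssd) / n_bb)
        if (rmsd < best - 1e-12) {
          best <- rmsd
          best_k <- k - 1L
        }
      }
      if (which_ref == "closed") {
        out$rmsd_to_closed[f] <- best
        out$topology_closed[f] <- best_k
      } else {
        out$rmsd_to_open[f] <- best
        out$topology_open[f] <- best_k
      }
    }
  }
  out
}

#' Write features to CSV
#'
#' @param features result of [featurize_ensemble()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
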