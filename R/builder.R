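# Synthetic coiled-coil generator: endpoint structures (open C6 barrel,
# collapsed C2 sandwich), mixture-of-states ensembles, and simulated
# titration curves. These stand in for the study data (crystal endpoints and
# MD trajectory frames) in all desk-scale tests.

# Ideal backbone internal coordinates (alpha-helix): bond lengths (A), bond
# angles and torsions (degrees).
HELIX_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.530,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5,
  phi = -57.8, psi = -47.0, omega = 180.0
)

# Idealized side-chain pseudo-centroid distances from CA along the CA->CB
# direction (A). The "SC" pseudo-atom is placed so that the mean of CB and SC
# approximates the true heavy-atom side-chain centroid of the residue type.
# ALA has no SC (CB is its centroid); GLY has no side chain at all.
SC_DISTANCES <- c(LEU = 3.7, ILE = 3.3, GLU = 3.5, LYS = 4.0, GLN = 3.6,
                  VAL = 2.9, PHE = 4.2, MET = 3.8, ARG = 4.4, ASP = 3.2,
                  ASN = 3.2, SER = 2.4, THR = 2.6, TRP = 4.5, TYR = 4.4,
                  HIS = 3.8, CYS = 2.8, PRO = 2.4)

# One heptad of the default 28-residue peptide, repeated 4x. With
# register_offset = 1 residue 1 sits at b, so Leu falls at a, Ile at d,
# Gly at e and Ala-13 at g -- the interface layout of the switchable hexamer.
DEFAULT_HEPTAD <- c("LYS", "GLU", "ILE", "GLY", "GLN", "ALA", "LEU")

#' Crick-style parameters for an idealized alpha-helical barrel
#'
#' @param n_helices number of chains (default 6, a hexamer).
#' @param superhelix_radius distance of each helix axis from the bundle axis
#'   (Angstrom).
#' @param superhelical_pitch pitch of the supercoil (Angstrom); `Inf` (the
#'   default) places straight helices parallel to the bundle axis, which keeps
#'   the generator's symmetry properties exact.
#' @param helix_radius radius of the alpha-helix CA trace (Angstrom).
#' @param residues_per_turn alpha-helical periodicity.
#' @param rise_per_residue rise along the helix axis per residue (Angstrom).
#' @param interface_angle additional rotation of every helix about its own
#'   axis (degrees); 0 points the a/d hydrophobic face at the bundle axis.
#' @param chain_length residues per chain (default 28, four heptads).
#' @param sequence vector of 3-letter residue codes recycled to
#'   `chain_length`; default is the 4x `KEIGQAL` repeat.
#' @return A list of class `crick_params`.
#' @export
crick_params <- function(n_helices = 6L, superhelix_radius = 8.5,
                         superhelical_pitch = Inf, helix_radius = 2.26,
                         residues_per_turn = 3.62, rise_per_residue = 1.51,
                         interface_angle = 0, chain_length = 28L,
                         sequence = rep(DEFAULT_HEPTAD, length.out = 28L)) {
  stopifnot(n_helices >= 2L, superhelix_radius > 0, helix_radius > 0,
            chain_length >= 7L)
  p <- list(
    n_helices = as.integer(n_helices), superhelix_radius = superhelix_radius,
    superhelical_pitch = superhelical_pitch, helix_radius = helix_radius,
    residues_per_turn = residues_per_turn, rise_per_residue = rise_per_residue,
    interface_angle = interface_angle, chain_length = as.integer(chain_length),
    sequence = rep(sequence, length.out = chain_length)
  )
  class(p) <- "crick_params"
  p
}

# Natural-extension-reference-frame placement: position D with |CD| = bond,
# angle(B,C,D) = angle_deg and dihedral(A,B,C,D) = torsion_deg.
place_atom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  b2u <- unit(C - B)
  nv <- unit(cross3(B - A, b2u))
  mv <- cross3(nv, b2u)
  C + bond * (-cos(ang) * b2u + sin(ang) * (cos(tor) * mv + sin(tor) * nv))
}

# Linear least-squares (Kasa) circle-centre fit in the plane.
fit_circle_center <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- solve(crossprod(A), crossprod(A, b))
  c(sol[1], sol[2])
}

# Direction of the screw axis relating consecutive CA positions: the
# rotation axis of the optimal superposition of CA[1..n-1] onto CA[2..n].
screw_axis_direction <- function(ca) {
  n <- nrow(ca)
  R <- kabsch_superpose(ca[-n, , drop = FALSE], ca[-1, , drop = FALSE])$rotation
  A <- R - t(R)   # skew part encodes the rotation axis
  unit(c(A[3, 2], A[1, 3], A[2, 1]))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Build one ideal alpha-helix (N, CA, C, O plus CB and SC pseudo-centroids),
# axis aligned with +z, centred at the origin, with the mean a/d side-chain
# direction pointing along -x (towards the bundle axis once the helix is
# placed at +x). Returns list(atom = data.frame, xyz = matrix).
build_helix_template <- function(n_res, sequence, register_offset = 1L) {
  g <- HELIX_GEOM
  N <- matrix(NA_real_, n_res, 3)
  CA <- matrix(NA_real_, n_res, 3)
  C <- matrix(NA_real_, n_res, 3)
  O <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  C[1, ] <- CA[1, ] + g$b_ca_c *
    c(cos(pi - g$a_n_ca_c * pi / 180), sin(pi - g$a_n_ca_c * pi / 180), 0)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, g$psi)
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, g$phi)
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o,
                         g$psi + 180)
  }
  # CB: tetrahedral construction symmetric about the N-CA-C bisector, with
  # the out-of-plane sign chosen for L-amino acids.
  CB <- matrix(NA_real_, n_res, 3)
  for (i in seq_len(n_res)) {
    nv <- unit(N[i, ] - CA[i, ])
    cv <- unit(C[i, ] - CA[i, ])
    bis <- unit(nv + cv)
    perp <- unit(cross3(cv, nv))
    CB[i, ] <- CA[i, ] + g$b_ca_cb * (-0.618 * bis - 0.786 * perp)
  }

  seq3 <- rep(sequence, length.out = n_res)
  atoms <- list()
  xyz <- list()
  for (i in seq_len(n_res)) {
    res_atoms <- c("N", "CA", "C", "O")
    res_xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (seq3[i] != "GLY") {
      res_atoms <- c(res_atoms, "CB")
      res_xyz <- rbind(res_xyz, CB[i, ])
      if (seq3[i] %in% names(SC_DISTANCES)) {
        sc <- CA[i, ] + SC_DISTANCES[[seq3[i]]] * unit(CB[i, ] - CA[i, ])
        res_atoms <- c(res_atoms, "SC")
        res_xyz <- rbind(res_xyz, sc)
      }
    }
    atoms[[i]] <- data.frame(name = res_atoms, resname = seq3[i], resno = i,
                             stringsAsFactors = FALSE)
    xyz[[i]] <- res_xyz
  }
  atom <- do.call(rbind, atoms)
  xyz <- do.call(rbind, xyz)

  # align the helix axis with +z (oriented N->C), centre on origin; the
  # axis is the screw axis of the one-residue step (exact for an ideal
  # helix, unlike the principal axis of a non-integer number of turns)
  ca <- xyz[atom$name == "CA", , drop = FALSE]
  ctr <- colMeans(ca)
  ax <- screw_axis_direction(ca)
  if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
  rot_axis <- cross3(ax, c(0, 0, 1))
  if (vec_norm(rot_axis) > 1e-9) {
    R <- rotation_about_axis(rot_axis, acos(max(-1, min(1, ax[3]))))
  } else {
    R <- diag(3) * sign(ax[3])
    if (ax[3] < 0) R <- rotation_about_axis(c(1, 0, 0), pi)
  }
  xyz <- sweep(xyz, 2L, ctr) %*% t(R)

  # the CA centroid of a non-integer number of helical turns is off-axis;
  # recentre on the axis proper via a circle fit to the CA trace in xy
  ca2 <- xyz[atom$name == "CA", , drop = FALSE]
  cc <- fit_circle_center(ca2[, 1], ca2[, 2])
  xyz[, 1] <- xyz[, 1] - cc[1]
  xyz[, 2] <- xyz[, 2] - cc[2]

  # azimuth: rotate about z so the mean a/d CB direction points along -x
  # (skipped when the sequence has no side chains at a/d, e.g. poly-Gly)
  reg <- letters[1:7][((seq_len(n_res) - 1L + 1L) %% 7L) + 1L]
  ad <- which(reg %in% c("a", "d") & seq3 != "GLY")
  if (length(ad) > 0L) {
    cb_rows <- vapply(ad, function(i) {
      which(atom$resno == i & atom$name == "CB")
    }, integer(1))
    dirs <- xyz[cb_rows, 1:2, drop = FALSE]
    mean_dir <- colMeans(dirs / sqrt(rowSums(dirs^2)))
    phi <- atan2(mean_dir[2], mean_dir[1])
    xyz <- xyz %*% t(rotation_about_axis(c(0, 0, 1), pi - phi))
  }

  list(atom = atom, xyz = xyz)
}

#' Build an idealized open C6-symmetric alpha-helical barrel
#'
#' Places `n_helices` identical, parallel alpha-helices with exact cyclic
#' symmetry about the z-axis, each helix axis at `superhelix_radius` from the
#' bundle axis. Atoms are backbone (N, CA, C, O) plus CB and an idealized
#' side-chain pseudo-centroid `SC` per residue type, which is sufficient for
#' all downstream geometry, packing and SASA analyses on synthetic
#' structures.
#'
#' @param params a [crick_params()] object.
#' @return A `cc_structure` with chains `A`, `B`, ... arranged
#'   counter-clockwise; the Crick parameters are attached as attribute
#'   `"crick_params"`.
#' @export
build_open_barrel <- function(params = crick_params()) {
  stopifnot(inherits(params, "crick_params"))
  tpl <- build_helix_template(params$chain_length, params$sequence)
  n <- params$n_helices
  Rz_iface <- rotation_about_axis(c(0, 0, 1),
                                  params$interface_angle * pi / 180)
  base_xyz <- tpl$xyz %*% t(Rz_iface)
  if (is.finite(params$superhelical_pitch)) {
    alpha <- atan2(2 * pi * params$superhelix_radius,
                   abs(params$superhelical_pitch)) *
      sign(params$superhelical_pitch)
    # left-handed supercoil for positive pitch: tilt about the radial (+x)
    # direction so the helix leans along the tangential (y) direction
    base_xyz <- base_xyz %*% t(rotation_about_axis(c(1, 0, 0), -alpha))
  }
  base_xyz <- sweep(base_xyz, 2L, c(-params$superhelix_radius, 0, 0))

  chains_xyz <- vector("list", n)
  atoms <- vector("list", n)
  for (k in seq_len(n)) {
    theta <- 2 * pi * (k - 1) / n
    chains_xyz[[k]] <- base_xyz %*% t(rotation_about_axis(c(0, 0, 1), theta))
    a <- tpl$atom
    a$chain <- LETTERS[k]
    atoms[[k]] <- a
  }
  atom <- do.call(rbind, atoms)
  atom$serial <- seq_len(nrow(atom))
  atom$occ <- 1
  atom$element <- substr(atom$name, 1L, 1L)
  atom$element[atom$name == "SC"] <- "C"
  atom <- atom[, c("serial", "name", "resname", "chain", "resno", "occ",
                   "element")]
  s <- cc_structure(atom, do.call(rbind, chains_xyz))
  attr(s, "crick_params") <- params
  s
}

#' Default shear specification for the collapsed C2 sandwich
#'
#' The closed state is built from the open barrel by translating its helices
#' perpendicular to the C6 axis into a two-sheet helical sandwich: chains
#' are grouped into three-helix sheets (F, A, B) and (C, D, E); each sheet
#' is flattened onto a plane, the two planes are brought together, and one
#' sheet slides past the other along the sheet direction. With the default
#' slide of a quarter of the in-sheet spacing the helices of one sheet nest
#' into the grooves of the other, interleaving the two sheets into a
#' compact quasi-lattice whose lumen is collapsed (no continuous channel
#' survives), as in the crystallographic closed state. Opposite chains
#' receive equal and opposite translations, so the sandwich is exactly
#' C2-symmetric about the bundle axis. Sheet flattening means the sheets
#' are not carried rigidly: in-sheet pairwise axis distances change by up
#' to ~4 A (a declared property of this construction; the crystallographic
#' sheets also deform internally, since their per-helix translations are
#' unequal).
#'
#' @param open the open barrel (`cc_structure`, 6 chains).
#' @param sheet_separation distance between the two flattened sheet planes
#'   (A).
#' @param sheet_spacing helix spacing within each flattened sheet (A).
#' @param slide half the relative inter-sheet slide (A).
#' @param spin rotation of every helix about its own axis (degrees); equal
#'   spins preserve the C2 symmetry.
#' @return A list of class `shear_spec` with `chains`, `translations`
#'   (n x 3 matrix) and `rotations` (degrees about each helix axis).
#' @export
default_shear <- function(open, sheet_separation = 7.2, sheet_spacing = 9.2,
                          slide = sheet_spacing / 4, spin = 0) {
  ch <- chains(open)
  if (length(ch) != 6L) stop("default shear is defined for hexamers")
  axes <- helix_axes(open)
  names(axes) <- vapply(axes, function(a) a$chain, character(1))
  ord <- cyclic_chain_order(open, axes)
  # sheets: the first chain, its two cyclic neighbours -> sheet 1
  a_pos <- match(ch[1], ord)
  idx <- function(k) ord[((a_pos - 1L + k) %% 6L) + 1L]
  sheet1 <- c(idx(-1L), idx(0L), idx(1L))   # e.g. F, A, B
  sheet2 <- c(idx(2L), idx(3L), idx(4L))    # e.g. C, D, E
  h <- sheet_separation / 2
  s <- sheet_spacing
  u <- slide
  target <- rbind(
    c(h, -s + u), c(h, u), c(h, s + u),       # sheet 1 (F, A, B)
    c(-h, s - u), c(-h, -u), c(-h, -s - u)    # sheet 2 (C, D, E), = C2 image
  )
  rownames(target) <- c(sheet1, sheet2)
  tr <- matrix(0, 6L, 3L)
  for (i in seq_along(ch)) {
    cur <- axes[[ch[i]]]$centroid[1:2]
    tr[i, 1:2] <- target[ch[i], ] - cur
  }
  shear_spec(ch, tr, rotations = spin)
}

#' Construct a shear specification
#'
#' @param chains chain identifiers, one per row of `translations`.
#' @param translations numeric n x 3 matrix of per-chain translations (A).
#' @param rotations per-chain rotation about the chain's own helix axis
#'   (degrees).
#' @return A list of class `shear_spec`.
#' @export
shear_spec <- function(chains, translations, rotations = 0) {
  translations <- as.matrix(translations)
  if (nrow(translations) != length(chains) || ncol(translations) != 3L) {
    stop("translations must be an n_chains x 3 matrix")
  }
  if (!all(is.finite(translations))) stop("non-finite translations")
  structure(
    list(chains = chains, translations = unname(translations),
         rotations = rep(rotations, length.out = length(chains))),
    class = "shear_spec"
  )
}

#' Build the collapsed C2-symmetric sandwich from the open barrel
#'
#' Applies a rigid per-chain transform (rotation about the chain's own axis,
#' then translation) to each helix of the open barrel. With the default shear
#' the result is an exactly C2-symmetric two-sheet helical sandwich whose
#' lumen is collapsed.
#'
#' @param open the open barrel (`cc_structure`).
#' @param shear a [shear_spec()]; defaults to [default_shear()].
#' @return A `cc_structure` of identical topology to `open`.
#' @export
build_closed_sandwich <- function(open, shear = default_shear(open)) {
  if (length(chains(open)) < 4L) stop("need at least 4 chains")
  if (!setequal(shear$chains, chains(open))) {
    stop("shear spec chains do not match structure chains")
  }
  xyz <- open$xyz
  for (i in seq_along(shear$chains)) {
    ch <- shear$chains[i]
    rows <- open$atom$chain == ch
    sub <- xyz[rows, , drop = FALSE]
    if (abs(shear$rotations[i]) > 1e-12) {
      ca <- sub[open$atom$name[rows] == "CA", , drop = FALSE]
      ctr <- colMeans(ca)
      pc <- prcomp(ca)
      ax <- pc$rotation[, 1]
      R <- rotation_about_axis(ax, shear$rotations[i] * pi / 180)
      sub <- sweep(sweep(sub, 2L, ctr) %*% t(R), 2L, -ctr)
    }
    sub <- sweep(sub, 2L, -shear$translations[i, ])
    xyz[rows, ] <- sub
  }
  out <- cc_structure(open$atom, xyz, model_id = open$model_id)
  attr(out, "crick_params") <- attr(open, "crick_params")
  if (identical(chains(open), LETTERS[1:6])) {
    attr(out, "sheets") <- list(c("F", "A", "B"), c("C", "D", "E"))
  }
  out
}

#' Specify a mixture-of-states ensemble
#'
#' Each state is a Gaussian along the open-to-closed interpolation coordinate
#' `lambda` (0 = open endpoint, 1 = closed endpoint), with a weight
#' (population), a lambda spread, and an isotropic Cartesian noise level.
#'
#' @param centers state centres on `[0, 1]`.
#' @param weights state populations; must sum to 1.
#' @param spreads per-state standard deviation of lambda.
#' @param noise_sd per-state isotropic coordinate noise (A).
#' @param n_frames number of frames to draw.
#' @param seed integer seed; the generator is bit-reproducible under it.
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(centers, weights, spreads = 0.015, noise_sd = 0.25,
                          n_frames = 1000L, seed = 1L) {
  stopifnot(length(centers) == length(weights), n_frames >= 1L)
  if (abs(sum(weights) - 1) > 1e-8) stop("state weights must sum to 1")
  structure(
    list(centers = centers, weights = weights,
         spreads = rep(spreads, length.out = length(centers)),
         noise_sd = rep(noise_sd, length.out = length(centers)),
         n_frames = as.integer(n_frames), seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

#' The default six-state ensemble preset
#'
#' Emulates the qualitative description of the aqueous free-energy landscape:
#' six metastable states spanning the closed-to-open coordinate with
#' populations (5, 5, 5, 10, 60, 15)%, the dominant state roughly
#' equidistant from both endpoints and the most open state modestly
#' populated. Illustrative of the reported state structure, not a fit to it.
#'
#' @param n_frames frames to draw (default 5000).
#' @param seed integer seed.
#' @return An [ensemble_spec()].
#' @export
paperlike_spec <- function(n_frames = 5000L, seed = 1L) {
  ensemble_spec(
    centers = c(0.78, 0.70, 0.62, 0.55, 0.48, 0.28),
    weights = c(0.05, 0.05, 0.05, 0.10, 0.60, 0.15),
    spreads = 0.015, noise_sd = 0.25, n_frames = n_frames, seed = seed
  )
}

#' Sample a synthetic conformational ensemble between two endpoints
#'
#' Frames are drawn from the mixture of states of `spec`: a state is chosen
#' by weight, a coordinate `lambda ~ N(center, spread)` is clipped to
#' `[0, 1]`, coordinates are interpolated linearly between the superposed
#' endpoints, and isotropic Gaussian noise is added. The closed endpoint is
#' first superposed onto the open endpoint over all backbone atoms.
#'
#' @param open,closed endpoint `cc_structure`s sharing one topology.
#' @param spec an [ensemble_spec()].
#' @return A `cc_ensemble`; provenance carries the spec, seed and the true
#'   per-frame state index and lambda (for validation against recovery).
#' @export
sample_ensemble <- function(open, closed, spec) {
  if (!identical(paste(open$atom$chain, open$atom$resno, open$atom$name),
                 paste(closed$atom$chain, closed$atom$resno, closed$atom$name))) {
    stop("open/closed endpoint topology mismatch")
  }
  bb <- which(open$atom$name %in% BACKBONE_ATOMS)
  sup <- kabsch_superpose(closed$xyz[bb, , drop = FALSE],
                          open$xyz[bb, , drop = FALSE])
  closed_xyz <- sweep(closed$xyz %*% sup$rotation, 2L, -sup$translation)

  set.seed(spec$seed)
  n <- spec$n_frames
  state <- sample.int(length(spec$weights), n, replace = TRUE,
                      prob = spec$weights)
  lambda <- pmin(1, pmax(0, rnorm(n, spec$centers[state],
                                  spec$spreads[state])))
  na <- nrow(open$xyz)
  coords <- array(NA_real_, dim = c(na, 3L, n))
  for (f in seq_len(n)) {
    base <- (1 - lambda[f]) * open$xyz + lambda[f] * closed_xyz
    if (spec$noise_sd[state[f]] > 0) {
      base <- base + matrix(rnorm(3L * na, 0, spec$noise_sd[state[f]]),
                            na, 3L)
    }
    coords[, , f] <- base
  }
  cc_ensemble(open$atom, coords, provenance = list(
    source = "sample_ensemble", seed = spec$seed, spec = spec,
    truth = data.frame(frame = seq_len(n), state = state, lambda = lambda)
  ))
}

#' Simulate a saturation-binding titration curve
#'
#' The noiseless signal follows the quadratic tight-binding model (see
#' [fraction_bound()]); Gaussian noise of standard deviation `noise_sd` is
#' added to each point.
#'
#' @param kd dissociation constant (uM).
#' @param bmax signal at saturation (arbitrary units).
#' @param c fixed concentration of the constant component (uM), e.g. the
#'   fluorophore held at 0.1 uM while the peptide is titrated.
#' @param x concentrations of the variable component (uM), strictly
#'   increasing.
#' @param noise_sd signal noise standard deviation.
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @return A list of class `binding_curve` with `x`, `y`, `c` and the
#'   simulation truth.
#' @export
simulate_binding_curve <- function(kd, bmax, c, x, noise_sd = 0, seed = 1L) {
  stopifnot(kd >= 0, c > 0, all(x >= 0), !is.unsorted(x, strictly = TRUE))
  y <- fraction_bound(x, kd = kd, bmax = bmax, c = c)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(x), 0, noise_sd)
  }
  structure(list(x = x, y = y, c = c, truth = list(kd = kd, bmax = bmax)),
            class = "binding_curve")
}

#' Write / read a binding curve as two-column CSV
#'
#' @param curve a `binding_curve`.
#' @param path CSV path; columns `x` and `y` with a header.
#' @return Invisibly `path` (write) or a `binding_curve` (read; `c` must be
#'   supplied since the CSV holds the titration only).
#' @export
write_binding_curve <- function(curve, path) {
  utils::write.csv(data.frame(x = curve$x, y = curve$y), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_binding_curve
#' @param c constant-component concentration (uM) for the curve being read.
#' @export
read_binding_curve <- function(path, c) {
  df <- utils::read.csv(path)
  structure(list(x = df$x, y = df$y, c = c, truth = NULL),
            class = "binding_curve")
}
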