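# Helix-bundle geometry: per-chain helix axes, cyclic neighbour spacings,
# helix-triad angles, and HOLE-style channel-radius profiles.

#' Fit a helix axis through one chain
#'
#' The direction is the screw axis of the one-residue CA step (the rotation
#' axis of the optimal superposition of the CA trace onto itself shifted by
#' one residue), which is exact for an ideal helix; the axis point is the
#' centre of the circle the CA trace describes around that direction. The
#' first and last `trim` residues are excluded, and the direction is
#' oriented N-terminus to C-terminus.
#'
#' @param structure a `cc_structure`.
#' @param chain chain identifier.
#' @param residue_range optional `c(lo, hi)` residue-number window (applied
#'   before trimming).
#' @param trim residues dropped at each end (default 2).
#' @return A list of class `helix_axis`: `centroid`, unit `direction`,
#'   `chain`, `residue_range`.
#' @export
fit_helix_axis <- function(structure, chain, residue_range = NULL, trim = 2L) {
  atom <- structure$atom
  rows <- which(atom$chain == chain & atom$name == "CA")
  if (!is.null(residue_range)) {
    rows <- rows[atom$resno[rows] >= residue_range[1] &
                   atom$resno[rows] <= residue_range[2]]
  }
  rows <- rows[order(atom$resno[rows])]
  if (length(rows) > 2L * trim + 3L) {
    rows <- rows[(trim + 1L):(length(rows) - trim)]
  }
  if (length(rows) < 7L) {
    stop("chain ", chain, ": need at least 7 consecutive CA atoms")
  }
  ca <- structure$xyz[rows, , drop = FALSE]
  ctr <- colMeans(ca)
  dir <- screw_axis_direction(ca)
  if (sum(dir * (ca[nrow(ca), ] - ca[1, ])) < 0) dir <- -dir
  # the CA centroid of a non-integer number of turns lies off the helix
  # axis; recentre by fitting the circle the CA trace describes in the
  # plane perpendicular to the direction
  pb <- plane_basis(dir)
  rel <- sweep(ca, 2L, ctr)
  cc <- fit_circle_center(rel %*% pb$e1, rel %*% pb$e2)
  ctr <- ctr + cc[1] * pb$e1 + cc[2] * pb$e2
  structure(
    list(centroid = ctr, direction = unname(dir), chain = chain,
         residue_range = range(atom$resno[rows])),
    class = "helix_axis"
  )
}

#' Fit helix axes for all chains
#'
#' @inheritParams fit_helix_axis
#' @return List of `helix_axis`, one per chain.
#' @export
helix_axes <- function(structure, trim = 2L) {
  lapply(chains(structure), function(ch) fit_helix_axis(structure, ch,
                                                        trim = trim))
}

# Bundle axis: sign-aligned mean of the helix-axis unit directions (the
# helices of these bundles are nearly parallel), anchored at the mean of the
# axis centroids.
bundle_axis <- function(axes) {
  ref <- axes[[1]]$direction
  dirs <- t(vapply(axes, function(a) {
    if (sum(a$direction * ref) < 0) -a$direction else a$direction
  }, numeric(3)))
  list(point = colMeans(t(vapply(axes, function(a) a$centroid, numeric(3)))),
       direction = unit(colMeans(dirs)))
}

# Orthonormal in-plane basis perpendicular to unit vector u.
plane_basis <- function(u) {
  seed <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(seed - sum(seed * u) * u)
  e2 <- cross3(u, e1)
  list(e1 = e1, e2 = e2)
}

# Chains sorted by angular position of their helix-axis centroids about the
# bundle axis (cyclic order around the bundle).
cyclic_chain_order <- function(structure, axes = helix_axes(structure)) {
  ba <- bundle_axis(axes)
  pb <- plane_basis(ba$direction)
  ang <- vapply(axes, function(a) {
    v <- a$centroid - ba$point
    atan2(sum(v * pb$e2), sum(v * pb$e1))
  }, numeric(1))
  vapply(axes, function(a) a$chain, character(1))[order(ang)]
}

#' CA-CA distances of one residue between cyclically adjacent chains
#'
#' Adjacency is the angular order of the helix-axis centroids about the
#' bundle axis (which for a sheared sandwich may differ from chain-name
#' order). Distances are between the CA atoms of `residue_number` on each
#' pair of adjacent chains, in cyclic order.
#'
#' @param structure a `cc_structure` with at least 3 chains.
#' @param residue_number residue whose CA atoms are measured (e.g. the Ala
#'   at a g interface site).
#' @return A list with `distances` (named by chain pair) and their `mean`.
#' @export
neighbour_ca_distances <- function(structure, residue_number) {
  atom <- structure$atom
  ch <- chains(structure)
  if (length(ch) < 3L) stop("need at least 3 chains")
  ca_row <- vapply(ch, function(cc) {
    hit <- which(atom$chain == cc & atom$resno == residue_number &
                   atom$name == "CA")
    if (length(hit) != 1L) NA_integer_ else hit
  }, integer(1))
  if (anyNA(ca_row)) {
    stop("residue ", residue_number, " missing CA in chain(s): ",
         paste(ch[is.na(ca_row)], collapse = ", "))
  }
  ord <- cyclic_chain_order(structure)
  nxt <- c(ord[-1], ord[1])
  d <- vapply(seq_along(ord), function(i) {
    vec_norm(structure$xyz[ca_row[ord[i]], ] - structure$xyz[ca_row[nxt[i]], ])
  }, numeric(1))
  names(d) <- paste(ord, nxt, sep = "-")
  list(distances = d, mean = mean(d))
}

#' Spacing between cyclically adjacent helix axes
#'
#' Distances between the axis points of adjacent helices after projection
#' onto the plane normal to the bundle axis (i.e. axis spacing at
#' mid-height). For an ideal Cn barrel with n = 6 this equals the
#' superhelix radius exactly (a regular hexagon's side equals its
#' circumradius).
#'
#' @param structure a `cc_structure` with at least 3 chains.
#' @return A list with `distances` (named by chain pair) and their `mean`.
#' @export
neighbour_axis_spacing <- function(structure) {
  axes <- helix_axes(structure)
  if (length(axes) < 3L) stop("need at least 3 chains")
  ba <- bundle_axis(axes)
  pb <- plane_basis(ba$direction)
  proj <- t(vapply(axes, function(a) {
    v <- a$centroid - ba$point
    c(sum(v * pb$e1), sum(v * pb$e2))
  }, numeric(2)))
  rownames(proj) <- vapply(axes, function(a) a$chain, character(1))
  ord <- cyclic_chain_order(structure, axes)
  nxt <- c(ord[-1], ord[1])
  d <- vapply(seq_along(ord), function(i) {
    vec_norm(proj[ord[i], ] - proj[nxt[i], ])
  }, numeric(1))
  names(d) <- paste(ord, nxt, sep = "-")
  list(distances = d, mean = mean(d))
}

#' Helix-triad angles around the bundle
#'
#' For each helix `i` (in cyclic order), the angle at helix `i`'s axis
#' centroid subtended by its two cyclic neighbours, measured after projecting
#' the centroids onto the plane normal to the bundle axis. An ideal C6
#' barrel gives six angles of 120 degrees; shearing into the collapsed
#' sandwich spreads them widely.
#'
#' @param structure a `cc_structure` with at least 3 chains.
#' @return Named numeric vector of angles (degrees), one per chain in cyclic
#'   order.
#' @export
helix_triad_angles <- function(structure) {
  axes <- helix_axes(structure)
  if (length(axes) < 3L) stop("need at least 3 chains")
  ba <- bundle_axis(axes)
  pb <- plane_basis(ba$direction)
  proj <- t(vapply(axes, function(a) {
    v <- a$centroid - ba$point
    c(sum(v * pb$e1), sum(v * pb$e2))
  }, numeric(2)))
  rownames(proj) <- vapply(axes, function(a) a$chain, character(1))
  ord <- cyclic_chain_order(structure, axes)
  n <- length(ord)
  ang <- vapply(seq_len(n), function(i) {
    p0 <- proj[ord[i], ]
    pm <- proj[ord[if (i == 1L) n else i - 1L], ]
    pp <- proj[ord[if (i == n) 1L else i + 1L], ]
    v1 <- pm - p0
    v2 <- pp - p0
    if (vec_norm(v1) < 1e-6 || vec_norm(v2) < 1e-6) {
      stop("degenerate (coincident) helix centroids")
    }
    acos(max(-1, min(1, sum(v1 * v2) / (vec_norm(v1) * vec_norm(v2))))) *
      180 / pi
  }, numeric(1))
  names(ang) <- ord
  ang
}

#' HOLE-style channel-radius profile along the bundle axis
#'
#' At each position `z` along the bundle axis, the radius of the largest
#' sphere that touches no atom's van der Waals sphere, centred on a point
#' optimised within the slice plane. The channel is tracked like a sphere
#' squeezed along the pore: the middle slice is seeded at the bundle axis,
#' and each successive slice starts from the previous slice's centre, which
#' may drift at most `max_drift` per step (so interstitial grooves away
#' from the pore are not picked up). Centres are additionally constrained
#' to the bundle hull -- the convex hull of the helix-axis positions in the
#' slice plane, dilated by `hull_margin`. A slice reports "no channel" when
#' the best radius falls below `min_radius`; a fully collapsed structure
#' yields a profile with no channel anywhere.
#'
#' @param structure a `cc_structure`.
#' @param step slice spacing along the axis (Angstrom, default 1).
#' @param min_radius radius below which a slice counts as closed (default
#'   0.5).
#' @param hull_margin outward dilation of the bundle hull (Angstrom).
#' @param max_drift maximum in-plane movement of the channel centre per
#'   slice (Angstrom).
#' @param axis_drift maximum distance of the seed slice's centre from the
#'   bundle axis (Angstrom).
#' @return A data frame of class `channel_profile` with columns `z`,
#'   `radius` (`NA` where closed) and `channel`; attributes `mean_radius`
#'   and `sd_radius` are computed over open slices only.
#' @export
channel_radius_profile <- function(structure, step = 1, min_radius = 0.5,
                                   hull_margin = 1.0, max_drift = 1.0,
                                   axis_drift = 2.0) {
  if (n_atoms(structure) == 0L) stop("empty structure")
  axes <- helix_axes(structure)
  ba <- bundle_axis(axes)
  pb <- plane_basis(ba$direction)
  rel <- sweep(structure$xyz, 2L, ba$point)
  s <- rel %*% ba$direction
  a1 <- rel %*% pb$e1
  a2 <- rel %*% pb$e2
  radii <- vdw_radii(structure)

  # common extent of the helices along the axis
  ca <- structure$atom$name == "CA"
  z_lo <- max(vapply(chains(structure), function(cc)
    min(s[ca & structure$atom$chain == cc]), numeric(1)))
  z_hi <- min(vapply(chains(structure), function(cc)
    max(s[ca & structure$atom$chain == cc]), numeric(1)))
  zs <- seq(z_lo, z_hi, by = step)

  # bundle hull: convex hull of the in-plane helix-axis positions, dilated
  ax_xy <- t(vapply(axes, function(a) {
    v <- a$centroid - ba$point
    c(sum(v * pb$e1), sum(v * pb$e2))
  }, numeric(2)))
  hull <- make_hull(ax_xy, hull_margin)
  slab_half <- max(sqrt(rowSums(ax_xy^2))) + 6

  slice_opt <- function(z, anchor, drift) {
    slab <- which(abs(s - z) <= slab_half)
    if (length(slab) == 0L) return(list(radius = -Inf, center = anchor))
    b1 <- a1[slab]
    b2 <- a2[slab]
    dz2 <- (s[slab] - z)^2
    rr <- radii[slab]
    objective <- function(c12) {
      pen <- 100 * hull_violation(hull, c12)
      if (is.finite(drift)) {
        pen <- pen + 100 * max(0, vec_norm(c12 - anchor) - drift)
      }
      -(min(sqrt((b1 - c12[1])^2 + (b2 - c12[2])^2 + dz2) - rr) - pen)
    }
    starts <- list(anchor)
    best <- -Inf
    best_c <- anchor
    for (st in starts) {
      opt <- stats::optim(st, objective, method = "Nelder-Mead",
                          control = list(reltol = 1e-6, maxit = 300))
      if (-opt$value > best) {
        best <- -opt$value
        best_c <- opt$par
      }
    }
    list(radius = best, center = best_c)
  }

  n <- length(zs)
  out_r <- rep(NA_real_, n)
  i0 <- which.min(abs(zs - stats::median(zs)))
  mid <- slice_opt(zs[i0], c(0, 0), axis_drift)
  out_r[i0] <- mid$radius
  for (dir in c(1L, -1L)) {
    anchor <- mid$center
    i <- i0 + dir
    while (i >= 1L && i <= n) {
      res <- slice_opt(zs[i], anchor, max_drift)
      out_r[i] <- res$radius
      anchor <- res$center
      i <- i + dir
    }
  }
  out_r[out_r < min_radius] <- NA_real_
  prof <- data.frame(z = zs, radius = out_r, channel = !is.na(out_r))
  attr(prof, "mean_radius") <- if (any(prof$channel))
    mean(out_r, na.rm = TRUE) else NA_real_
  attr(prof, "sd_radius") <- if (sum(prof$channel) > 1L)
    stats::sd(out_r, na.rm = TRUE) else NA_real_
  runs <- rle(prof$channel)
  attr(prof, "open_fraction") <- mean(prof$channel)
  attr(prof, "longest_span_fraction") <- if (any(prof$channel))
    max(runs$lengths[runs$values]) / nrow(prof) else 0
  class(prof) <- c("channel_profile", class(prof))
  prof
}

#' Does a profile describe a traversable channel?
#'
#' A bundle has a channel when its profile is open over one contiguous span
#' of at least `min_span` of the slices -- a pore must be continuous to be
#' traversable. A collapsed sandwich retains scattered interstitial voids
#' (sub-probe pockets between helices) but no contiguous pore, and is
#' reported channel-less.
#'
#' @param profile a `channel_profile`.
#' @param min_span minimum contiguous open fraction (default 0.5).
#' @return `TRUE` or `FALSE`.
#' @export
has_channel <- function(profile, min_span = 0.5) {
  attr(profile, "longest_span_fraction") >= min_span
}

#' Largest inscribed-sphere radius in one slice plane
#'
#' Low-level building block of [channel_radius_profile()]: the radius of the
#' largest sphere centred on a point of the plane through `z` (measured
#' along `axis_direction` from `axis_point`) that touches none of the given
#' van der Waals spheres. The centre is optimised by Nelder-Mead from the
#' axis seed plus four offset starts; no hull or drift constraint is
#' applied.
#'
#' @param xyz numeric n x 3 atom coordinates.
#' @param radii per-atom van der Waals radii.
#' @param z slice position along the axis.
#' @param axis_point,axis_direction the slicing axis.
#' @return A list with `radius` and the in-plane `center` (2-vector in the
#'   plane basis).
#' @export
slice_channel_radius <- function(xyz, radii, z = 0,
                                 axis_point = c(0, 0, 0),
                                 axis_direction = c(0, 0, 1)) {
  u <- unit(axis_direction)
  pb <- plane_basis(u)
  rel <- sweep(as.matrix(xyz), 2L, axis_point)
  s <- rel %*% u
  b1 <- rel %*% pb$e1
  b2 <- rel %*% pb$e2
  dz2 <- as.vector(s - z)^2
  # the centre must stay inside the structure: constrain to the convex
  # hull of the atoms' in-plane positions (open space outside the atom
  # cloud is not a channel)
  hull <- make_hull(cbind(as.vector(b1), as.vector(b2)), 0)
  objective <- function(c12) {
    -(min(sqrt((b1 - c12[1])^2 + (b2 - c12[2])^2 + dz2) - radii) -
        100 * hull_violation(hull, c12))
  }
  best <- -Inf
  best_c <- c(0, 0)
  for (st in list(c(0, 0), c(2, 0), c(-2, 0), c(0, 2), c(0, -2))) {
    opt <- stats::optim(st, objective, method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = 500))
    if (-opt$value > best) {
      best <- -opt$value
      best_c <- opt$par
    }
  }
  list(radius = best, center = best_c)
}

# Convex hull of 2-D points, dilated outward by `margin` from its centroid,
# stored as counter-clockwise vertices.
make_hull <- function(xy, margin = 0) {
  idx <- grDevices::chull(xy)       # clockwise order
  v <- xy[rev(idx), , drop = FALSE] # counter-clockwise
  ctr <- colMeans(v)
  if (margin > 0) {
    v <- t(apply(v, 1L, function(p) {
      d <- p - ctr
      p + margin * d / max(vec_norm(d), 1e-9)
    }))
  }
  list(vertices = v, centroid = ctr)
}

# Outside-hull violation: max outward distance over edges (0 when inside).
hull_violation <- function(hull, p) {
  v <- hull$vertices
  n <- nrow(v)
  worst <- 0
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[if (i == n) 1L else i + 1L, ]
    e <- b - a
    # outward normal of a CCW polygon edge
    nrm <- c(e[2], -e[1]) / max(vec_norm(e), 1e-9)
    worst <- max(worst, sum((p - a) * nrm))
  }
  worst
}

#' Per-state mean channel radii
#'
#' Samples representative conformations from each core state, profiles each,
#' and summarises the per-conformation mean radii. A conformation counts as
#' channel-less when it has no contiguous open span covering at least half
#' of its slices (see [has_channel()]).
#'
#' @param states a `cc_states`.
#' @param ensemble the source `cc_ensemble`.
#' @param n_rep representative conformations per state (default 1000).
#' @param seed integer seed for the per-state sampling.
#' @param step slice spacing (A).
#' @return A data frame with one row per state: `state`, `population`,
#'   `mean_radius`, `sd_radius`, `n_channel`, `n_no_channel`.
#' @export
state_mean_channel_radius <- function(states, ensemble, n_rep = 1000L,
                                      seed = 1L, step = 1) {
  rows <- lapply(states, function(st) {
    reps <- sample_state_conformations(st, ensemble, n = n_rep,
                                       seed = seed + st$id)
    per_conf <- vapply(seq_len(n_frames(reps)), function(f) {
      prof <- channel_radius_profile(get_frame(reps, f), step = step)
      if (has_channel(prof)) attr(prof, "mean_radius") else NA_real_
    }, numeric(1))
    data.frame(
      state = st$id, population = st$population,
      mean_radius = if (any(!is.na(per_conf)))
        mean(per_conf, na.rm = TRUE) else NA_real_,
      sd_radius = if (sum(!is.na(per_conf)) > 1L)
        stats::sd(per_conf, na.rm = TRUE) else NA_real_,
      n_channel = sum(!is.na(per_conf)),
      n_no_channel = sum(is.na(per_conf))
    )
  })
  do.call(rbind, rows)
}
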