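# Shared constants and small numeric helpers.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# van der Waals radii (Angstrom). "SC" is the idealized side-chain
# pseudo-centroid emitted by the builder; it stands for several heavy atoms,
# so it carries a larger effective radius than a single carbon.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, SC = 2.20)

#' van der Waals radii for the atoms of a structure
#'
#' @param structure a `cc_structure`.
#' @return Numeric vector of radii (Angstrom), one per atom.
#' @export
vdw_radii <- function(structure) {
  elem <- structure$atom$element
  elem[structure$atom$name == "SC"] <- "SC"
  r <- VDW_RADII[elem]
  if (anyNA(r)) {
    stop(
      "unknown element(s): ",
      paste(unique(elem[is.na(r)]), collapse = ", ")
    )
  }
  unname(r)
}

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# Rotation matrix for angle theta (radians) about unit axis (Rodrigues).
rotation_about_axis <- function(axis, theta) {
  a <- unit(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3L, 3L)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Apply rigid motion y = x R + t (row-vector convention) to an n x 3 matrix.
apply_rigid <- function(xyz, R = diag(3), t = c(0, 0, 0)) {
  sweep(xyz %*% R, 2L, -t)
}

# Row-wise euclidean distance from each row of `xyz` to point `p`.
dist_to_point <- function(xyz, p) {
  sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
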