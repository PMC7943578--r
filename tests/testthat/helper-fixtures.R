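# Shared fixtures, built once per test run and cached. Everything is
# generated in code from the synthetic builder; no data files are used.

.fx <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

fx_open <- function() fx("open", build_open_barrel())

fx_closed <- function() fx("closed", build_closed_sandwich(fx_open()))

fx_ensemble <- function() {
  fx("ens300", sample_ensemble(fx_open(), fx_closed(),
                               paperlike_spec(n_frames = 300L, seed = 11L)))
}

fx_features <- function() {
  fx("feat300", featurize_ensemble(fx_ensemble(), fx_open(), fx_closed()))
}

# 2-D mixture-of-Gaussians sample with given weights/means/sd
rgauss_mix <- function(n, weights, means, sd = 0.12, seed = 7L) {
  set.seed(seed)
  comp <- sample(seq_along(weights), n, replace = TRUE, prob = weights)
  X <- t(vapply(comp, function(k) means[[k]] + rnorm(2, 0, sd), numeric(2)))
  colnames(X) <- c("rmsd_to_closed", "rmsd_to_open")
  attr(X, "component") <- comp
  X
}

fx_gauss3 <- function() {
  fx("gauss3", rgauss_mix(20000L, c(0.60, 0.25, 0.15),
                          list(c(1.2, 2.6), c(2.0, 1.8), c(2.8, 1.0)),
                          sd = 0.12, seed = 7L))
}

# random rigid motion applied to an n x 3 coordinate matrix
random_rigid <- function(xyz, seed = 1L) {
  set.seed(seed)
  ax <- unit_vec(rnorm(3))
  R <- rot_axis_angle(ax, runif(1, 0, 2 * pi))
  sweep(xyz %*% R, 2L, -rnorm(3, 0, 10))
}

unit_vec <- function(v) v / sqrt(sum(v^2))

rot_axis_angle <- function(a, theta) {
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3L, 3L)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# independent superposition oracle: bio3d's least-squares fit (its rmsd()
# helper rounds to 3 decimals, so the RMSD is recomputed from the fitted
# coordinates)
bio3d_fit_rmsd <- function(a_xyz, b_xyz) {
  a <- as.vector(t(a_xyz))
  b <- as.vector(t(b_xyz))
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = b, mobile = matrix(a, nrow = 1L)))
  sqrt(sum((as.vector(fitted) - b)^2) / nrow(a_xyz))
}
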