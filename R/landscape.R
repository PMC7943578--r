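# Free-energy landscape over the 2-D conformational coordinates: a Gaussian
# mixture density is fitted to the feature cloud, F(x) = -kT ln p(x) is
# evaluated on a regular grid, and metastable core states are extracted by
# following the density gradient from each mixture component to its basin
# maximum (InfleCS-style), with transition-region frames left unassigned.

# kT at 293.15 K in kcal/mol (R = 1.98720425e-3 kcal/mol/K)
KT_293 <- 0.0019872 * 293.15

feature_matrix <- function(features) {
  if (is.matrix(features)) {
    stopifnot(ncol(features) == 2L)
    return(unname(features))
  }
  if (!all(c("rmsd_to_closed", "rmsd_to_open") %in% names(features))) {
    stop("features must have rmsd_to_closed and rmsd_to_open columns")
  }
  unname(cbind(features$rmsd_to_closed, features$rmsd_to_open))
}

#' Fit a Gaussian mixture density to the feature cloud
#'
#' Full-covariance Gaussian mixtures are fitted by EM over a range of
#' component counts; the count is selected by the Bayesian information
#' criterion. Initialisation uses model-based hierarchical clustering on a
#' seeded random subsample (one fifth of the frames by default, capped at
#' 2000 points), after which all frames enter the EM fit — so the result is
#' deterministic under a fixed seed.
#'
#' @param features feature data frame (see [featurize_ensemble()]) or a
#'   two-column matrix.
#' @param component_range integer vector of candidate component counts.
#' @param seed integer seed controlling the initialisation subsample.
#' @param init_fraction fraction of frames used for initialisation.
#' @param init_cap maximum initialisation subsample size.
#' @return An object of class `cc_density`: weights, means (2 x G),
#'   covariances (2 x 2 x G), selected `G`, per-candidate BIC scores, the
#'   seed, and the underlying mclust fit.
#' @export
fit_density <- function(features, component_range = 1:10, seed = 1L,
                        init_fraction = 0.2, init_cap = 2000L) {
  X <- feature_matrix(features)
  n <- nrow(X)
  if (n < 10L * max(component_range)) {
    stop("need at least 10x max(component_range) frames")
  }
  set.seed(seed)
  n_init <- min(max(100L, ceiling(n * init_fraction)), init_cap, n)
  subset <- sample.int(n, n_init)
  fit <- mclust::Mclust(X, G = component_range, modelNames = "VVV",
                        initialization = list(subset = subset),
                        verbose = FALSE)
  if (is.null(fit)) {
    fit <- mclust::Mclust(X, G = component_range, modelNames = "VVV",
                          prior = mclust::priorControl(),
                          initialization = list(subset = subset),
                          verbose = FALSE)
  }
  if (is.null(fit)) {
    stop("mixture fit failed (singular covariance); try a larger ",
         "regularisation or fewer components")
  }
  G <- fit$G
  covs <- array(NA_real_, dim = c(2L, 2L, G))
  for (k in seq_len(G)) {
    covs[, , k] <- fit$parameters$variance$sigma[, , k] + diag(1e-6, 2L)
  }
  structure(
    list(weights = fit$parameters$pro, means = fit$parameters$mean,
         covariances = covs, G = G,
         bic_scores = fit$BIC[, "VVV"], seed = seed, mclust_fit = fit),
    class = "cc_density"
  )
}

#' @export
print.cc_density <- function(x, ...) {
  cat(sprintf("cc_density: %d Gaussian components (BIC-selected), weights: %s\n",
              x$G, paste(sprintf("%.3f", x$weights), collapse = " ")))
  invisible(x)
}

# Mixture density and its gradient at points X (n x 2)
mixture_density <- function(model, X, gradient = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- numeric(n)
  grad <- if (gradient) matrix(0, n, 2L) else NULL
  for (k in seq_len(model$G)) {
    mu <- model$means[, k]
    S <- model$covariances[, , k]
    Sinv <- solve(S)
    dx <- sweep(X, 2L, mu)
    q <- rowSums((dx %*% Sinv) * dx)
    dk <- model$weights[k] * exp(-0.5 * q) /
      (2 * pi * sqrt(det(S)))
    p <- p + dk
    if (gradient) grad <- grad - dk * (dx %*% Sinv)
  }
  if (gradient) list(density = p, gradient = grad) else p
}

#' Evaluate the free-energy landscape on a regular grid
#'
#' `F(x) = -kT log p(x)` is evaluated on an `n_grid x n_grid` grid spanning
#' the feature ranges with 5% padding per side, shifted so the minimum is
#' exactly zero. Nodes more than `f_cap` above the minimum are masked
#' (`Inf`): the mixture density there is too low to be meaningful.
#'
#' @param model a `cc_density` from [fit_density()].
#' @param features the features the model was fitted to (sets the grid
#'   extent).
#' @param kT thermal energy in kcal/mol (default: 293.15 K).
#' @param n_grid nodes per axis (default 151).
#' @param padding fractional padding of the feature range per side.
#' @param f_cap masking threshold above the minimum (kcal/mol).
#' @return An object of class `cc_landscape`: grid axes `x` (RMSD to
#'   closed), `y` (RMSD to open), matrix `free_energy` (x varies over rows),
#'   `kT` and `f_cap`.
#' @export
evaluate_landscape <- function(model, features, kT = KT_293, n_grid = 151L,
                               padding = 0.05, f_cap = 6) {
  X <- feature_matrix(features)
  rng_x <- range(X[, 1])
  rng_y <- range(X[, 2])
  pad_x <- diff(rng_x) * padding
  pad_y <- diff(rng_y) * padding
  gx <- seq(rng_x[1] - pad_x, rng_x[2] + pad_x, length.out = n_grid)
  gy <- seq(rng_y[1] - pad_y, rng_y[2] + pad_y, length.out = n_grid)
  nodes <- cbind(rep(gx, times = n_grid), rep(gy, each = n_grid))
  p <- mixture_density(model, nodes)
  FE <- -kT * log(pmax(p, .Machine$double.xmin))
  FE <- FE - min(FE)
  FE[FE > f_cap] <- Inf
  structure(
    list(x = gx, y = gy,
         free_energy = matrix(FE, n_grid, n_grid), kT = kT, f_cap = f_cap),
    class = "cc_landscape"
  )
}

#' Location of the landscape minimum
#'
#' @param landscape a `cc_landscape`.
#' @return Numeric length-2 vector (grid node of the free-energy minimum).
#' @export
landscape_minimum <- function(landscape) {
  idx <- which(landscape$free_energy == 0, arr.ind = TRUE)[1, ]
  c(landscape$x[idx[1]], landscape$y[idx[2]])
}

#' Write a landscape grid to CSV
#'
#' Long format: one row per node with columns `rmsd_to_closed`,
#' `rmsd_to_open`, `free_energy` (masked nodes as `NA`).
#'
#' @param landscape a `cc_landscape`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_landscape <- function(landscape, path) {
  df <- expand.grid(rmsd_to_closed = landscape$x,
                    rmsd_to_open = landscape$y)
  fe <- as.vector(landscape$free_energy)
  df$free_energy <- ifelse(is.finite(fe), fe, NA_real_)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Contour plot of the free-energy landscape
#'
#' Contours are drawn every `contour_step` kcal/mol (0.25 by default) from
#' darker to lighter with increasing energy; state peaks can be overlaid.
#'
#' @param landscape a `cc_landscape`.
#' @param states optional `cc_states` (peak markers).
#' @param contour_step contour spacing in kcal/mol.
#' @param ... passed to [graphics::contour()].
#' @return Invisibly, `NULL`.
#' @export
plot_landscape <- function(landscape, states = NULL, contour_step = 0.25,
                           ...) {
  FE <- landscape$free_energy
  FE[!is.finite(FE)] <- NA
  lv <- seq(0, landscape$f_cap, by = contour_step)
  cols <- grDevices::hcl.colors(length(lv), "Blues 3", rev = TRUE)
  graphics::contour(landscape$x, landscape$y, FE, levels = lv, col = cols,
                    drawlabels = FALSE, xlab = "RMSD to closed (Å)",
                    ylab = "RMSD to open (Å)", ...)
  if (!is.null(states)) {
    pk <- t(vapply(states, function(s) s$peak, numeric(2)))
    graphics::points(pk[, 1], pk[, 2], pch = 4, col = "red3", lwd = 2)
    graphics::text(pk[, 1], pk[, 2],
                   labels = sprintf("S%d (%.0f%%)",
                                    seq_along(states),
                                    100 * vapply(states, function(s)
                                      s$population, numeric(1))),
                   pos = 3, cex = 0.8)
  }
  invisible(NULL)
}
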