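# Metastable core states: mixture components are grouped into basins of the
# density by gradient ascent from each component mean; frames are assigned
# crisply to a basin only where the density is high (core region), so
# transition points do not dilute the state statistics.

#' Extract metastable core states from a fitted density
#'
#' Each mixture component's mean is carried uphill on the mixture density to
#' its local maximum; components converging to the same maximum form one
#' basin. A frame belongs to the basin of its maximum-responsibility
#' component, and is a *core* member only if that responsibility is at least
#' `responsibility_min` and its mixture density is above the
#' `density_quantile` quantile within the basin; all other frames are
#' treated as transition points and left unassigned. Populations are the
#' core-member fractions renormalised over assigned frames.
#'
#' @param model a `cc_density` from [fit_density()].
#' @param features the featurized frames the model was fitted to.
#' @param responsibility_min crisp-assignment responsibility threshold.
#' @param density_quantile within-basin density quantile below which frames
#'   are treated as transition points (default 0.20).
#' @param merge_tol distance below which two basin maxima are merged;
#'   default 2% of the feature-range diagonal.
#' @return A list of class `cc_states`; each element has `id`, `population`,
#'   `members` (frame indices), `n_members`, `peak` (basin maximum) and
#'   `components` (mixture components in the basin). States are ordered by
#'   decreasing population.
#' @export
extract_core_states <- function(model, features, responsibility_min = 0.5,
                                density_quantile = 0.20, merge_tol = NULL) {
  X <- feature_matrix(features)
  if (is.null(merge_tol)) {
    merge_tol <- 0.02 * sqrt(sum((apply(X, 2L, function(v)
      diff(range(v))))^2))
  }

  # gradient ascent from each component mean to its basin maximum
  peaks <- matrix(NA_real_, model$G, 2L)
  for (k in seq_len(model$G)) {
    peaks[k, ] <- ascend_density(model, model$means[, k])
  }
  if (!all(is.finite(peaks))) stop("no basin found (flat density)")

  # merge components whose ascents converged to the same maximum
  basin_of <- integer(model$G)
  basin_peaks <- list()
  for (k in seq_len(model$G)) {
    hit <- 0L
    for (b in seq_along(basin_peaks)) {
      if (vec_norm(peaks[k, ] - basin_peaks[[b]]) < merge_tol) {
        hit <- b
        break
      }
    }
    if (hit == 0L) {
      basin_peaks[[length(basin_peaks) + 1L]] <- peaks[k, ]
      hit <- length(basin_peaks)
    } else {
      # keep the higher of the two merged maxima as the basin peak
      if (mixture_density(model, matrix(peaks[k, ], 1L)) >
          mixture_density(model, matrix(basin_peaks[[hit]], 1L))) {
        basin_peaks[[hit]] <- peaks[k, ]
      }
    }
    basin_of[k] <- hit
  }
  n_basin <- length(basin_peaks)

  # crisp assignment
  resp <- component_responsibilities(model, X)
  comp <- max.col(resp, ties.method = "first")
  resp_max <- resp[cbind(seq_len(nrow(X)), comp)]
  basin <- basin_of[comp]
  dens <- mixture_density(model, X)
  core <- resp_max >= responsibility_min
  for (b in seq_len(n_basin)) {
    in_b <- basin == b
    if (!any(in_b)) next
    floor_b <- stats::quantile(dens[in_b], density_quantile, names = FALSE)
    core[in_b] <- core[in_b] & dens[in_b] >= floor_b
  }

  n_assigned <- sum(core)
  if (n_assigned == 0L) stop("no frames assigned to any core state")
  states <- lapply(seq_len(n_basin), function(b) {
    members <- which(core & basin == b)
    list(id = b, population = length(members) / n_assigned,
         members = members, n_members = length(members),
         peak = basin_peaks[[b]],
         components = which(basin_of == b))
  })
  states <- states[vapply(states, function(s) s$n_members, integer(1)) > 0L]
  ord <- order(-vapply(states, function(s) s$population, numeric(1)),
               vapply(states, function(s) s$peak[1], numeric(1)))
  states <- states[ord]
  for (i in seq_along(states)) states[[i]]$id <- i
  structure(states, class = "cc_states")
}

# Steepest ascent on the mixture density with backtracking line search.
ascend_density <- function(model, start, max_iter = 500L, tol = 1e-8) {
  x <- as.numeric(start)
  scale <- sqrt(mean(apply(model$means, 1L, stats::var))) + 1e-6
  step <- 0.1 * scale
  for (i in seq_len(max_iter)) {
    dg <- mixture_density(model, matrix(x, 1L), gradient = TRUE)
    g <- as.numeric(dg$gradient)
    gn <- vec_norm(g)
    if (gn * step < tol * max(dg$density, 1e-300)) break
    dir <- g / gn
    # backtracking: shrink until the density increases
    improved <- FALSE
    s <- step
    for (j in 1:30) {
      x_new <- x + s * dir
      if (mixture_density(model, matrix(x_new, 1L)) > dg$density) {
        x <- x_new
        step <- s * 1.5
        improved <- TRUE
        break
      }
      s <- s / 2
    }
    if (!improved) break
  }
  x
}

component_responsibilities <- function(model, X) {
  n <- nrow(X)
  num <- matrix(0, n, model$G)
  for (k in seq_len(model$G)) {
    mu <- model$means[, k]
    S <- model$covariances[, , k]
    Sinv <- solve(S)
    dx <- sweep(X, 2L, mu)
    q <- rowSums((dx %*% Sinv) * dx)
    num[, k] <- model$weights[k] * exp(-0.5 * q) / (2 * pi * sqrt(det(S)))
  }
  num / pmax(rowSums(num), .Machine$double.xmin)
}

#' @export
print.cc_states <- function(x, ...) {
  cat(sprintf("cc_states: %d metastable core state(s)\n", length(x)))
  for (s in x) {
    cat(sprintf(
      "  S%-2d population %5.1f%%  (%d frames)  peak (%.2f, %.2f)\n",
      s$id, 100 * s$population, s$n_members, s$peak[1], s$peak[2]))
  }
  invisible(x)
}

#' State populations as a named vector
#'
#' @param states a `cc_states`.
#' @return Named numeric vector of populations (fractions summing to 1).
#' @export
state_populations <- function(states) {
  stats::setNames(vapply(states, function(s) s$population, numeric(1)),
                  paste0("S", vapply(states, function(s) s$id, integer(1))))
}

#' Sample representative conformations from a core state
#'
#' Uniform draws with replacement from the state's member frames,
#' reproducible under the seed.
#'
#' @param state one element of a `cc_states`.
#' @param ensemble the `cc_ensemble` the features came from.
#' @param n number of conformations to draw (default 1000).
#' @param seed integer seed.
#' @return A `cc_ensemble` of the sampled conformations; the drawn frame
#'   indices are recorded in its provenance.
#' @export
sample_state_conformations <- function(state, ensemble, n = 1000L, seed = 1L) {
  if (length(state$members) < 1L) stop("state has no member frames")
  set.seed(seed)
  idx <- state$members[sample.int(length(state$members), n, replace = TRUE)]
  cc_ensemble(ensemble$atom, ensemble$coords[, , idx, drop = FALSE],
              provenance = list(source = "sample_state_conformations",
                                state = state$id, indices = idx, seed = seed))
}

#' Write core states to JSON
#'
#' @param states a `cc_states`.
#' @param path output JSON path.
#' @param max_members representative member indices written per state.
#' @return Invisibly, `path`.
#' @export
write_states <- function(states, path, max_members = 1000L) {
  out <- lapply(states, function(s) {
    list(id = s$id, population = s$population, n_members = s$n_members,
         peak = as.numeric(s$peak),
         representative_frames = utils::head(s$members, max_members))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Sampling-convergence check by subsampling
#'
#' Refits the density on a random fraction of the frames (1/50 by default)
#' and compares the resulting free-energy landscape and state populations
#' with the full-data result: Pearson correlation of free energy over the
#' basin region (grid nodes within `region_cap` of the free-energy minimum,
#' unmasked in both landscapes), and per-state population differences after
#' matching states by nearest basin peaks.
#'
#' @param features featurized frames.
#' @param fraction subsample fraction.
#' @param seed integer seed for the subsample.
#' @param component_range candidate component counts for both fits.
#' @param kT,n_grid,f_cap landscape parameters (see [evaluate_landscape()]).
#' @param region_cap free-energy ceiling (kcal/mol above the minimum) of the
#'   basin region over which the correlation is computed.
#' @return A list of class `cc_convergence`: `free_energy_correlation`,
#'   `populations_full`, `populations_subsample`, `population_differences`
#'   (matched), state counts and the subsample size.
#' @export
convergence_check <- function(features, fraction = 1 / 50, seed = 1L,
                              component_range = 1:10, kT = KT_293,
                              n_grid = 151L, f_cap = 6, region_cap = 3) {
  X <- feature_matrix(features)
  n <- nrow(X)
  if (n < 50L) stop("need at least 50 frames")
  set.seed(seed)
  m <- max(10L * max(component_range), round(n * fraction))
  idx <- if (fraction >= 1) seq_len(n) else sample.int(n, m)
  Xs <- X[idx, , drop = FALSE]

  fit_full <- fit_density(X, component_range, seed = seed)
  fit_sub <- if (fraction >= 1) fit_full else
    fit_density(Xs, component_range, seed = seed)

  land_full <- evaluate_landscape(fit_full, X, kT, n_grid, f_cap = f_cap)
  # common grid: evaluate the subsample model on the full-data grid
  nodes <- cbind(rep(land_full$x, times = n_grid),
                 rep(land_full$y, each = n_grid))
  p_sub <- mixture_density(fit_sub, nodes)
  fe_sub <- -kT * log(pmax(p_sub, .Machine$double.xmin))
  fe_sub <- fe_sub - min(fe_sub)
  fe_sub[fe_sub > f_cap] <- Inf
  fe_full <- as.vector(land_full$free_energy)
  ok <- is.finite(fe_full) & is.finite(fe_sub) & fe_full <= region_cap
  r <- stats::cor(fe_full[ok], fe_sub[ok])

  st_full <- extract_core_states(fit_full, X)
  st_sub <- extract_core_states(fit_sub, Xs)
  pop_full <- state_populations(st_full)
  pop_sub <- state_populations(st_sub)
  # match subsample states to full states by nearest peak
  pk_full <- t(vapply(st_full, function(s) s$peak, numeric(2)))
  pk_sub <- t(vapply(st_sub, function(s) s$peak, numeric(2)))
  match_idx <- apply(pk_sub, 1L, function(p) {
    which.min(sqrt(rowSums(sweep(pk_full, 2L, p)^2)))
  })
  diffs <- rep(NA_real_, length(st_full))
  for (j in seq_along(st_sub)) {
    i <- match_idx[j]
    diffs[i] <- pop_sub[j] - pop_full[i]
  }
  structure(
    list(free_energy_correlation = r, populations_full = pop_full,
         populations_subsample = pop_sub, population_differences = diffs,
         n_states_full = length(st_full), n_states_subsample = length(st_sub),
         subsample_size = length(idx)),
    class = "cc_convergence"
  )
}

#' @export
print.cc_convergence <- function(x, ...) {
  cat(sprintf(
    "convergence check: F correlation %.3f; %d vs %d states; max |dpop| %.3f\n",
    x$free_energy_correlation, x$n_states_full, x$n_states_subsample,
    max(abs(x$population_differences), na.rm = TRUE)))
  invisible(x)
}
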