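# Gaussian-mixture density estimation, free-energy landscape evaluation,
# metastable core-state extraction and the subsampling convergence check.

test_that("density fitting is parsimonious, accurate and deterministic", {
  # single isotropic Gaussian: component count stays small, mean recovered
  set.seed(1)
  X1 <- cbind(rnorm(5000, 1.5, 0.2), rnorm(5000, 2.5, 0.2))
  colnames(X1) <- c("rmsd_to_closed", "rmsd_to_open")
  fit1 <- fit_density(X1, component_range = 1:5, seed = 1L)
  expect_lte(fit1$G, 2L)
  mu <- rowSums(sweep(fit1$means, 2L, fit1$weights, "*"))
  se <- 0.2 / sqrt(5000)
  expect_lt(abs(mu[1] - 1.5), 3 * se + 1e-3)
  expect_lt(abs(mu[2] - 2.5), 3 * se + 1e-3)

  # two well-separated equal Gaussians: two components, equal weights
  X2 <- rgauss_mix(8000L, c(0.5, 0.5), list(c(1, 1), c(3, 3)), sd = 0.15,
                   seed = 2L)
  fit2 <- fit_density(X2, component_range = 1:4, seed = 2L)
  expect_equal(fit2$G, 2L)
  expect_equal(sort(fit2$weights), c(0.5, 0.5), tolerance = 0.04)

  # determinism under the seed
  fit2b <- fit_density(X2, component_range = 1:4, seed = 2L)
  expect_identical(fit2$means, fit2b$means)
  expect_identical(fit2$weights, fit2b$weights)

  expect_error(fit_density(X2[1:30, ], component_range = 1:4), "10x")
})

test_that("landscape grid is min-shifted, kT-linear, and finds analytic modes", {
  set.seed(3)
  X <- cbind(rnorm(5000, 1.5, 0.2), rnorm(5000, 2.5, 0.2))
  colnames(X) <- c("rmsd_to_closed", "rmsd_to_open")
  fit <- fit_density(X, 1:4, seed = 3L)
  land <- evaluate_landscape(fit, X)

  expect_equal(min(land$free_energy[is.finite(land$free_energy)]), 0)
  expect_equal(length(land$x), 151L)

  # analytic mode within one grid cell
  mode <- landscape_minimum(land)
  cell <- c(diff(land$x[1:2]), diff(land$y[1:2]))
  expect_lt(abs(mode[1] - 1.5), cell[1] + 3 * 0.2 / sqrt(5000))
  expect_lt(abs(mode[2] - 2.5), cell[2] + 3 * 0.2 / sqrt(5000))

  # doubling kT doubles the (shifted) free energy where both unmasked
  land2 <- evaluate_landscape(fit, X, kT = 2 * land$kT, f_cap = 12)
  ok <- is.finite(land$free_energy) & is.finite(land2$free_energy)
  expect_equal(land2$free_energy[ok], 2 * land$free_energy[ok],
               tolerance = 1e-9)

  # two equal basins have equal depth
  X2 <- rgauss_mix(10000L, c(0.5, 0.5), list(c(1, 1), c(3, 3)), sd = 0.15,
                   seed = 4L)
  fit2 <- fit_density(X2, 1:4, seed = 4L)
  land_2 <- evaluate_landscape(fit2, X2)
  st2 <- extract_core_states(fit2, X2)
  depths <- vapply(st2, function(s) {
    ix <- which.min(abs(land_2$x - s$peak[1]))
    iy <- which.min(abs(land_2$y - s$peak[2]))
    land_2$free_energy[ix, iy]
  }, numeric(1))
  expect_lt(abs(depths[1] - depths[2]), 0.1)

  # landscape is invariant under frame-order permutation
  set.seed(5)
  perm <- sample(nrow(X2))
  fitp <- fit_density(X2[perm, ], 1:4, seed = 4L)
  landp <- evaluate_landscape(fitp, X2[perm, ])
  okp <- is.finite(land_2$free_energy) & is.finite(landp$free_energy)
  expect_gt(cor(land_2$free_energy[okp], landp$free_energy[okp]), 0.999)
})

test_that("core states recover mixture structure and merge shared modes", {
  X <- fx_gauss3()
  fit <- fit_density(X, 1:6, seed = 7L)
  st <- extract_core_states(fit, X)
  expect_equal(length(st), 3L)
  pops <- sort(state_populations(st), decreasing = TRUE)
  expect_lt(max(abs(pops - c(0.60, 0.25, 0.15))), 0.03)
  expect_equal(sum(state_populations(st)), 1, tolerance = 1e-9)

  # two heavily overlapping components share one mode -> one core state
  Xov <- rgauss_mix(6000L, c(0.5, 0.5), list(c(2, 2), c(2.05, 2.05)),
                    sd = 0.25, seed = 8L)
  fit_ov <- fit_density(Xov, 2:3, seed = 8L)
  st_ov <- extract_core_states(fit_ov, Xov)
  expect_equal(length(st_ov), 1L)
  expect_equal(st_ov[[1]]$population, 1)
})

test_that("state conformation sampling is uniform-with-replacement and seeded", {
  ens <- fx_ensemble()
  st1 <- list(id = 1L, members = 5L, population = 1)
  reps <- sample_state_conformations(st1, ens, n = 3L, seed = 1L)
  expect_equal(n_frames(reps), 3L)
  for (f in 2:3) expect_identical(reps$coords[, , f], reps$coords[, , 1])

  st2 <- list(id = 2L, members = 1:250, population = 1)
  a <- sample_state_conformations(st2, ens, n = 100L, seed = 42L)
  b <- sample_state_conformations(st2, ens, n = 100L, seed = 42L)
  expect_identical(a$provenance$indices, b$provenance$indices)

  # multinomial sanity: no member index drawn implausibly often
  big <- sample_state_conformations(st2, ens, n = 1000L, seed = 7L)
  expect_lte(max(table(big$provenance$indices)), 13L)  # qpois(1 - 1e-3/250, 4)

  expect_error(sample_state_conformations(list(id = 3, members = integer(0)),
                                          ens, n = 2L), "no member")
})

test_that("subsampling convergence check reports high fidelity for iid data", {
  X <- fx_gauss3()
  cv <- convergence_check(X, fraction = 1 / 50, seed = 3L,
                          component_range = 1:6)
  expect_gt(cv$free_energy_correlation, 0.95)
  expect_equal(cv$n_states_full, cv$n_states_subsample)
  expect_lt(max(abs(cv$population_differences), na.rm = TRUE), 0.05)

  # fraction 1 compares the fit with itself
  cv1 <- convergence_check(X[1:2000, ], fraction = 1, seed = 3L,
                           component_range = 1:4)
  expect_equal(cv1$free_energy_correlation, 1)
})
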