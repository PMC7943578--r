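# Symmetry-aware conformational features: Kabsch superposition, joint
# backbone RMSD, and the minimum over the six cyclic chain-name topologies.

test_that("Kabsch superposition recovers rigid motions and excludes reflections", {
  set.seed(21)
  P <- matrix(rnorm(60), ncol = 3)

  s <- kabsch_superpose(P, P)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)

  Q <- random_rigid(P, seed = 22)
  s2 <- kabsch_superpose(P, Q)
  expect_lt(s2$rmsd, 1e-6)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-6)
  expect_equal(sweep(P %*% s2$rotation, 2, -s2$translation), Q,
               tolerance = 1e-6)

  # reflected target: the proper-rotation optimum cannot reach rmsd 0
  Qr <- P %*% diag(c(1, 1, -1))
  s3 <- kabsch_superpose(P, Qr)
  expect_equal(det(s3$rotation), 1, tolerance = 1e-6)
  expect_gt(s3$rmsd, 0.1)

  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "3 points")
  expect_error(kabsch_superpose(P[1:4, ], P[1:5, ]), "mismatch")
})

test_that("Kabsch rmsd equals a gradient-free numerical minimisation", {
  set.seed(33)
  P <- matrix(rnorm(12), ncol = 3)            # 4-point asymmetric set
  Q <- random_rigid(P, seed = 34) + matrix(rnorm(12, 0, 0.3), ncol = 3)
  got <- kabsch_superpose(P, Q)$rmsd

  # oracle: direct minimisation over axis-angle rotation + translation
  obj <- function(par) {
    th <- sqrt(sum(par[1:3]^2))
    R <- if (th < 1e-12) diag(3) else rot_axis_angle(par[1:3] / th, th)
    moved <- sweep(P %*% R, 2, -par[4:6])
    sqrt(mean(rowSums((moved - Q)^2)))
  }
  best <- Inf
  for (i in 1:8) {
    set.seed(i)
    o <- optim(c(rnorm(3), rnorm(3)), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(got, best, tolerance = 1e-4)
  expect_lte(got, best + 1e-6)                # Kabsch is the global optimum
})

test_that("backbone RMSD is symmetric, zero on identity, and matches bio3d", {
  open <- fx_open()
  closed <- fx_closed()
  expect_equal(backbone_rmsd(open, open), 0, tolerance = 1e-10)
  expect_equal(backbone_rmsd(open, closed), backbone_rmsd(closed, open),
               tolerance = 1e-6)

  # independent implementation: bio3d's fitted RMSD on the same atoms
  bb <- open$atom$name %in% c("N", "CA", "C", "O")
  oracle <- bio3d_fit_rmsd(open$xyz[bb, ], closed$xyz[bb, ])
  expect_equal(backbone_rmsd(open, closed), oracle, tolerance = 1e-4)
})

test_that("cyclic-topology minimisation undoes chain relabelling", {
  open <- fx_open()
  m0 <- min_rmsd_over_cyclic_topologies(open, open)
  expect_equal(m0$rmsd, 0, tolerance = 1e-8)
  expect_equal(m0$topology, 0L)

  # relabel the chains of an asymmetric frame cyclically by k: the naive
  # identity-map RMSD is large but topology k recovers zero (an exactly
  # symmetric structure would superpose back under any relabelling, so a
  # noisy frame is used)
  fr <- get_frame(fx_ensemble(), 2L)
  for (k in c(1L, 3L)) {
    lab <- LETTERS[1:6]
    new_lab <- lab[((seq_along(lab) - 1L + k) %% 6L) + 1L]  # old i -> new
    relab_atom <- fr$atom
    relab_atom$chain <- new_lab[match(fr$atom$chain, lab)]
    ord <- order(match(relab_atom$chain, lab))
    relabelled <- cc_structure(relab_atom[ord, ], fr$xyz[ord, ])
    naive <- backbone_rmsd(relabelled, fr)
    mk <- min_rmsd_over_cyclic_topologies(relabelled, fr)
    # the naive identity-map RMSD retains the relabelling artefact (for
    # k = 3 the frame is close to C2-symmetric, so the artefact is small
    # but still far above the recovered minimum)
    expect_gt(naive, 100 * mk$rmsd)
    expect_lt(mk$rmsd, 1e-6)
    expect_equal(mk$topology, (6L - k) %% 6L)  # undoes the relabelling
    expect_lte(mk$rmsd, naive)
  }

  five <- select_atoms(open, "not chain F")
  expect_error(min_rmsd_over_cyclic_topologies(five, open), "six chains")
})

test_that("featurize_ensemble matches per-frame brute force and endpoint identities", {
  open <- fx_open()
  closed <- fx_closed()
  ens <- fx_ensemble()
  feats <- fx_features()

  # endpoints: frame = open reference
  ends <- as_ensemble(list(open, closed))
  fe <- featurize_ensemble(ends, open, closed)
  d <- backbone_rmsd(open, closed)
  expect_equal(fe$rmsd_to_open, c(0, d), tolerance = 1e-6)
  expect_equal(fe$rmsd_to_closed, c(d, 0), tolerance = 1e-6)

  # oracle equivalence on 20 random frames: explicit 6-way brute force
  set.seed(44)
  pick <- sample(n_frames(ens), 20L)
  for (f in pick) {
    fr <- get_frame(ens, f)
    brute_c <- min_rmsd_over_cyclic_topologies(fr, closed)
    brute_o <- min_rmsd_over_cyclic_topologies(fr, open)
    expect_equal(feats$rmsd_to_closed[f], brute_c$rmsd, tolerance = 1e-9)
    expect_equal(feats$rmsd_to_open[f], brute_o$rmsd, tolerance = 1e-9)
    # the chosen topology achieves the minimum (symmetric references make
    # several topologies exactly degenerate, so indices may differ)
    maps <- barrelswitch:::cyclic_chain_maps(chains(fr), chains(closed))
    r_at <- backbone_rmsd(fr, closed,
                          chain_map = maps[[feats$topology_closed[f] + 1L]])
    expect_equal(r_at, brute_c$rmsd, tolerance = 1e-9)
  }

  # rigid-motion invariance of the features
  fr <- get_frame(ens, 1L)
  moved <- cc_structure(fr$atom, random_rigid(fr$xyz, seed = 5))
  m1 <- min_rmsd_over_cyclic_topologies(fr, open)
  m2 <- min_rmsd_over_cyclic_topologies(moved, open)
  expect_equal(m1$rmsd, m2$rmsd, tolerance = 1e-6)

  # generator coordinate ordering is recovered: larger lambda (more closed)
  # means smaller rmsd_to_closed
  truth <- ens$provenance$truth
  expect_lt(cor(truth$lambda, feats$rmsd_to_closed, method = "spearman"),
            -0.9)
})
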