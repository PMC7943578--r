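# Synthetic generator: open barrel symmetry, sandwich construction,
# mixture-of-states ensemble sampling, and binding-curve simulation.

test_that("open barrel has exact C6 symmetry and the declared geometry", {
  open <- fx_open()
  expect_equal(length(chains(open)), 6L)
  res_counts <- vapply(chains(open), function(ch)
    length(unique(open$atom$resno[open$atom$chain == ch])), integer(1))
  expect_true(all(res_counts == 28L))

  # rotating by 60 degrees and relabelling chains cyclically is a symmetry
  R60 <- rot_axis_angle(c(0, 0, 1), pi / 3)
  rotated <- cc_structure(open$atom, open$xyz %*% R60)
  m <- min_rmsd_over_cyclic_topologies(rotated, open)
  expect_lt(m$rmsd, 1e-8)

  # helix axes sit at the superhelix radius; adjacent spacing = radius
  ax <- fit_helix_axis(open, "A")
  expect_equal(sqrt(sum(ax$centroid[1:2]^2)), 8.5, tolerance = 0.2 / 8.5)
  sp <- neighbour_axis_spacing(open)
  expect_equal(unname(sp$mean), 8.5, tolerance = 0.01 / 8.5)
  expect_lt(max(abs(sp$distances - 8.5)), 0.01)

  # hydrophobic a/d faces point at the lumen: mean CB direction inward
  ad <- c(7, 14, 21, 28, 3, 10, 17, 24)   # a and d positions
  inward <- vapply(ad, function(r) {
    cb <- open$xyz[open$atom$resno == r & open$atom$name == "CB" &
                     open$atom$chain == "A", ]
    ca <- open$xyz[open$atom$resno == r & open$atom$name == "CA" &
                     open$atom$chain == "A", ]
    sum((cb - ca)[1:2] * ca[1:2])
  }, numeric(1))
  expect_lt(mean(inward), 0)
})

test_that("closed sandwich: rigid transforms, exact C2, collapsed lumen", {
  open <- fx_open()
  closed <- fx_closed()

  # zero shear reproduces the input
  zero <- shear_spec(chains(open), matrix(0, 6, 3))
  expect_equal(build_closed_sandwich(open, zero)$xyz, open$xyz)

  # a translation moves the chain centroid by exactly its magnitude
  tr <- matrix(0, 6, 3); tr[2, ] <- c(0, 6.98, 0)
  moved <- build_closed_sandwich(open, shear_spec(chains(open), tr))
  ch2 <- open$atom$chain == chains(open)[2]
  d <- colMeans(moved$xyz[ch2, ]) - colMeans(open$xyz[ch2, ])
  expect_equal(sqrt(sum(d^2)), 6.98, tolerance = 1e-9)

  # mismatched chain set rejected
  expect_error(build_closed_sandwich(open, shear_spec(LETTERS[7:12],
                                                      matrix(0, 6, 3))),
               "chains")

  # default shear admits a C2 axis: the 180-degree rotation about the
  # bundle axis maps the structure onto itself under a cyclic relabelling
  ctr <- colMeans(closed$xyz)
  flipped <- cc_structure(closed$atom,
                          sweep(sweep(closed$xyz, 2, ctr) %*%
                                  diag(c(-1, -1, 1)), 2, -ctr))
  expect_lt(min_rmsd_over_cyclic_topologies(closed, flipped)$rmsd, 0.5)

  # two three-helix sheets survive: in-sheet axis spacings stay within the
  # declared tolerance of the flattened-sheet construction
  axes <- helix_axes(closed)
  names(axes) <- vapply(axes, function(a) a$chain, character(1))
  for (sheet in attr(closed, "sheets")) {
    d12 <- sqrt(sum((axes[[sheet[1]]]$centroid - axes[[sheet[2]]]$centroid)^2))
    d23 <- sqrt(sum((axes[[sheet[2]]]$centroid - axes[[sheet[3]]]$centroid)^2))
    expect_lt(abs(d12 - d23), 1.0)      # even spacing within a sheet
    expect_gt(min(d12, d23), 8.0)       # no intra-sheet collapse
  }

  # the lumen is collapsed: no contiguous channel, unlike the open barrel
  expect_true(has_channel(channel_radius_profile(open)))
  expect_false(has_channel(channel_radius_profile(closed)))
})

test_that("ensemble sampling hits the endpoints, the weights, and is seeded", {
  open <- fx_open()
  closed <- fx_closed()

  at_open <- sample_ensemble(open, closed,
                             ensemble_spec(0, 1, spreads = 0, noise_sd = 0,
                                           n_frames = 2L, seed = 1L))
  fx0 <- featurize_ensemble(at_open, open, closed)
  expect_lt(max(fx0$rmsd_to_open), 1e-8)

  at_closed <- sample_ensemble(open, closed,
                               ensemble_spec(1, 1, spreads = 0, noise_sd = 0,
                                             n_frames = 2L, seed = 1L))
  fx1 <- featurize_ensemble(at_closed, open, closed)
  expect_lt(max(fx1$rmsd_to_closed), 1e-8)

  # two states, weights 0.6/0.4: cluster fractions within 3 binomial SE
  spec <- ensemble_spec(c(0.2, 0.8), c(0.6, 0.4), spreads = 0.02,
                        noise_sd = 0.1, n_frames = 5000L, seed = 5L)
  ens <- sample_ensemble(open, closed, spec)
  fx2 <- featurize_ensemble(ens, open, closed)
  lambda_hat <- fx2$rmsd_to_open / (fx2$rmsd_to_open + fx2$rmsd_to_closed)
  frac1 <- mean(lambda_hat < 0.5)
  se <- sqrt(0.6 * 0.4 / 5000)
  expect_lt(abs(frac1 - 0.6), 3 * se)

  # bit-reproducible under a fixed seed
  ens_a <- sample_ensemble(open, closed, paperlike_spec(50L, seed = 9L))
  ens_b <- sample_ensemble(open, closed, paperlike_spec(50L, seed = 9L))
  expect_identical(ens_a$coords, ens_b$coords)

  # features stay in the rectangle [0, d(open, closed)]^2 up to noise
  d <- backbone_rmsd(open, closed)
  noise_allow <- 3 * sqrt(3) * 0.25
  expect_lt(max(fx2$rmsd_to_open), d + noise_allow)
  expect_lt(max(fx2$rmsd_to_closed), d + noise_allow)

  expect_error(ensemble_spec(c(0.5, 0.5), c(0.6, 0.5)), "sum to 1")
})

test_that("simulated binding curves follow the tight-binding forward model", {
  x <- c(2.4, 4, 6.5, 10, 16, 25, 40, 60, 90, 120)
  noiseless <- simulate_binding_curve(kd = 0.23, bmax = 10, c = 0.1,
                                      x = c(0, x), noise_sd = 0)
  expect_equal(noiseless$y[1], 0)
  expect_true(all(diff(noiseless$y) >= 0))  # monotone titration

  sat <- simulate_binding_curve(0.23, 10, 0.1, x = c(0, 1000 * (0.23 + 0.1)),
                                noise_sd = 0)
  expect_equal(sat$y[2], 10, tolerance = 0.01)

  a <- simulate_binding_curve(0.23, 10, 0.1, x, noise_sd = 0.3, seed = 2L)
  b <- simulate_binding_curve(0.23, 10, 0.1, x, noise_sd = 0.3, seed = 2L)
  expect_identical(a$y, b$y)

  f <- withr::local_tempfile(fileext = ".csv")
  write_binding_curve(a, f)
  back <- read_binding_curve(f, c = 0.1)
  expect_equal(back$x, a$x)
  expect_equal(back$y, a$y)
})
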