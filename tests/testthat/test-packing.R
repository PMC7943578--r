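# Knobs-into-holes detection/classification and Shrake-Rupley SASA burial.

# Two parallel helices facing each other, axis separation `sep` along x.
two_helix_fixture <- function(sep = 9.5) {
  tpl <- barrelswitch:::build_helix_template(
    28L, rep(barrelswitch:::DEFAULT_HEPTAD, 4L))
  flip <- rot_axis_angle(c(0, 0, 1), pi)
  atom <- tpl$atom
  atom$occ <- 1; atom$element <- substr(atom$name, 1, 1)
  atom$element[atom$name == "SC"] <- "C"
  a <- atom; a$chain <- "A"
  b <- atom; b$chain <- "B"
  # A at x = 0 faces +x (flipped template); B at x = sep faces -x (default)
  xyz_a <- tpl$xyz %*% flip
  xyz_b <- sweep(tpl$xyz, 2L, c(-sep, 0, 0))
  ab <- rbind(a, b)
  ab$serial <- seq_len(nrow(ab))
  cc_structure(ab, rbind(xyz_a, xyz_b))
}

test_that("KIH detection obeys the SOCKET-style count rule", {
  # a single helix has no partner chain
  single <- select_atoms(fx_open(), "chain A")
  expect_equal(nrow(detect_kih(single)), 0L)

  pair <- two_helix_fixture(9.5)
  kih <- detect_kih(pair, cutoff = 7.0, register_offset = 1L)
  expect_gt(nrow(kih), 0L)
  expect_true(all(kih$knob_chain != kih$hole_chain))
  expect_setequal(unique(kih$knob_chain), c("A", "B"))
  # interface positions dominate the knob registers
  expect_true(all(kih$knob_register %in% c("a", "d", "e", "g")))
  expect_true(any(kih$knob_register %in% c("a", "d")))
  # glycine can never be a knob
  expect_false(any(kih$knob_resname == "GLY"))

  # hand-check the rule for every reported knob: >= 4 centroids of the hole
  # chain within the cutoff, and the hole is the 4 nearest
  cen <- side_chain_centroids(pair)
  for (i in seq_len(nrow(kih))) {
    kx <- cen[cen$chain == kih$knob_chain[i] & cen$resno == kih$knob_resno[i],
              c("x", "y", "z")]
    other <- cen[cen$chain == kih$hole_chain[i], ]
    d <- sqrt((other$x - kx$x)^2 + (other$y - kx$y)^2 + (other$z - kx$z)^2)
    expect_gte(sum(d <= 7.0), 4L)
    hole <- sort(other$resno[order(d)][1:4])
    expect_equal(hole, sort(c(kih$hole_resno1[i], kih$hole_resno2[i],
                              kih$hole_resno3[i], kih$hole_resno4[i])))
  }

  # far-apart helices interact with nothing
  expect_equal(nrow(detect_kih(two_helix_fixture(25))), 0L)

  # no side-chain representation -> actionable error
  bare <- select_atoms(fx_open(), "backbone")
  expect_error(detect_kih(bare), "side-chain")
})

test_that("KIH classes split into cyclic, non-cyclic and inter-sheet", {
  open <- fx_open()
  closed <- fx_closed()
  sheets <- list(c("F", "A", "B"), c("C", "D", "E"))

  kih_o <- classify_kih(detect_kih(open, register_offset = 1L), sheets,
                        structure = open)
  # the barrel's cyclic interactions come from a/d knobs into adjacent
  # chains, all in one rotational direction
  cyc <- kih_o[kih_o$class == "cyclic", ]
  expect_gt(nrow(cyc), 0L)
  expect_true(all(cyc$knob_register %in% c("a", "d")))
  ord <- barrelswitch:::cyclic_chain_order(open)
  step <- (match(cyc$hole_chain, ord) - match(cyc$knob_chain, ord)) %% 6L
  expect_equal(length(unique(step)), 1L)        # one consistent direction
  expect_equal(nrow(kih_o[kih_o$class == "inter-sheet", ]), 0L)

  kih_c <- classify_kih(detect_kih(closed, register_offset = 1L), sheets,
                        structure = closed)
  expect_gt(sum(kih_c$class == "inter-sheet"), 0L)
  # any non-a/d knob between adjacent chains is non-cyclic
  adj <- (match(kih_c$hole_chain, ord) - match(kih_c$knob_chain, ord)) %% 6L
  bc <- kih_c$knob_register %in% c("b", "c") & adj %in% c(1L, 5L)
  if (any(bc)) expect_true(all(kih_c$class[bc] == "non-cyclic"))

  expect_error(classify_kih(kih_c, list(c("A", "B"), c("C", "D")),
                            structure = closed), "partition")

  # the collapsed state gains interactions relative to the barrel
  cmp <- compare_kih_counts(open, closed)
  expect_equal(cmp$percent_difference,
               100 * (cmp$count_b - cmp$count_a) / cmp$count_a)
  expect_gt(cmp$percent_difference, 0)
  expect_equal(compare_kih_counts(open, open)$percent_difference, 0)

  # label-free: relabelling chains leaves the counts unchanged
  relab <- closed
  relab$atom$chain <- chartr("ABCDEF", "DEFABC", relab$atom$chain)
  expect_equal(nrow(detect_kih(relab)), nrow(detect_kih(closed)))
})

test_that("Shrake-Rupley SASA matches sphere analytics", {
  lone <- cc_structure(
    data.frame(serial = 1L, name = "C", resname = "UNK", chain = "A",
               resno = 1L, occ = 1, element = "C"),
    matrix(0, 1L, 3L))
  expect_equal(shrake_rupley_sasa(lone), 4 * pi * 3.1^2,
               tolerance = 0.01)

  # an atom enclosed by a tight shell of neighbours has zero SASA
  dirs <- rbind(diag(3), -diag(3),
                cbind(c(1, 1, 1, 1, -1, -1, -1, -1),
                      c(1, 1, -1, -1, 1, 1, -1, -1),
                      c(1, -1, 1, -1, 1, -1, 1, -1)) / sqrt(3))
  shell <- cc_structure(
    data.frame(serial = 1:15, name = "C", resname = "UNK", chain = "A",
               resno = 1:15, occ = 1, element = "C"),
    rbind(c(0, 0, 0), dirs * 1.0))
  expect_equal(shrake_rupley_sasa(shell, atoms = 1L), 0)

  # two identical atoms at vdW-sum separation: analytic spherical cap
  d <- 3.4; R <- 1.7 + 1.4
  duo <- cc_structure(
    data.frame(serial = 1:2, name = "C", resname = "UNK", chain = "A",
               resno = 1:2, occ = 1, element = "C"),
    rbind(c(0, 0, 0), c(d, 0, 0)))
  cap <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
  got <- shrake_rupley_sasa(duo)
  expect_equal(got[1], cap, tolerance = 0.02)
  expect_equal(got[2], cap, tolerance = 0.02)

  # per-atom SASA never exceeds the isolated-sphere area
  open <- fx_open()
  cb <- which(open$atom$resno == 13L & open$atom$name == "CB")
  vals <- shrake_rupley_sasa(open, atoms = cb)
  expect_true(all(vals <= 4 * pi * 3.1^2 + 1e-9))
  expect_true(all(vals >= 0))

  bad <- lone; bad$atom$element <- "Xx"
  expect_error(shrake_rupley_sasa(bad), "unknown element")
})

test_that("burial occupancy weights state fractions by population", {
  open <- fx_open()
  # one state of identical open-barrel frames: Ala-13 CB fully buried
  ens <- as_ensemble(list(open, open, open))
  one_state <- structure(list(
    list(id = 1L, population = 1, members = 1:3, n_members = 3L,
         peak = c(0, 0))), class = "cc_states")
  bur <- burial_occupancy(one_state, ens, resno = 13L, n_rep = 3L)
  expect_equal(bur$per_state$buried_fraction, 1)
  expect_equal(bur$weighted_buried, 1)
  expect_equal(bur$weighted_buried + bur$weighted_exposed, 1)

  # convexity: weighted fraction lies between the per-state extremes
  closed <- fx_closed()
  ens2 <- as_ensemble(list(open, open, closed, closed))
  two_states <- structure(list(
    list(id = 1L, population = 0.75, members = 1:2, n_members = 2L,
         peak = c(0, 0)),
    list(id = 2L, population = 0.25, members = 3:4, n_members = 2L,
         peak = c(0, 0))), class = "cc_states")
  bur2 <- burial_occupancy(two_states, ens2, resno = 13L, n_rep = 2L)
  fr <- bur2$per_state$buried_fraction
  expect_gte(bur2$weighted_buried, min(fr) - 1e-12)
  expect_lte(bur2$weighted_buried, max(fr) + 1e-12)
  expect_equal(bur2$weighted_buried, sum(c(0.75, 0.25) * fr))

  expect_error(burial_occupancy(one_state, ens, resno = 99L), "CB")
})
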