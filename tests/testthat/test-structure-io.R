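# Multi-model PDB I/O, atom selection and heptad-register assignment.

test_that("PDB write/read round-trip preserves topology and coordinates", {
  open <- fx_open()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(open, f)

  lines <- readLines(f)
  expect_false(any(grepl("^MODEL", lines)))  # single implicit model
  expect_equal(sum(lines == "TER"), length(chains(open)))

  back <- read_pdb(f)
  expect_equal(n_frames(back), 1L)
  s <- get_frame(back, 1L)
  expect_identical(chains(s), chains(open))
  expect_identical(s$atom$resno, open$atom$resno)
  expect_identical(s$atom$name, open$atom$name)
  expect_equal(s$xyz, open$xyz, tolerance = 1e-3)
  expect_lt(max(abs(s$xyz - open$xyz)), 1e-3 + 1e-9)
})

test_that("multi-model ensembles round-trip with MODEL/ENDMDL records", {
  ens <- sample_ensemble(fx_open(), fx_closed(),
                         ensemble_spec(centers = 0.5, weights = 1,
                                       spreads = 0.05, noise_sd = 0.1,
                                       n_frames = 3L, seed = 4L))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^MODEL", lines)), 3L)
  expect_equal(sum(grepl("^ENDMDL", lines)), 3L)
  back <- read_pdb(f, models = "all")
  expect_equal(n_frames(back), 3L)
  expect_equal(back$coords, ens$coords, tolerance = 1e-3)
  expect_equal(n_frames(read_pdb(f, models = "single")), 1L)
})

test_that("malformed ATOM lines are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(fx_open(), f)
  lines <- readLines(f)
  lines[5] <- paste0(substr(lines[5], 1, 30), " garbage coordinates      ")
  writeLines(lines, f)
  expect_error(read_pdb(f), "line 5")
})

test_that("HETATM records are dropped and altlocs reduced to top occupancy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.600   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  0.00  0.00           O",
    "HETATM    6  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "TER",
    "END"), f)
  s <- get_frame(read_pdb(f), 1L)
  expect_equal(n_atoms(s), 4L)                       # HETATM dropped
  ca <- s$xyz[s$atom$name == "CA", ]
  expect_equal(ca[1], 1.600)                          # occupancy 0.6 wins
  expect_true(any(s$atom$occ == 0))                   # zero-occ retained
  expect_equal(n_atoms(select_atoms(s, "occ > 0")), 3L)
})

test_that("selection language selects, partitions, and is idempotent", {
  open <- fx_open()
  bbA <- select_atoms(open, "backbone and chain A")
  expect_equal(n_atoms(bbA), 28L * 4L)

  # partition: chain A plus its complement restores the atom count
  a <- select_atoms(open, "chain A")
  not_a <- select_atoms(open, "not chain A")
  expect_equal(n_atoms(a) + n_atoms(not_a), n_atoms(open))

  # idempotence
  twice <- select_atoms(select_atoms(open, "backbone"), "backbone")
  expect_identical(twice$atom, select_atoms(open, "backbone")$atom)

  # empty selection allowed: no Ala CB in an all-Gly chain
  gly <- build_open_barrel(crick_params(sequence = rep("GLY", 28)))
  expect_equal(n_atoms(select_atoms(gly, "name CB and resname ALA")), 0L)

  # selection distributes over ensemble frames
  ens <- fx_ensemble()
  sub <- select_atoms(ens, "name CA and resno 13")
  expect_equal(dim(sub$coords), c(6L, 3L, n_frames(ens)))

  expect_error(select_atoms(open, "flavour strange"), "selection error")
  expect_error(select_atoms(open, "chain A and"), "selection error")
})

test_that("heptad register is cyclic, balanced, offset-controlled and rigid-motion invariant", {
  open <- fx_open()
  reg <- assign_register(open, register_offset = 1L)

  # residue 13 is the g-site Ala; the g letter recurs with period 7
  expect_equal(register_of(reg, "A", 13L), "g")
  expect_equal(register_of(reg, "A", 6L), "g")
  expect_equal(register_of(reg, "A", 20L), "g")
  expect_equal(register_of(reg, "A", 27L), "g")
  # the Gly positions sit at e sites
  gly_res <- unique(reg$resno[reg$resname == "GLY"])
  expect_true(all(reg$register[reg$resno %in% gly_res] == "e"))

  # balanced letter counts: ceiling(28/7) = 4 of each per chain
  counts <- table(reg$register[reg$chain == "A"])
  expect_true(all(counts %in% c(floor(28 / 7), ceiling(28 / 7))))

  # invariance to rigid motion of the coordinates
  moved <- cc_structure(open$atom, random_rigid(open$xyz, seed = 3))
  reg2 <- assign_register(moved, register_offset = 1L)
  expect_identical(reg$register, reg2$register)

  expect_error(assign_register(open, 7L), "0..6")
})
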