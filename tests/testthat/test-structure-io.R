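test_that("PDB fixture parses to one model, one chain, three residues", {
  st <- read_structure(fixture_path("minimal_3res.pdb"))
  expect_s3_class(st, "fod_structure")
  expect_equal(st$n_models, 1)
  expect_equal(unique(st$atoms$chain), "A")
  expect_true(any(st$atoms$hydrogen))          # hydrogens kept but flagged
  rec <- effective_atoms(st)
  expect_equal(nrow(rec), 3)                   # HOH excluded
  expect_equal(rec$aa, c("G", "A", "S"))
})

test_that("effective atom is the heavy-atom mean; altloc by occupancy", {
  rec <- effective_atoms(read_structure(fixture_path("minimal_3res.pdb")))
  # glycine: 4 heavy atoms at the corners of a square, hydrogen ignored
  expect_equal(unlist(rec[1, c("x", "y", "z")], use.names = FALSE),
               c(1, 1, 0))
  # alanine: shared N plus the occupancy-0.6 altloc A CA only
  expect_equal(rec$x[2], (3.8 + 4.8) / 2)
  expect_equal(rec$x[3], 7.6)
})

test_that("mmCIF dialect is sniffed and agrees with the PDB twin", {
  stc <- read_structure(fixture_path("minimal_3res.cif"), format = "auto")
  expect_equal(stc$format, "mmcif")
  rec_cif <- effective_atoms(stc)
  rec_pdb <- effective_atoms(read_structure(fixture_path("minimal_3res.pdb")))
  expect_equal(rec_cif[, c("chain_id", "seq_id", "aa", "x", "y", "z")],
               rec_pdb[, c("chain_id", "seq_id", "aa", "x", "y", "z")])
})

test_that("unreadable or empty input gives a parse error", {
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("not a structure at all", bad)
  expect_error(read_structure(bad), "format|parse")
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")),
               "not found")
})

test_that("multi-model files expose each model's coordinates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(path)
  st <- read_structure(path)
  expect_equal(st$n_models, 2)
  r1 <- effective_atoms(st, model = 1)
  r2 <- effective_atoms(st, model = 2)
  expect_equal(r2$x, r1$x + 10)                 # model 2 shifted in x
  expect_equal(r2$aa, r1$aa)
  expect_error(effective_atoms(st, model = 3), "not present")
})

test_that("effective atoms are invariant to atom order within a residue", {
  p1 <- fixture_path("minimal_3res.pdb")
  lines <- readLines(p1)
  gly <- grep("GLY", lines)
  shuffled <- lines
  shuffled[gly] <- lines[rev(gly)]
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(shuffled, p2)
  expect_equal(effective_atoms(read_structure(p2))[, c("x", "y", "z")],
               effective_atoms(read_structure(p1))[, c("x", "y", "z")])
})

test_that("select_unit applies inclusive author-numbered ranges", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(path)
  rec <- effective_atoms(read_structure(path))
  u <- select_unit(rec, chains = "A", range = c(2, 4), level = "chain")
  expect_equal(length(u), 3)
  expect_equal(u$residues$seq_id, 2:4)
  full <- select_unit(rec, chains = "A", level = "chain")
  expect_equal(length(full), 4)
})

test_that("select_unit is idempotent and validates its inputs", {
  rec <- effective_atoms(read_structure(fixture_path("minimal_3res.pdb")))
  u1 <- select_unit(rec, chains = "A", range = c(1, 3), level = "chain")
  u2 <- select_unit(u1$residues, chains = "A", range = c(1, 3),
                    level = "chain")
  expect_equal(u1$residues, u2$residues)
  expect_error(select_unit(rec, chains = "Z", level = "chain"),
               "available")
  expect_error(select_unit(rec, chains = "A", range = c(200, 300),
                           level = "chain"), "empty selection")
  expect_error(select_unit(rec, chains = "A", range = c(3, 1),
                           level = "chain"), "start <= end")
})

test_that("multi-chain selections concatenate chains in the given order", {
  u <- generate_unit(synthetic_spec("micelle", n_residues = 12,
                                    n_chains = 3, geometry = "ribbon_stack",
                                    seed = 5))
  rec <- u$residues
  proto <- select_unit(rec, chains = c("C", "A"), level = "proto-fibril")
  expect_equal(unique(proto$residues$chain_id), c("C", "A"))
  expect_equal(length(proto), 24)
  expect_equal(proto$level, "proto-fibril")
})

test_that("units written as pseudo-atom PDB round-trip their sequence", {
  u <- generate_unit(synthetic_spec("micelle", n_residues = 20, seed = 9))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_unit_pdb(u, path)
  rec <- effective_atoms(read_structure(path))
  expect_equal(rec$aa, u$residues$aa)
  expect_equal(rec$seq_id, u$residues$seq_id)
  expect_equal(rec$x, u$residues$x, tolerance = 1e-3)  # 3-decimal PDB field
})
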