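test_that("generate_macrocycle: plans, validation, determinism", {
  # undecorated ring is cyclododecane
  g <- generate_macrocycle(macrocycle_spec(12), "bare")
  expect_true(mol_isomorphic(g$mol, parse_smiles("C1CCCCCCCCCCC1")))
  expect_equal(g$truth$N, 12L)
  expect_equal(nrow(g$truth$peripheral_atoms), 0L)
  # hexapeptide-like ring reproduces the hand-derived values
  g2 <- generate_macrocycle(macrocycle_spec(18, amide_at = c(1, 4, 7, 10, 13, 16)))
  expect_equal(g2$truth$ring_het_over_N, 1 / 3, tolerance = 1e-12)
  expect_equal(g2$truth$peptide_index, 1)
  expect_true(mol_isomorphic(
    g2$mol,
    parse_smiles("O=C1CNC(=O)CNC(=O)CNC(=O)CNC(=O)CNC(=O)CN1")))
  # same spec twice -> identical SMILES
  sp <- macrocycle_spec(14, ring_o = 3, peripheral = list(`5` = "methyl"),
                        substituents = list(list(position = 8, kind = "chain",
                                                 size = 3)))
  expect_identical(generate_macrocycle(sp)$smiles,
                   generate_macrocycle(sp)$smiles)
  # unsatisfiable plans name the violated constraint
  expect_error(macrocycle_spec(10), "ring_size")
  expect_error(macrocycle_spec(12, ring_o = 1, amide_at = 1), "already used")
  expect_error(macrocycle_spec(12, peripheral = list(`1` = "methyl"),
                               substituents = list(list(position = 1,
                                                        kind = "phenyl"))),
               "two decorations")
})

test_that("generate_library profiles, determinism and error paths", {
  expect_error(generate_library(0, "oral-like"), "n must be")
  a <- generate_library(6, "oral-like", seed = 3)
  b <- generate_library(6, "oral-like", seed = 3)
  expect_identical(a$smiles, b$smiles)
  expect_equal(nrow(a$truth_table), 6L)
  # generated structures parse and are macrocycles
  for (s in a$smiles) {
    m <- parse_smiles(s)
    expect_gte(length(largest_ring(m)), 11L)
  }
})

test_that("oral-like libraries sit inside, sparse outside, the key ranges", {
  oral <- generate_library(25, "oral-like", seed = 61)
  dmo <- descriptor_matrix(oral$mols)
  vo <- violation_report(dmo$matrix)$violations
  expect_gte(mean(vo <= 4), 0.8)
  sparse <- generate_library(25, "sparse", seed = 62)
  dms <- descriptor_matrix(sparse$mols)
  vs <- violation_report(dms$matrix)$violations
  expect_gt(stats::median(vs), 4)
})

test_that("write_library emits SMILES + truth CSV that re-read cleanly", {
  lib <- generate_library(4, "kinase-like", seed = 8)
  smi <- withr::local_tempfile(fileext = ".smi")
  tru <- withr::local_tempfile(fileext = ".csv")
  write_library(lib, smi, tru)
  mols <- read_structures(smi)
  expect_length(mols, 4L)
  tt <- read.csv(tru)
  expect_equal(tt$id, vapply(lib$mols, `[[`, "", "id"))
  for (i in seq_along(mols))
    expect_true(mol_isomorphic(mols[[i]], lib$mols[[i]]))
})
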