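test_that("read_structures parses SMILES files, skips bad lines, strips salts", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("C1CCCCCCCCCCC1 cdd1",
               "CC(=O)NC1CCCCCCCCCC1O amide1",
               "not_a_smiles$$ bad1",
               "C1CCCCCCCCCCC1.[Na+] salt1"), f)
  mols <- suppressMessages(read_structures(f))
  expect_length(mols, 3L)
  expect_equal(mols[[1]]$id, "cdd1")
  expect_equal(nrow(mols[[1]]$atoms), 12L)
  # salt stripped to largest covalent component
  expect_equal(nrow(mols[[3]]$atoms), 12L)
})

test_that("missing file and empty set raise typed errors", {
  expect_error(read_structures("no/such/file.smi"),
               class = "mcspace_input_error")
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines("garbage((", f)
  expect_error(suppressMessages(read_structures(f)),
               class = "mcspace_empty_set")
})

test_that("duplicate ids are suffixed, never dropped", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("C1CCCCCCCCCCC1 dup", "C1CCCCCCCCCCCC1 dup"), f)
  mols <- suppressMessages(read_structures(f))
  expect_setequal(vapply(mols, `[[`, "", "id"), c("dup_1", "dup_2"))
})

test_that("SDF V2000 records are read with ids from the title line", {
  f <- withr::local_tempfile(fileext = ".sdf")
  blk <- function(id) c(
    id, "  mcspace", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    0.0000    0.0000    0.0000 O   0  0",
    "  1  2  1  0", "  2  3  1  0",
    "M  END", "$$$$")
  writeLines(c(blk("ethanol_a"), blk("ethanol_b")), f)
  mols <- read_structures(f, format = "sdf")
  expect_length(mols, 2L)
  expect_equal(vapply(mols, `[[`, "", "id"), c("ethanol_a", "ethanol_b"))
  expect_equal(mols[[1]]$atoms$element, c("C", "C", "O"))
})

test_that("SMILES round trips preserve the labelled graph", {
  for (s in roundtrip_smiles) {
    m <- parse_smiles(s)
    m2 <- parse_smiles(write_smiles(m))
    expect_true(mol_isomorphic(m, m2), label = s)
  }
})

test_that("filter_macrocycles keeps >= threshold rings and is idempotent", {
  mols <- list(parse_smiles("C1CCCCCCCCCCC1", id = "c12"),
               parse_smiles("c1ccccc1", id = "benzene"),
               parse_smiles("C1CCCCCCCCC1", id = "c10"),
               parse_smiles("C1CCCCCCCCCC1", id = "c11"))
  rep <- filter_macrocycles(mols)
  expect_setequal(rep$kept, c("c12", "c11"))
  expect_equal(sort(rep$excluded$id), c("benzene", "c10"))
  expect_match(rep$excluded$reason[rep$excluded$id == "benzene"],
               "largest ring 6 < 11")
  # cyclodecane excluded at the default threshold
  expect_true("c10" %in% rep$excluded$id)
  # idempotence
  rep2 <- filter_macrocycles(rep$records)
  expect_setequal(rep2$kept, rep$kept)
  expect_equal(nrow(rep2$excluded), 0L)
  # threshold is configuration
  expect_true("c10" %in% filter_macrocycles(mols, min_ring_size = 10L)$kept)
  # partition: kept + excluded = input
  expect_setequal(c(rep$kept, rep$excluded$id),
                  vapply(mols, `[[`, "", "id"))
})

test_that("filter report CSV round trips", {
  mols <- list(parse_smiles("C1CCCCCCCCCCC1", id = "a"),
               parse_smiles("c1ccccc1", id = "b"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_filter_report(filter_macrocycles(mols), f)
  df <- read.csv(f)
  expect_setequal(df$id, c("a", "b"))
  expect_equal(df$status[df$id == "a"], "kept")
})
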