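test_that("registry manifest has the documented composition", {
  man <- registry_manifest()
  expect_equal(nrow(man), 90L)
  expect_equal(sum(man$origin == "novel"), 46L)
  expect_equal(sum(man$origin == "guideline"), 12L)
  expect_equal(sum(man$origin == "classic"), 32L)
  expect_false(any(duplicated(man$mold_id)))
  expect_equal(sort(man$mold_id), 1:90)
  expect_equal(sort(man$name[man$scaling_kind == "continuous"]),
               c("CLogP", "MW", "tPSA"))
  # every key-property id resolves to a registered formula
  key <- oral_mc_ranges()
  expect_true(all(key$mold_id %in% man$mold_id))
  expect_equal(man$name[match(key$mold_id, man$mold_id)], key$name)
})

test_that("worked examples: cyclododecane and the cyclic hexapeptide", {
  dv <- compute_descriptor_vector(parse_smiles("C1CCCCCCCCCCC1", id = "cdd"))
  v <- dv$values
  expect_equal(v[["mold_22"]], 0)   # RingHet/N
  expect_equal(v[["mold_82"]], 0)   # restricted fraction
  expect_equal(v[["mold_38"]], 0)   # peripheral HA
  expect_equal(v[["mold_35"]], 0)   # spiro rings
  expect_true(64 %in% dv$exceptions$mold_id)  # no substituent carbons

  chg <- parse_smiles("O=C1CNC(=O)CNC(=O)CNC(=O)CNC(=O)CNC(=O)CN1", "chg")
  v2 <- compute_descriptor_vector(chg)$values
  expect_equal(v2[["mold_22"]], 1 / 3, tolerance = 1e-12)
  expect_equal(v2[["mold_82"]], 1 / 3, tolerance = 1e-12)
  expect_equal(v2[["mold_89"]], 1)    # peptide character index
  expect_equal(v2[["mold_46"]], 1)    # all peripheral atoms are carbonyl O
  expect_equal(v2[["mold_16"]], 1 / 7)

  # N=14 ring with gaps {2,1,4,3}
  spec <- macrocycle_spec(14, substituents = list(
    list(position = 1, kind = "chain", size = 2),
    list(position = 4, kind = "chain", size = 2),
    list(position = 6, kind = "chain", size = 2),
    list(position = 11, kind = "chain", size = 2)))
  v3 <- compute_descriptor_vector(generate_macrocycle(spec)$mol)$values
  expect_equal(v3[["mold_76"]], 4 / 14, tolerance = 1e-12)
  expect_equal(v3[["mold_77"]], 1 / 14, tolerance = 1e-12)
})

test_that("ratio bounds and normalization consistency on generated molecules", {
  lib <- generate_library(25, "random", seed = 5)
  ratio_ids <- paste0("mold_", c(9, 22, 46, 49, 50, 64, 66, 76, 77, 78, 79,
                                 82, 85, 87, 89, 90))
  for (mol in lib$mols) {
    v <- compute_descriptor_vector(mol)$values
    for (id in ratio_ids) {
      expect_gte(v[[id]], 0)
      expect_lte(v[[id]], 1)
    }
    expect_gt(v[["mold_16"]], 0)
    # normalized gap descriptors are their raw counterpart over N
    N <- v[["mold_37"]]
    expect_equal(v[["mold_76"]] * N, v[["mold_72"]], tolerance = 1e-9)
    expect_equal(v[["mold_77"]] * N, v[["mold_73"]], tolerance = 1e-9)
    expect_equal(v[["mold_78"]] * N, v[["mold_74"]], tolerance = 1e-9)
    expect_equal(v[["mold_79"]] * N, v[["mold_75"]], tolerance = 1e-9)
  }
})

test_that("identical structures give identical vectors (determinism)", {
  a <- compute_descriptor_vector(parse_smiles("CCC1CCCCCCCCOC1C", "a"))
  b <- compute_descriptor_vector(parse_smiles("CCC1CCCCCCCCOC1C", "b"))
  expect_equal(a$values, b$values)
  # and via a SMILES round trip
  m <- generate_library(3, "oral-like", seed = 2)$mols[[1]]
  m2 <- parse_smiles(write_smiles(m))
  expect_equal(unname(compute_descriptor_vector(m)$values),
               unname(compute_descriptor_vector(m2)$values),
               tolerance = 1e-12)
})

test_that("generator ground truth matches the mandatory descriptors", {
  lib <- generate_library(20, "oral-like", seed = 31)
  for (i in seq_along(lib$mols)) {
    tr <- lib$truth[[i]]
    v <- compute_descriptor_vector(lib$mols[[i]])$values
    expect_equal(v[["mold_22"]], tr$ring_het_over_N, tolerance = 1e-12)
    expect_equal(v[["mold_89"]], tr$peptide_index, tolerance = 1e-12)
    expect_equal(v[["mold_82"]], tr$restricted_fraction, tolerance = 1e-12)
    expect_equal(v[["mold_35"]], tr$spiro_rings)
    expect_equal(v[["mold_58"]], tr$periph_O)
    expect_equal(v[["mold_38"]], tr$periph_HA)
    expect_equal(v[["mold_64"]], tr$subst_fsp3, tolerance = 1e-12)
    expect_equal(v[["mold_72"]], tr$max_gap)
    expect_equal(v[["mold_73"]], tr$min_gap)
    expect_equal(v[["mold_75"]], tr$stdev_gap, tolerance = 1e-12)
  }
})

test_that("NRB excludes macrocycle ring sigma bonds but counts substituents", {
  # bare ring: 0 rotatable
  expect_equal(compute_descriptor_vector(
    parse_smiles("C1CCCCCCCCCCC1"))$values[["mold_5"]], 0)
  # propyl substituent: 2 rotatable bonds (attachment + chain interior)
  v <- compute_descriptor_vector(parse_smiles("CCCC1CCCCCCCCCCC1"))$values
  expect_equal(v[["mold_5"]], 2)
})

test_that("multifusion exception policy excludes flagged compounds", {
  at <- data.frame(element = rep("C", 19))
  b <- data.frame(a1 = c(1:12,  1, 2, 13, 14, 15, 3, 17, 18, 19),
                  a2 = c(2:12, 1, 16, 13, 14, 15, 16, 17, 18, 19, 13),
                  order = 1)
  peri <- mc_mol(at, b, id = "peri")
  plain <- parse_smiles("C1CCCCCCCCCCC1", id = "plain")
  dm <- descriptor_matrix(list(peri, plain),
                          multifusion_policy = "exception")
  expect_equal(dm$ids, "plain")
  expect_true("peri" %in% dm$excluded)
  dm2 <- descriptor_matrix(list(peri, plain), multifusion_policy = "merge")
  expect_setequal(dm2$ids, c("peri", "plain"))
})
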