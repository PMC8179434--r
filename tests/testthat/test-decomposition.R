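test_that("find_mc_ring returns the macrocycle, with typed failures", {
  expect_length(find_mc_ring(parse_smiles("C1CCCCCCCCCCC1"), 11L), 12L)
  expect_error(find_mc_ring(parse_smiles("C1CCCC1"), 11L),
               class = "mcspace_no_macrocycle")
  # ortho-fused benzene: the 12-ring wins over both the 6-ring and the
  # envelope cycle (hand-labelled construction)
  g <- generate_macrocycle(macrocycle_spec(
    12, substituents = list(list(position = 1, kind = "fused"))), "bf")
  ring <- find_mc_ring(g$mol, 11L)
  expect_length(ring, 12L)
  expect_setequal(ring, 1:12)
  # bridged macrocycle absent from the minimal basis is still found
  at <- data.frame(element = rep("C", 15))
  b <- data.frame(a1 = c(1:12, 1, 13, 14), a2 = c(2:12, 1, 13, 14, 6),
                  order = 1)
  expect_length(find_mc_ring(mc_mol(at, b), 11L), 12L)
})

test_that("cycle enumeration respects its node budget", {
  # peri-fused system forces enumeration; a tiny budget must raise the
  # typed complexity condition rather than stall
  at <- data.frame(element = rep("C", 19))
  b <- data.frame(a1 = c(1:12,  1, 2, 13, 14, 15, 3, 17, 18, 19),
                  a2 = c(2:12, 1, 16, 13, 14, 15, 16, 17, 18, 19, 13),
                  order = 1)
  m <- mc_mol(at, b)
  expect_error(enumerate_simple_cycles(m, 1:19, budget = 10L),
               class = "mcspace_complexity")
  expect_silent(invisible(largest_ring(m)))
})

test_that("classify_atoms implements the positional classes", {
  # hydroxyl -> peripheral O
  d <- decompose(parse_smiles("OC1CCCCCCCCCCC1"))
  expect_equal(nrow(d$peripheral), 1L)
  expect_equal(d$peripheral$element, "O")
  expect_length(d$substituents, 0L)
  # lactone: carbonyl O peripheral, ring O a ring atom
  d2 <- decompose(parse_smiles("O=C1CCCCCCCCCCO1"))
  expect_equal(d2$N, 12L)
  expect_equal(nrow(d2$peripheral), 1L)
  expect_equal(d2$peripheral$bond_order, 2L)
  # ethyl: one 2-atom substituent, no peripheral
  d3 <- decompose(parse_smiles("CCC1CCCCCCCCCCC1"))
  expect_length(d3$substituents, 1L)
  expect_length(d3$substituents[[1]]$atoms, 2L)
  expect_equal(nrow(d3$peripheral), 0L)
})

test_that("fused / spiro / multifusion flags", {
  fused <- decompose(parse_smiles("C1CCCCCCCCCc2ccccc2C1"))
  expect_true(fused$substituents[[1]]$fused)
  expect_false(fused$substituents[[1]]$spiro)
  expect_false(fused$multifusion)

  spiro <- decompose(parse_smiles("C1CCCC2(CCCCC2)CCCCCCC1"))
  expect_true(spiro$substituents[[1]]$spiro)
  expect_false(spiro$substituents[[1]]$fused)
  expect_false(spiro$multifusion)
  expect_equal(detect_multifusion(spiro)$action, "none")

  # two mutually fused six-membered rings, both fused to the MC ring
  at <- data.frame(element = rep("C", 19))
  b <- data.frame(a1 = c(1:12,  1, 2, 13, 14, 15, 3, 17, 18, 19),
                  a2 = c(2:12, 1, 16, 13, 14, 15, 16, 17, 18, 19, 13),
                  order = 1)
  peri <- decompose(mc_mol(at, b))
  expect_true(peri$multifusion)
  expect_equal(detect_multifusion(peri, "exception")$action, "exception")
  expect_equal(detect_multifusion(peri, "merge")$action, "merged")
})

test_that("compute_gaps follows the stated conventions", {
  # N=14, attachments at ring positions 1,4,6,11 -> gaps {2,1,4,3}
  spec <- macrocycle_spec(14, substituents = list(
    list(position = 1, kind = "chain", size = 2),
    list(position = 4, kind = "chain", size = 2),
    list(position = 6, kind = "chain", size = 2),
    list(position = 11, kind = "chain", size = 2)))
  g <- compute_gaps(decompose(generate_macrocycle(spec)$mol))
  expect_setequal(g$gaps, c(2L, 1L, 4L, 3L))
  expect_equal(g$max_gap, 4)
  expect_equal(g$min_gap, 1)
  expect_equal(g$mean_gap, 2.5)
  expect_equal(sum(g$gaps) + length(g$attachment_points), 14L)
  # one substituent -> single gap N-1
  one <- compute_gaps(decompose(parse_smiles("CCC1CCCCCCCCCCC1")))
  expect_equal(one$gaps, 11L)
  # no substituents -> (N, N, N, 0); peripheral groups are not delimiters
  none <- compute_gaps(decompose(parse_smiles("OC1CCCCCCCCCCC1")))
  expect_equal(c(none$max_gap, none$min_gap, none$mean_gap, none$stdev_gap),
               c(12, 12, 12, 0))
  # optional peripheral-inclusive mode does count them
  with_p <- compute_gaps(decompose(parse_smiles("OC1CCCCCCCCCCC1")),
                         include_peripheral = TRUE)
  expect_equal(with_p$gaps, 11L)
})

test_that("restricted_fraction counts pi, amide and fusion bonds", {
  expect_equal(restricted_fraction(
    d <- decompose(m <- parse_smiles("C1CCCCCCCCCCC1")), m), 0)
  m2 <- parse_smiles("C1CCCCCCCCCC=C1")
  expect_equal(restricted_fraction(decompose(m2), m2), 1 / 12)
  chg <- parse_smiles("O=C1CNC(=O)CNC(=O)CNC(=O)CNC(=O)CNC(=O)CN1")
  expect_equal(restricted_fraction(decompose(chg), chg), 6 / 18)
  # fused benzene contributes its shared (aromatic) bond once
  bf <- generate_macrocycle(macrocycle_spec(
    12, substituents = list(list(position = 1, kind = "fused"))))$mol
  expect_equal(restricted_fraction(decompose(bf), bf), 1 / 12)
})

test_that("partition completeness and gap conservation hold on generated sets", {
  lib <- generate_library(40, "random", seed = 99)
  for (i in seq_along(lib$mols)) {
    mol <- lib$mols[[i]]
    d <- decompose(mol)
    n_sub <- sum(vapply(d$substituents, function(s) length(s$atoms), 1L))
    expect_equal(d$N + nrow(d$peripheral) + n_sub, nrow(mol$atoms),
                 label = lib$smiles[i])
    g <- compute_gaps(d)
    if (length(g$attachment_points) >= 1L)
      expect_equal(sum(g$gaps) + length(g$attachment_points), d$N)
    rf <- restricted_fraction(d, mol)
    expect_gte(rf, 0); expect_lte(rf, 1)
  }
})

test_that("decomposition JSON export is well-formed and 0-based", {
  d <- decompose(parse_smiles("CCC1CCCCCCCCCCC1", id = "x"))
  js <- jsonlite::fromJSON(decomposition_to_json(d), simplifyVector = TRUE)
  expect_equal(js$N, 12L)
  expect_equal(sort(js$ring_atoms), sort(d$ring_atoms) - 1L)
})
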