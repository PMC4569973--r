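# Fingerprints, Tanimoto matching, class assignment, graph descriptors.

test_that("tanimoto follows the bit-set formula", {
  a <- logical(16); a[c(1, 2, 3)] <- TRUE
  b <- logical(16); b[c(2, 3, 4)] <- TRUE
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1)
  d <- logical(16); d[10] <- TRUE
  expect_equal(tanimoto(a, d), 0)
  expect_warning(expect_equal(tanimoto(logical(16), logical(16)), 1),
                 "empty")
  expect_error(tanimoto(a, logical(8)), "mismatch")
})

test_that("tanimoto is symmetric and 1 iff identical on random bit sets", {
  set.seed(3)
  for (i in 1:100) {
    a <- runif(64) < 0.3; b <- runif(64) < 0.3
    if (!any(a) || !any(b)) next
    expect_identical(tanimoto(a, b), tanimoto(b, a))
    if (tanimoto(a, b) == 1) expect_identical(a, b)
  }
})

test_that("fingerprints separate molecules and are graph-invariant", {
  benzene <- make_compound("BNZ", rep("C", 6),
                           data.frame(a1 = 1:6, a2 = c(2:6, 1),
                                      order = c(2, 1, 2, 1, 2, 1)))
  hexane <- make_compound("HEX", rep("C", 6),
                          data.frame(a1 = 1:5, a2 = 2:6, order = 1))
  expect_lt(tanimoto(benzene$fingerprint, hexane$fingerprint), 0.95)
  # atom relabeling leaves the fingerprint unchanged
  hexane_rev <- make_compound("HEX2", rep("C", 6),
                              data.frame(a1 = 6:2, a2 = 5:1, order = 1))
  expect_equal(tanimoto(hexane$fingerprint, hexane_rev$fingerprint), 1)
})

test_that("library mapping honors MW tolerance, strict Tanimoto, and
           the overlap rule", {
  cmp <- make_compound("AAA", c("C", "C", "O"),
                       data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1))
  same <- make_compound("DB1", c("C", "C", "O"),
                        data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1))
  other <- make_compound("DB2", c("C", "C", "C", "C"),
                         data.frame(a1 = 1:3, a2 = 2:4, order = 1))
  a1 <- map_compound(cmp, list(same), list(list(other)))
  expect_equal(a1$class, "drug")
  a2 <- map_compound(cmp, list(same), list(list(same)))
  expect_equal(a2$class, "overlapping")
  a3 <- map_compound(cmp, list(other), list(list(other)))
  expect_equal(a3$class, "unassigned")
  # same fingerprint but shifted weight: outside the +-1 Da window
  heavy <- same; heavy$molecular_weight <- same$molecular_weight + 5
  expect_equal(map_compound(cmp, list(heavy), list())$class, "unassigned")
  # T = t_min exactly must NOT match (strict inequality)
  twin <- same
  expect_equal(tanimoto(cmp$fingerprint, twin$fingerprint), 1)
  expect_equal(map_compound(cmp, list(twin), list(), t_min = 1)$class,
               "unassigned")
  # library order does not change the call
  b1 <- map_compound(cmp, list(other, same), list(list(other)))
  b2 <- map_compound(cmp, list(same, other), list(list(other)))
  expect_equal(b1$class, b2$class)
})

test_that("Wiener index matches hand computation and a shortest-path
           oracle on random trees", {
  butane <- make_compound("BUT", rep("C", 4),
                          data.frame(a1 = 1:3, a2 = 2:4, order = 1))
  expect_equal(compute_graph_descriptors(butane)$wiener_index, 10)
  set.seed(8)
  for (i in 1:25) {
    mol <- random_tree_molecule(sample(2:8, 1))
    cmp <- make_compound("T", mol$elements, mol$bonds)
    d <- compute_graph_descriptors(cmp)
    expect_equal(d$wiener_index,
                 oracle_wiener(length(mol$elements), mol$bonds))
    # Platt index oracle: sum over edges of (deg(u) + deg(v) - 2)
    deg <- tabulate(c(mol$bonds$a1, mol$bonds$a2),
                    nbins = length(mol$elements))
    platt <- sum(deg[mol$bonds$a1] + deg[mol$bonds$a2] - 2)
    expect_equal(d$relative_platt_index, platt / length(mol$elements))
  }
})

test_that("ring, rotatable-bond and sp3 descriptors behave on knowns", {
  cyclohexane <- make_compound("CHX", rep("C", 6),
                               data.frame(a1 = 1:6, a2 = c(2:6, 1),
                                          order = 1))
  d <- compute_graph_descriptors(cyclohexane)
  expect_equal(d$ring_atom_count, 6)
  expect_equal(d$relative_ring_atom_count, 1.0)
  expect_equal(d$relative_rotatable_bond_count, 0)
  expect_equal(d$relative_sp3_carbons, 1.0)
  methane <- make_compound("CH4", "C",
                           data.frame(a1 = integer(0), a2 = integer(0),
                                      order = numeric(0)))
  dm <- compute_graph_descriptors(methane)
  expect_equal(dm$rotatable_bond_count, 0)
  expect_equal(dm$relative_sp3_carbons, 1.0)
  expect_equal(dm$atom_count, 5)  # CH4
  # n-pentane: two internal C-C bonds are rotatable
  pentane <- make_compound("PEN", rep("C", 5),
                           data.frame(a1 = 1:4, a2 = 2:5, order = 1))
  expect_equal(compute_graph_descriptors(pentane)$rotatable_bond_count, 2)
  # balaban index of n-hexane (literature value 2.339)
  hexane <- make_compound("HEX", rep("C", 6),
                          data.frame(a1 = 1:5, a2 = 2:6, order = 1))
  expect_equal(compute_graph_descriptors(hexane)$balaban_index, 2.339,
               tolerance = 1e-3)
})

test_that("descriptor tables override computed values and flag unknowns", {
  cmp <- make_compound("AAA", c("C", "C", "O"),
                       data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1))
  desc <- descriptor_table(list(cmp))
  expect_true(is.na(desc$logp))
  tab <- file.path(tempdir(), "desc.tsv")
  writeLines(c("compound_id\tlogp", "AAA\t1.25", "ZZZ\t0.1"), tab)
  expect_message(merged <- load_descriptor_table(tab, desc), "unknown")
  expect_equal(merged$logp, 1.25)
  # missing key column is a format error
  bad <- file.path(tempdir(), "bad.tsv")
  writeLines(c("id\tlogp", "AAA\t1"), bad)
  expect_error(load_descriptor_table(bad, desc), "compound_id")
})
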