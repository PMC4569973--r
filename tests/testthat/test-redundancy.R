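# Bray-Curtis, pocket dedup, target clustering, promiscuity labels.

test_that("bray_curtis evaluates the count-vector formula", {
  a <- residue_composition(c("A", "A", "H"))
  expect_equal(bray_curtis(a, a), 0)
  b <- residue_composition(c("A", "H", "G", "G"))
  expect_equal(bray_curtis(a, b), 3 / 7)
  expect_equal(bray_curtis(residue_composition("A"),
                           residue_composition("G")), 1)
  expect_error(bray_curtis(numeric(20), numeric(20)), "zero")
})

test_that("bray_curtis is a bounded symmetric semimetric (vs vegan)", {
  set.seed(11)
  for (i in 1:300) {
    a <- random_composition(); b <- random_composition()
    d <- bray_curtis(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_identical(d, bray_curtis(b, a))
    expect_equal(d, as.numeric(vegan::vegdist(rbind(a, b), "bray")),
                 tolerance = 1e-12)
    if (d == 0) expect_identical(a, b)
  }
})

test_that("dedup keeps one representative for identical pockets and
           separates dissimilar ones", {
  p1 <- fix_pocket(c("A", "A", "H"), structure_id = "S1")
  p2 <- fix_pocket(c("A", "A", "H"), structure_id = "S2")
  expect_length(dedup_pockets(list(p1, p2)), 1)
  # d_BC = 0.5 > 0.3: both survive
  q1 <- fix_pocket(c("A", "A", "A", "A"), structure_id = "S1")
  q2 <- fix_pocket(c("A", "G", "G", "G"), structure_id = "S2")
  expect_equal(bray_curtis(q1$composition, q2$composition), 6 / 8)
  expect_length(dedup_pockets(list(q1, q2)), 2)
  # three pockets pairwise within the cutoff collapse to one
  r <- list(fix_pocket(rep("A", 10), structure_id = "S1"),
            fix_pocket(c(rep("A", 9), "H"), structure_id = "S2"),
            fix_pocket(c(rep("A", 9), "G"), structure_id = "S3"))
  dmax <- max(bray_curtis(r[[1]]$composition, r[[2]]$composition),
              bray_curtis(r[[1]]$composition, r[[3]]$composition),
              bray_curtis(r[[2]]$composition, r[[3]]$composition))
  expect_lte(dmax, 0.3)
  expect_length(dedup_pockets(r), 1)
})

test_that("dedup representative is the largest pocket, ties by id", {
  small <- fix_pocket(c("A", "A", "H"), structure_id = "S2")
  large <- fix_pocket(c("A", "A", "H", "H"), structure_id = "S1")
  rep1 <- dedup_pockets(list(small, large))
  expect_equal(bray_curtis(small$composition, large$composition), 1 / 7)
  expect_length(rep1, 1)
  expect_equal(nrow(rep1[[1]]$residues), 4)
  tie_a <- fix_pocket(c("A", "A", "H"), structure_id = "S9")
  tie_b <- fix_pocket(c("A", "A", "H"), structure_id = "S1")
  expect_equal(dedup_pockets(list(tie_a, tie_b))[[1]]$structure_id, "S1")
})

test_that("dedup agrees with brute-force complete linkage on random
           tie-free instances", {
  set.seed(23)
  done <- 0
  while (done < 60) {
    n <- sample(2:12, 1)
    comps <- replicate(n, random_composition(), simplify = FALSE)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- bray_curtis(comps[[i]], comps[[j]])
    off <- d[upper.tri(d)]
    if (any(duplicated(signif(off, 12)))) next
    done <- done + 1
    pockets <- lapply(seq_len(n), function(i)
      fix_pocket_comp(comps[[i]], structure_id = sprintf("S%02d", i)))
    reps <- dedup_pockets(pockets, cutoff = 0.3)
    memb <- oracle_complete_linkage(d, 0.3)
    expect_length(reps, max(memb))
    # same representative per oracle cluster under the package's rule
    expected_ids <- vapply(seq_len(max(memb)), function(g) {
      members <- pockets[memb == g]
      sizes <- vapply(members, function(p) nrow(p$residues), integer(1))
      ids <- vapply(members, `[[`, "", "structure_id")
      ids[order(-sizes, ids)[1]]
    }, "")
    expect_setequal(vapply(reps, `[[`, "", "structure_id"), expected_ids)
  }
})

test_that("target clustering joins homologs and splits unrelated chains", {
  base <- paste(rep(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                    6), collapse = "")
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    idx <- seq(1, length(v), length.out = k)
    v[idx] <- "W"
    paste(v, collapse = "")
  }
  mk <- function(seqstr, sid, cid) {
    types <- strsplit(seqstr, "")[[1]]
    fix_chain(types, matrix(0, length(types), 3), structure_id = sid,
              chain_id = cid)
  }
  set.seed(5)
  rand <- paste(sample(AA20, 60, TRUE), collapse = "")
  chains <- list(mk(base, "S1", "A"),          # family member
                 mk(mutate(base, 10), "S2", "A"),  # ~83% identical
                 mk(rand, "S3", "A"))          # unrelated
  cl <- cluster_targets(chains)
  expect_length(cl, 2)
  sizes <- sort(vapply(cl, function(x) length(x$members), integer(1)))
  expect_equal(sizes, c(1, 2))
  # identical sequences always cluster
  cl2 <- cluster_targets(list(mk(base, "S1", "A"), mk(base, "S2", "B")))
  expect_length(cl2, 1)
  # single-linkage transitivity: A~B, B~C at ~50% identity, A~C unrelated
  far <- paste(sample(AA20, 60, TRUE), collapse = "")
  bridge <- paste0(substr(base, 1, 30), substr(far, 31, 60))
  expect_length(cluster_targets(list(mk(base, "S1", "A"),
                                     mk(bridge, "S2", "A"),
                                     mk(far, "S3", "A")),
                                length_coverage = 0.5), 1)
  expect_error(cluster_targets(list()), "no chains")
})

test_that("cluster counts do not increase with a stricter identity cutoff", {
  set.seed(9)
  chains <- lapply(1:8, function(i) {
    types <- sample(AA20, 50, TRUE)
    fix_chain(types, matrix(0, 50, 3), structure_id = sprintf("S%d", i))
  })
  n1 <- length(cluster_targets(chains, identity_cutoff = 0.10,
                               length_coverage = 0))
  n2 <- length(cluster_targets(chains, identity_cutoff = 0.30,
                               length_coverage = 0))
  n3 <- length(cluster_targets(chains, identity_cutoff = 0.90,
                               length_coverage = 0))
  expect_lte(n1, n2); expect_lte(n2, n3)
})

test_that("nonredundant_events collapses homolog-bound duplicates and
           keeps distinct targets", {
  seqA <- paste(rep("ADEF", 15), collapse = "")
  set.seed(77)
  mkch <- function(seqstr, sid, cid = "A") {
    types <- strsplit(seqstr, "")[[1]]
    fix_chain(types, matrix(0, length(types), 3), structure_id = sid,
              chain_id = cid)
  }
  rand1 <- paste(sample(AA20, 60, TRUE), collapse = "")
  rand2 <- paste(sample(AA20, 60, TRUE), collapse = "")
  chains <- list(`S1.A` = mkch(seqA, "S1"), `S2.A` = mkch(seqA, "S2"),
                 `S3.A` = mkch(rand1, "S3"), `S4.A` = mkch(rand2, "S4"))
  # compound bound twice to the same protein sequence (identical pockets)
  # and once each to two unrelated proteins
  pockets <- list(
    fix_pocket(c("A", "D", "E"), "CMP", "S1", "A"),
    fix_pocket(c("A", "D", "E"), "CMP", "S2", "A"),
    fix_pocket(c("H", "K", "W"), "CMP", "S3", "A"),
    fix_pocket(c("S", "T", "Y"), "CMP", "S4", "A"))
  ev <- nonredundant_events(pockets, chains)
  expect_named(ev, "CMP")
  expect_length(ev$CMP, 3)
  lab <- classify_promiscuity(ev)
  expect_equal(lab$label, "promiscuous")
  expect_equal(lab$n_pockets, 3)
})

test_that("promiscuity labels partition compounds at the 3-event rule", {
  counts <- c(X1 = 1L, X2 = 2L, X3 = 3L, X4 = 7L)
  lab <- classify_promiscuity(counts)
  expect_equal(lab$label, c("selective", "selective", "promiscuous",
                            "promiscuous"))
  expect_equal(nrow(lab), sum(counts >= 1))
  expect_message(classify_promiscuity(c(A = 0L, B = 2L)), "zero events")
})
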