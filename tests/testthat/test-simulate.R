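# Synthetic-data generator: determinism, contract closure, anchoring.

test_that("generated structures realize the planted pockets exactly", {
  cfg <- sim_config(seed = 41, n_compounds = 10, n_proteins = 15,
                    chains_per_file = 5)
  dir <- file.path(tempdir(), "sim_struct")
  unlink(dir, recursive = TRUE)
  events <- data.frame(compound_id = bindscape:::cc_code(1:10),
                       n_pockets = rep(c(1, 2), 5))
  st <- generate_structures(cfg, events, dir, seed = 41)
  expect_true(all(file.exists(st$files)))
  models <- lapply(st$files, read_structure)
  names(models) <- vapply(models, `[[`, "", "structure_id")
  for (i in seq_len(nrow(st$expected_pockets))) {
    row <- st$expected_pockets[i, ]
    m <- models[[row$structure_id]]
    lig <- Filter(function(l) l$chain_id == row$chain_id, m$ligands)[[1]]
    pk <- extract_pockets(m, lig)
    pk <- Filter(function(p) p$chain_id == row$chain_id, pk)
    expect_length(pk, 1)
    expect_equal(paste(pk[[1]]$residues$seq_number, collapse = ","),
                 row$site)
  }
})

test_that("a two-residue contact request yields no pocket", {
  # construct the degenerate geometry directly
  chain <- fix_chain(c("A", "H", "G", "S"),
                     rbind(c(3, 0, 0), c(0, 4, 0), c(9, 0, 0), c(0, 9, 0)))
  lig <- fix_ligand(c(0, 0, 0))
  expect_length(extract_pockets(fix_model(list(chain), list(lig)), lig), 0)
})

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 13, n_compounds = 15, n_proteins = 12)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  unlink(c(d1, d2), recursive = TRUE)
  generate_bundle(cfg, d1)
  generate_bundle(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
})

test_that("every emitted file parses back through the readers", {
  d1 <- file.path(tempdir(), "bundle_a")  # written above
  sdf <- read_compound_library(file.path(d1, "pdb_compounds.sdf"))
  expect_length(sdf, 15)
  expect_true(all(vapply(sdf, `[[`, numeric(1), "molecular_weight") > 0))
  for (f in list.files(file.path(d1, "structures"), full.names = TRUE)) {
    m <- read_structure(f)
    expect_gt(length(m$chains), 0)
    expect_false(is.na(m$resolution))
    expect_lte(m$resolution, 2.0)
  }
  desc <- read.delim(file.path(d1, "descriptors.tsv"))
  expect_equal(nrow(desc), 15)
})

test_that("drug-class molecular weights are anchored to the configured
           median", {
  cfg <- sim_config(seed = 55, n_compounds = 400)
  cs <- generate_compound_set(cfg)
  mw <- cs$descriptors$molecular_weight
  drugs <- cs$truth$class == "drug"
  expect_gt(sum(drugs), 50)
  expect_lt(abs(median(mw[drugs]) - 330.2) / 330.2, 0.10)
  met <- cs$truth$class == "metabolite"
  expect_lt(abs(median(mw[met]) - 238.7) / 238.7, 0.15)
  # class mixture control: a pure-metabolite mixture
  cfg2 <- sim_config(seed = 56, n_compounds = 40,
                     class_mix = c(drug = 0, metabolite = 1,
                                   overlapping = 0, unassigned = 0))
  cs2 <- generate_compound_set(cfg2)
  expect_true(all(cs2$truth$class == "metabolite"))
  expect_length(cs2$drug_lib, 0)
})

test_that("a zero beta vector decouples promiscuity from descriptors", {
  cfg <- sim_config(seed = 60, n_compounds = 2000,
                    beta = c(molecular_weight = 0))
  set.seed(60)
  fake <- list(descriptors = data.frame(
    compound_id = sprintf("C%04d", 1:2000),
    molecular_weight = rlnorm(2000, log(280), 0.4),
    relative_rotatable_bond_count = runif(2000)))
  ps <- vapply(1:10, function(s) {
    ev <- generate_binding_events(cfg, fake, seed = 600 + s)
    hi <- fake$descriptors$molecular_weight >
      median(fake$descriptors$molecular_weight)
    suppressWarnings(chisq.test(table(hi, ev$events$label))$p.value)
  }, numeric(1))
  expect_gt(max(ps), 0.01)        # no consistent association
  expect_gt(mean(ps > 0.01), 0.5)
})

test_that("EC concentration drives per-compound entropy to its limits", {
  base_cfg <- sim_config(seed = 61, n_compounds = 5)
  # near-zero concentration: each compound sticks to one category
  cfg_lo <- modifyList(base_cfg, list(ec_alpha = 0.005))
  class(cfg_lo) <- "sim_config"
  cs <- generate_compound_set(sim_config(seed = 61, n_compounds = 5))
  cs$descriptors <- cs$descriptors[1, , drop = FALSE]
  mk_entropy <- function(cfg, n_targets) {
    set.seed(cfg$seed)
    p <- bindscape:::rdirichlet1(cfg$ec_alpha *
                                   cfg$ec_background /
                                   sum(cfg$ec_background) * 7)
    cats <- sample(1:7, n_targets, TRUE, prob = p)
    targets <- lapply(cats, function(k) if (k == 7) integer(0) else k)
    ec_entropy(targets, background_sizes = rep(1, 7))$entropy
  }
  expect_lt(mk_entropy(cfg_lo, 500), 0.2)
  cfg_hi <- modifyList(base_cfg, list(ec_alpha = 100,
                                      ec_background = rep(1 / 7, 7)))
  class(cfg_hi) <- "sim_config"
  expect_lt(abs(mk_entropy(cfg_hi, 500) - log(7)), 0.1)
})

test_that("planted pathway enrichment raises promiscuous membership", {
  cfg <- sim_config(seed = 62)
  labels <- data.frame(compound_id = sprintf("C%04d", 1:2000),
                       label = rep(c("promiscuous", "selective"),
                                   c(500, 1500)))
  ann <- generate_pathway_annotations(cfg, labels, seed = 62)
  planted <- ann[ann$term == "Signal transduction", ]
  in_term <- labels$compound_id %in% planted$compound_id
  p_prom <- mean(in_term[labels$label == "promiscuous"])
  p_sel <- mean(in_term[labels$label == "selective"])
  or_hat <- (p_prom / (1 - p_prom)) / (p_sel / (1 - p_sel))
  expect_gt(or_hat, 2)
  neutral <- ann[ann$term == "Membrane transport", ]
  in_n <- labels$compound_id %in% neutral$compound_id
  or_n <- (mean(in_n[labels$label == "promiscuous"]) /
             (1 - mean(in_n[labels$label == "promiscuous"]))) /
    (mean(in_n[labels$label == "selective"]) /
       (1 - mean(in_n[labels$label == "selective"])))
  expect_lt(abs(log(or_n)), log(1.8))
})
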