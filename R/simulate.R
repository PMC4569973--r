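# Synthetic-data generator: compound sets, binding events, structures and
# pathway annotations with recorded ground truth.

# approximate natural amino-acid background frequencies (UniProt-scale),
# in the canonical AA_TYPES order
BG_AA <- c(A = 0.083, R = 0.055, N = 0.040, D = 0.054, C = 0.014,
           Q = 0.039, E = 0.067, G = 0.071, H = 0.022, I = 0.059,
           L = 0.097, K = 0.058, M = 0.024, F = 0.039, P = 0.047,
           S = 0.066, T = 0.053, W = 0.011, Y = 0.029, V = 0.068)

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. Class-specific
#' descriptor locations are anchored to the observed medians of real
#' drug/metabolite sets (molecular weight 330.2 vs 238.7 Da, logP 1.43 vs
#' -0.3, and so on); the promiscuity model draws the non-redundant pocket
#' count as `1 + Poisson(exp(beta0 + beta . z))` over standardized
#' descriptors, with defaults giving roughly one promiscuous compound in
#' five, a negative molecular-weight effect and a positive flexibility
#' effect.
#'
#' @param seed Integer RNG seed.
#' @param n_compounds Number of structure-derived compounds.
#' @param class_mix Named proportions over
#'   drug/metabolite/overlapping/unassigned (must sum to 1).
#' @param mw_median,mw_sdlog Log-normal molecular-weight parameters per
#'   class (Dalton).
#' @param logp_mean,logp_sd Normal logP parameters per class.
#' @param beta0 Intercept of the log pocket-count link.
#' @param beta Named coefficients over descriptor columns.
#' @param ec_background Proportions of the seven EC categories
#'   (EC1..EC6, None) in the target universe.
#' @param ec_alpha Dirichlet concentration of per-compound EC preference
#'   (small = concentrated on few classes, large = uniform).
#' @param pocket_conc Dirichlet concentration of per-pocket composition
#'   around the compound's base composition (large = low dispersion).
#' @param pocket_conc_sdlog Log-normal spread of per-compound
#'   concentration, giving compounds genuinely different dispersions.
#' @param pocket_size_min,pocket_size_lambda Pocket residue count is
#'   `pocket_size_min + Poisson(pocket_size_lambda)`.
#' @param duplicate_prob Probability that a binding event is additionally
#'   deposited a second time on the same protein (a redundant event the
#'   pipeline must collapse).
#' @param n_proteins,chain_length,chains_per_file Structure-pool geometry.
#' @param baseline_term_prob Baseline pathway-membership probability for
#'   collective terms (detailed terms use half).
#' @param mapped_prob Probability that a compound is mapped to the
#'   pathway resource at all.
#' @param planted_terms Data frame `term`, `category`, `level`,
#'   `odds_ratio` of terms enriched among promiscuous compounds.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_compounds = 500,
                       class_mix = c(drug = 0.38, metabolite = 0.21,
                                     overlapping = 0.31, unassigned = 0.10),
                       mw_median = c(drug = 330.2, metabolite = 238.7,
                                     overlapping = 250, unassigned = 260),
                       mw_sdlog = 0.40,
                       logp_mean = c(drug = 1.43, metabolite = -0.3,
                                     overlapping = -0.1, unassigned = 0.2),
                       logp_sd = 1.3,
                       beta0 = -0.25,
                       beta = c(molecular_weight = -0.4,
                                relative_rotatable_bond_count = 0.3),
                       ec_background = c(0.26, 0.21, 0.24, 0.08, 0.05,
                                         0.05, 0.11),
                       ec_alpha = 1,
                       pocket_conc = 30,
                       pocket_conc_sdlog = 0.6,
                       pocket_size_min = 4,
                       pocket_size_lambda = 4,
                       duplicate_prob = 0.3,
                       n_proteins = 150,
                       chain_length = 60,
                       chains_per_file = 10,
                       baseline_term_prob = 0.12,
                       mapped_prob = 0.8,
                       planted_terms = data.frame(
                         term = "Signal transduction",
                         category = "Environmental Information Processing",
                         level = "collective",
                         odds_ratio = 3,
                         stringsAsFactors = FALSE)) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-9, all(class_mix >= 0),
            mw_sdlog > 0, pocket_conc > 0, length(ec_background) == 7)
  structure(as.list(environment()), class = "sim_config")
}

cc_code <- function(i) {
  # deterministic 3-character chemical-component-style codes, skipping
  # anything on the default ion/solvent exclusion list
  alph <- c(LETTERS, 0:9)
  k <- seq_len(max(i) + length(default_ligand_exclusions)) - 1
  codes <- paste0(LETTERS[k %/% 1296 %% 26 + 1],
                  alph[k %/% 36 %% 36 + 1], alph[k %% 36 + 1])
  setdiff(codes, default_ligand_exclusions)[i]
}

build_molecule <- function(id, n_chain_c, rings, n_o, n_n, aromatic,
                           fp_bits = 1024) {
  elements <- character(0)
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0))
  add_bond <- function(a, b, o = 1)
    bonds <<- rbind(bonds, data.frame(a1 = a, a2 = b, order = o))
  attach_at <- integer(0)
  for (r in seq_len(rings)) {
    base <- length(elements)
    elements <- c(elements, rep("C", 6))
    orders <- if (aromatic[r]) c(2, 1, 2, 1, 2, 1) else rep(1, 6)
    for (k in 1:6) add_bond(base + k, base + (k %% 6) + 1, orders[k])
    if (length(attach_at) > 0) add_bond(attach_at[length(attach_at)], base + 1)
    attach_at <- c(attach_at, base + 4)
  }
  if (n_chain_c > 0) {
    base <- length(elements)
    elements <- c(elements, rep("C", n_chain_c))
    if (n_chain_c > 1)
      for (k in seq_len(n_chain_c - 1)) add_bond(base + k, base + k + 1)
    if (length(attach_at) > 0) add_bond(attach_at[length(attach_at)], base + 1)
    attach_at <- c(attach_at, base + seq_len(n_chain_c))
  }
  hetero <- c(rep("O", n_o), rep("N", n_n))
  for (h in seq_along(hetero)) {
    host <- attach_at[(h - 1) %% length(attach_at) + 1]
    elements <- c(elements, hetero[h])
    add_bond(host, length(elements))
  }
  make_compound(id, elements, bonds, fp_bits = fp_bits)
}

#' Generate a class-labeled compound set with descriptors
#'
#' Assembles unique molecular graphs from ring/chain/heteroatom templates
#' sized so that class-conditional molecular-weight medians land on the
#' configured anchors, computes graph descriptors, samples the non-graph
#' descriptors (logP etc.) from class-conditional distributions, and
#' builds the reference libraries: drug-class and overlapping molecules
#' are deposited in the drug library, metabolite-class and overlapping
#' molecules in the metabolite library, `unassigned` molecules in
#' neither. The generator guarantees that no two molecules of different
#' classes are mutually matchable under the +-1 Da / Tanimoto > 0.95
#' rule, so class recovery is exact by construction.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes
#'   `pdb_compounds.sdf`, `drugs.sdf`, `metabolites.sdf`,
#'   `descriptors.tsv` and `compound_truth.tsv`.
#' @param seed Seed (defaults to `config$seed`).
#' @return List: `compounds` (list of `bind_compound`, ids are synthetic
#'   3-character component codes), `drug_lib`, `metabolite_lib`,
#'   `descriptors` (data frame), `truth` (data frame `compound_id`,
#'   `class`).
#' @export
generate_compound_set <- function(config, out_dir = NULL,
                                  seed = config$seed) {
  set.seed(seed)
  n <- config$n_compounds
  classes <- sample(names(config$class_mix), n, replace = TRUE,
                    prob = config$class_mix)
  used <- new.env(parent = emptyenv())
  compounds <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    mw_target <- rlnorm(1, log(config$mw_median[[cls]]), config$mw_sdlog)
    mw_target <- min(max(mw_target, 100), 950)
    rings <- if (cls == "drug") sample(1:3, 1, prob = c(0.3, 0.45, 0.25))
    else sample(0:2, 1, prob = c(0.35, 0.45, 0.2))
    n_o <- if (cls == "drug") sample(0:3, 1) else sample(1:5, 1)
    n_n <- sample(0:3, 1)
    # cap the scaffold so the molecule can actually reach small targets
    rings <- min(rings, max(0, floor((mw_target - 40) / 85)))
    n_o <- min(n_o, max(0, floor((mw_target - 6 * rings * 13 - 20) / 17)))
    n_n <- min(n_n, max(0, floor((mw_target - 6 * rings * 13 -
                                    17 * n_o - 20) / 15)))
    arom_p <- if (cls == "drug") 0.9 else 0.35
    aromatic <- runif(rings) < arom_p
    n_chain <- max(1, round((mw_target - 6 * rings * 13 - 17 * n_o -
                               15 * n_n) / 14))
    # keep graphs unique; explore chain lengths alternately up and down
    # so collisions do not bias the class weight medians
    key_of <- function(nc) paste(nc, rings, n_o, n_n,
                                 paste(as.integer(aromatic), collapse = ""))
    key <- key_of(n_chain)
    step <- 0L
    while (!is.null(used[[key]])) {
      step <- step + 1L
      cand <- n_chain + c(step, -step)
      cand <- cand[cand >= 1]
      key <- key_of(cand[1])
      if (!is.null(used[[key]]) && length(cand) > 1) key <- key_of(cand[2])
    }
    n_chain <- as.integer(strsplit(key, " ")[[1]][1])
    used[[key]] <- TRUE
    compounds[[i]] <- build_molecule(cc_code(i), n_chain, rings, n_o, n_n,
                                     aromatic)
  }
  # resolve residual cross-class near-matches (same MW within 1 Da and
  # Tanimoto > 0.95) so library mapping can never mislabel a compound
  mws <- vapply(compounds, `[[`, numeric(1), "molecular_weight")
  repeat {
    clash <- FALSE
    ord <- order(mws)
    for (a in seq_len(n - 1)) {
      i <- ord[a]
      for (b in (a + 1):n) {
        j <- ord[b]
        if (mws[j] - mws[i] > 1) break
        if (classes[i] == classes[j]) next
        if (tanimoto(compounds[[i]]$fingerprint,
                     compounds[[j]]$fingerprint) > 0.95) {
          cmp <- compounds[[j]]
          compounds[[j]] <- make_compound(cmp$compound_id,
                                          c(cmp$elements, "O", "O"),
                                          rbind(cmp$bonds,
                                                data.frame(a1 = c(1, 1),
                                                           a2 = length(cmp$elements) + 1:2,
                                                           order = 1)))
          mws[j] <- compounds[[j]]$molecular_weight
          clash <- TRUE
        }
      }
    }
    if (!clash) break
  }
  desc <- descriptor_table(compounds)
  desc$logp <- rnorm(n, config$logp_mean[classes], config$logp_sd)
  desc$strongest_acidic_pka <- rnorm(n, ifelse(classes == "drug", 8.9, 4.4), 2.5)
  desc$strongest_basic_pka <- rnorm(n, ifelse(classes == "drug", 2.3, -1.5), 2.5)
  desc$isoelectric_point <- rnorm(n, ifelse(classes == "drug", 7.0, 5.2), 1.8)
  desc$tpsa <- pmax(0, rnorm(n, 90, 30))
  desc$accessible_surface_area <-
    pmax(50, 1.35 * desc$molecular_weight + rnorm(n, 0, 60))
  drug_lib <- list(); metab_lib <- list()
  for (i in seq_len(n)) {
    cmp <- compounds[[i]]
    if (classes[i] %in% c("drug", "overlapping")) {
      lib_cmp <- cmp; lib_cmp$compound_id <- sprintf("DB%05d", i)
      drug_lib[[length(drug_lib) + 1L]] <- lib_cmp
    }
    if (classes[i] %in% c("metabolite", "overlapping")) {
      lib_cmp <- cmp; lib_cmp$compound_id <- sprintf("MB%05d", i)
      metab_lib[[length(metab_lib) + 1L]] <- lib_cmp
    }
  }
  truth <- data.frame(compound_id = vapply(compounds, `[[`, "", "compound_id"),
                      class = classes, stringsAsFactors = FALSE)
  out <- list(compounds = compounds, drug_lib = drug_lib,
              metabolite_lib = metab_lib, descriptors = desc, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sdf(compounds, file.path(out_dir, "pdb_compounds.sdf"))
    write_sdf(drug_lib, file.path(out_dir, "drugs.sdf"))
    write_sdf(metab_lib, file.path(out_dir, "metabolites.sdf"))
    write_tsv(desc, file.path(out_dir, "descriptors.tsv"))
    write_tsv(truth, file.path(out_dir, "compound_truth.tsv"))
  }
  out
}

#' Write compounds to an SDF (V2000) file
#'
#' Minimal structure-data writer for synthetic molecules: all-zero
#' coordinates, element symbols and the bond block. Files round-trip
#' through [read_compound_library()].
#'
#' @param compounds List of `bind_compound`.
#' @param path Output file.
#' @export
write_sdf <- function(compounds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cmp in compounds) {
    na <- length(cmp$elements); nb <- nrow(cmp$bonds)
    writeLines(c(cmp$compound_id, "  bindscape synthetic", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)),
               con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       0, 0, 0, cmp$elements), con)
    if (nb > 0)
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", cmp$bonds$a1,
                         cmp$bonds$a2, as.integer(cmp$bonds$order)), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Generate binding events, EC labels and pocket compositions
#'
#' Table-level generator for the statistical stages: for each compound
#' the non-redundant pocket count is drawn as
#' `1 + Poisson(exp(beta0 + beta . z))` with `z` the standardized
#' descriptor columns named in `beta`, per-target EC labels follow a
#' compound-specific Dirichlet-categorical over the seven EC categories,
#' and per-pocket amino-acid compositions are Dirichlet-multinomial
#' around a compound base composition with per-compound dispersion
#' (recorded in the ground truth as `1 / concentration`).
#'
#' @param config A [sim_config()].
#' @param compounds Output of [generate_compound_set()] (or any list
#'   with `descriptors` and `truth`).
#' @param seed Seed (defaults to `config$seed + 1`).
#' @return List: `events` (`compound_id`, `n_pockets`, `label`),
#'   `ec_labels` (per compound, a list of per-target EC vectors),
#'   `compositions` (per compound, a pockets x 20 count matrix),
#'   `truth` (`compound_id`, `lambda`, `dispersion`).
#' @export
generate_binding_events <- function(config, compounds,
                                    seed = config$seed + 1) {
  set.seed(seed)
  desc <- compounds$descriptors
  n <- nrow(desc)
  eta <- rep(config$beta0, n)
  for (nm in names(config$beta)) {
    v <- desc[[nm]]
    z <- (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
    z[is.na(z)] <- 0
    eta <- eta + config$beta[[nm]] * z
  }
  lambda <- exp(eta)
  n_pockets <- 1L + rpois(n, lambda)
  ec_base <- config$ec_background / sum(config$ec_background)
  ec_labels <- vector("list", n)
  compositions <- vector("list", n)
  conc <- rlnorm(n, log(config$pocket_conc), config$pocket_conc_sdlog)
  for (i in seq_len(n)) {
    p_ec <- rdirichlet1(config$ec_alpha * ec_base * 7)
    cats <- sample(seq_len(7), n_pockets[i], replace = TRUE, prob = p_ec)
    ec_labels[[i]] <- lapply(cats, function(k) if (k == 7) integer(0) else k)
    base <- rdirichlet1(BG_AA * 40)
    mat <- matrix(0L, n_pockets[i], 20, dimnames = list(NULL, AA_TYPES))
    for (j in seq_len(n_pockets[i])) {
      pp <- rdirichlet1(base * conc[i])
      size <- config$pocket_size_min + rpois(1, config$pocket_size_lambda)
      mat[j, ] <- as.integer(rmultinom_one(size, pp))
    }
    compositions[[i]] <- mat
  }
  ids <- desc$compound_id
  names(ec_labels) <- ids; names(compositions) <- ids
  list(events = data.frame(compound_id = ids, n_pockets = n_pockets,
                           label = ifelse(n_pockets >= 3, "promiscuous",
                                          "selective"),
                           stringsAsFactors = FALSE),
       ec_labels = ec_labels, compositions = compositions,
       truth = data.frame(compound_id = ids, lambda = lambda,
                          dispersion = 1 / conc,
                          stringsAsFactors = FALSE))
}

rmultinom_one <- function(size, prob) {
  tabulate(sample.int(length(prob), size, replace = TRUE, prob = prob),
           nbins = length(prob))
}

#' Generate pathway annotations with planted enrichment
#'
#' Builds a membership table over a fixed ontology of collective and
#' detailed terms in the Metabolism, Environmental Information Processing
#' and Organismal Systems categories. Each compound is mapped at all with
#' probability `mapped_prob`; term membership is Bernoulli at the
#' baseline probability, except that for terms listed in
#' `config$planted_terms` the membership odds of promiscuous compounds
#' are multiplied by the planted odds ratio.
#'
#' @param config A [sim_config()].
#' @param labels Data frame `compound_id`, `label`.
#' @param seed Seed (defaults to `config$seed + 2`).
#' @return Data frame `compound_id`, `category`, `level`, `term`.
#' @export
generate_pathway_annotations <- function(config, labels,
                                         seed = config$seed + 2) {
  set.seed(seed)
  ontology <- sim_ontology()
  p0 <- ifelse(ontology$level == "collective", config$baseline_term_prob,
               config$baseline_term_prob / 2)
  mapped <- labels$compound_id[runif(nrow(labels)) < config$mapped_prob]
  is_prom <- setNames(labels$label == "promiscuous", labels$compound_id)
  rows <- list()
  for (t in seq_len(nrow(ontology))) {
    key <- match(paste(ontology$term[t], ontology$category[t],
                       ontology$level[t]),
                 paste(config$planted_terms$term,
                       config$planted_terms$category,
                       config$planted_terms$level))
    or <- if (is.na(key)) 1 else config$planted_terms$odds_ratio[key]
    odds <- p0[t] / (1 - p0[t])
    p_prom <- (odds * or) / (1 + odds * or)
    prob <- ifelse(is_prom[mapped], p_prom, p0[t])
    member <- mapped[runif(length(mapped)) < prob]
    if (length(member) > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = member, category = ontology$category[t],
        level = ontology$level[t], term = ontology$term[t],
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$compound_id, out$category, out$level, out$term), ]
}

sim_ontology <- function() {
  rbind(
    data.frame(category = "Metabolism", level = "collective",
               term = c("Carbohydrate metabolism", "Energy metabolism",
                        "Lipid metabolism", "Nucleotide metabolism",
                        "Amino acid metabolism",
                        "Metabolism of cofactors and vitamins")),
    data.frame(category = "Metabolism", level = "detailed",
               term = c("Glycolysis", "Citrate cycle",
                        "Pentose phosphate pathway", "Purine metabolism",
                        "Oxidative phosphorylation",
                        "Polyketide sugar unit biosynthesis")),
    data.frame(category = "Environmental Information Processing",
               level = "collective",
               term = c("Signal transduction", "Membrane transport")),
    data.frame(category = "Environmental Information Processing",
               level = "detailed",
               term = c("AMPK signaling pathway", "ABC transporters",
                        "HIF-1 signaling pathway")),
    data.frame(category = "Organismal Systems", level = "collective",
               term = c("Digestive system", "Nervous system",
                        "Endocrine system")),
    data.frame(category = "Organismal Systems", level = "detailed",
               term = c("Vitamin digestion and absorption",
                        "Synaptic vesicle cycle", "Insulin signaling")))
}

#' Generate structure files realizing a set of binding events
#'
#' Creates a pool of unrelated protein sequences (pairwise identity kept
#' below the homology cutoff by rejection), assigns each compound's
#' events to distinct pool proteins, optionally deposits duplicate events
#' on the same protein (redundancy the pipeline must collapse), and
#' writes PDB files in which each chain carries one ligand whose planted
#' pocket residues lie within 5 Angstrom (heavy-atom distance 3.5-4.6)
#' and all other residues beyond 6 Angstrom. EC classes are assigned per
#' pool protein from the configured background.
#'
#' @param config A [sim_config()].
#' @param events Data frame `compound_id`, `n_pockets` (true
#'   non-redundant counts), as from [generate_binding_events()].
#' @param out_dir Directory for the `structures/` files and tables.
#' @param seed Seed (defaults to `config$seed + 3`).
#' @return List: `expected_pockets` (data frame: structure, chain,
#'   compound, planted residue numbers), `targets` (chain-level table
#'   with protein ids and EC annotations), `files` (paths written).
#' @export
generate_structures <- function(config, events, out_dir,
                                seed = config$seed + 3) {
  set.seed(seed)
  dir.create(file.path(out_dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  n_prot <- config$n_proteins
  L <- config$chain_length
  pool <- replicate(n_prot, paste(sample(AA_TYPES, L, TRUE, prob = BG_AA),
                                  collapse = ""))
  pool <- decorrelate_pool(pool, config)
  prot_ec <- lapply(seq_len(n_prot), function(i) {
    if (runif(1) < config$ec_background[7] /
        sum(config$ec_background)) return(integer(0))
    k <- 1 + (runif(1) < 0.15)
    sort(unique(sample(1:6, k, replace = TRUE,
                       prob = config$ec_background[1:6])))
  })
  # event plan: per compound, its true pockets on distinct proteins,
  # plus redundant duplicates on the same protein
  plan <- list()
  for (i in seq_len(nrow(events))) {
    k <- events$n_pockets[i]
    if (k > n_prot) stop("pocket count exceeds protein pool size")
    prots <- sample(n_prot, k)
    for (p in prots) {
      size <- min(config$pocket_size_min + rpois(1, config$pocket_size_lambda),
                  L - 5)
      site <- sort(sample(L, size))
      reps <- 1L + (runif(1) < config$duplicate_prob)
      for (r in seq_len(reps))
        plan[[length(plan) + 1L]] <- list(
          compound_id = events$compound_id[i], protein = p,
          site = site)
    }
  }
  n_ev <- length(plan)
  per_file <- config$chains_per_file
  n_files <- ceiling(n_ev / per_file)
  expected <- list(); targets <- list(); files <- character(0)
  chain_letters <- c(LETTERS, letters, 0:9)
  ev <- 0L
  for (f in seq_len(n_files)) {
    sid <- sprintf("S%04d", f)
    lines <- c(sprintf("HEADER    SYNTHETIC COMPLEX                       %s", sid),
               sprintf("REMARK   2 RESOLUTION.    %4.2f ANGSTROMS.",
                       round(runif(1, 1.2, 2.0), 2)))
    serial <- 0L
    for (u in seq_len(per_file)) {
      if (ev >= n_ev) break
      ev <- ev + 1L
      e <- plan[[ev]]
      ch <- chain_letters[u]
      offset <- c(40 * (u - 1), 0, 0)
      seq_aa <- strsplit(pool[e$protein], "")[[1]]
      aa1to3 <- setNames(names(AA3), unname(AA3))
      for (res in seq_len(L)) {
        if (res %in% e$site) {
          rad <- runif(1, 3.5, 4.6)
        } else {
          rad <- runif(1, 6.5, 25)
        }
        dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
        xyz <- offset + rad * dirv
        serial <- serial + 1L
        lines <- c(lines, pdb_atom_line("ATOM", serial, " CA ",
                                        aa1to3[seq_aa[res]], ch, res,
                                        xyz, "C"))
      }
      for (a in 1:5) {
        dirv <- rnorm(3); v <- runif(1, 0, 0.3)
        dirv <- dirv / sqrt(sum(dirv^2))
        xyz <- offset + v * dirv
        serial <- serial + 1L
        lines <- c(lines, pdb_atom_line("HETATM", serial, sprintf(" C%-2d", a),
                                        e$compound_id, ch, 900 + u, xyz, "C"))
      }
      expected[[ev]] <- data.frame(
        structure_id = sid, chain_id = ch, compound_id = e$compound_id,
        protein_id = sprintf("P%04d", e$protein),
        site = paste(e$site, collapse = ","), stringsAsFactors = FALSE)
      targets[[ev]] <- data.frame(
        structure_id = sid, chain_id = ch,
        protein_id = sprintf("P%04d", e$protein),
        ec = paste(prot_ec[[e$protein]], collapse = ";"),
        stringsAsFactors = FALSE)
    }
    lines <- c(lines, "END")
    path <- file.path(out_dir, "structures", paste0(sid, ".pdb"))
    writeLines(lines, path)
    files <- c(files, path)
  }
  expected <- do.call(rbind, expected)
  targets <- do.call(rbind, targets)
  write_tsv(expected, file.path(out_dir, "expected_pockets.tsv"))
  write_tsv(targets, file.path(out_dir, "targets.tsv"))
  list(expected_pockets = expected, targets = targets, files = files)
}

# regenerate pool sequences until no pair crosses the homology cutoff,
# so that distinct pool proteins are guaranteed non-homologous
decorrelate_pool <- function(pool, config, max_iter = 20) {
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  for (iter in seq_len(max_iter)) {
    bad <- integer(0)
    for (j in 2:length(pool)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(pool[1:(j - 1)]), pool[j],
        substitutionMatrix = B62, gapOpening = 10, gapExtension = 0.5,
        type = "global")
      if (any(Biostrings::pid(aln, type = "PID1") / 100 >= 0.28))
        bad <- c(bad, j)
    }
    if (length(bad) == 0) return(pool)
    L <- nchar(pool[1])
    for (j in bad)
      pool[j] <- paste(sample(AA_TYPES, L, TRUE, prob = BG_AA),
                       collapse = "")
  }
  stop("could not decorrelate protein pool")
}

pdb_atom_line <- function(rec, serial, name, resname, chain, resno, xyz,
                          element) {
  sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], 1.0, 0.0, element)
}

#' Generate a complete input bundle
#'
#' Runs [generate_compound_set()], [generate_binding_events()],
#' [generate_structures()] and [generate_pathway_annotations()] with
#' seeds derived from the configuration seed and writes every pipeline
#' input under `out_dir`: `structures/`, `pdb_compounds.sdf`,
#' `drugs.sdf`, `metabolites.sdf`, `descriptors.tsv`, `pathways.tsv`,
#' `targets.tsv`, `expected_pockets.tsv`, `compound_truth.tsv` and
#' `event_truth.tsv`. Byte-identical across runs at the same seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return Invisible list with the in-memory pieces.
#' @export
generate_bundle <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cs <- generate_compound_set(config, out_dir = out_dir)
  ev <- generate_binding_events(config, cs)
  st <- generate_structures(config, ev$events, out_dir)
  pw <- generate_pathway_annotations(config, ev$events)
  write_tsv(pw, file.path(out_dir, "pathways.tsv"))
  truth <- merge(cs$truth, ev$events, by = "compound_id")
  write_tsv(truth[order(truth$compound_id), ],
            file.path(out_dir, "event_truth.tsv"))
  invisible(list(compounds = cs, events = ev, structures = st,
                 pathways = pw))
}
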