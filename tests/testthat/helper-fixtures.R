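# In-code fixtures and independent oracles shared across tests.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# build a bind_chain directly: one CA atom per residue at given coords
fix_chain <- function(res_types, coords, structure_id = "TEST",
                      chain_id = "A", seq_numbers = seq_along(res_types)) {
  coords <- matrix(coords, ncol = 3)
  residues <- data.frame(seq_number = seq_numbers, ins = "",
                         res_name = ifelse(res_types %in% AA20,
                                           AA1TO3[res_types], res_types),
                         res_type = ifelse(res_types %in% AA20,
                                           res_types, "OTHER"),
                         stringsAsFactors = FALSE)
  atoms <- data.frame(res_index = seq_along(res_types), name = "CA",
                      element = "C", x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], is_heavy = TRUE,
                      stringsAsFactors = FALSE)
  structure(list(structure_id = structure_id, chain_id = chain_id,
                 residues = residues, atoms = atoms,
                 sequence = paste(ifelse(res_types %in% AA20, res_types,
                                         "X"), collapse = ""),
                 ec_numbers = integer(0)), class = "bind_chain")
}

fix_ligand <- function(coords, compound_id = "LIG", structure_id = "TEST",
                       chain_id = "A", resno = 901, elements = NULL,
                       mw = 100) {
  coords <- matrix(coords, ncol = 3)
  if (is.null(elements)) elements <- rep("C", nrow(coords))
  atoms <- data.frame(name = paste0(elements, seq_len(nrow(coords))),
                      element = elements, x = coords[, 1], y = coords[, 2],
                      z = coords[, 3],
                      is_heavy = bindscape:::is_heavy_element(elements),
                      stringsAsFactors = FALSE)
  structure(list(compound_id = compound_id, structure_id = structure_id,
                 chain_id = chain_id, resno = resno, atoms = atoms,
                 molecular_weight = mw, covalent_flag = FALSE),
            class = "bind_ligand")
}

fix_model <- function(chains, ligands, structure_id = "TEST",
                      resolution = 1.5) {
  names(chains) <- vapply(chains, `[[`, "", "chain_id")
  structure(list(structure_id = structure_id, resolution = resolution,
                 chains = chains, ligands = ligands),
            class = "bind_structure")
}

# a pocket directly from residue types (composition derived)
fix_pocket <- function(res_types, compound_id = "LIG",
                       structure_id = "TEST", chain_id = "A",
                       resno = 901, seq_numbers = seq_along(res_types)) {
  residues <- data.frame(seq_number = seq_numbers, ins = "",
                         res_name = ifelse(res_types %in% AA20,
                                           AA1TO3[res_types], res_types),
                         res_type = ifelse(res_types %in% AA20,
                                           res_types, "OTHER"),
                         stringsAsFactors = FALSE)
  structure(list(compound_id = compound_id, structure_id = structure_id,
                 chain_id = chain_id, ligand_resno = resno,
                 residues = residues,
                 composition = residue_composition(residues$res_type)),
            class = "bind_pocket")
}

# pocket with an explicit composition count vector
fix_pocket_comp <- function(comp, ...) {
  types <- rep(AA20, comp)
  fix_pocket(types, ...)
}

# ---- independent oracles -------------------------------------------------

# brute-force all-pairs contact search (double loop, no vectorization)
oracle_pocket_residues <- function(chain, ligand, cutoff) {
  lig <- ligand$atoms[ligand$atoms$is_heavy, , drop = FALSE]
  hits <- integer(0)
  for (i in seq_len(nrow(chain$atoms))) {
    if (!chain$atoms$is_heavy[i]) next
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((chain$atoms$x[i] - lig$x[j])^2 +
                  (chain$atoms$y[i] - lig$y[j])^2 +
                  (chain$atoms$z[i] - lig$z[j])^2)
      if (d <= cutoff) {
        hits <- c(hits, chain$atoms$res_index[i])
        break
      }
    }
  }
  sort(unique(hits))
}

# brute-force agglomerative complete linkage cut at `cutoff`
oracle_complete_linkage <- function(d, cutoff) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- NULL; bestd <- Inf
    for (i in seq_len(length(clusters) - 1))
      for (j in (i + 1):length(clusters)) {
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    if (bestd > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  memb <- integer(n)
  for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
  memb
}

normalize_partition <- function(m) match(m, unique(m))

# two-sided Fisher exact p by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# step-up BH by hand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Wiener index by Floyd-Warshall
oracle_wiener <- function(n, bonds) {
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (k in seq_len(nrow(bonds))) {
    D[bonds$a1[k], bonds$a2[k]] <- 1
    D[bonds$a2[k], bonds$a1[k]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  sum(D[upper.tri(D)]) / 1
}

# random linear/branched test molecule as element+bond lists
random_tree_molecule <- function(n) {
  elements <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
  bonds <- if (n > 1)
    data.frame(a1 = 2:n,
               a2 = vapply(2:n, function(i) sample(i - 1, 1), integer(1)),
               order = 1)
  else data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0))
  list(elements = elements, bonds = bonds)
}

random_composition <- function(lambda = 1.5) {
  repeat {
    v <- rpois(20, lambda)
    if (sum(v) > 0) return(v)
  }
}
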