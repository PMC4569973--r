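# Redundancy reduction: pocket dedup, target clustering, promiscuity labels.

#' Bray-Curtis dissimilarity between two composition count vectors
#'
#' `sum(|a_i - b_i|) / sum(a_i + b_i)` over the 20 amino-acid counts:
#' symmetric, bounded in `[0, 1]`, and 0 exactly for identical vectors.
#'
#' @param a,b Non-negative count vectors of equal length.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  stopifnot(length(a) == length(b))
  tot <- sum(a + b)
  if (tot == 0) stop("Bray-Curtis dissimilarity undefined for two zero vectors")
  sum(abs(a - b)) / tot
}

#' Collapse redundant pockets of one compound on one protein
#'
#' Hierarchical complete-linkage clustering of the pocket composition
#' vectors under Bray-Curtis dissimilarity; the tree is cut so that every
#' cluster has complete-linkage merge height at or below `cutoff`, and one
#' representative pocket is kept per cluster (largest residue count, ties
#' broken by smallest `(structure_id, chain_id, ligand_resno)`).
#'
#' @param pockets List of `bind_pocket` objects sharing one compound and
#'   one target protein.
#' @param cutoff Dissimilarity cut (default 0.3).
#' @return List of representative pockets.
#' @export
dedup_pockets <- function(pockets, cutoff = 0.3) {
  n <- length(pockets)
  if (n <= 1) return(pockets)
  comp <- t(vapply(pockets, `[[`, numeric(20), "composition"))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- bray_curtis(comp[i, ], comp[j, ])
  tree <- hclust(as.dist(d), method = "complete")
  grp <- cutree(tree, h = cutoff)
  out <- list()
  for (g in sort(unique(grp))) {
    members <- pockets[grp == g]
    out[[length(out) + 1L]] <- members[[pick_representative(members)]]
  }
  out
}

pick_representative <- function(pockets) {
  sizes <- vapply(pockets, function(p) nrow(p$residues), integer(1))
  keys <- vapply(pockets, function(p)
    paste(p$structure_id, p$chain_id, sprintf("%09d", as.integer(p$ligand_resno))), "")
  order(-sizes, keys)[1]
}

#' Cluster target chains by sequence identity
#'
#' Builds a graph joining chain pairs whose global pairwise identity
#' (identical positions / alignment length, Needleman-Wunsch with
#' BLOSUM62) reaches `identity_cutoff` and whose aligned length covers at
#' least `length_coverage` of at least one member, then takes
#' single-linkage (connected-component) clusters. One representative per
#' cluster: longest sequence, ties broken by smallest
#' `(structure_id, chain_id)`. Identical sequences are aligned only once.
#'
#' @param chains List of `bind_chain` objects.
#' @param identity_cutoff Fractional identity threshold (default 0.30).
#' @param length_coverage Fractional coverage required on at least one
#'   member (default 0.95).
#' @return List of clusters; each is a list with `members` (indices into
#'   `chains`) and `representative` (one index).
#' @export
cluster_targets <- function(chains, identity_cutoff = 0.30,
                            length_coverage = 0.95) {
  if (length(chains) == 0) stop("no chains to cluster")
  seqs <- vapply(chains, `[[`, "", "sequence")
  useqs <- unique(seqs)
  m <- length(useqs)
  edge_i <- integer(0); edge_j <- integer(0)
  if (m > 1) {
    utils::data("BLOSUM62", package = "Biostrings", envir = environment())
    B62 <- get("BLOSUM62", envir = environment())
    lens <- nchar(useqs)
    for (j in 2:m) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(useqs[1:(j - 1)]), useqs[j],
        substitutionMatrix = B62, gapOpening = 10, gapExtension = 0.5,
        type = "global")
      ident <- Biostrings::pid(aln, type = "PID1") / 100
      aligned <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
      cover <- pmax(aligned / lens[1:(j - 1)], aligned / lens[j])
      hit <- which(ident >= identity_cutoff & cover >= length_coverage)
      edge_i <- c(edge_i, hit); edge_j <- c(edge_j, rep(j, length(hit)))
    }
  }
  g <- igraph::make_empty_graph(m, directed = FALSE)
  if (length(edge_i) > 0) g <- igraph::add_edges(g, rbind(edge_i, edge_j))
  membership <- igraph::components(g)$membership
  chain_grp <- membership[match(seqs, useqs)]
  out <- list()
  for (cl in sort(unique(chain_grp))) {
    members <- which(chain_grp == cl)
    lens <- nchar(seqs[members])
    keys <- vapply(chains[members], function(ch)
      paste(ch$structure_id, ch$chain_id), "")
    rep_idx <- members[order(-lens, keys)[1]]
    out[[length(out) + 1L]] <- list(members = members,
                                    representative = rep_idx)
  }
  out
}

#' Reduce a compound's pockets to non-redundant, non-homologous events
#'
#' For each compound: pockets are first deduplicated per protein (chains
#' with 100% identical sequence are one protein) with [dedup_pockets()],
#' then the compound's target chains are clustered with
#' [cluster_targets()] and only pockets on each cluster's representative
#' protein are kept.
#'
#' @param pockets List of `bind_pocket` objects (any number of compounds).
#' @param chains Named list of `bind_chain`; names must be
#'   `"<structure_id>.<chain_id>"` keys covering every pocket's chain.
#' @param identity_cutoff,length_coverage Passed to [cluster_targets()].
#' @param bc_cutoff Passed to [dedup_pockets()].
#' @return Named list (by compound id) of lists of non-redundant pockets.
#' @export
nonredundant_events <- function(pockets, chains, identity_cutoff = 0.30,
                                length_coverage = 0.95, bc_cutoff = 0.3) {
  if (length(pockets) == 0) return(list())
  ckey <- function(p) paste(p$structure_id, p$chain_id, sep = ".")
  pkeys <- vapply(pockets, ckey, "")
  missing <- setdiff(unique(pkeys), names(chains))
  if (length(missing) > 0)
    stop("chains absent from chain set: ", paste(missing, collapse = ", "))
  seqs <- vapply(chains, `[[`, "", "sequence")
  compounds <- vapply(pockets, `[[`, "", "compound_id")
  out <- list()
  for (cmp in unique(compounds)) {
    pk <- pockets[compounds == cmp]
    keys <- vapply(pk, ckey, "")
    # protein = identical full-chain sequence
    prot <- match(seqs[keys], unique(seqs[keys]))
    deduped <- list()
    for (pr in unique(prot))
      deduped <- c(deduped, dedup_pockets(pk[prot == pr], cutoff = bc_cutoff))
    dkeys <- vapply(deduped, ckey, "")
    target_keys <- unique(dkeys)
    cl <- cluster_targets(chains[target_keys],
                          identity_cutoff = identity_cutoff,
                          length_coverage = length_coverage)
    keep_keys <- character(0)
    for (x in cl) {
      # keep pockets on any chain sharing the representative's sequence
      rep_seq <- seqs[target_keys[x$representative]]
      member_keys <- target_keys[x$members]
      keep_keys <- c(keep_keys, member_keys[seqs[member_keys] == rep_seq])
    }
    out[[cmp]] <- deduped[dkeys %in% keep_keys]
  }
  out
}

#' Label compounds promiscuous or selective
#'
#' A compound with at least `min_pockets` non-redundant target pockets is
#' promiscuous; compounds with one or two events are selective. Compounds
#' with zero events are excluded (with a message).
#'
#' @param events Named list (compound id -> list of pockets), as returned
#'   by [nonredundant_events()], or a named integer vector of event counts.
#' @param min_pockets Promiscuity threshold (default 3).
#' @return Data frame `compound_id`, `n_pockets`, `label`.
#' @export
classify_promiscuity <- function(events, min_pockets = 3) {
  if (is.list(events)) {
    counts <- vapply(events, length, integer(1))
  } else counts <- events
  zero <- counts == 0
  if (any(zero)) {
    message(sum(zero), " compound(s) with zero events excluded")
    counts <- counts[!zero]
  }
  data.frame(compound_id = names(counts),
             n_pockets = unname(counts),
             label = ifelse(counts >= min_pockets, "promiscuous", "selective"),
             stringsAsFactors = FALSE, row.names = NULL)
}
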