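# Physicochemical descriptors from the molecular graph, plus table override.

#' Graph-based molecular descriptors
#'
#' Computes the descriptors that are functions of the heavy-atom graph
#' alone: atom counts, ring-atom counts, rotatable bonds, sp3 carbon
#' fraction, hydrogen-bond donor/acceptor counts (simple N/O rules),
#' Wiener index (half-sum of all-pairs shortest-path lengths), Balaban's
#' J index, the Platt index (sum of edge degrees) normalized by heavy-atom
#' count, and the vertex adjacency information magnitude
#' (`1 + log2(bond count)`). Descriptors that require 3D structure or an
#' empirical model (logP, pKa, pI, TPSA, ASA) are returned as `NA` and are
#' expected from [load_descriptor_table()]. "Relative" descriptors are
#' normalized by heavy-atom count. A disconnected graph is reduced to its
#' largest fragment with a warning.
#'
#' @param compound A `bind_compound`.
#' @return One-row data frame of descriptor values.
#' @export
compute_graph_descriptors <- function(compound) {
  els <- compound$elements
  bonds <- compound$bonds
  n <- length(els)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(bonds) > 0) g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  if (igraph::components(g)$no > 1) {
    warning("disconnected graph for '", compound$compound_id,
            "'; descriptors computed on largest fragment")
    cc <- make_compound(compound$compound_id, els, bonds)
    return(compute_graph_descriptors(cc))
  }
  m <- nrow(bonds)
  deg <- igraph::degree(g)
  # ring atoms: endpoints of edges lying on a cycle (non-bridge edges)
  ring_atoms <- integer(0)
  if (m > 0) {
    br <- igraph::bridges(g)
    cyc_edges <- setdiff(seq_len(m), as.integer(br))
    ring_atoms <- unique(c(bonds$a1[cyc_edges], bonds$a2[cyc_edges]))
    bridge_set <- as.integer(br)
  } else bridge_set <- integer(0)
  rot <- if (m > 0) sum(bonds$order == 1 &
                          seq_len(m) %in% bridge_set &
                          deg[bonds$a1] >= 2 & deg[bonds$a2] >= 2) else 0L
  # sp3 carbon: carbon with only single bonds
  multi <- logical(n)
  if (m > 0) {
    hit <- bonds$order > 1
    multi[unique(c(bonds$a1[hit], bonds$a2[hit]))] <- TRUE
  }
  sp3_c <- sum(els == "C" & !multi)
  h_total <- sum(compound$implicit_h)
  donors <- sum(els %in% c("N", "O") & compound$implicit_h >= 1)
  acceptors <- sum(els %in% c("N", "O"))
  D <- if (n > 1) igraph::distances(g) else matrix(0, 1, 1)
  wiener <- sum(D[upper.tri(D)])
  balaban <- NA_real_
  if (m > 0) {
    s <- rowSums(D)
    gamma <- m - n + 1  # cyclomatic number
    balaban <- m / (gamma + 1) *
      sum(1 / sqrt(s[bonds$a1] * s[bonds$a2]))
  }
  platt <- if (m > 0) sum(deg[bonds$a1] + deg[bonds$a2] - 2) else 0
  data.frame(
    compound_id = compound$compound_id,
    molecular_weight = compound$molecular_weight,
    atom_count = n + h_total,
    heavy_atom_count = n,
    ring_atom_count = length(ring_atoms),
    relative_ring_atom_count = length(ring_atoms) / n,
    h_bond_donor_count = donors,
    h_bond_acceptor_count = acceptors,
    relative_hbond_donor_count = donors / n,
    relative_hbond_acceptor_count = acceptors / n,
    rotatable_bond_count = rot,
    relative_rotatable_bond_count = rot / n,
    relative_sp3_carbons = sp3_c / n,
    wiener_index = wiener,
    balaban_index = balaban,
    relative_platt_index = platt / n,
    vertex_adjacency_information = if (m > 0) 1 + log2(m) else NA_real_,
    accessible_surface_area = NA_real_,
    tpsa = NA_real_,
    logp = NA_real_,
    strongest_acidic_pka = NA_real_,
    strongest_basic_pka = NA_real_,
    isoelectric_point = NA_real_,
    stringsAsFactors = FALSE)
}

#' Descriptor table for a list of compounds
#'
#' @param compounds List of `bind_compound` objects.
#' @return Data frame with one row per compound (see
#'   [compute_graph_descriptors()]).
#' @export
descriptor_table <- function(compounds) {
  do.call(rbind, lapply(compounds, compute_graph_descriptors))
}

#' Attach or override descriptors from a tab-separated table
#'
#' Columns supplied in the table override computed values, decoupling the
#' pipeline from any particular chemistry engine. Rows keyed to unknown
#' compounds are reported and ignored; a supplied `molecular_weight`
#' disagreeing with the computed one by more than 1 Da triggers a warning.
#'
#' @param path TSV file with a `compound_id` key column.
#' @param descriptors Data frame as from [descriptor_table()].
#' @return The merged descriptor data frame.
#' @export
load_descriptor_table <- function(path, descriptors) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!"compound_id" %in% names(tab))
    stop("descriptor table lacks the 'compound_id' key column")
  unknown <- setdiff(tab$compound_id, descriptors$compound_id)
  if (length(unknown) > 0)
    message(length(unknown), " descriptor row(s) for unknown compounds ignored")
  idx <- match(descriptors$compound_id, tab$compound_id)
  for (col in setdiff(names(tab), "compound_id")) {
    vals <- tab[[col]][idx]
    if (col == "molecular_weight" &&
        any(abs(vals - descriptors$molecular_weight) > 1, na.rm = TRUE))
      warning("supplied molecular weights differ from computed by > 1 Da")
    if (!col %in% names(descriptors)) {
      descriptors[[col]] <- vals
    } else {
      descriptors[[col]][!is.na(vals)] <- vals[!is.na(vals)]
    }
  }
  descriptors
}

#' Crude group-contribution logP estimate
#'
#' A deliberately simple additive hydrophobicity estimate (per-element
#' contributions plus a ring-carbon bonus) intended only to give synthetic
#' test molecules a logP-like quantity with a realistic range and
#' size-dependence. It is approximate and must not be used for real
#' compounds; supply measured or engine-computed values through
#' [load_descriptor_table()] instead.
#'
#' @param compound A `bind_compound`.
#' @return Numeric scalar.
#' @export
estimate_logp_crude <- function(compound) {
  contrib <- c(C = 0.36, N = -0.74, O = -0.64, S = 0.25, P = -0.5,
               F = 0.22, CL = 0.63, BR = 0.82, I = 1.1)
  v <- contrib[compound$elements]
  v[is.na(v)] <- 0
  sum(v) - 0.12 * sum(compound$implicit_h > 0 &
                        compound$elements %in% c("N", "O"))
}
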