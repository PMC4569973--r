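# Binding-pocket definition by heavy-atom contact geometry.

#' Extract binding pockets for a ligand instance
#'
#' A pocket is the set of residues of one chain having at least one heavy
#' atom within `cutoff` (inclusive) of any ligand heavy atom; a chain
#' yields a pocket only when at least `min_residues` residues are in
#' contact. Chains are treated as separate targets, so a ligand wedged
#' between two chains yields up to two pockets. No crystallographic
#' symmetry expansion is performed.
#'
#' @param model A `bind_structure`.
#' @param ligand A `bind_ligand` belonging to `model`.
#' @param cutoff Contact distance in Angstrom (closed ball, default 5.0).
#' @param min_residues Minimum number of contacting residues (default 3).
#' @return List of `bind_pocket` objects (possibly empty). Each pocket
#'   carries the compound/structure/chain identifiers, the contacting
#'   residue table sorted by sequence number, and the 20-dimensional
#'   amino-acid composition vector. Residues with non-standard types count
#'   toward the size threshold but contribute nothing to the composition.
#' @export
extract_pockets <- function(model, ligand, cutoff = 5.0, min_residues = 3) {
  stopifnot(cutoff > 0)
  lxyz <- as.matrix(ligand$atoms[ligand$atoms$is_heavy, c("x", "y", "z"),
                                 drop = FALSE])
  if (nrow(lxyz) == 0)
    stop("ligand '", ligand$compound_id, "' has no heavy atoms")
  pockets <- list()
  for (chain in model$chains) {
    heavy <- chain$atoms[chain$atoms$is_heavy, , drop = FALSE]
    if (nrow(heavy) == 0) next
    axyz <- as.matrix(heavy[, c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(axyz^2), rowSums(lxyz^2), "+") - 2 * axyz %*% t(lxyz)
    touch <- sqrt(pmax(d2, 0)) <= cutoff + 1e-9
    hit_res <- sort(unique(heavy$res_index[rowSums(touch) > 0]))
    if (length(hit_res) < min_residues) next
    residues <- chain$residues[hit_res, , drop = FALSE]
    residues <- residues[order(residues$seq_number, residues$ins), ,
                         drop = FALSE]
    rownames(residues) <- NULL
    pockets[[length(pockets) + 1L]] <- structure(list(
      compound_id = ligand$compound_id,
      structure_id = model$structure_id,
      chain_id = chain$chain_id,
      ligand_resno = ligand$resno,
      residues = residues,
      composition = residue_composition(residues$res_type)),
      class = "bind_pocket")
  }
  pockets
}

#' Amino-acid composition of a residue-type vector
#' @param res_types Character vector of one-letter residue types
#'   (`"OTHER"` entries are ignored).
#' @return Named integer vector over the 20 standard amino acids.
#' @export
residue_composition <- function(res_types) {
  counts <- table(factor(res_types, levels = AA_TYPES))
  setNames(as.integer(counts), AA_TYPES)
}

#' Composition vector of a binding pocket
#'
#' Order-invariant count vector over the 20 standard residue types; this
#' is the vector compared by [bray_curtis()] during pocket deduplication.
#'
#' @param pocket A `bind_pocket`.
#' @return Named integer vector of length 20.
#' @export
pocket_composition <- function(pocket) {
  residue_composition(pocket$residues$res_type)
}

#' @export
print.bind_pocket <- function(x, ...) {
  cat("<bind_pocket>", x$compound_id, "on", x$structure_id,
      paste0("chain ", x$chain_id), "|", nrow(x$residues), "residues\n")
  invisible(x)
}

#' Tabulate pockets
#'
#' Flattens a list of pockets into the pipeline's pocket table: one row
#' per pocket with identifiers, the residue list, and 20 count columns.
#'
#' @param pockets List of `bind_pocket` objects.
#' @return A data frame.
#' @export
pocket_table <- function(pockets) {
  if (length(pockets) == 0) {
    base <- data.frame(structure_id = character(0), chain_id = character(0),
                       compound_id = character(0), ligand_resno = integer(0),
                       n_residues = integer(0), residues = character(0),
                       stringsAsFactors = FALSE)
    comp <- as.data.frame(matrix(integer(0), 0, 20,
                                 dimnames = list(NULL, AA_TYPES)))
    return(cbind(base, comp))
  }
  base <- data.frame(
    structure_id = vapply(pockets, `[[`, "", "structure_id"),
    chain_id = vapply(pockets, `[[`, "", "chain_id"),
    compound_id = vapply(pockets, `[[`, "", "compound_id"),
    ligand_resno = vapply(pockets, function(p) as.integer(p$ligand_resno),
                          integer(1)),
    n_residues = vapply(pockets, function(p) nrow(p$residues), integer(1)),
    residues = vapply(pockets, function(p)
      paste(paste0(p$residues$res_type, p$residues$seq_number),
            collapse = ","), ""),
    stringsAsFactors = FALSE)
  comp <- t(vapply(pockets, `[[`, numeric(20), "composition"))
  colnames(comp) <- AA_TYPES
  cbind(base, as.data.frame(comp))
}
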