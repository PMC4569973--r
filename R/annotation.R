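# Compound class assignment against drug and metabolite reference libraries.

#' Map one compound to drug/metabolite libraries
#'
#' A library compound matches when the molecular weights agree within
#' `mw_tol` Dalton and the fingerprint Tanimoto similarity strictly
#' exceeds `t_min`. A compound matched only in the drug library is a
#' `drug`, only in a metabolite library a `metabolite`, in both an
#' `overlapping` compound, in neither `unassigned`.
#'
#' @param pdb_compound A `bind_compound`.
#' @param drug_lib List of `bind_compound` (the drug library).
#' @param metabolite_libs A list of one or more metabolite libraries
#'   (each a list of `bind_compound`), or a single library.
#' @param mw_tol Molecular-weight tolerance in Dalton (default 1.0).
#' @param t_min Tanimoto threshold, strict inequality (default 0.95).
#' @return List with `compound_id`, `class`, `drug_matches`,
#'   `metabolite_matches` (character vectors of matched library ids).
#' @export
map_compound <- function(pdb_compound, drug_lib, metabolite_libs,
                         mw_tol = 1.0, t_min = 0.95) {
  if (length(metabolite_libs) > 0 &&
      inherits(metabolite_libs[[1]], "bind_compound"))
    metabolite_libs <- list(metabolite_libs)
  dm <- lib_matches(pdb_compound, drug_lib, mw_tol, t_min)
  mm <- unlist(lapply(metabolite_libs, lib_matches,
                      compound = pdb_compound, mw_tol = mw_tol,
                      t_min = t_min))
  cls <- if (length(dm) > 0 && length(mm) > 0) "overlapping"
  else if (length(dm) > 0) "drug"
  else if (length(mm) > 0) "metabolite"
  else "unassigned"
  list(compound_id = pdb_compound$compound_id, class = cls,
       drug_matches = dm, metabolite_matches = unname(mm))
}

lib_matches <- function(compound, lib, mw_tol, t_min) {
  if (length(lib) == 0) return(character(0))
  mws <- vapply(lib, `[[`, numeric(1), "molecular_weight")
  cand <- which(abs(mws - compound$molecular_weight) <= mw_tol)
  hits <- character(0)
  for (i in cand) {
    if (tanimoto(compound$fingerprint, lib[[i]]$fingerprint) > t_min)
      hits <- c(hits, lib[[i]]$compound_id)
  }
  hits
}

#' Classify a set of compounds
#'
#' Vectorized wrapper around [map_compound()].
#'
#' @inheritParams map_compound
#' @param compounds List of `bind_compound`.
#' @return Data frame `compound_id`, `class`, `n_drug_matches`,
#'   `n_metabolite_matches`.
#' @export
classify_compounds <- function(compounds, drug_lib, metabolite_libs,
                               mw_tol = 1.0, t_min = 0.95) {
  rows <- lapply(compounds, function(cmp) {
    a <- map_compound(cmp, drug_lib, metabolite_libs, mw_tol, t_min)
    data.frame(compound_id = a$compound_id, class = a$class,
               n_drug_matches = length(a$drug_matches),
               n_metabolite_matches = length(a$metabolite_matches),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
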