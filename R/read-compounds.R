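# Compound library ingestion (SDF) and molecular-graph bookkeeping.

#' Read a compound library from an SDF file
#'
#' Parses a structure-data file through [ChemmineR::read.SDFset()] and
#' converts each molecule to a `bind_compound` record: heavy-atom graph,
#' molecular weight (graph atoms plus implicit hydrogens inferred from
#' standard valences), and a hashed path fingerprint for similarity
#' matching. Records containing R-group/query placeholders are dropped, as
#' are empty molecules; for multi-fragment entries (salts, counter-ions)
#' the largest covalently connected fragment defines the molecule.
#'
#' @param path SDF file path.
#' @param fp_bits Fingerprint length in bits (default 1024).
#' @return List of `bind_compound` objects. The number of dropped records
#'   is attached as attribute `n_dropped` and reported via `message()`.
#' @export
read_compound_library <- function(path, fp_bits = 1024) {
  if (!file.exists(path)) stop("SDF file not found: ", path)
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                     error = function(e) stop("cannot parse SDF '", path,
                                              "': ", conditionMessage(e),
                                              call. = FALSE))
  ids <- ChemmineR::sdfid(sdfset)
  out <- list()
  dropped <- 0L
  for (i in seq_along(sdfset)) {
    rec <- sdf_to_compound(sdfset[[i]], ids[i], fp_bits)
    if (is.null(rec)) dropped <- dropped + 1L else out[[length(out) + 1L]] <- rec
  }
  if (length(out) == 0L) stop("no parsable molecules in '", path, "'")
  if (dropped > 0)
    message(dropped, " record(s) dropped from '", basename(path),
            "' (R-groups or empty structures)")
  attr(out, "n_dropped") <- dropped
  out
}

sdf_to_compound <- function(sdf, id, fp_bits = 1024) {
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0) return(NULL)
  elements <- toupper(gsub("_.*$", "", rownames(ab)))
  # R-group / query-atom placeholders invalidate the record
  if (any(elements %in% c("R", "R#", "*", "A", "Q", "X"))) return(NULL)
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (is.null(bb) || nrow(bb) == 0)
    data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0))
  else data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                  order = as.numeric(bb[, 3]))
  make_compound(id, elements, bonds, fp_bits = fp_bits)
}

#' Build a compound record from an explicit heavy-atom graph
#'
#' Lower-level constructor used by the SDF reader and the synthetic
#' generator. Keeps the largest connected fragment, infers implicit
#' hydrogens from standard valences (aromatic bond order 4 is counted as
#' 1.5) and computes molecular weight and fingerprint.
#'
#' @param id Compound identifier.
#' @param elements Character vector of heavy-atom element symbols.
#' @param bonds Data frame with columns `a1`, `a2`, `order`.
#' @param smiles Optional line notation, kept as metadata only.
#' @param fp_bits Fingerprint length.
#' @return A `bind_compound` object, or `NULL` for an empty graph.
#' @export
make_compound <- function(id, elements, bonds, smiles = NA_character_,
                          fp_bits = 1024) {
  if (length(elements) == 0) return(NULL)
  elements <- toupper(elements)
  n <- length(elements)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(bonds) > 0)
    g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    keep <- which(comp$membership == which.max(comp$csize))
    sel <- bonds$a1 %in% keep & bonds$a2 %in% keep
    remap <- match(seq_len(n), keep)
    bonds <- data.frame(a1 = remap[bonds$a1[sel]], a2 = remap[bonds$a2[sel]],
                        order = bonds$order[sel])
    elements <- elements[keep]
    n <- length(elements)
  }
  ord <- ifelse(bonds$order == 4, 1.5, bonds$order)
  bondsum <- numeric(n)
  for (k in seq_len(nrow(bonds))) {
    bondsum[bonds$a1[k]] <- bondsum[bonds$a1[k]] + ord[k]
    bondsum[bonds$a2[k]] <- bondsum[bonds$a2[k]] + ord[k]
  }
  val <- STD_VALENCE[elements]
  val[is.na(val)] <- 0
  implicit_h <- pmax(0, round(val - ceiling(bondsum - 1e-9)))
  mw <- sum(aa_mass(elements)) + ATOMIC_MASS[["H"]] * sum(implicit_h)
  structure(list(compound_id = id, elements = elements, bonds = bonds,
                 implicit_h = implicit_h, molecular_weight = mw,
                 smiles = smiles,
                 fingerprint = path_fingerprint(elements, bonds,
                                                nbits = fp_bits)),
            class = "bind_compound")
}

#' @export
print.bind_compound <- function(x, ...) {
  cat("<bind_compound>", x$compound_id, "|", length(x$elements),
      "heavy atoms | MW", round(x$molecular_weight, 2), "Da\n")
  invisible(x)
}
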