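# Structure ingestion: PDB/mmCIF parsing and admission filters.

#' Read a protein-ligand complex structure
#'
#' Parses a PDB or mmCIF file into a structure model holding the protein
#' chains (polymer `ATOM` records) and the co-crystallized ligand instances
#' (`HETATM` groups). Coordinate parsing is delegated to
#' [bio3d::read.pdb()] / [bio3d::read.cif()]; only the first model of
#' multi-model files is used. Hydrogen atoms are retained but flagged as
#' non-heavy. Alternate locations are resolved by keeping the
#' highest-occupancy copy of each atom (ties: first in file order).
#'
#' @param path Path to the structure file.
#' @param dialect `"pdb"` or `"mmcif"`; default guesses from the extension.
#' @return An object of class `bind_structure`: a list with
#'   `structure_id`, `resolution` (Angstrom, `NA` when the file carries no
#'   resolution record, e.g. NMR entries), `chains` (named list of
#'   `bind_chain` objects) and `ligands` (list of `bind_ligand` objects).
#' @details Each chain holds a residue table (`seq_number`, `ins`,
#'   `res_name`, `res_type` with unknown residues mapped to `"OTHER"`), an
#'   atom table with Cartesian coordinates, and the one-letter `sequence`
#'   (`OTHER` residues appear as `X`). Each ligand instance holds its
#'   component code, atom table, a molecular weight summed over the atoms
#'   present in the file (hydrogens are usually absent from X-ray models,
#'   so this is in effect a heavy-atom weight) and a covalency flag set
#'   when any ligand heavy atom lies closer than 1.9 Angstrom to a protein
#'   heavy atom, the conventional upper bound for a covalent bond.
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (dialect == "pdb") bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("cannot parse '", path, "' as ", dialect, ": ",
                             conditionMessage(e), call. = FALSE))
  atoms <- parsed$atom
  structure_id <- sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "",
                      basename(path), ignore.case = TRUE)
  res <- read_resolution(path, dialect)

  atoms$insert[is.na(atoms$insert) | atoms$insert == "?"] <- ""
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms$o[is.na(atoms$o)] <- 1
  atoms$element <- atom_element(atoms)
  atoms <- resolve_altloc(atoms)
  atoms$is_heavy <- is_heavy_element(atoms$element)

  prot <- atoms[atoms$type == "ATOM", , drop = FALSE]
  het <- atoms[atoms$type == "HETATM", , drop = FALSE]

  chains <- list()
  for (ch in unique(prot$chain)) {
    ca <- prot[prot$chain == ch, , drop = FALSE]
    key <- paste(ca$resno, ca$insert, sep = "_")
    ridx <- match(key, unique(key))
    first <- !duplicated(key)
    residues <- data.frame(seq_number = ca$resno[first],
                           ins = ca$insert[first],
                           res_name = ca$resid[first],
                           res_type = res3_to_type(ca$resid[first]),
                           stringsAsFactors = FALSE)
    atom_tab <- data.frame(res_index = ridx, name = ca$elety,
                           element = ca$element,
                           x = ca$x, y = ca$y, z = ca$z,
                           is_heavy = ca$is_heavy, stringsAsFactors = FALSE)
    seq1 <- ifelse(residues$res_type == "OTHER", "X", residues$res_type)
    chains[[ch]] <- structure(list(
      structure_id = structure_id, chain_id = ch, residues = residues,
      atoms = atom_tab, sequence = paste(seq1, collapse = ""),
      ec_numbers = integer(0)), class = "bind_chain")
  }
  if (length(chains) == 0L)
    stop("no protein chains in structure '", structure_id, "'")

  ligands <- list()
  if (nrow(het) > 0) {
    grp <- paste(het$chain, het$resno, het$insert, het$resid, sep = "|")
    for (g in unique(grp)) {
      la <- het[grp == g, , drop = FALSE]
      lig_atoms <- data.frame(name = la$elety, element = la$element,
                              x = la$x, y = la$y, z = la$z,
                              is_heavy = la$is_heavy, stringsAsFactors = FALSE)
      ligands[[length(ligands) + 1L]] <- structure(list(
        compound_id = la$resid[1], structure_id = structure_id,
        chain_id = la$chain[1], resno = la$resno[1],
        atoms = lig_atoms,
        molecular_weight = sum(aa_mass(la$element)),
        covalent_flag = FALSE), class = "bind_ligand")
    }
    pxyz <- as.matrix(prot[prot$is_heavy, c("x", "y", "z"), drop = FALSE])
    for (i in seq_along(ligands)) {
      lxyz <- as.matrix(ligands[[i]]$atoms[ligands[[i]]$atoms$is_heavy,
                                           c("x", "y", "z"), drop = FALSE])
      if (nrow(lxyz) > 0 && nrow(pxyz) > 0)
        ligands[[i]]$covalent_flag <- min_cross_dist(lxyz, pxyz) < 1.9
    }
  }

  structure(list(structure_id = structure_id, resolution = res,
                 chains = chains, ligands = ligands),
            class = "bind_structure")
}

#' @export
print.bind_structure <- function(x, ...) {
  cat("<bind_structure>", x$structure_id,
      "| resolution:", ifelse(is.na(x$resolution), "NA", x$resolution),
      "| chains:", length(x$chains),
      "| ligand instances:", length(x$ligands), "\n")
  invisible(x)
}

# element symbol: trust the element column when present, else derive from
# the atom name (strip digits/primes, first alphabetic token)
atom_element <- function(atoms) {
  e <- trimws(as.character(atoms$elesy))
  bad <- is.na(e) | e == ""
  if (any(bad)) {
    nm <- gsub("[^A-Za-z]", "", atoms$elety[bad])
    e[bad] <- toupper(substr(nm, 1, 1))
  }
  toupper(e)
}

resolve_altloc <- function(atoms) {
  alt <- atoms$alt
  alt[is.na(alt) | alt == "?"] <- ""
  if (all(alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$elety, sep = "|")
  ord <- order(match(key, unique(key)), -atoms$o,
               seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

min_cross_dist <- function(a, b) {
  # minimum Euclidean distance between two coordinate matrices
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  min(sqrt(pmax(d2, 0)))
}

read_resolution <- function(path, dialect) {
  lines <- readLines(path, warn = FALSE)
  if (dialect == "pdb") {
    hit <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(hit) == 0) return(NA_real_)
    num <- regmatches(hit[1], regexpr("[0-9]+\\.?[0-9]*", sub("RESOLUTION", "", hit[1])))
    if (length(num) == 0) return(NA_real_)
    as.numeric(num)
  } else {
    hit <- grep("_refine\\.ls_d_res_high", lines, value = TRUE)
    if (length(hit) == 0) return(NA_real_)
    num <- regmatches(hit[1], regexpr("[0-9]+\\.?[0-9]*$", trimws(hit[1])))
    if (length(num) == 0) NA_real_ else as.numeric(num)
  }
}

#' Filter structures by crystallographic resolution
#'
#' Keeps structures whose resolution is recorded and at or below the
#' cutoff ("2 Angstrom or better" read inclusively). Structures without a
#' resolution record (e.g. NMR models) cannot satisfy the bound and are
#' removed.
#'
#' @param models List of `bind_structure` objects.
#' @param max_resolution Inclusive resolution bound in Angstrom.
#' @return Filtered list.
#' @export
filter_structures <- function(models, max_resolution = 2.0) {
  keep <- vapply(models, function(m)
    !is.na(m$resolution) && m$resolution <= max_resolution, logical(1))
  models[keep]
}

#' Identify analyzable ligand instances
#'
#' Applies the ligand admission rules: molecular weight within
#' `[min_mw, max_mw]`, component code not on the ion/solvent exclusion
#' list, and not covalently bound (see [read_structure()] for the
#' covalency heuristic).
#'
#' @param model A `bind_structure`.
#' @param min_mw,max_mw Molecular-weight window in Dalton.
#' @param exclusion_list Component codes to drop;
#'   defaults to [default_ligand_exclusions].
#' @return List of `bind_ligand` objects passing all predicates.
#' @export
identify_ligands <- function(model, min_mw = 30, max_mw = 1000,
                             exclusion_list = default_ligand_exclusions) {
  keep <- vapply(model$ligands, function(l) {
    l$molecular_weight >= min_mw && l$molecular_weight <= max_mw &&
      !(l$compound_id %in% exclusion_list) && !l$covalent_flag
  }, logical(1))
  model$ligands[keep]
}
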