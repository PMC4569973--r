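# Full-pipeline orchestration: ingest -> pockets -> redundancy ->
# annotation -> statistics -> models -> enrichment, with flat-file outputs.

#' Pipeline configuration
#'
#' Paths and thresholds for [run_full_analysis()]. All thresholds default
#' to the analysis constants of the method: resolution 2.0 Angstrom,
#' ligand weight window 30-1000 Da, contact cutoff 5.0 Angstrom, minimum
#' 3 pocket residues, Bray-Curtis cut 0.3, target identity 0.30 with
#' coverage 0.95, library matching at +-1 Da and Tanimoto > 0.95,
#' promiscuity at >= 3 events, 10 propensity bins.
#'
#' @param structures_dir Directory of PDB/mmCIF files.
#' @param pdb_compounds_sdf SDF of the structure-derived compounds
#'   (ids must equal the ligand component codes).
#' @param drug_sdf,metabolite_sdfs Reference libraries (SDF paths;
#'   `metabolite_sdfs` may name several files).
#' @param descriptors_tsv Optional descriptor table overriding computed
#'   values (see [load_descriptor_table()]).
#' @param pathways_tsv Optional pathway membership table
#'   (`compound_id`, `category`, `level`, `term`).
#' @param targets_tsv Optional chain-level EC table
#'   (`structure_id`, `chain_id`, `ec` with `;`-separated classes).
#' @param out_dir Output directory for the stage tables.
#' @param max_resolution,min_mw,max_mw,contact_cutoff,min_residues
#'   Admission and pocket thresholds.
#' @param bc_cutoff,identity_cutoff,length_coverage Redundancy thresholds.
#' @param mw_tol,t_min Library-matching thresholds.
#' @param promiscuity_min,n_bins Statistics thresholds.
#' @param properties Descriptor columns profiled for promiscuity
#'   propensity and used as model predictors.
#' @param exclusion_list Ligand component codes to ignore.
#' @param seed Seed for model cross-validation folds.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(structures_dir, pdb_compounds_sdf,
                            drug_sdf = NULL, metabolite_sdfs = NULL,
                            descriptors_tsv = NULL, pathways_tsv = NULL,
                            targets_tsv = NULL, out_dir = "bindscape_out",
                            max_resolution = 2.0, min_mw = 30,
                            max_mw = 1000, contact_cutoff = 5.0,
                            min_residues = 3, bc_cutoff = 0.3,
                            identity_cutoff = 0.30, length_coverage = 0.95,
                            mw_tol = 1.0, t_min = 0.95,
                            promiscuity_min = 3, n_bins = 10,
                            properties = c("molecular_weight", "atom_count",
                                           "ring_atom_count",
                                           "relative_ring_atom_count",
                                           "relative_hbond_donor_count",
                                           "relative_hbond_acceptor_count",
                                           "relative_rotatable_bond_count",
                                           "relative_sp3_carbons",
                                           "wiener_index", "balaban_index",
                                           "relative_platt_index",
                                           "vertex_adjacency_information",
                                           "logp", "tpsa",
                                           "accessible_surface_area"),
                            exclusion_list = default_ligand_exclusions,
                            seed = 1) {
  stopifnot(max_resolution > 0, contact_cutoff > 0, promiscuity_min >= 2)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments;
#'   relative paths are resolved against the file's directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  for (key in c("structures_dir", "pdb_compounds_sdf", "drug_sdf",
                "descriptors_tsv", "pathways_tsv", "targets_tsv",
                "out_dir")) {
    if (!is.null(vals[[key]]) && !grepl("^/", vals[[key]]))
      vals[[key]] <- file.path(root, vals[[key]])
  }
  if (!is.null(vals$metabolite_sdfs))
    vals$metabolite_sdfs <- ifelse(grepl("^/", vals$metabolite_sdfs),
                                   vals$metabolite_sdfs,
                                   file.path(root, vals$metabolite_sdfs))
  do.call(pipeline_config, vals)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", stage, "]: ", conditionMessage(e), call. = FALSE))
}

#' Run the full binding-promiscuity analysis
#'
#' Executes every stage on the configured inputs and writes flat
#' tab-separated stage tables plus a JSON report under
#' `config$out_dir`: pocket table, non-redundant event table with
#' promiscuity labels, compound classes, merged descriptors, propensity
#' profiles, pocket composition propensities, per-compound diversity
#' (EC entropy, pocket variability), model summaries, enrichment table,
#' a compounds-with->=k-pockets summary by class, and a log of every
#' dropped-record count. Deterministic for a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with all in-memory stage results.
#' @export
run_full_analysis <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  ## ingest: structures, resolution filter, ligands, pockets
  ingest <- with_stage("ingest", {
    paths <- sort(list.files(config$structures_dir,
                             pattern = "\\.(pdb|ent|cif|mmcif)$",
                             full.names = TRUE))
    if (length(paths) == 0)
      stop("no structure files in ", config$structures_dir)
    models <- lapply(paths, read_structure)
    kept <- filter_structures(models, config$max_resolution)
    note("structures read: ", length(models))
    note("structures failing resolution filter: ",
         length(models) - length(kept))
    kept
  })
  pockets <- list(); chains <- list(); n_lig <- 0L; n_lig_kept <- 0L
  with_stage("pockets", {
    for (model in ingest) {
      for (ch in model$chains)
        chains[[paste(model$structure_id, ch$chain_id, sep = ".")]] <- ch
      ligs <- identify_ligands(model, config$min_mw, config$max_mw,
                               config$exclusion_list)
      n_lig <- n_lig + length(model$ligands)
      n_lig_kept <- n_lig_kept + length(ligs)
      for (lig in ligs)
        pockets <- c(pockets, extract_pockets(model, lig,
                                              cutoff = config$contact_cutoff,
                                              min_residues = config$min_residues))
    }
    note("ligand instances: ", n_lig, " (", n_lig - n_lig_kept,
         " excluded by weight/exclusion-list/covalency)")
    note("pockets extracted: ", length(pockets))
  })
  write_tsv(pocket_table(pockets), file.path(config$out_dir, "pockets.tsv"))

  ## compounds: libraries, classes, descriptors
  compounds <- with_stage("compounds",
                          read_compound_library(config$pdb_compounds_sdf))
  classes <- with_stage("classification", {
    drug_lib <- if (is.null(config$drug_sdf)) list()
    else read_compound_library(config$drug_sdf)
    metab_libs <- lapply(config$metabolite_sdfs %||% character(0),
                         read_compound_library)
    classify_compounds(compounds, drug_lib, metab_libs,
                       mw_tol = config$mw_tol, t_min = config$t_min)
  })
  write_tsv(classes, file.path(config$out_dir, "classes.tsv"))
  descriptors <- with_stage("descriptors", {
    d <- descriptor_table(compounds)
    if (!is.null(config$descriptors_tsv))
      d <- load_descriptor_table(config$descriptors_tsv, d)
    d
  })
  write_tsv(descriptors, file.path(config$out_dir, "descriptors_merged.tsv"))

  ## redundancy reduction and promiscuity labels
  events <- with_stage("redundancy",
                       nonredundant_events(pockets, chains,
                                           identity_cutoff = config$identity_cutoff,
                                           length_coverage = config$length_coverage,
                                           bc_cutoff = config$bc_cutoff))
  labels <- with_stage("promiscuity", {
    lab <- classify_promiscuity(events, min_pockets = config$promiscuity_min)
    no_event <- setdiff(classes$compound_id, lab$compound_id)
    note("compounds with zero binding events: ", length(no_event))
    lab
  })
  write_tsv(labels, file.path(config$out_dir, "events.tsv"))

  ## promiscuity propensity profiles per property and class selection
  profiles <- with_stage("propensity", {
    merged <- merge(labels, classes, by = "compound_id")
    merged <- merge(merged, descriptors, by = "compound_id")
    selections <- c("all", setdiff(unique(merged$class), "unassigned"))
    out <- list()
    for (sel in selections) {
      sub <- if (sel == "all") merged else merged[merged$class == sel, ]
      for (prop in intersect(config$properties, names(sub))) {
        pr <- tryCatch(
          propensity_profile(sub[[prop]], sub$label, property = prop,
                             class_label = sel, n_bins = config$n_bins),
          error = function(e) NULL)
        if (!is.null(pr))
          out[[length(out) + 1L]] <- cbind(property = prop, class = sel,
                                           as.data.frame(pr))
      }
    }
    if (length(out) == 0) NULL else do.call(rbind, out)
  })
  if (!is.null(profiles))
    write_tsv(profiles, file.path(config$out_dir, "propensity_profiles.tsv"))

  ## pocket composition propensities by class and by promiscuity
  comp_prop <- with_stage("composition", {
    cmp_class <- setNames(classes$class, classes$compound_id)
    cmp_label <- setNames(labels$label, labels$compound_id)
    groups <- list(all = rep(TRUE, length(pockets)))
    pk_cmp <- vapply(pockets, `[[`, "", "compound_id")
    for (cl in setdiff(unique(classes$class), "unassigned"))
      groups[[cl]] <- !is.na(cmp_class[pk_cmp]) & cmp_class[pk_cmp] == cl
    for (lb in c("promiscuous", "selective"))
      groups[[lb]] <- !is.na(cmp_label[pk_cmp]) & cmp_label[pk_cmp] == lb
    out <- list()
    for (g in names(groups)) {
      if (!any(groups[[g]])) next
      cp <- tryCatch(composition_propensity(pockets[groups[[g]]], chains,
                                            all_pockets = pockets),
                     error = function(e) NULL)
      if (!is.null(cp))
        out[[length(out) + 1L]] <- cbind(group = g, cp)
    }
    if (length(out) == 0) NULL else do.call(rbind, out)
  })
  if (!is.null(comp_prop))
    write_tsv(comp_prop, file.path(config$out_dir,
                                   "composition_propensity.tsv"))

  ## target diversity: EC entropy and pocket variability
  diversity <- with_stage("diversity", {
    chain_ecs <- chain_ec_table(config$targets_tsv, chains)
    diversity_table(events, chain_ecs,
                    min_targets = config$promiscuity_min,
                    min_pockets = config$promiscuity_min)
  })
  write_tsv(diversity, file.path(config$out_dir, "diversity.tsv"))

  ## prediction models
  models <- with_stage("models", {
    merged <- merge(labels, descriptors, by = "compound_id")
    merged <- merge(merged, classes, by = "compound_id")
    pred_cols <- intersect(config$properties, names(merged))
    usable <- pred_cols[vapply(pred_cols, function(cl)
      !all(is.na(merged[[cl]])), logical(1))]
    X <- as.matrix(merged[, usable, drop = FALSE])
    out <- list()
    out$plsr_pocket_count <- tryCatch(
      fit_plsr(X, log10(merged$n_pockets), seed = config$seed),
      error = function(e) NULL)
    dv <- diversity[match(merged$compound_id, diversity$compound_id), ]
    out$plsr_pv <- tryCatch(fit_plsr(X, dv$pv, seed = config$seed),
                            error = function(e) NULL)
    out$plsr_ec_entropy <- tryCatch(fit_plsr(X, dv$entropy,
                                             seed = config$seed),
                                    error = function(e) NULL)
    out$svm <- tryCatch(fit_svm_promiscuity(X, merged$label,
                                            seed = config$seed),
                        error = function(e) NULL)
    cls_rows <- merged$class != "unassigned"
    out$cart <- tryCatch(fit_cart_class(X[cls_rows, , drop = FALSE],
                                        merged$class[cls_rows],
                                        seed = config$seed),
                         error = function(e) NULL)
    out
  })
  write_model_report(models, file.path(config$out_dir, "models.txt"))

  ## enrichment
  enrichment <- with_stage("enrichment", {
    if (is.null(config$pathways_tsv)) NULL else {
      membership <- read.delim(config$pathways_tsv, sep = "\t",
                               stringsAsFactors = FALSE)
      metab <- classes$compound_id[classes$class %in%
                                     c("metabolite", "overlapping")]
      tryCatch(fisher_enrichment(membership[membership$compound_id %in%
                                              metab, , drop = FALSE],
                                 labels),
               error = function(e) { note("enrichment skipped: ",
                                          conditionMessage(e)); NULL })
    }
  })
  if (!is.null(enrichment))
    write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))

  ## summary: compounds with >= k pockets per class
  summary_tab <- with_stage("summary", {
    merged <- merge(labels, classes, by = "compound_id")
    rows <- list()
    for (k in 1:5) {
      row <- list(min_pockets = k)
      for (cl in c("drug", "metabolite", "overlapping", "unassigned")) {
        sub <- merged[merged$class == cl & merged$n_pockets >= k, ]
        row[[cl]] <- nrow(sub)
        row[[paste0(cl, "_pockets")]] <- sum(sub$n_pockets)
      }
      row$all <- sum(merged$n_pockets >= k)
      row$all_pockets <- sum(merged$n_pockets[merged$n_pockets >= k])
      rows[[k]] <- as.data.frame(row)
    }
    do.call(rbind, rows)
  })
  write_tsv(summary_tab, file.path(config$out_dir, "summary_table.tsv"))

  ## conservation: every compound is classified, unassigned, or dropped
  note("compounds in SDF: ", length(compounds) +
         (attr(compounds, "n_dropped") %||% 0L),
       " = classified ", nrow(classes), " + dropped ",
       attr(compounds, "n_dropped") %||% 0L)
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  report <- list(
    n_structures = length(ingest), n_pockets = length(pockets),
    n_compounds = nrow(classes),
    n_with_events = nrow(labels),
    n_promiscuous = sum(labels$label == "promiscuous"),
    promiscuous_fraction = mean(labels$label == "promiscuous"),
    class_counts = as.list(table(classes$class)))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(pockets = pockets, chains = chains, classes = classes,
                 descriptors = descriptors, events = events,
                 labels = labels, profiles = profiles,
                 composition = comp_prop, diversity = diversity,
                 models = models, enrichment = enrichment,
                 summary = summary_tab, report = report,
                 log = log_lines))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

chain_ec_table <- function(targets_tsv, chains) {
  out <- setNames(vector("list", length(chains)), names(chains))
  for (k in names(out)) out[[k]] <- integer(0)
  if (!is.null(targets_tsv)) {
    tab <- read.delim(targets_tsv, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = "character")
    keys <- paste(tab$structure_id, tab$chain_id, sep = ".")
    for (i in seq_along(keys)) {
      if (!keys[i] %in% names(out)) next
      ec <- tab$ec[i]
      out[[keys[i]]] <- if (is.na(ec) || ec == "") integer(0)
      else as.integer(strsplit(ec, ";")[[1]])
    }
  }
  out
}

write_model_report <- function(models, path) {
  lines <- character(0)
  for (nm in names(models)) {
    m <- models[[nm]]
    if (is.null(m)) {
      lines <- c(lines, paste0(nm, ": not fitted"))
    } else if (inherits(m, "plsr_fit")) {
      lines <- c(lines,
                 sprintf("%s: nComp=%d LOO_r=%.4f RMSEP=[%s]", nm,
                         m$n_components, m$r,
                         paste(sprintf("%.4f", m$rmsep), collapse = ", ")))
    } else if (inherits(m, "svm_fit")) {
      lines <- c(lines, sprintf("%s: best=%s cv_error=%.4f (%s)", nm,
                                m$best_kernel, m$best_error,
                                paste(names(m$cv_error),
                                      sprintf("%.4f", m$cv_error),
                                      collapse = ", ")))
    } else if (inherits(m, "cart_fit")) {
      lines <- c(lines, sprintf("%s: splits=%d cv_error=%.4f", nm,
                                m$n_splits, m$cv_error))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
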