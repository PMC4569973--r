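# Target diversity metrics: EC-class entropy and pocket variability.

EC_LEVELS <- c("1", "2", "3", "4", "5", "6", "None")

#' EC-class entropy of a compound's target set
#'
#' Counts the compound's protein targets over the six top-level EC
#' classes (1 oxidoreductases, 2 transferases, 3 hydrolases, 4 lyases,
#' 5 isomerases, 6 ligases) plus `"None"` for targets without EC
#' annotation. A target with several top-level classes contributes one
#' count to each. By default the counts are weighted by the inverse of
#' the background class sizes (`w_i = c_i / N_i`), normalized to
#' probabilities, and the Shannon entropy `H = -sum p_i ln p_i` (natural
#' log) is returned; `weighted = FALSE` gives the unweighted
#' `p_i = c_i / sum(c)` variant.
#'
#' @param target_ecs List with one element per target: an integer vector
#'   of top-level EC classes in 1..6 (empty vector = no annotation).
#' @param background_sizes Positive sizes `N_1..N_7` of the seven
#'   categories in the full target universe (named or in the order
#'   EC1..EC6, None). Default: equal sizes (no reweighting).
#' @param min_targets Minimum number of targets (default 3); compounds
#'   with fewer are rejected with an error.
#' @param weighted Use background weighting (default `TRUE`).
#' @return List: `p` (probabilities over the 7 categories), `entropy`
#'   (nats, in `[0, ln 7]`), `n_targets`.
#' @export
ec_entropy <- function(target_ecs, background_sizes = rep(1, 7),
                       min_targets = 3, weighted = TRUE) {
  if (length(target_ecs) < min_targets)
    stop("compound has fewer than ", min_targets, " targets")
  stopifnot(length(background_sizes) == 7, all(background_sizes > 0))
  cnt <- setNames(numeric(7), EC_LEVELS)
  for (ecs in target_ecs) {
    ecs <- ecs[ecs %in% 1:6]
    if (length(ecs) == 0) cnt["None"] <- cnt["None"] + 1
    else for (e in unique(ecs)) cnt[as.character(e)] <- cnt[as.character(e)] + 1
  }
  w <- if (weighted) cnt / as.numeric(background_sizes) else cnt
  p <- w / sum(w)
  pos <- p[p > 0]
  list(p = p, entropy = -sum(pos * log(pos)),
       n_targets = length(target_ecs))
}

#' Pocket variability of a compound's pocket set
#'
#' Measures how much the amino-acid composition of a compound's binding
#' pockets varies across its (non-redundant) binding events:
#' `PV = sum_i var_i / mean_i` over the residue types `i` present in at
#' least one pocket, with the sample variance (`n - 1` denominator) and
#' mean of the per-pocket counts. `PV = 0` exactly when all pockets have
#' identical composition; the index is independent of compound size.
#'
#' @param pockets List of `bind_pocket` objects for one compound, or a
#'   numeric matrix of composition vectors (pockets in rows).
#' @param min_pockets Minimum pocket count (default 3); fewer is an error.
#' @return List: `pv`, `per_type` (data frame `res_type`, `mean`,
#'   `variance`), `n_pockets`.
#' @export
pocket_variability <- function(pockets, min_pockets = 3) {
  comp <- if (is.matrix(pockets)) pockets
  else t(vapply(pockets, `[[`, numeric(20), "composition"))
  if (nrow(comp) < min_pockets)
    stop("compound has fewer than ", min_pockets, " pockets")
  mu <- colMeans(comp)
  v <- apply(comp, 2, var)
  present <- mu > 0
  per_type <- data.frame(
    res_type = if (!is.null(colnames(comp))) colnames(comp)[present]
    else as.character(which(present)),
    mean = mu[present], variance = v[present], row.names = NULL,
    stringsAsFactors = FALSE)
  list(pv = sum(v[present] / mu[present]), per_type = per_type,
       n_pockets = nrow(comp))
}

#' Per-compound diversity table
#'
#' Computes EC entropy and pocket variability for every compound with
#' enough targets/pockets and reports the four-quadrant classification of
#' high/low enzymatic diversity versus high/low pocket variability.
#'
#' @param events Named list (compound -> list of pockets) of
#'   non-redundant events, as from [nonredundant_events()].
#' @param chain_ecs Named list keyed `"<structure_id>.<chain_id>"` of
#'   integer EC-class vectors.
#' @param background_sizes Passed to [ec_entropy()]; default computed
#'   from `chain_ecs` (one count per chain and class, `None` for
#'   unannotated chains).
#' @param min_targets,min_pockets Admission thresholds (default 3).
#' @param ec_high,ec_low,pv_high,pv_low Quadrant thresholds (defaults
#'   2, 1, 1.2, 0.8).
#' @param weighted Passed to [ec_entropy()].
#' @return Data frame: `compound_id`, `entropy`, `pv`, `n_targets`,
#'   `n_pockets`, `quadrant` (`NA` outside the extreme quadrants).
#' @export
diversity_table <- function(events, chain_ecs,
                            background_sizes = NULL,
                            min_targets = 3, min_pockets = 3,
                            ec_high = 2, ec_low = 1,
                            pv_high = 1.2, pv_low = 0.8,
                            weighted = TRUE) {
  if (is.null(background_sizes)) {
    background_sizes <- setNames(numeric(7), EC_LEVELS)
    for (ecs in chain_ecs) {
      ecs <- ecs[ecs %in% 1:6]
      if (length(ecs) == 0) background_sizes["None"] <-
          background_sizes["None"] + 1
      else for (e in unique(ecs))
        background_sizes[as.character(e)] <- background_sizes[as.character(e)] + 1
    }
    background_sizes[background_sizes == 0] <- 1
  }
  rows <- list()
  for (cmp in names(events)) {
    pk <- events[[cmp]]
    keys <- vapply(pk, function(p)
      paste(p$structure_id, p$chain_id, sep = "."), "")
    targets <- unique(keys)
    H <- NA_real_; pv <- NA_real_
    if (length(targets) >= min_targets)
      H <- ec_entropy(chain_ecs[targets], background_sizes,
                      min_targets = min_targets,
                      weighted = weighted)$entropy
    if (length(pk) >= min_pockets)
      pv <- pocket_variability(pk, min_pockets = min_pockets)$pv
    rows[[cmp]] <- data.frame(compound_id = cmp, entropy = H, pv = pv,
                              n_targets = length(targets),
                              n_pockets = length(pk),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$quadrant <- NA_character_
  hi_ec <- !is.na(out$entropy) & out$entropy >= ec_high
  lo_ec <- !is.na(out$entropy) & out$entropy < ec_low
  hi_pv <- !is.na(out$pv) & out$pv >= pv_high
  lo_pv <- !is.na(out$pv) & out$pv < pv_low
  out$quadrant[hi_ec & hi_pv] <- "EC_high_PV_high"
  out$quadrant[hi_ec & lo_pv] <- "EC_high_PV_low"
  out$quadrant[lo_ec & hi_pv] <- "EC_low_PV_high"
  out$quadrant[lo_ec & lo_pv] <- "EC_low_PV_low"
  out
}
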