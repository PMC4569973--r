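# Pathway / process / organismal-system enrichment of promiscuous vs
# selective compounds.

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate correction (wraps
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (empty input returns an empty vector).
#' @export
bh_correct <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stopifnot(all(p_values >= 0 & p_values <= 1 + 1e-8, na.rm = TRUE))
  p.adjust(pmin(p_values, 1), method = "BH")
}

#' Term enrichment of promiscuous vs selective compounds
#'
#' For every annotation term, builds the 2x2 table (promiscuous/selective
#' x in-term/not-in-term) over the mapped-compound universe and applies
#' the two-sided Fisher exact test, so both enrichment and depletion are
#' detected. Within each category a `"Not assigned"` pseudo-term collects
#' universe compounds carrying no term of that category. P-values are
#' BH-corrected within each (category, level) family by default, or
#' globally with `family = "global"`. Categories annotating fewer than
#' `min_compounds` unique compounds are dropped.
#'
#' @param membership Data frame `compound_id`, `category`, `level`,
#'   `term` (one row per compound-term assignment).
#' @param labels Data frame `compound_id`, `label`
#'   (promiscuous/selective), as from [classify_promiscuity()].
#' @param min_compounds Minimum unique compounds per category (default 20).
#' @param family `"per_category_level"` (default) or `"global"` BH family.
#' @return Data frame: `category`, `level`, `term`, the four cell counts
#'   (`promiscuous_in`, `promiscuous_out`, `selective_in`,
#'   `selective_out`), `odds_ratio` (sample cross-product ratio),
#'   `direction`, `p`, `p_fdr`.
#' @export
fisher_enrichment <- function(membership, labels, min_compounds = 20,
                              family = c("per_category_level", "global")) {
  family <- match.arg(family)
  required <- c("compound_id", "category", "level", "term")
  if (!all(required %in% names(membership)))
    stop("membership needs columns: ", paste(required, collapse = ", "))
  universe <- intersect(unique(membership$compound_id), labels$compound_id)
  if (length(universe) == 0) stop("no mapped compounds with labels")
  lab <- setNames(labels$label, labels$compound_id)[universe]
  is_prom <- lab == "promiscuous"
  if (!any(is_prom) || !any(!is_prom))
    stop("both promiscuous and selective compounds required in the universe")
  rows <- list()
  for (cat_name in unique(membership$category)) {
    sub_cat <- membership[membership$category == cat_name, , drop = FALSE]
    if (length(intersect(unique(sub_cat$compound_id), universe)) <
        min_compounds) next
    for (lev in unique(sub_cat$level)) {
      sub <- sub_cat[sub_cat$level == lev, , drop = FALSE]
      terms <- unique(sub$term)
      term_members <- lapply(terms, function(tm)
        intersect(unique(sub$compound_id[sub$term == tm]), universe))
      names(term_members) <- terms
      unassigned <- setdiff(universe, unique(sub$compound_id))
      if (length(unassigned) > 0)
        term_members[["Not assigned"]] <- unassigned
      for (tm in names(term_members)) {
        inset <- universe %in% term_members[[tm]]
        a <- sum(is_prom & inset); b <- sum(is_prom & !inset)
        c_ <- sum(!is_prom & inset); d <- sum(!is_prom & !inset)
        p <- min(1, fisher.test(matrix(c(a, b, c_, d), 2,
                                       byrow = TRUE))$p.value)
        or <- (a * d) / (b * c_)
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat_name, level = lev, term = tm,
          promiscuous_in = a, promiscuous_out = b,
          selective_in = c_, selective_out = d,
          odds_ratio = or,
          direction = if (is.nan(or)) NA_character_ else
            if (or > 1) "enriched" else if (or < 1) "depleted" else "equal",
          p = p, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    stop("no category retained >= ", min_compounds, " mapped compounds")
  out <- do.call(rbind, rows)
  if (family == "global") {
    out$p_fdr <- bh_correct(out$p)
  } else {
    out$p_fdr <- NA_real_
    for (key in unique(paste(out$category, out$level))) {
      sel <- paste(out$category, out$level) == key
      out$p_fdr[sel] <- bh_correct(out$p[sel])
    }
  }
  out[order(out$category, out$level, out$p), ]
}
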