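# Promiscuity propensity statistics over descriptor bins and over
# pocket amino-acid composition.

#' Equal-count interval edges
#'
#' Quantile-style binning: interval edges are placed between consecutive
#' order statistics so that, on tie-free data, bin occupancies differ by
#' at most one. Duplicate edges arising from ties are merged, yielding
#' fewer bins with a warning.
#'
#' @param values Numeric vector (NAs removed).
#' @param n_bins Requested number of bins (>= 2).
#' @return Data frame `lo`, `hi`; intervals are `[lo, hi)` with the last
#'   closed, jointly spanning the observed range.
#' @export
equal_count_bins <- function(values, n_bins) {
  values <- values[!is.na(values)]
  stopifnot(n_bins >= 2)
  if (length(unique(values)) < n_bins)
    stop("fewer distinct values (", length(unique(values)),
         ") than requested bins (", n_bins, ")")
  s <- sort(values)
  n <- length(s)
  idx <- round(seq(0, n, length.out = n_bins + 1))
  inner <- vapply(idx[2:n_bins], function(k) (s[k] + s[k + 1]) / 2,
                  numeric(1))
  edges <- c(s[1], inner, s[n])
  ue <- unique(edges)
  if (length(ue) < length(edges)) {
    warning("tied values merged ", length(edges) - length(ue),
            " bin edge(s); returning fewer bins")
    edges <- ue
  }
  data.frame(lo = edges[-length(edges)], hi = edges[-1])
}

bin_counts <- function(values, bins) {
  edges <- c(bins$lo, bins$hi[nrow(bins)])
  idx <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tabulate(idx, nbins = nrow(bins))
}

propensity_core <- function(q, s) {
  zero_adjusted <- (q == 0 | s == 0)
  if (any(zero_adjusted)) {
    q <- q + 0.5
    s <- s + 0.5
  }
  f <- q / sum(q)
  g <- s / sum(s)
  P <- f / g
  se <- (1 / g) * sqrt(f * (1 - f) / sum(q))
  data.frame(q = q, s = s, f = f, g = g, propensity = P,
             log10_propensity = log10(P), se = se,
             zero_adjusted = zero_adjusted)
}

#' Promiscuity propensity profile of one descriptor
#'
#' Bins the pooled promiscuous-plus-selective descriptor values into
#' near-equal-count intervals and reports, per bin, the ratio of the
#' relative frequency of promiscuous compounds to that of selective
#' compounds: `P_i = (q_i / sum(q)) / (s_i / sum(s))`, log10-transformed,
#' with standard errors `se_i = (1/g_i) * sqrt(f_i (1 - f_i) / sum(q))`.
#' Bins above 1 (positive log propensity) mark descriptor ranges
#' characteristic of promiscuous compounds. If any bin has a zero count a
#' pseudo-count of 0.5 is added to every count of the profile (flagged in
#' the `zero_adjusted` column).
#'
#' @param values Named or unnamed numeric descriptor values, one per
#'   compound (NAs dropped pairwise with the labels).
#' @param labels Character vector, `"promiscuous"` or `"selective"`,
#'   aligned with `values`.
#' @param property Descriptor name (metadata).
#' @param class_label Compound-class selection the profile refers to
#'   (metadata, default `"all"`).
#' @param n_bins Number of equal-count bins (default 10).
#' @param bins Optional explicit intervals (data frame `lo`, `hi`)
#'   overriding the equal-count binning, e.g. to reuse the bins of
#'   another class selection.
#' @return Data frame of class `propensity_profile`: `lo`, `hi`, counts
#'   and the propensity columns, with attributes `property` and `class`.
#' @export
propensity_profile <- function(values, labels, property = "descriptor",
                               class_label = "all", n_bins = 10,
                               bins = NULL) {
  keep <- !is.na(values) & !is.na(labels)
  n_missing <- sum(!keep)
  if (n_missing > 0)
    message(n_missing, " compound(s) without '", property, "' value excluded")
  values <- values[keep]; labels <- labels[keep]
  if (!any(labels == "promiscuous") || !any(labels == "selective"))
    stop("both promiscuous and selective compounds are required")
  if (is.null(bins)) bins <- equal_count_bins(values, n_bins)
  q <- bin_counts(values[labels == "promiscuous"], bins)
  s <- bin_counts(values[labels == "selective"], bins)
  out <- cbind(bins, propensity_core(q, s))
  attr(out, "property") <- property
  attr(out, "class") <- class_label
  class(out) <- c("propensity_profile", "data.frame")
  out
}

#' Amino-acid composition propensities of binding pockets
#'
#' Compares the residue-type composition of binding pockets against the
#' composition of the non-pocket parts of the target chains, using the
#' same propensity ratio as [propensity_profile()] with `q_i` the count
#' of residue type `i` aggregated over pockets and `s_i` the count over
#' chain residues not in any pocket. Positive log propensities mark
#' residue types over-represented in binding sites. Call once per group
#' (compound class or promiscuity label) by subsetting `pockets`;
#' `all_pockets` should remain the full pocket set so that the background
#' never includes any binding-site residue.
#'
#' @param pockets Pockets of the analyzed group (list of `bind_pocket`).
#' @param chains Named list of `bind_chain` keyed
#'   `"<structure_id>.<chain_id>"`.
#' @param all_pockets Full pocket set defining binding-site residues for
#'   the background (defaults to `pockets`).
#' @return Data frame: `res_type`, `q`, `s`, `propensity`,
#'   `log10_propensity`, `se`, `zero_adjusted`; residue types absent from
#'   both pockets and background are omitted.
#' @export
composition_propensity <- function(pockets, chains, all_pockets = pockets) {
  if (length(pockets) == 0) stop("no pockets in the analyzed group")
  q <- Reduce(`+`, lapply(pockets, `[[`, "composition"))
  # residues belonging to any pocket, per chain
  in_pocket <- list()
  for (p in all_pockets) {
    key <- paste(p$structure_id, p$chain_id, sep = ".")
    in_pocket[[key]] <- union(in_pocket[[key]],
                              paste(p$residues$seq_number, p$residues$ins))
  }
  s <- setNames(integer(20), AA_TYPES)
  for (key in names(chains)) {
    ch <- chains[[key]]
    res_key <- paste(ch$residues$seq_number, ch$residues$ins)
    bg <- ch$residues$res_type[!(res_key %in% in_pocket[[key]])]
    s <- s + residue_composition(bg)
  }
  if (sum(s) == 0) stop("no non-pocket residues available as background")
  present <- (q + s) > 0
  core <- propensity_core(as.numeric(q[present]), as.numeric(s[present]))
  cbind(data.frame(res_type = AA_TYPES[present], stringsAsFactors = FALSE),
        core)
}
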