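# Hashed path-based molecular fingerprints and Tanimoto similarity.

#' Hashed linear-path fingerprint
#'
#' Enumerates all simple linear paths of up to `max_len` atoms through the
#' heavy-atom graph, labels each path by its element symbols and bond
#' orders (taking the lexicographically smaller reading direction so the
#' label is orientation-free), and hashes the labels into a fixed-length
#' bit set. This is a configurable, dependency-light scheme of the same
#' family as path-based "extended" fingerprints used for near-identity
#' compound matching; it is not bit-compatible with any particular
#' cheminformatics engine.
#'
#' @param elements Heavy-atom element symbols.
#' @param bonds Data frame `a1`, `a2`, `order`.
#' @param nbits Fingerprint length (default 1024).
#' @param max_len Maximum path length in atoms (default 5).
#' @return Logical vector of length `nbits`.
#' @export
path_fingerprint <- function(elements, bonds, nbits = 1024, max_len = 5) {
  n <- length(elements)
  fp <- logical(nbits)
  if (n == 0) return(fp)
  adj <- vector("list", n)
  bord <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$a1[k]; j <- bonds$a2[k]; o <- bonds$order[k]
      adj[[i]] <- c(adj[[i]], j); bord[[i]] <- c(bord[[i]], o)
      adj[[j]] <- c(adj[[j]], i); bord[[j]] <- c(bord[[j]], o)
    }
  }
  labels <- character(0)
  walk <- function(path, blab) {
    at <- path[length(path)]
    lab_f <- path_label(elements[path], blab)
    lab_r <- path_label(rev(elements[path]), rev(blab))
    labels[[length(labels) + 1L]] <<- if (lab_f <= lab_r) lab_f else lab_r
    if (length(path) >= max_len) return(invisible())
    nb <- adj[[at]]
    for (t in seq_along(nb)) {
      if (!(nb[t] %in% path)) walk(c(path, nb[t]), c(blab, bord[[at]][t]))
    }
  }
  for (s in seq_len(n)) walk(s, numeric(0))
  idx <- unique(vapply(labels, hash_string, numeric(1), USE.NAMES = FALSE) %% nbits) + 1
  fp[idx] <- TRUE
  fp
}

path_label <- function(els, orders) {
  if (length(orders) == 0) return(els)
  paste(c(rbind(els[-length(els)], orders), els[length(els)]), collapse = "~")
}

hash_string <- function(s) {
  h <- 7
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 1048573
  h
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` on equal-length bit sets. Two all-zero
#' fingerprints are defined as identical (similarity 1) with a warning.
#'
#' @param fp_a,fp_b Logical vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b))
    stop("fingerprint length mismatch: ", length(fp_a), " vs ", length(fp_b))
  uni <- sum(fp_a | fp_b)
  if (uni == 0) {
    warning("both fingerprints empty; similarity defined as 1")
    return(1)
  }
  sum(fp_a & fp_b) / uni
}
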