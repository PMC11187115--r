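#' Build a molecular network from MS/MS spectra
#'
#' Computes pairwise modified-cosine similarities on filtered spectra and
#' keeps an edge when the score reaches `cosine_cutoff` and at least
#' `min_matched` fragment pairs align. Connected components ("molecular
#' families") larger than `family_cap` are pruned by repeatedly deleting the
#' lowest-scoring edge inside an oversized component until the cap holds.
#'
#' Spectra whose precursors differ by no more than `precursor_tol` are treated
#' as the same precursor species: their comparison uses direct fragment
#' matches only (no precursor-shifted matches).
#'
#' @param spectra List of `"spectrum"` objects.
#' @param precursor_tol Precursor ion mass tolerance in Da (default 0.02).
#' @param cosine_cutoff Minimum modified cosine for an edge (default 0.7).
#' @param min_matched Minimum matched fragment pairs (default 4, i.e. "more
#'   than three").
#' @param family_cap Maximum molecular family size (default 100).
#' @param fragment_tol Fragment match tolerance in Da (default 0.05).
#' @param preprocess Apply [preprocess_spectrum()] first (default TRUE).
#' @return A `"molecular_network"`: list with `nodes` (spectrum ids), `edges`
#'   (data frame: `source`, `target`, `score`, `matched`, `delta_mz`) and
#'   `membership` (data frame: `node`, `component`).
#' @export
build_network <- function(spectra, precursor_tol = 0.02, cosine_cutoff = 0.7,
                          min_matched = 4L, family_cap = 100L,
                          fragment_tol = 0.05, preprocess = TRUE) {
  if (!length(spectra)) stop("need at least one spectrum", call. = FALSE)
  stopifnot(all(vapply(spectra, inherits, logical(1), "spectrum")))
  ids <- vapply(spectra, function(s) s$id, character(1))
  if (anyNA(ids) || anyDuplicated(ids))
    ids <- make.unique(ifelse(is.na(ids), "spec", ids))
  if (preprocess) spectra <- lapply(spectra, preprocess_spectrum)
  n <- length(spectra)
  src <- tgt <- integer(0); sc <- dm <- numeric(0); mt <- integer(0)
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      dprec <- spectra[[i]]$precursor_mz - spectra[[j]]$precursor_mz
      res <- modified_cosine(spectra[[i]], spectra[[j]],
                             fragment_tol = fragment_tol,
                             allow_precursor_shift = abs(dprec) > precursor_tol)
      if (res$score >= cosine_cutoff && res$matched >= min_matched) {
        src <- c(src, i); tgt <- c(tgt, j)
        sc <- c(sc, res$score); mt <- c(mt, res$matched); dm <- c(dm, dprec)
      }
    }
  }
  edges <- data.frame(source = ids[src], target = ids[tgt], score = sc,
                      matched = mt, delta_mz = dm,
                      stringsAsFactors = FALSE)
  edges <- .prune_families(edges, ids, family_cap)
  membership <- .components(edges, ids)
  structure(list(nodes = ids, edges = edges, membership = membership),
            class = "molecular_network")
}

.components <- function(edges, ids) {
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target")], directed = FALSE,
    vertices = data.frame(name = ids))
  cmp <- igraph::components(g)
  data.frame(node = ids, component = unname(cmp$membership[ids]),
             stringsAsFactors = FALSE)
}

## Remove globally lowest-score edges from oversized components until every
## family respects the cap.
.prune_families <- function(edges, ids, family_cap) {
  repeat {
    if (!nrow(edges)) return(edges)
    mem <- .components(edges, ids)
    sizes <- table(mem$component)
    over <- as.integer(names(sizes)[sizes > family_cap])
    if (!length(over)) return(edges)
    comp_of <- stats::setNames(mem$component, mem$node)
    in_over <- comp_of[edges$source] %in% over
    cand <- which(in_over)
    drop <- cand[which.min(edges$score[cand])]
    edges <- edges[-drop, , drop = FALSE]
  }
}

#' @export
print.molecular_network <- function(x, ...) {
  nfam <- length(unique(x$membership$component))
  cat(sprintf("<molecular_network> %d nodes, %d edges, %d components\n",
              length(x$nodes), nrow(x$edges), nfam))
  invisible(x)
}
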