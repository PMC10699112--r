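# Over-representation analysis: one-tailed hypergeometric test of a
# query gene set against flat term annotations, BH control within an
# annotation source, consensus across two sources, and extraction of
# the genes covered by the significant terms.

#' Construct an annotation set
#'
#' @param terms Named list: term id -> character vector of member
#'   genes.  Empty terms are rejected.
#' @param descriptions Optional named character vector of term
#'   descriptions.
#' @param universe Background gene universe; defaults to the union of
#'   all term members.  Every member must belong to it.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(terms, descriptions = NULL, universe = NULL) {
  if (length(terms) == 0L) stop("no terms given")
  if (is.null(names(terms)) || anyDuplicated(names(terms)))
    stop("terms must be uniquely named")
  if (any(vapply(terms, length, 1L) == 0L)) stop("empty terms are not allowed")
  terms <- lapply(terms, function(x) sort(unique(as.character(x))))
  members <- sort(unique(unlist(terms, use.names = FALSE)))
  if (is.null(universe)) universe <- members
  if (!all(members %in% universe)) stop("term members outside the universe")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(terms)), names(terms))
  structure(list(terms = terms, descriptions = descriptions,
                 universe = sort(unique(universe))),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation set:", length(x$terms), "terms over a universe of",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Hypergeometric over-representation test
#'
#' For each term computes the upper-tail probability
#' `P[X >= k]`, `X ~ Hypergeom(N_u, K, n)` — the one-tailed variant of
#' Fisher's exact test — where `k` is the query/term overlap, `K` the
#' term size, `n` the (universe-restricted) query size and `N_u` the
#' universe size.  P-values are BH-adjusted across the tested terms.
#'
#' @param query Nonempty character vector; genes outside the universe
#'   are dropped with a logged count.
#' @param annotations An [annotation_set].
#' @param alpha Adjusted-p cutoff for the `enriched` flag.
#' @return Data frame of class `enrichment_table`: `term_id`,
#'   `description`, `k`, `K`, `n`, `N_u`, `p_raw`, `p_adj`, `enriched`,
#'   ordered by `p_raw`.
#' @export
hypergeom_enrich <- function(query, annotations, alpha = 0.05) {
  stopifnot(inherits(annotations, "annotation_set"))
  query <- unique(as.character(query))
  if (length(query) == 0L) stop("query is empty")
  outside <- setdiff(query, annotations$universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  if (length(query) == 0L) stop("query is empty after restriction to the universe")
  N_u <- length(annotations$universe)
  n <- length(query)
  K <- vapply(annotations$terms, length, 1L)
  k <- vapply(annotations$terms, function(m) length(intersect(m, query)), 1L)
  p_raw <- stats::phyper(k - 1L, K, N_u - K, n, lower.tail = FALSE)
  p_adj <- adjust_bh(p_raw)
  res <- data.frame(term_id = names(annotations$terms),
                    description = unname(annotations$descriptions[names(annotations$terms)]),
                    k = unname(k), K = unname(K), n = n, N_u = N_u,
                    p_raw = unname(p_raw), p_adj = unname(p_adj),
                    enriched = unname(p_adj < alpha),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_table", "data.frame")
  res
}

#' Consensus of two enrichment runs
#'
#' Terms called enriched by both runs (the study's "common biological
#' processes of the two databases" step).
#'
#' @param run_a,run_b `enrichment_table`s (or character vectors of
#'   enriched term ids).
#' @return Sorted character vector of common enriched term ids.
#' @export
consensus_terms <- function(run_a, run_b) {
  ids <- function(r) if (is.character(r)) r else r$term_id[r$enriched]
  a <- ids(run_a); b <- ids(run_b)
  if ((is.data.frame(run_a) && nrow(run_a) == 0L) ||
      (is.data.frame(run_b) && nrow(run_b) == 0L)) stop("both runs must be nonempty")
  common <- sort(intersect(a, b))
  if (length(common) == 0L) warning("no consensus: enriched term sets are disjoint")
  common
}

#' Genes covered by a set of enriched terms
#'
#' Union over the enriched terms of the term members intersected with
#' the query — the "functionally enriched genes" carried into the GRN
#' stage.
#'
#' @param enriched_terms Character vector of term ids (subset of the
#'   annotation's terms).
#' @param annotations An [annotation_set].
#' @param query The gene set that was tested.
#' @return Sorted character vector of genes.
#' @export
enriched_gene_pool <- function(enriched_terms, annotations, query) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (!all(enriched_terms %in% names(annotations$terms)))
    stop("enriched_terms contains ids absent from the annotation set")
  if (length(enriched_terms) == 0L) return(character(0))
  pool <- unique(unlist(annotations$terms[enriched_terms], use.names = FALSE))
  sort(intersect(pool, query))
}
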