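# Network reconstruction and hierarchy analysis: phase PPIN and GRN
# assembly, integration into a directed TF-TF / TF-TG / TG-TG cascade,
# the hierarchy index v = (out - in) / (out + in), and master-regulator
# calls (v == 1).

#' Construct an undirected interaction network
#'
#' Normalizes an edge table: endpoints sorted within each edge,
#' self-loops dropped, duplicate undirected edges collapsed.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b` (or any two
#'   character columns).
#' @return Object of class `interaction_network`: list with `edges`
#'   (normalized data frame) and `nodes`.
#' @export
interaction_network <- function(edges) {
  if (ncol(edges) < 2L) stop("edge table needs two columns")
  df <- data.frame(gene_a = as.character(edges[[1]]),
                   gene_b = as.character(edges[[2]]), stringsAsFactors = FALSE)
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]; df$gene_a[swap] <- df$gene_b[swap]; df$gene_b[swap] <- tmp
  df <- unique(df)
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(edges = df, nodes = sort(unique(c(df$gene_a, df$gene_b)))),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction network:", length(x$nodes), "nodes,", nrow(x$edges), "undirected edges\n")
  invisible(x)
}

#' Construct a directed regulatory network
#'
#' @param edges Data frame with columns `tf`, `target`.  Duplicate
#'   directed edges are collapsed; TF self-loops are dropped (counting
#'   autoregulation as an incoming edge would silently disqualify
#'   autoregulatory master regulators from the v = 1 call).
#' @return Object of class `regulatory_network`: list with `edges`,
#'   `tfs`, `targets`.
#' @export
regulatory_network <- function(edges) {
  if (ncol(edges) < 2L) stop("edge table needs two columns")
  df <- data.frame(tf = as.character(edges[[1]]),
                   target = as.character(edges[[2]]), stringsAsFactors = FALSE)
  n_self <- sum(df$tf == df$target)
  if (n_self > 0L) message("dropping ", n_self, " TF self-loop(s)")
  df <- unique(df[df$tf != df$target, , drop = FALSE])
  df <- df[order(df$tf, df$target), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(edges = df, tfs = sort(unique(df$tf)),
                 targets = sort(unique(df$target))),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory network:", length(x$tfs), "TFs ->", length(x$targets),
      "targets,", nrow(x$edges), "directed edges\n")
  invisible(x)
}

#' Build a phase PPIN from seed genes and a global interaction network
#'
#' Induces the subnetwork on the seed genes, optionally expanded by
#' their first neighbours.  Seed genes left without any edge are
#' dropped (their count is logged).
#'
#' @param seed_genes Nonempty character vector.
#' @param global_interactions An [interaction_network] (or edge data
#'   frame).
#' @param expand_neighbors Include first neighbours of seeds before
#'   inducing the subnetwork.
#' @return An [interaction_network] restricted to the retained nodes.
#' @export
build_ppin <- function(seed_genes, global_interactions, expand_neighbors = TRUE) {
  if (length(seed_genes) == 0L) stop("seed_genes must be nonempty")
  if (!inherits(global_interactions, "interaction_network"))
    global_interactions <- interaction_network(global_interactions)
  ed <- global_interactions$edges
  if (!any(seed_genes %in% global_interactions$nodes))
    stop("no seed gene occurs in the global interaction network")
  keep_nodes <- intersect(seed_genes, global_interactions$nodes)
  if (expand_neighbors) {
    nb <- c(ed$gene_b[ed$gene_a %in% keep_nodes], ed$gene_a[ed$gene_b %in% keep_nodes])
    keep_nodes <- union(keep_nodes, nb)
  }
  sub <- ed[ed$gene_a %in% keep_nodes & ed$gene_b %in% keep_nodes, , drop = FALSE]
  if (nrow(sub) == 0L) stop("induced subnetwork is empty")
  net <- interaction_network(sub)
  dropped <- setdiff(intersect(seed_genes, global_interactions$nodes), net$nodes)
  if (length(dropped))
    message(length(dropped), " isolated seed gene(s) dropped from the PPIN")
  net
}

#' Build a phase GRN by restricting a binding table to target genes
#'
#' Keeps the edges whose target lies in `target_genes`; TFs losing all
#' their targets are excluded.  TFs that are themselves target genes
#' keep both roles.
#'
#' @param target_genes Nonempty character vector.
#' @param binding_table A [regulatory_network] (or edge data frame).
#' @return A [regulatory_network].
#' @export
build_grn <- function(target_genes, binding_table) {
  if (length(target_genes) == 0L) stop("target_genes must be nonempty")
  if (!inherits(binding_table, "regulatory_network"))
    binding_table <- regulatory_network(binding_table)
  sub <- binding_table$edges[binding_table$edges$target %in% target_genes, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no TF in the binding table targets any of the given genes")
  regulatory_network(sub)
}

#' Top transcription factors by mean target count
#'
#' The cutoff is the mean, over TFs, of the number of distinct targets
#' each regulates; the returned TFs are those strictly above it.
#'
#' @param grn A [regulatory_network].
#' @return List with `tfs` (character vector), `cutoff` (numeric) and
#'   `target_counts` (named vector).
#' @export
top_tfs <- function(grn) {
  if (!inherits(grn, "regulatory_network")) grn <- regulatory_network(grn)
  if (length(grn$tfs) == 0L) stop("GRN has no TFs")
  counts <- table(grn$edges$tf)
  cutoff <- mean(counts)
  list(tfs = sort(names(counts)[counts > cutoff]), cutoff = unname(cutoff),
       target_counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Hierarchy index of a node
#'
#' `v = (out - in) / (out + in)`, in `[-1, 1]`: 1 for a pure source
#' (master-regulator candidate), -1 for a pure sink.  Vectorized.
#'
#' @param in_deg,out_deg Nonnegative integer degrees; `in + out >= 1`
#'   (isolated nodes must be excluded by the caller).
#' @return Numeric vector of hierarchy indices.
#' @export
hierarchy_index <- function(in_deg, out_deg) {
  if (any(in_deg < 0 | out_deg < 0)) stop("degrees must be nonnegative")
  if (any(in_deg + out_deg == 0)) stop("hierarchy index undefined for isolated nodes")
  (out_deg - in_deg) / (out_deg + in_deg)
}

#' Integrate GRN and PPIN into a hierarchical directed cascade
#'
#' Directed edges are the union of: all GRN edges, labelled `TF-TF`
#' when the target is itself a TF and `TF-TG` otherwise; and, for every
#' PPIN edge between two non-TF nodes, a reciprocal pair of directed
#' edges labelled `TG-TG` (undirected physical interactions carry no
#' hierarchy information, so they enter symmetrically and leave target
#' genes hierarchically neutral).  PPIN edges touching a TF are not
#' added.  Node roles: `MR` for TFs with `v == 1` and at least one
#' outgoing edge, `TF` for the remaining TFs, `TG` otherwise.
#'
#' @param grn A [regulatory_network].
#' @param ppin An [interaction_network].
#' @return Object of class `integrated_cascade`: list with `nodes`
#'   (data frame `gene_id`, `in_deg`, `out_deg`, `v`, `role`), `edges`
#'   (data frame `source`, `target`, `layer`) and `tf_set`.
#' @export
integrate_cascade <- function(grn, ppin) {
  if (!inherits(grn, "regulatory_network")) grn <- regulatory_network(grn)
  if (!inherits(ppin, "interaction_network")) ppin <- interaction_network(ppin)
  tf_set <- grn$tfs
  ge <- grn$edges
  grn_layer <- ifelse(ge$target %in% tf_set, "TF-TF", "TF-TG")
  pe <- ppin$edges[!(ppin$edges$gene_a %in% tf_set) & !(ppin$edges$gene_b %in% tf_set), , drop = FALSE]
  edges <- rbind(
    data.frame(source = ge$tf, target = ge$target, layer = grn_layer,
               stringsAsFactors = FALSE),
    data.frame(source = c(pe$gene_a, pe$gene_b), target = c(pe$gene_b, pe$gene_a),
               layer = "TG-TG", stringsAsFactors = FALSE))
  edges <- edges[!duplicated(edges[, c("source", "target")]), , drop = FALSE]
  if (nrow(edges) == 0L) stop("integrated cascade is empty")
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$source, edges$target)))
  out_deg <- stats::setNames(rep(0L, length(nodes)), nodes)
  in_deg <- out_deg
  ot <- table(edges$source); it <- table(edges$target)
  out_deg[names(ot)] <- as.integer(ot)
  in_deg[names(it)] <- as.integer(it)
  v <- hierarchy_index(in_deg, out_deg)
  role <- ifelse(nodes %in% tf_set,
                 ifelse(v == 1 & out_deg >= 1L, "MR", "TF"), "TG")
  node_df <- data.frame(gene_id = nodes, in_deg = unname(in_deg),
                        out_deg = unname(out_deg), v = unname(v), role = role,
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = node_df, edges = edges, tf_set = tf_set),
            class = "integrated_cascade")
}

#' @export
print.integrated_cascade <- function(x, ...) {
  cat("integrated cascade:", nrow(x$nodes), "nodes,", nrow(x$edges), "directed edges\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$nodes$role)),
                                table(x$nodes$role)), collapse = ", "), "\n")
  invisible(x)
}

#' Identify master regulators of an integrated cascade
#'
#' Master regulators are the TF nodes at the apex of the hierarchy:
#' hierarchy index exactly 1 (no incoming edges, at least one outgoing
#' edge).
#'
#' @param cascade An [integrated_cascade].
#' @return Sorted character vector of MR gene ids (possibly empty, with
#'   a warning).
#' @export
identify_mrs <- function(cascade) {
  if (!inherits(cascade, "integrated_cascade")) stop("cascade must be an integrated_cascade")
  mrs <- cascade$nodes$gene_id[cascade$nodes$role == "MR"]
  if (length(mrs) == 0L) warning("no node with hierarchy index 1: empty MR set")
  sort(mrs)
}
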