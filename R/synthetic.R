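# Synthetic-data generators.  These stand in for the microarray,
# STRING/YEASTRACT and Ensembl inputs of the original study: every
# generator plants a known ground truth (up-regulated genes, master
# regulators, enriched terms, per-pair omega) so each downstream stage
# has a parameter-recovery test.

#' Simulation configuration
#'
#' Central parameter object for the synthetic study.  Defaults describe
#' a small but realistic two-condition microarray contrast (log2
#' intensities around 6-10 with noise SD 0.3, planted 2-fold-plus
#' effects), a sparse interaction network, and codon pairs of 300
#' codons at moderate divergence.
#'
#' @param seed Integer seed; identical seeds give identical outputs.
#' @param n_genes Number of genes in the universe.
#' @param n_samples_per_condition Samples per condition (>= 2).
#' @param n_planted_up Number of genes planted as up-regulated.
#' @param planted_lfc Planted log2 fold-change.
#' @param noise_sd SD of log2 intensities within condition.
#' @param n_tfs Number of transcription factors.
#' @param n_planted_mrs Number of TFs planted as master regulators
#'   (no incoming regulatory edges).
#' @param mean_targets Mean number of targets per TF.
#' @param ppin_edge_prob Edge probability of the Erdos-Renyi PPIN.
#' @param ppin_model `"erdos_renyi"` or `"preferential_attachment"`.
#' @param pa_m Edges added per node under preferential attachment.
#' @param n_terms Number of annotation terms.
#' @param term_sizes Term sizes (recycled to `n_terms`).
#' @param n_planted_terms Number of terms planted as enriched.
#' @param planted_frac Fraction of a planted term's members drawn from
#'   the target set.
#' @param n_codons Codons per simulated alignment (>= 50).
#' @param divergence Expected substitution attempts per codon for a
#'   pair (split evenly over the two branches).
#' @param omega_by_group Named numeric: target omega per phase label.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 1000L, n_samples_per_condition = 5L,
                       n_planted_up = 50L, planted_lfc = 2, noise_sd = 0.3,
                       n_tfs = 20L, n_planted_mrs = 3L, mean_targets = 8,
                       ppin_edge_prob = 0.01, ppin_model = c("erdos_renyi", "preferential_attachment"),
                       pa_m = 3L, n_terms = 50L, term_sizes = 30L,
                       n_planted_terms = 5L, planted_frac = 0.8,
                       n_codons = 300L, divergence = 0.6,
                       omega_by_group = c(initiation = 0.3, commitment = 0.1)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_samples_per_condition = as.integer(n_samples_per_condition),
              n_planted_up = as.integer(n_planted_up), planted_lfc = planted_lfc,
              noise_sd = noise_sd, n_tfs = as.integer(n_tfs),
              n_planted_mrs = as.integer(n_planted_mrs), mean_targets = mean_targets,
              ppin_edge_prob = ppin_edge_prob, ppin_model = match.arg(ppin_model),
              pa_m = as.integer(pa_m), n_terms = as.integer(n_terms),
              term_sizes = as.integer(term_sizes),
              n_planted_terms = as.integer(n_planted_terms), planted_frac = planted_frac,
              n_codons = as.integer(n_codons), divergence = divergence,
              omega_by_group = omega_by_group)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes <= 0L || n_samples_per_condition <= 0L || n_tfs <= 0L)
      stop("counts must be positive")
    if (n_planted_up < 0L || n_planted_up > n_genes)
      stop("n_planted_up must lie in [0, n_genes]")
    if (!(n_planted_mrs <= n_tfs && n_tfs <= n_genes))
      stop("need n_planted_mrs <= n_tfs <= n_genes")
    if (noise_sd <= 0) stop("noise_sd must be > 0")
    if (any(omega_by_group <= 0)) stop("planted omega values must be > 0")
    if (n_codons < 50L) stop("n_codons must be >= 50")
    if (planted_frac < 0 || planted_frac > 1) stop("planted_frac must lie in [0, 1]")
    if (n_planted_terms > n_terms) stop("n_planted_terms must be <= n_terms")
  })
  invisible(cfg)
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate a two-condition expression dataset with planted DE genes
#'
#' Log2 intensities are drawn as gene baselines (uniform on 6..10) plus
#' Gaussian noise; planted genes get `planted_lfc` added in the
#' treatment condition.  The returned matrix is on the linear scale, so
#' the differential-expression stage's log transform round-trips.
#'
#' @param config A [sim_config].
#' @param contrast_label Label stored with the dataset (e.g. the name
#'   of the emulated contrast).
#' @param planted_gene_ids Optional explicit set of genes to plant
#'   (default: sampled).
#' @param planted_lfc Log2 fold-change planted in the treatment
#'   condition (default from `config`; negative plants
#'   down-regulation).
#' @param seed Seed override (default from `config`).
#' @return List with `dataset` (an `expression_dataset`: linear-scale
#'   `matrix`, `condition_of`, `gene_ids`, `sample_ids`) and `truth`
#'   (`up_gene_ids`, empty when `planted_lfc <= 0`).
#' @export
simulate_expression <- function(config, contrast_label = "treatment_vs_control",
                                planted_gene_ids = NULL,
                                planted_lfc = config$planted_lfc,
                                seed = config$seed) {
  validate_sim_config(config)
  if (config$n_samples_per_condition < 2L)
    stop("need >= 2 samples per condition")
  set.seed(seed)
  g <- gene_ids(config$n_genes)
  ns <- config$n_samples_per_condition
  samples <- c(sprintf("ctl_%02d", seq_len(ns)), sprintf("trt_%02d", seq_len(ns)))
  condition_of <- stats::setNames(rep(c("control", "treatment"), each = ns), samples)
  if (is.null(planted_gene_ids)) {
    planted_gene_ids <- sort(sample(g, config$n_planted_up))
  } else {
    stopifnot(all(planted_gene_ids %in% g))
  }
  baseline <- stats::runif(config$n_genes, 6, 10)
  mu <- matrix(baseline, config$n_genes, 2 * ns)
  mu[g %in% planted_gene_ids, condition_of == "treatment"] <-
    mu[g %in% planted_gene_ids, condition_of == "treatment"] + planted_lfc
  log2mat <- mu + matrix(stats::rnorm(length(mu), sd = config$noise_sd),
                         nrow = nrow(mu))
  mat <- 2^log2mat
  dimnames(mat) <- list(g, samples)
  dataset <- structure(list(matrix = mat, condition_of = condition_of,
                            gene_ids = g, sample_ids = samples,
                            contrast_label = contrast_label),
                       class = "expression_dataset")
  list(dataset = dataset,
       truth = list(up_gene_ids = if (planted_lfc > 0) planted_gene_ids else character(0),
                    planted_gene_ids = planted_gene_ids))
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression dataset:", length(x$gene_ids), "genes x", length(x$sample_ids),
      "samples;", x$contrast_label, "\n")
  cat("  conditions:", paste(sprintf("%s (n=%d)", names(table(x$condition_of)),
                                     table(x$condition_of)), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate interaction and regulation networks with planted MRs
#'
#' The undirected interaction network (PPIN stand-in) is Erdos-Renyi by
#' default.  The directed TF-to-target table plants `n_planted_mrs`
#' master regulators: they receive no incoming regulatory edge from any
#' TF and regulate at least one target; every non-MR TF receives at
#' least one incoming edge.  Regulatory targets never include MRs and
#' self-loops are never emitted.
#'
#' @param config A [sim_config].
#' @return List with `interactions` (data frame `gene_a`, `gene_b`),
#'   `regulation` (data frame `tf`, `target`) and `truth` (`mr_ids`,
#'   `tf_ids`).
#' @export
simulate_networks <- function(config) {
  validate_sim_config(config)
  if (config$n_planted_mrs < 1L) stop("need n_planted_mrs >= 1")
  set.seed(config$seed + 1L)
  g <- gene_ids(config$n_genes)
  tfs <- sort(sample(g, config$n_tfs))
  mrs <- sort(sample(tfs, config$n_planted_mrs))
  non_mr_tfs <- setdiff(tfs, mrs)

  # regulation: forbidden targets are the MRs themselves
  allowed_targets <- setdiff(g, mrs)
  edges <- list()
  # every non-MR TF gets >= 1 incoming edge from another TF
  for (tf in non_mr_tfs) {
    src <- sample(setdiff(tfs, tf), 1L)
    edges[[length(edges) + 1L]] <- c(src, tf)
  }
  # every TF regulates >= 1 target plus a Poisson number of extras
  for (tf in tfs) {
    k <- 1L + stats::rpois(1L, max(config$mean_targets - 1, 0))
    tgt <- sample(setdiff(allowed_targets, tf), min(k, length(allowed_targets) - 1L))
    for (t in tgt) edges[[length(edges) + 1L]] <- c(tf, t)
  }
  reg <- unique(do.call(rbind, edges))
  regulation <- data.frame(tf = reg[, 1], target = reg[, 2], stringsAsFactors = FALSE)
  regulation <- regulation[order(regulation$tf, regulation$target), ]
  rownames(regulation) <- NULL

  interactions <- switch(config$ppin_model,
    erdos_renyi = {
      ig <- igraph::sample_gnp(config$n_genes, config$ppin_edge_prob)
      el <- igraph::as_edgelist(ig)
      data.frame(gene_a = g[el[, 1]], gene_b = g[el[, 2]], stringsAsFactors = FALSE)
    },
    preferential_attachment = {
      ig <- igraph::sample_pa(config$n_genes, m = config$pa_m, directed = FALSE)
      el <- igraph::as_edgelist(ig)
      data.frame(gene_a = g[el[, 1]], gene_b = g[el[, 2]], stringsAsFactors = FALSE)
    })
  # normalize undirected edges: sorted endpoints, no self-loops, unique
  swap <- interactions$gene_a > interactions$gene_b
  tmp <- interactions$gene_a[swap]
  interactions$gene_a[swap] <- interactions$gene_b[swap]
  interactions$gene_b[swap] <- tmp
  interactions <- unique(interactions[interactions$gene_a != interactions$gene_b, ])
  interactions <- interactions[order(interactions$gene_a, interactions$gene_b), ]
  rownames(interactions) <- NULL

  list(interactions = interactions, regulation = regulation,
       truth = list(mr_ids = mrs, tf_ids = tfs))
}

# --- codon-pair evolution ----------------------------------------------------

# Pre-computed proposal structure: for each codon index and position,
# the non-stop single-base neighbours.  Proposals are uniform over
# positions, then uniform over the non-stop alternatives at that
# position, so the realized synonymous/nonsynonymous substitution-rate
# ratio equals omega measured in NG86 site units (see the methods
# vignette for why stop-creating proposals are resampled rather than
# counted as rejections).
codon_proposal_table <- function() {
  if (is.null(.ng86_env$prop)) {
    aa <- genetic_code_vector()
    nbr <- codon_neighbors()
    prop <- vector("list", 64L)
    for (i in which(aa != "*")) {
      per_pos <- vector("list", 3L)
      for (p in 1:3) {
        alt <- nbr[i, p, ]
        alt <- alt[aa[alt] != "*"]
        per_pos[[p]] <- alt
      }
      prop[[i]] <- per_pos
    }
    .ng86_env$prop <- prop
  }
  .ng86_env$prop
}

#' Simulate an in-frame codon alignment pair under target omega
#'
#' Two sequences descend from a common random ancestor of sense codons.
#' Each branch receives a Poisson number of substitution attempts
#' (`divergence / 2` expected attempts per codon).  An attempt picks a
#' codon, a position, and a non-stop alternative base; synonymous
#' changes are accepted with probability 1, nonsynonymous changes with
#' probability `omega_target`.  Stop codons can never arise, and
#' alignments are gap-free by construction.
#'
#' @param n_codons Number of codons (>= 50).
#' @param omega_target Target dN/dS in (0, 1]; values > 1 are not
#'   supported (the study's regime is purifying selection throughout).
#' @param divergence Expected substitution attempts per codon for the
#'   pair (> 0, or 0 for identical sequences).
#' @param seed Integer seed.
#' @param meta Optional metadata list passed to the alignment object.
#' @return List with `pair` (a [codon_alignment_pair]), `omega_true`,
#'   and `accepted` (realized counts of accepted synonymous and
#'   nonsynonymous changes per branch).
#' @export
simulate_codon_pair <- function(n_codons, omega_target, divergence, seed,
                                meta = list()) {
  if (n_codons < 50L) stop("n_codons must be >= 50")
  if (omega_target <= 0) stop("omega_target must be > 0")
  if (omega_target > 1) stop("omega_target > 1 is not supported (purifying regime only)")
  if (divergence < 0) stop("divergence must be >= 0")
  set.seed(seed)
  aa <- genetic_code_vector()
  sense <- which(aa != "*")
  prop <- codon_proposal_table()
  ancestor <- sample(sense, n_codons, replace = TRUE)

  evolve <- function(seq_idx) {
    n_attempts <- stats::rpois(1L, divergence / 2 * n_codons)
    acc <- c(syn = 0L, nonsyn = 0L)
    for (k in seq_len(n_attempts)) {
      j <- sample.int(n_codons, 1L)
      p <- sample.int(3L, 1L)
      alts <- prop[[seq_idx[j]]][[p]]
      new <- alts[sample.int(length(alts), 1L)]
      if (aa[new] == aa[seq_idx[j]]) {
        seq_idx[j] <- new
        acc["syn"] <- acc["syn"] + 1L
      } else if (stats::runif(1L) < omega_target) {
        seq_idx[j] <- new
        acc["nonsyn"] <- acc["nonsyn"] + 1L
      }
    }
    list(seq = seq_idx, accepted = acc)
  }
  a <- evolve(ancestor)
  b <- evolve(ancestor)
  pair <- codon_alignment_pair(paste(index_codon(a$seq), collapse = ""),
                               paste(index_codon(b$seq), collapse = ""),
                               meta = meta)
  list(pair = pair, omega_true = omega_target,
       accepted = list(branch_a = a$accepted, branch_b = b$accepted))
}

#' Simulate annotation gene sets with planted enrichment
#'
#' Most terms draw members uniformly from the gene universe; the first
#' `n_planted_terms` terms draw `planted_frac` of their members from
#' `target_set`, making them detectably over-represented in any query
#' overlapping `target_set`.  When `target_set` is a named list of
#' gene sets (e.g. one signature per phase), planted terms cycle over
#' the sets so each set gets phase-coherent enriched terms.
#'
#' @param config A [sim_config].
#' @param target_set Character vector of genes (subset of the
#'   universe) that planted terms over-sample, or a named list of such
#'   vectors.
#' @return List with `annotations` (an `annotation_set`, see
#'   [annotation_set]) and `truth` (`enriched_term_ids`, plus
#'   `planted_target` naming the target set each planted term drew
#'   from).
#' @export
simulate_annotations <- function(config, target_set) {
  validate_sim_config(config)
  g <- gene_ids(config$n_genes)
  targets <- if (is.list(target_set)) target_set else list(target = target_set)
  if (!all(unlist(targets) %in% g)) stop("target_set must be a subset of the gene universe")
  sizes <- rep_len(config$term_sizes, config$n_terms)
  if (any(sizes > config$n_genes)) stop("term size exceeds universe size")
  if (config$n_planted_terms > 0L && any(lengths(targets) == 0L))
    stop("planted terms requested but a target set is empty")
  set.seed(config$seed + 2L)
  terms <- vector("list", config$n_terms)
  ids <- sprintf("T%03d", seq_len(config$n_terms))
  planted <- ids[seq_len(config$n_planted_terms)]
  which_target <- rep_len(seq_along(targets), config$n_planted_terms)
  for (i in seq_len(config$n_terms)) {
    if (i <= config$n_planted_terms) {
      tset <- targets[[which_target[i]]]
      k_target <- min(round(config$planted_frac * sizes[i]), length(tset))
      from_target <- sample(tset, k_target)
      from_rest <- sample(setdiff(g, from_target), sizes[i] - k_target)
      terms[[i]] <- sort(c(from_target, from_rest))
    } else {
      terms[[i]] <- sort(sample(g, sizes[i]))
    }
  }
  names(terms) <- ids
  ann <- annotation_set(terms,
                        descriptions = stats::setNames(
                          ifelse(ids %in% planted, "planted enriched term", "background term"), ids),
                        universe = g)
  list(annotations = ann,
       truth = list(enriched_term_ids = planted,
                    planted_target = stats::setNames(names(targets)[which_target], planted)))
}
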