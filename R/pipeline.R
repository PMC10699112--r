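# End-to-end orchestration: synthetic-study generation to flat files,
# pipeline configuration, and the run_all() driver executing
# deg -> netbuild -> enrich -> cascade comparison -> molecular
# evolution, writing a machine-readable JSON report.

#' Generate a complete synthetic two-phase study on disk
#'
#' Emits every input `run_all()` consumes: four expression contrasts
#' (two replicate datasets for initiation; the committed-vs-noncommitted
#' and return-to-growth contrasts for commitment), a global interaction
#' table and TF-binding table with planted master regulators, two
#' annotation sources with planted enriched terms, and ortholog
#' metadata plus per-pair codon alignments evolved at the phase-specific
#' target omega from `config$omega_by_group`.  A `ground_truth.json`
#' records everything planted.
#'
#' The planted up-sets of both phases include all TFs, so that the
#' regulatory edges among TFs survive the restriction of the binding
#' table to the functionally enriched gene pool (see the methods
#' vignette on why this matters for end-to-end MR recovery).
#'
#' @param config A [sim_config].
#' @param outdir Output directory (created if needed).
#' @param n_pairs_per_phase Ortholog pairs per phase per species.
#' @param species Labels of the emulated species.
#' @return Invisibly, a list with the file manifest and the ground
#'   truth.
#' @export
simulate_study <- function(config, outdir, n_pairs_per_phase = 30L,
                           species = c("species_1", "species_2")) {
  validate_sim_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "alns"), showWarnings = FALSE)
  g <- gene_ids(config$n_genes)

  nets <- simulate_networks(config)
  tfs <- nets$truth$tf_ids

  set.seed(config$seed + 3L)
  pick_signature <- function() {
    n_extra <- max(config$n_planted_up - length(tfs), 0L)
    sort(union(tfs, sample(setdiff(g, tfs), n_extra)))
  }
  init_up <- pick_signature()
  commit_up <- pick_signature()
  # genes reverted on return to growth: planted down in the return
  # contrast; part overlaps the committed up-set
  n_overlap <- ceiling(0.25 * length(setdiff(commit_up, tfs)))
  revert <- sort(c(sample(setdiff(commit_up, tfs), n_overlap),
                   sample(setdiff(g, commit_up), n_overlap)))

  # each TF regulates a few genes inside each phase signature, so the
  # planted regulator tier drives both phase programs and survives the
  # restriction of the binding table to the enriched gene pool
  mrs <- nets$truth$mr_ids
  extra <- list()
  for (tf in tfs) {
    for (sig in list(init_up, commit_up)) {
      cand <- setdiff(sig, c(mrs, tf))
      tgt <- sample(cand, min(3L, length(cand)))
      if (length(tgt))
        extra[[length(extra) + 1L]] <- data.frame(tf = tf, target = tgt,
                                                  stringsAsFactors = FALSE)
    }
  }
  regulation <- unique(rbind(nets$regulation, do.call(rbind, extra)))
  regulation <- regulation[order(regulation$tf, regulation$target), ]
  rownames(regulation) <- NULL
  nets$regulation <- regulation

  sims <- list(
    init_a     = simulate_expression(config, "initiation_dataset_a", init_up,
                                     seed = config$seed + 11L),
    init_b     = simulate_expression(config, "initiation_dataset_b", init_up,
                                     seed = config$seed + 12L),
    commit_up  = simulate_expression(config, "committed_vs_noncommitted", commit_up,
                                     seed = config$seed + 13L),
    commit_ret = simulate_expression(config, "return_to_growth", revert,
                                     planted_lfc = -config$planted_lfc,
                                     seed = config$seed + 14L))
  paths <- list()
  for (nm in names(sims)) {
    paths[[paste0(nm, "_matrix")]] <- file.path(outdir, paste0(nm, "_matrix.tsv"))
    paths[[paste0(nm, "_conditions")]] <- file.path(outdir, paste0(nm, "_conditions.tsv"))
    write_expression(sims[[nm]]$dataset, paths[[paste0(nm, "_matrix")]],
                     paths[[paste0(nm, "_conditions")]])
  }

  paths$interactions <- file.path(outdir, "interactions.tsv")
  paths$regulation <- file.path(outdir, "regulation.tsv")
  write_tsv_file(nets$interactions, paths$interactions)
  write_tsv_file(nets$regulation, paths$regulation)

  target_set <- list(initiation = init_up, commitment = commit_up)
  ann_cfg_a <- config; ann_cfg_a$seed <- config$seed + 21L
  ann_cfg_b <- config; ann_cfg_b$seed <- config$seed + 22L
  ann_a <- simulate_annotations(ann_cfg_a, target_set)
  ann_b <- simulate_annotations(ann_cfg_b, target_set)
  paths$gmt_a <- file.path(outdir, "annotations_a.gmt")
  paths$gmt_b <- file.path(outdir, "annotations_b.gmt")
  write_gmt(ann_a$annotations, paths$gmt_a)
  write_gmt(ann_b$annotations, paths$gmt_b)

  omega <- config$omega_by_group
  stopifnot(all(c("initiation", "commitment") %in% names(omega)))
  meta_rows <- list()
  pair_no <- 0L
  set.seed(config$seed + 4L)
  pool_by_phase <- list(initiation = init_up, commitment = commit_up)
  pair_seeds <- sample.int(.Machine$integer.max %/% 2L,
                           2L * length(species) * n_pairs_per_phase)
  for (phase in c("initiation", "commitment")) {
    for (sp in species) {
      genes <- sample(pool_by_phase[[phase]], n_pairs_per_phase,
                      replace = n_pairs_per_phase > length(pool_by_phase[[phase]]))
      for (gene in genes) {
        pair_no <- pair_no + 1L
        sim <- simulate_codon_pair(config$n_codons, omega[[phase]],
                                   config$divergence, seed = pair_seeds[pair_no],
                                   meta = list(id_a = paste0("scerevisiae|", gene),
                                               id_b = paste0(sp, "|", gene, "_o")))
        aln <- sprintf("alns/pair_%04d.fasta", pair_no)
        write_fasta_pair(sim$pair, file.path(outdir, aln))
        meta_rows[[pair_no]] <- data.frame(
          gene_a = gene, gene_b = paste0(gene, "_o"), species = sp,
          orthology_type = "one-to-one", confidence = 1,
          percent_identity = 100 * mean(strsplit(sim$pair$seq_a, "")[[1]] ==
                                          strsplit(sim$pair$seq_b, "")[[1]]),
          group_label = phase, omega_true = omega[[phase]],
          alignment_file = aln, stringsAsFactors = FALSE)
      }
    }
  }
  orthologs <- do.call(rbind, meta_rows)
  paths$orthologs <- file.path(outdir, "orthologs.tsv")
  write_tsv_file(orthologs, paths$orthologs)

  truth <- list(init_up = init_up, commit_up = commit_up, revert = revert,
                commitment_set = sort(setdiff(commit_up, revert)),
                mr_ids = nets$truth$mr_ids, tf_ids = tfs,
                enriched_term_ids = ann_a$truth$enriched_term_ids,
                omega_by_group = as.list(omega))
  paths$ground_truth <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, truth = truth))
}

#' Pipeline configuration
#'
#' Collects the file paths and thresholds `run_all()` needs.  All
#' paths are interpreted relative to `dir`.
#'
#' @param dir Study directory (as written by [simulate_study], or laid
#'   out identically from curated data).
#' @param outdir Output directory for reports (default
#'   `file.path(dir, "results")`).
#' @param alpha_deg,lfc_min DEG thresholds (adjusted p < 0.05,
#'   |log2 FC| > 1).
#' @param enrich_alpha Enrichment adjusted-p cutoff.
#' @param identity_min_by_species Named identity thresholds for
#'   [filter_orthologs]; `.default` covers unnamed species.
#' @param gesd_alpha,k_max GESD parameters.
#' @param n_boot Bootstrap replicates for the codon Z-test.
#' @param seed Master seed for all stochastic steps.
#' @param stages Character vector of stages to run, subset of
#'   `c("deg", "network", "enrich", "compare", "evolution")`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(dir, outdir = file.path(dir, "results"),
                            alpha_deg = 0.05, lfc_min = 1, enrich_alpha = 0.05,
                            identity_min_by_species = c(.default = 30),
                            gesd_alpha = 0.05, k_max = 5L, n_boot = 1000L,
                            seed = 1L,
                            stages = c("deg", "network", "enrich", "compare", "evolution")) {
  stopifnot(alpha_deg > 0, alpha_deg < 1, enrich_alpha > 0, enrich_alpha < 1,
            lfc_min >= 0, gesd_alpha > 0, gesd_alpha < 1, n_boot >= 200L)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(dir = dir, outdir = outdir, alpha_deg = alpha_deg,
                 lfc_min = lfc_min, enrich_alpha = enrich_alpha,
                 identity_min_by_species = identity_min_by_species,
                 gesd_alpha = gesd_alpha, k_max = as.integer(k_max),
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config] (`dir` required).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$dir)) stop("config must set `dir`")
  if (!is.null(y$identity_min_by_species))
    y$identity_min_by_species <- unlist(y$identity_min_by_species)
  do.call(pipeline_config, y)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

run_deg_contrast <- function(dir, prefix, alpha, lfc_min) {
  ds <- read_expression(file.path(dir, paste0(prefix, "_matrix.tsv")),
                        file.path(dir, paste0(prefix, "_conditions.tsv")))
  test_differential(ds, alpha = alpha, lfc_min = lfc_min)
}

# Enrichment of one query against two annotation sources; returns the
# consensus terms and the union of the covered genes.
run_enrichment_pair <- function(query, ann_a, ann_b, alpha) {
  ea <- hypergeom_enrich(query, ann_a, alpha = alpha)
  eb <- hypergeom_enrich(query, ann_b, alpha = alpha)
  terms <- consensus_terms(ea, eb)
  pool <- sort(union(enriched_gene_pool(terms, ann_a, query),
                     enriched_gene_pool(terms, ann_b, query)))
  list(run_a = ea, run_b = eb, consensus = terms, pool = pool)
}

run_network_phase <- function(phase_genes, interactions, regulation, ann_a, ann_b,
                              enrich_alpha) {
  ppin <- build_ppin(phase_genes, interactions, expand_neighbors = TRUE)
  enr <- run_enrichment_pair(ppin$nodes, ann_a, ann_b, enrich_alpha)
  grn <- build_grn(enr$pool, regulation)
  top <- top_tfs(grn)
  cascade <- integrate_cascade(grn, ppin)
  mrs <- identify_mrs(cascade)
  list(ppin = ppin, enrichment = enr, grn = grn, top_tfs = top,
       cascade = cascade, mrs = mrs)
}

#' Run the full pipeline
#'
#' Executes, per the configured stages: differential-expression
#' screening and phase set logic; phase PPIN construction, functional
#' enrichment with two-source consensus, GRN restriction, cascade
#' integration and master-regulator calls; the cascade comparison;
#' ortholog filtering, NG86 dN/dS with the codon Z-test per pair, and
#' the per-species phase comparison.  All randomness is derived from
#' `config$seed`; two runs with the same config produce byte-identical
#' reports.
#'
#' @param config A [pipeline_config].
#' @return The report (list), invisibly also written as
#'   `report.json` under `config$outdir` together with per-stage TSVs.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$dir
  need <- c("init_a_matrix.tsv", "init_b_matrix.tsv", "commit_up_matrix.tsv",
            "commit_ret_matrix.tsv", "interactions.tsv", "regulation.tsv",
            "annotations_a.gmt", "annotations_b.gmt", "orthologs.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing input file(s) under ", dir, ": ", paste(missing, collapse = ", "))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)

  wrap_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] stage failed: %s", stage, conditionMessage(e)), call. = FALSE))
  }

  # --- differential expression + set logic -----------------------------------
  if (!"deg" %in% config$stages) stop("the deg stage cannot be disabled: later stages depend on it")
  sets <- wrap_stage("deg", {
    log_stage("deg", "screening four contrasts")
    deg <- lapply(c(init_a = "init_a", init_b = "init_b",
                    commit_up = "commit_up", commit_ret = "commit_ret"),
                  function(p) run_deg_contrast(dir, p, config$alpha_deg, config$lfc_min))
    for (nm in names(deg))
      write_deg_table(deg[[nm]], file.path(config$outdir, paste0("deg_", nm, ".tsv")))
    init <- initiation_gene_set(deg[c("init_a", "init_b")])
    commit <- commitment_gene_set(deg_up(deg$commit_up), deg_down(deg$commit_ret))
    write_gene_set(init, file.path(config$outdir, "initiation_genes.txt"))
    write_gene_set(commit, file.path(config$outdir, "commitment_genes.txt"))
    list(deg = deg, init = init, commit = commit)
  })
  report$deg <- list(
    n_up = lapply(sets$deg, function(d) length(deg_up(d))),
    n_initiation = length(sets$init), n_commitment = length(sets$commit),
    commitment_counts = as.list(attr(sets$commit, "counts")))

  phases <- NULL
  if (all(c("network", "enrich") %in% config$stages)) {
    phases <- wrap_stage("network", {
      log_stage("network", "building phase cascades")
      interactions <- interaction_network(
        read_tsv_file(file.path(dir, "interactions.tsv"), c("gene_a", "gene_b")))
      regulation <- regulatory_network(
        read_tsv_file(file.path(dir, "regulation.tsv"), c("tf", "target")))
      ann_a <- read_gmt(file.path(dir, "annotations_a.gmt"))
      ann_b <- read_gmt(file.path(dir, "annotations_b.gmt"))
      res <- list(
        initiation = run_network_phase(sets$init, interactions, regulation,
                                       ann_a, ann_b, config$enrich_alpha),
        commitment = run_network_phase(sets$commit, interactions, regulation,
                                       ann_a, ann_b, config$enrich_alpha))
      for (ph in names(res)) {
        write_cascade_nodes(res[[ph]]$cascade,
                            file.path(config$outdir, paste0("cascade_", ph, "_nodes.tsv")))
        write_tsv_file(res[[ph]]$cascade$edges,
                       file.path(config$outdir, paste0("cascade_", ph, "_edges.tsv")))
        write_cascade_graphml(res[[ph]]$cascade,
                              file.path(config$outdir, paste0("cascade_", ph, ".graphml")))
        write_cascade_sif(res[[ph]]$cascade,
                          file.path(config$outdir, paste0("cascade_", ph, ".sif")))
      }
      res
    })
    report$network <- lapply(phases, function(ph) list(
      ppin_nodes = length(ph$ppin$nodes), ppin_edges = nrow(ph$ppin$edges),
      n_consensus_terms = length(ph$enrichment$consensus),
      n_enriched_genes = length(ph$enrichment$pool),
      grn_tfs = length(ph$grn$tfs), grn_edges = nrow(ph$grn$edges),
      top_tf_cutoff = ph$top_tfs$cutoff, top_tfs = ph$top_tfs$tfs,
      mrs = ph$mrs))
  }

  if ("compare" %in% config$stages && !is.null(phases)) {
    cmp <- wrap_stage("compare", {
      log_stage("compare", "comparing phase cascades")
      summ <- lapply(names(phases), function(ph) {
        x <- phases[[ph]]
        tg <- setdiff(x$cascade$nodes$gene_id, c(x$mrs, x$top_tfs$tfs))
        phase_cascade_summary(ph, mr_ids = x$mrs, tf_ids = x$top_tfs$tfs, tg_ids = tg)
      })
      comparison <- compare_cascades(summ[[1]], summ[[2]])
      write_tsv_file(comparison_table(comparison),
                     file.path(config$outdir, "cascade_comparison.tsv"))
      comparison
    })
    report$compare <- list(counts = cmp$counts,
                           total_unique_initiation = cmp$total_unique_a,
                           total_unique_commitment = cmp$total_unique_b,
                           common_mrs = cmp$common$mr)
  }

  if ("evolution" %in% config$stages) {
    evo <- wrap_stage("evolution", {
      log_stage("evolution", "estimating dN/dS per ortholog pair")
      orth <- read_ortholog_table(file.path(dir, "orthologs.tsv"))
      orth <- filter_orthologs(orth, config$identity_min_by_species)
      if (nrow(orth) == 0L) stop("no ortholog pair passes the filters")
      est <- vector("list", nrow(orth))
      for (i in seq_len(nrow(orth))) {
        row <- orth[i, ]
        pair <- read_fasta_pair(file.path(dir, row$alignment_file))
        rec <- data.frame(row[c("gene_a", "gene_b", "species", "group_label")],
                          S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
                          dS = NA_real_, dN = NA_real_, omega = NA_real_,
                          Z = NA_real_, prob = NA_real_, flag = "ok",
                          stringsAsFactors = FALSE)
        zt <- tryCatch(codon_z_test(pair, n_boot = config$n_boot,
                                    seed = config$seed + i),
                       meiocascade_saturation = function(e) NULL)
        if (is.null(zt)) {
          rec$flag <- "saturated"
        } else {
          e <- zt$estimate
          rec[c("S", "N", "Sd", "Nd", "dS", "dN", "omega")] <-
            e[c("S", "N", "Sd", "Nd", "dS", "dN", "omega")]
          rec$Z <- zt$Z; rec$prob <- zt$prob
        }
        est[[i]] <- rec
      }
      est <- do.call(rbind, est)
      write_tsv_file(est, file.path(config$outdir, "dnds_estimates.tsv"))
      comp <- compare_phase_evolution(
        est[est$group_label == "initiation", ],
        est[est$group_label == "commitment", ],
        alpha = 0.05, gesd_alpha = config$gesd_alpha, k_max = config$k_max)
      write_tsv_file(comp, file.path(config$outdir, "phase_evolution_comparison.tsv"))
      list(estimates = est, comparison = comp)
    })
    report$evolution <- list(
      n_pairs = nrow(evo$estimates),
      n_saturated = sum(evo$estimates$flag == "saturated"),
      comparison = evo$comparison)
  }

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "columns")
  log_stage("done", "report written to ", file.path(config$outdir, "report.json"))
  invisible(report)
}
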