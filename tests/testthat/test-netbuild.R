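# Network construction, integration, hierarchy index and MR calls.

test_that("interaction networks are normalized: no self-loops, no duplicates", {
  net <- interaction_network(data.frame(a = c("b", "a", "a", "c"),
                                        b = c("a", "b", "a", "c")))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$gene_a, "a")
  expect_equal(net$edges$gene_b, "b")
})

test_that("regulatory networks drop self-loops and duplicates", {
  expect_message(net <- regulatory_network(
    data.frame(tf = c("A", "A", "A"), target = c("A", "x", "x"))), "self-loop")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$tfs, "A")
})

test_that("build_ppin induces on seeds with optional neighbour expansion", {
  glob <- interaction_network(data.frame(a = c("a", "b"), b = c("b", "c")))
  # expand: neighbours of {a} are {b}; induced edges {a-b} only (c is not
  # a neighbour of a)
  net <- build_ppin("a", glob, expand_neighbors = TRUE)
  expect_setequal(net$nodes, c("a", "b"))
  expect_equal(nrow(net$edges), 1)
  # no expansion, single seed: induced subnetwork is empty -> error
  expect_error(build_ppin("a", glob, expand_neighbors = FALSE), "empty")
  # seeds absent from the network
  expect_error(build_ppin("zzz", glob), "no seed gene")
  expect_error(build_ppin(character(0), glob), "nonempty")
})

test_that("build_ppin on synthetic data keeps at least the connected seeds", {
  cfg <- small_config(seed = 31L)
  nets <- simulate_networks(cfg)
  glob <- interaction_network(nets$interactions)
  seeds <- sample(glob$nodes, 40)
  net <- suppressMessages(build_ppin(seeds, glob, expand_neighbors = TRUE))
  expect_gte(length(net$nodes), sum(seeds %in% glob$nodes) -
               sum(!seeds %in% c(net$nodes)))
  expect_true(all(net$edges$gene_a %in% net$nodes))
})

test_that("build_grn restricts the binding table to the target genes", {
  tab <- data.frame(tf = c("A", "A", "B"), target = c("x", "z", "y"))
  grn <- build_grn(c("x", "y"), tab)
  expect_equal(grn$edges, data.frame(tf = c("A", "B"), target = c("x", "y")))
  expect_error(build_grn(c("q"), tab), "no TF")
  expect_error(build_grn(character(0), tab), "nonempty")
  # restriction to the full universe is the identity
  cfg <- small_config(seed = 32L)
  nets <- simulate_networks(cfg)
  grn_full <- build_grn(sprintf("g%04d", 1:cfg$n_genes), nets$regulation)
  expect_equal(grn_full$edges, nets$regulation)
})

test_that("top TFs are those strictly above the mean target count", {
  grn <- regulatory_network(data.frame(
    tf = rep(c("A", "B", "C"), c(2, 4, 30)),
    target = sprintf("t%02d", 1:36)))
  top <- top_tfs(grn)
  expect_equal(top$cutoff, 12)
  expect_equal(top$tfs, "C")
  # equal counts: strict inequality leaves the top set empty
  grn2 <- regulatory_network(data.frame(tf = c("A", "B"), target = c("x", "y")))
  expect_length(top_tfs(grn2)$tfs, 0)
  # a TF exactly at the cutoff is excluded
  counts <- c(12, 11, 10)  # mean = 11
  grn3 <- regulatory_network(data.frame(
    tf = rep(c("A", "B", "C"), counts), target = sprintf("t%02d", 1:33)))
  expect_equal(top_tfs(grn3)$cutoff, 11)
  expect_equal(top_tfs(grn3)$tfs, "A")
})

test_that("hierarchy index follows the degree formula", {
  expect_equal(hierarchy_index(0, 5), 1)
  expect_equal(hierarchy_index(7, 0), -1)
  expect_equal(hierarchy_index(1, 3), 0.5)
  expect_error(hierarchy_index(0, 0), "isolated")
  expect_error(hierarchy_index(-1, 2), "nonnegative")
  # antisymmetry under swapping in/out
  set.seed(33)
  a <- sample(0:10, 50, replace = TRUE); b <- sample(1:10, 50, replace = TRUE)
  expect_equal(hierarchy_index(a, b), -hierarchy_index(b, a))
})

test_that("integrate_cascade builds the layered directed graph", {
  grn <- regulatory_network(data.frame(tf = "A", target = "x"))
  ppin <- interaction_network(data.frame(a = "x", b = "y"))
  cas <- integrate_cascade(grn, ppin)
  nd <- cas$nodes
  expect_equal(nd$out_deg[nd$gene_id == "A"], 1)
  expect_equal(nd$in_deg[nd$gene_id == "A"], 0)
  expect_equal(nd$out_deg[nd$gene_id == "x"], 1)
  expect_equal(nd$in_deg[nd$gene_id == "x"], 2)
  expect_equal(nd$out_deg[nd$gene_id == "y"], 1)
  expect_equal(nd$in_deg[nd$gene_id == "y"], 1)
  expect_setequal(cas$edges$layer, c("TF-TG", "TG-TG"))
  expect_equal(identify_mrs(cas), "A")
})

test_that("physical interactions between TFs stay out of the TG-TG layer", {
  grn <- regulatory_network(data.frame(tf = c("A", "B"), target = c("B", "x")))
  ppin <- interaction_network(data.frame(a = c("A", "x"), b = c("B", "y")))
  cas <- integrate_cascade(grn, ppin)
  # the A-B physical edge is dropped; the A->B regulatory edge is TF-TF
  ab <- cas$edges[cas$edges$source == "A" & cas$edges$target == "B", ]
  expect_equal(ab$layer, "TF-TF")
  expect_false(any(cas$edges$source == "B" & cas$edges$target == "A"))
  # x-y enters as a reciprocal TG-TG pair
  expect_true(any(cas$edges$source == "x" & cas$edges$target == "y"))
  expect_true(any(cas$edges$source == "y" & cas$edges$target == "x"))
})

test_that("a regulatory cycle has no master regulator", {
  grn <- regulatory_network(data.frame(tf = c("A", "B"), target = c("B", "A")))
  cas <- integrate_cascade(grn, interaction_network(data.frame(a = "x", b = "y")))
  expect_warning(mrs <- identify_mrs(cas), "empty MR set")
  expect_length(mrs, 0)
})

test_that("degree bookkeeping: sum(out - in) is zero on any cascade", {
  for (seed in c(41L, 42L, 43L)) {
    nets <- simulate_networks(small_config(seed = seed))
    cas <- integrate_cascade(regulatory_network(nets$regulation),
                             interaction_network(nets$interactions))
    expect_equal(sum(cas$nodes$out_deg - cas$nodes$in_deg), 0)
    expect_true(all(cas$nodes$in_deg + cas$nodes$out_deg >= 1))
    expect_equal(cas$nodes$v,
                 hierarchy_index(cas$nodes$in_deg, cas$nodes$out_deg))
  }
})

test_that("planted MRs are recovered exactly from integrated synthetic networks", {
  for (seed in c(51L, 52L, 53L)) {
    cfg <- small_config(seed = seed)
    nets <- simulate_networks(cfg)
    cas <- integrate_cascade(regulatory_network(nets$regulation),
                             interaction_network(nets$interactions))
    expect_setequal(identify_mrs(cas), nets$truth$mr_ids)
  }
})

test_that("MR calls match a brute-force zero-in-degree scan on random DAG GRNs", {
  set.seed(60)
  for (rep in 1:10) {
    n_tf <- 6; n_tg <- 15
    tfs <- sprintf("TF%02d", 1:n_tf)
    tgs <- sprintf("TG%02d", 1:n_tg)
    # DAG orientation: TF i can regulate TF j only for i < j
    edges <- list()
    for (i in 1:(n_tf - 1)) for (j in (i + 1):n_tf)
      if (runif(1) < 0.4) edges[[length(edges) + 1]] <- c(tfs[i], tfs[j])
    for (i in 1:n_tf) for (t in sample(tgs, 3))
      edges[[length(edges) + 1]] <- c(tfs[i], t)
    tab <- do.call(rbind.data.frame, edges)
    names(tab) <- c("tf", "target")
    grn <- regulatory_network(tab)
    cas <- integrate_cascade(grn, interaction_network(
      data.frame(a = "zzz1", b = "zzz2")))
    # brute force on the raw edge list
    indeg <- table(factor(tab$target, levels = unique(c(tab$tf, tab$target))))
    brute <- sort(intersect(names(indeg)[indeg == 0], unique(tab$tf)))
    expect_identical(suppressWarnings(identify_mrs(cas)), brute)
  }
})

test_that("MR set is invariant to edge order and to node renaming", {
  nets <- simulate_networks(small_config(seed = 61L))
  reg <- nets$regulation
  perm <- sample(nrow(reg))
  cas1 <- integrate_cascade(regulatory_network(reg),
                            interaction_network(nets$interactions))
  cas2 <- integrate_cascade(regulatory_network(reg[perm, ]),
                            interaction_network(nets$interactions[sample(nrow(nets$interactions)), ]))
  expect_identical(identify_mrs(cas1), identify_mrs(cas2))
  # renaming
  rename <- function(x) paste0("X_", x)
  cas3 <- integrate_cascade(
    regulatory_network(data.frame(tf = rename(reg$tf), target = rename(reg$target))),
    interaction_network(data.frame(a = rename(nets$interactions$gene_a),
                                   b = rename(nets$interactions$gene_b))))
  expect_identical(identify_mrs(cas3), rename(identify_mrs(cas1)))
})
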