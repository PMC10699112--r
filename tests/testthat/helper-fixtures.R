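# Small shared fixtures, built in code at test time.

small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 200L, n_samples_per_condition = 5L,
             n_planted_up = 20L, n_tfs = 8L, n_planted_mrs = 3L,
             ppin_edge_prob = 0.02, n_terms = 20L, term_sizes = 15L,
             n_planted_terms = 3L, n_codons = 100L, ...)
}

tiny_grn <- function() {
  regulatory_network(data.frame(tf = c("A", "A", "B"), target = c("x", "B", "y")))
}

tiny_ppin <- function() {
  interaction_network(data.frame(gene_a = c("x", "y"), gene_b = c("y", "z")))
}
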