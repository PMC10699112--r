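# meiocascade

Master-regulator cascades and purifying selection in yeast meiosis.

Budding yeast enters meiosis in two distinguishable steps: a reversible
*initiation* phase and a later *commitment* phase after which cells can
no longer return to mitotic growth. `meiocascade` is an R package for
the two questions this raises at the systems level:

1. **Which transcription factors sit at the top of each phase's
   regulatory cascade?** Phase-specific up-regulated genes are screened
   from two-condition expression data (moderated Welch t on
   quantile-normalized log2 intensities, BH-adjusted p < 0.05 and
   |log2FC| > 1), expanded into a protein–protein interaction subnetwork,
   reduced to a functionally enriched gene pool (one-tailed
   hypergeometric test, consensus across two annotation sources), and
   wired into a directed TF–TF / TF–TG / TG–TG cascade. Each node gets
   the hierarchy index

   *v* = (out − in) / (out + in)  ∈ [−1, 1],

   and **master regulators (MRs)** are the TFs with *v* = 1 — only
   outgoing regulatory edges.

2. **Is the commitment cascade under stronger purifying selection?**
   For each one-to-one ortholog pair (confidence- and identity-filtered),
   ω = dN/dS is estimated by the Nei–Gojobori (1986) counting method
   (fractional sites per codon, mutational-pathway averaging,
   Jukes–Cantor correction), each pair is tested for negative selection
   with a bootstrap codon-based Z-test (alternative dN < dS), outliers
   are removed per phase with Rosner's generalized ESD procedure, and
   the phase ω distributions are compared per species with a
   Mann–Whitney U test.

Every external input (expression series, interaction and TF-binding
tables, annotation gene sets, codon alignments) is emulated by a
synthetic-data generator with planted ground truth, so the full pipeline
runs and is tested without any downloads.

## Worked example

Generate a synthetic two-phase study (3 planted master regulators,
commitment ortholog pairs evolved at ω = 0.1 vs initiation at ω = 0.3)
and run the whole pipeline:

```r
library(meiocascade)

cfg    <- sim_config(seed = 42, n_codons = 150)
study  <- simulate_study(cfg, "demo_study", n_pairs_per_phase = 15)
report <- run_all(pipeline_config("demo_study", seed = 42, n_boot = 500))

study$truth$mr_ids                  # planted
report$network$initiation$mrs       # called
report$evolution$comparison
```

Output (abridged):

```
[deg] screening four contrasts
commitment set: 50 up, 16 down-on-return, 8 overlap -> 42 retained
[network] building phase cascades
[compare] comparing phase cascades
[evolution] estimating dN/dS per ortholog pair
[done] report written to demo_study/results/report.json

planted MRs:          g0007, g0708, g0845
called (initiation):  g0007, g0708, g0845
called (commitment):  g0007, g0066, g0311, g0708, g0845

    species n_init n_commit mean_omega_init mean_omega_commit  median_omega_init
1 species_1     14       11       0.3292996        0.09835522          0.3144352
2 species_2     15       14       0.2862158        0.08237855          0.2841087
  median_omega_commit   U      p_value
1          0.09946178 154 2.814432e-05
2          0.08149537 210 5.097029e-06
```

All three planted MRs are recovered in both phases (commitment also
calls two spurious apex TFs — TFs whose incoming edges fell outside the
enriched gene pool; see the methods vignette), and the planted selection
difference is reproduced: commitment ω medians ≈ 0.08–0.10 versus
initiation ≈ 0.28–0.31, Mann–Whitney p < 1e-4 per species, matching the
generator's 0.1 vs 0.3 targets.

Individual stages are exported (`test_differential`, `build_ppin`,
`build_grn`, `integrate_cascade`, `identify_mrs`, `hypergeom_enrich`,
`ng86_pair`, `codon_z_test`, `gesd_outliers`, `mann_whitney`,
`compare_phase_evolution`, ...) and a CLI mirrors them:

```sh
exec/meiocascade simulate --outdir study --seed 1
exec/meiocascade run-all --dir study --seed 1
exec/meiocascade deg --matrix study/init_a_matrix.tsv --conditions study/init_a_conditions.tsv --out deg.tsv
```

## Package layout

- `R/synthetic.R` — generators with planted ground truth
- `R/diffexpr.R` — quantile normalization, moderated Welch test, BH, phase set logic
- `R/netbuild.R` — PPIN/GRN construction, cascade integration, hierarchy index, MR calls
- `R/enrich.R` — hypergeometric over-representation, consensus, gene pools
- `R/cascade_compare.R` — role-wise unique/common comparison of two phases
- `R/molevo.R` — NG86 dN/dS, codon Z-test, GESD, Mann–Whitney, ortholog filters
- `R/io.R`, `R/pipeline.R`, `R/cli.R` — formats, orchestration, CLI
- `vignettes/meiocascade-methods.Rmd` — models, assumptions, parameter choices, limitations
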