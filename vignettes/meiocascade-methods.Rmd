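---
title: "Methods: cascade inference and selection analysis in meiocascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascade inference and selection analysis in meiocascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiocascade)
```

# Scope and model

meiocascade implements a two-part analysis of the yeast meiotic program.
The first part infers *master regulators* (MRs) of two phases of meiosis
— initiation (the reversible entry into the program) and commitment (the
point after which cells can no longer return to mitotic growth) — by
integrating three data layers per phase: differentially expressed genes,
physical protein–protein interactions (PPIN), and directed
transcription-factor-to-target binding relations (GRN). The second part
asks whether the commitment cascade is under stronger purifying
selection than the initiation cascade, using pairwise dN/dS estimates on
ortholog pairs from related ascomycete species.

Because the original inputs are large external databases, the package
ships a synthetic-data generator that emulates every input *shape* with
planted ground truth. All statistical machinery is therefore testable by
parameter recovery, and a full study can be generated, run, and checked
end to end on a laptop.

# Differential-expression screen

Intensities are log2-transformed and quantile-normalized (every column
is mapped to the vector of row means of the column-sorted matrix; ties
take the average of the tied ranks' reference values, which makes the
operation deterministic and idempotent). Each gene is then tested with a
Welch two-sample t-statistic on the log2 scale. As a lightweight
stand-in for empirical-Bayes moderation, each group's variance is
optionally shrunk toward the across-gene mean variance with `d0`
pseudo-degrees of freedom (default `d0 = 4`; `d0 = 0` disables
moderation). P-values are adjusted by the Benjamini–Hochberg step-up;
a gene is called *up* when `p_adj < alpha` (default 0.05) **and**
`log2FC > lfc_min` (default 1), symmetrically for *down*.

The adjustment method is fixed to Benjamini–Hochberg: the upstream
description says only "adjusted P value", and BH is the default of the
standard microarray pipeline this stage emulates.

Phase set logic: the initiation signature is the **intersection** of the
up-sets of two independent datasets of the same contrast design; the
commitment signature is the up-set at the committed stage **minus** the
genes down-regulated when committed cells are returned to growth medium
(the classic 566 − 156 → 410 arithmetic, which the test suite reproduces
on synthetic sets of those sizes). Pooled time points are treated as
replicates within condition.

## A note on quantile normalization and planted effects

Quantile normalization assumes that most genes are unchanged between
conditions. When a large fraction of genes (≈10%) carries a strong
planted shift, QN measurably compresses the planted log2 fold-changes
and recall drops below the nominal power of the t-test. The recovery
tests therefore plant ≈2.5% of genes, which is a realistic prevalence
for a phase-specific induction signature; this is a property of QN
itself, not of the test statistic.

# Network integration and the hierarchy index

A phase PPIN is the subnetwork induced on the phase gene set, optionally
expanded by first neighbours (the default, mirroring how interaction
databases are queried around a seed list). The phase GRN restricts a
global TF→target binding table to targets in the functionally enriched
gene pool.

The integrated cascade is a directed multigraph built from three layers:

* **TF–TF** and **TF–TG**: all GRN edges, labelled by whether the target
  is itself a TF;
* **TG–TG**: every PPIN edge whose two endpoints are both non-TFs,
  inserted as a *reciprocal pair* of directed edges.

Each retained node gets the hierarchy index

$$v = \frac{\mathrm{out} - \mathrm{in}}{\mathrm{out} + \mathrm{in}} \in [-1, 1],$$

and master regulators are the TFs at the apex: $v = 1$ exactly, i.e.
in-degree 0 with at least one outgoing edge.

Design choices where the construction was genuinely open:

* **Orientation of physical edges.** Undirected PPIN edges carry no
  hierarchy information. Inserting them as reciprocal pairs makes
  target genes hierarchically neutral ($v \approx 0$), so the pyramid's
  apex is decided by the regulatory layers — consistent with target
  genes forming the centre of the integrated networks.
* **TF–TF physical edges are dropped.** A physical interaction between
  two TFs would, as a reciprocal pair, give both an incoming edge and
  silently disqualify genuine apex regulators.
* **Self-loops are dropped** when the binding table is loaded. An
  autoregulatory TF would otherwise have in-degree ≥ 1 and could never
  reach $v = 1$, yet autoregulation is common among genuine master
  regulators.
* **Isolated nodes are excluded** before computing $v$ (undefined at
  0/0).
* **Top TFs** are those whose distinct-target count strictly exceeds
  the mean count over TFs; top-TF status and MR status are computed
  independently.

In the end-to-end pipeline the GRN is restricted to the enriched gene
pool. A TF that falls out of that pool loses its incoming regulatory
edges (they are edges *onto* it) and can surface as a spurious $v = 1$
call; conversely a planted MR can only disappear if all its targets miss
the pool. The synthetic study generator therefore wires every TF to a
few targets inside each phase signature, and the end-to-end guarantee is
*planted ⊆ called*. Exact recovery is asserted at the network level,
where no enrichment restriction intervenes.

# Over-representation analysis

For a query of size $n$ against a term of size $K$ in a universe of
size $N_u$, the enrichment p-value is the upper hypergeometric tail
$P[X \ge k]$ (the one-tailed variant of Fisher's exact test, an identity
the tests verify numerically). BH adjustment is applied within one
annotation source, never pooled across sources; the consensus step
intersects the enriched term sets of two sources, and the resulting gene
pool is the union over consensus terms of term members restricted to the
query. The universe is all genes present in the annotation file — the
background is not stated upstream, and this choice is explicit and
overridable.

# Molecular evolution

## NG86 dN/dS

The estimator follows the counting method of Nei & Gojobori (1986).
Sites: at each codon position the synonymous fraction is computed over
the single-base changes that do **not** create a stop codon
(stop-creating changes are excluded from the denominator), so every
sense codon contributes exactly 3 sites. Differences: for a codon pair
differing at $d$ positions, all $d!$ orderings of the changes are
enumerated; pathways whose intermediates are stop codons are discarded
and the per-step synonymous/nonsynonymous classifications are averaged
over the admissible pathways (if every pathway is blocked — not
observed for sense-codon pairs under the standard code — the average is
taken over all pathways and the pair is flagged). Proportions
$p_S = S_d/S$, $p_N = N_d/N$ are corrected for multiple hits with the
Jukes–Cantor formula $d_X = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3} p_X)$,
and $\omega = d_N/d_S$.

Conventions: columns containing gaps or ambiguity codes in either
sequence are skipped whole (pairwise deletion at codon granularity);
$p_X \ge 0.75$ raises a typed saturation error and the pair is excluded
downstream; $\omega$ is **undefined** (NA), not zero, when $d_S = 0$,
so degenerate pairs cannot distort rank tests. All per-codon quantities
are precomputed into 61×61 lookup tables at first use, making the
per-alignment cost linear in its length.

## Codon-based Z-test for purifying selection

Per pair, the statistic is $Z = (d_S - d_N)/SE$, where $SE$ is the
standard deviation of $d_S - d_N$ over bootstrap resamples of codon
columns (default 1000, seeded; resamples are drawn as multinomial column
weights, so the cost is a matrix product). The p-value is the upper
normal tail, i.e. the alternative is $d_N < d_S$ (purifying selection).
An analytic variance is deliberately not implemented — the bootstrap
matches the described workflow and is exercised by the calibration
tests (empirical size ≈ 0.03–0.05 at $\omega = 1$, power ≈ 1 at
$\omega = 0.1$ with 300 codons).

## Outlier removal and phase comparison

Within each phase, Rosner's generalized extreme Studentized deviate
(GESD) procedure removes up to `k_max` outliers at `alpha = 0.05`,
using the exact critical-value formula
$\lambda_i = (n-i)\,t / \sqrt{(n-i-1+t^2)(n-i+1)}$ with $t$ the
$1 - \alpha/(2(n-i+1))$ Student quantile on $n-i-1$ df. Manual,
judgment-based outlier removal present in the original analysis is not
automated; only the formal GESD step is applied.

The phase comparison then: keeps pairs with a defined, unsaturated
$\omega$ and (by default, overridable) a significant codon Z-test;
applies GESD within phase; and compares the $\omega$ distributions with
a Mann–Whitney test, per species. The Mann–Whitney implementation uses
midranks for ties, exact enumeration of all rank assignments when both
samples have ≤ 8 observations without ties, and otherwise a normal
approximation with tie and continuity corrections. Sidedness defaults
to two-sided (the upstream description does not state it); one-sided
modes are available. Note that the continuity-corrected normal
approximation deviates from the exact two-sided p by up to 0.088 at the
extreme U of $n_a = n_b = 2$ — immaterial in practice because exact
enumeration is used at those sizes, and the acceptance check of the
approximation is asserted on the directional alternatives, where the
worst-case deviation over all $n_a = n_b \le 6$ configurations is 0.044.

# The synthetic world

The generator's defaults describe the stated world of the recovery
tests; none of them is tuned against test outcomes.

* **Expression**: gene baselines uniform on log2 6–10, Gaussian noise
  `noise_sd = 0.3`, planted `log2FC = 2`, 5 samples per condition —
  typical microarray magnitudes where the screen's power is ≈ 1.
  Values are generated on the log2 scale and exponentiated, so the DEG
  stage's log transform round-trips exactly.
* **Networks**: Erdős–Rényi PPIN (`p = 0.01` over 1000 genes, mean
  degree ≈ 10) with a preferential-attachment alternative — cascade
  correctness does not depend on the degree distribution, but tests can
  vary it. The regulation table plants MRs by construction: no incoming
  edge onto an MR, every non-MR TF regulated at least once, targets
  never include MRs, no self-loops.
* **Annotations**: uniform background terms plus planted terms drawing
  80% of their members from a target signature (term size 30), matching
  the order of enrichment seen in curated gene sets. When several
  signatures are supplied, planted terms cycle over them so each phase
  has phase-coherent enriched terms.
* **Codon pairs**: a random sense-codon ancestor evolves along two
  branches, each receiving a Poisson number of substitution attempts
  (`divergence = 0.6` expected attempts per codon for the pair —
  "moderate divergence": enough substitutions for stable estimates,
  far from saturation). An attempt picks a codon, then a position, then
  uniformly one of the *non-stop* alternative bases at that position;
  synonymous changes are always accepted, nonsynonymous ones with
  probability $\omega_\text{target}$. The per-position normalization
  over non-stop alternatives is deliberate: it makes the realized
  synonymous/nonsynonymous rate ratio equal $\omega$ *measured in NG86
  site units*, so the estimator is asked to recover exactly the
  quantity the generator controls. (A proposal scheme uniform over all
  nine single-base changes instead biases NG86 at stop-adjacent codons:
  e.g. TAT offers one synonymous change among seven non-stop changes
  but a full NG86 synonymous site.) Stop codons can never arise, and
  recovery is verified at targets 0.1 / 0.5 / 1.0. $\omega > 1$ is
  rejected — the biological regime under study is purifying selection
  throughout.

What a green test does **not** establish: the generator has no codon
usage bias, no transition/transversion asymmetry, no rate variation
across sites, no indels, no probe-level microarray artefacts, and no
realistic network topology beyond the chosen degree model. The pipeline
handles gaps and ambiguity codes from real inputs, but those paths are
exercised by constructed fixtures, not by the generator.

# Numerical and degenerate-input choices

* BH adjustment is the exact step-up with cumulative minima; output
  order matches input order.
* Quantile-normalization ties average the reference values of the tied
  ranks (deterministic; idempotent to 1e-12).
* `hierarchy_index(0, 0)` is an error; callers exclude isolated nodes.
* Identical sequences: $S_d = N_d = 0$, $d_S = d_N = 0$, $\omega$ NA,
  selection-test `prob = 1` with a warning.
* Degenerate bootstrap (zero variance) yields `prob = 1` with a
  warning rather than an unstable Z.
* GESD with zero variance returns zero outliers with a warning;
  `n >= k_max + 3` is required.
* Empty enriched-term or up-set intersections warn and return empty
  sets; they are not errors.
* All seeds are explicit; identical seeds give byte-identical emitted
  files, which the suite asserts.

# Known limitations

* The moderated Welch test is not an empirical-Bayes fit; its `d0` is a
  fixed constant, not estimated from the data.
* GO term hierarchy (parent propagation) is not modelled; terms are
  flat sets from the GMT.
* NG86 stop-handling conventions differ at the third decimal across
  toolchains; this implementation's convention (stop-excluded site
  denominators, stop-free pathway averaging) is fixed and documented.
* Maximum-likelihood codon models, tree-based comparisons, and
  transition/transversion-weighted NG86 variants are out of scope; all
  comparisons are pairwise.
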