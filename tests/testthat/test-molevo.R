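# NG86 estimation, selection test, outlier scan, rank comparison and
# ortholog filtering.

test_that("ng86_pair on identical sequences gives zero distances, undefined omega", {
  s <- random_sense_sequence(60)
  est <- ng86_pair(codon_alignment_pair(s, s))
  expect_equal(est$Sd, 0); expect_equal(est$Nd, 0)
  expect_equal(est$dS, 0); expect_equal(est$dN, 0)
  expect_true(is.na(est$omega))
  expect_equal(est$S + est$N, 3 * 60)
})

test_that("column-level difference attribution matches hand-computed cases", {
  cs <- meiocascade:::ng86_column_stats(codon_alignment_pair("TTT", "TTC"))
  expect_equal(cs$sd, 1); expect_equal(cs$nd, 0)
  cs2 <- meiocascade:::ng86_column_stats(codon_alignment_pair("TTT", "GTA"))
  expect_equal(cs2$sd, 0.5); expect_equal(cs2$nd, 1.5)
})

test_that("ng86_pair agrees with the pathway-enumeration oracle on random pairs", {
  set.seed(90)
  for (rep in 1:10) {
    sim <- simulate_codon_pair(80, 0.8, divergence = 1, seed = 90 + rep)
    cs <- meiocascade:::ng86_column_stats(sim$pair)
    ca <- substring(sim$pair$seq_a, seq(1, 238, 3), seq(3, 240, 3))
    cb <- substring(sim$pair$seq_b, seq(1, 238, 3), seq(3, 240, 3))
    orc <- t(mapply(function(x, y) oracle_diffs(x, y), ca, cb))
    expect_equal(sum(cs$sd), sum(orc[, "sd"]), tolerance = 1e-12)
    expect_equal(sum(cs$nd), sum(orc[, "nd"]), tolerance = 1e-12)
    sites <- t(vapply(ca, oracle_sites, c(s = 0, n = 0))) / 2 +
      t(vapply(cb, oracle_sites, c(s = 0, n = 0))) / 2
    expect_equal(sum(cs$s), sum(sites[, "s"]), tolerance = 1e-12)
  }
})

test_that("ng86_pair is symmetric in its two sequences", {
  sim <- simulate_codon_pair(100, 0.5, divergence = 0.8, seed = 91)
  e1 <- ng86_pair(sim$pair)
  e2 <- ng86_pair(codon_alignment_pair(sim$pair$seq_b, sim$pair$seq_a))
  for (f in c("S", "N", "Sd", "Nd", "dS", "dN", "omega"))
    expect_equal(e1[[f]], e2[[f]], label = f)
})

test_that("gap and ambiguity columns are skipped codon-wise", {
  sim <- simulate_codon_pair(60, 0.5, divergence = 0.5, seed = 92)
  a <- sim$pair$seq_a; b <- sim$pair$seq_b
  # gap out the first codon of a, ambiguity in the second codon of b
  substr(a, 1, 3) <- "---"
  substr(b, 4, 4) <- "N"
  est <- ng86_pair(codon_alignment_pair(a, b))
  expect_equal(est$n_codons, 58)
  expect_equal(est$S + est$N, 3 * 58)
})

test_that("alignment validation catches malformed input", {
  expect_error(codon_alignment_pair("AAATTT", "AAA"), "equal length")
  expect_error(codon_alignment_pair("AAAT", "AAAT"), "divisible by 3")
  expect_error(codon_alignment_pair("AAATAA", "AAAAAA"), "stop codon")
  expect_error(ng86_pair(codon_alignment_pair("---", "AAA")), "no usable codon")
})

test_that("saturated pairs raise a typed error", {
  # a single highly divergent codon column saturates pS
  err <- tryCatch(ng86_pair(codon_alignment_pair("TTT", "TTC")),
                  error = function(e) e)
  expect_s3_class(err, "meiocascade_saturation")
})

test_that("codon Z-test: identical sequences give prob 1; inputs validated", {
  s <- random_sense_sequence(60)
  expect_warning(zt <- codon_z_test(codon_alignment_pair(s, s), n_boot = 200,
                                    seed = 1), "identical")
  expect_equal(zt$prob, 1)
  sim <- simulate_codon_pair(60, 0.5, divergence = 0.5, seed = 93)
  expect_error(codon_z_test(sim$pair, n_boot = 50), ">= 200")
})

test_that("codon Z-test is seed-reproducible and detects strong purifying selection", {
  sim <- simulate_codon_pair(300, 0.1, divergence = 0.6, seed = 94)
  z1 <- codon_z_test(sim$pair, n_boot = 300, seed = 7)
  z2 <- codon_z_test(sim$pair, n_boot = 300, seed = 7)
  expect_identical(z1$Z, z2$Z)
  expect_lt(z1$prob, 0.05)
  expect_gt(z1$estimate$dS, z1$estimate$dN)
})

test_that("GESD flags a gross outlier and matches the direct formulas", {
  x <- c(1.0, 1.1, 0.9, 1.05, 0.95, 8.0)
  scan <- gesd_outliers(x, alpha = 0.05, k_max = 1)
  expect_equal(scan$n_outliers, 1L)
  expect_equal(scan$outlier_idx, 6L)
  step1 <- oracle_gesd_step1(x, 0.05)
  expect_equal(scan$R_stats[1], unname(step1["R1"]), tolerance = 1e-12)
  expect_equal(scan$lambdas[1], unname(step1["lambda1"]), tolerance = 1e-12)
})

test_that("GESD handles degenerate input and validates preconditions", {
  expect_warning(scan <- gesd_outliers(rep(1, 10), k_max = 2), "zero variance")
  expect_equal(scan$n_outliers, 0L)
  expect_error(gesd_outliers(c(1, 2, Inf, 4, 5, 6, 7, 8)), "finite")
  expect_error(gesd_outliers(c(1, 2, 3), k_max = 5), "k_max \\+ 3")
})

test_that("GESD recovers exactly k planted outliers for k in 1..3", {
  set.seed(95)
  for (k in 1:3) {
    x <- rnorm(100)
    x[1:k] <- x[1:k] + 8  # ~8 sd shift
    scan <- gesd_outliers(x, alpha = 0.05, k_max = 5)
    expect_equal(scan$n_outliers, k)
    expect_setequal(scan$outlier_idx, 1:k)
  }
})

test_that("Mann-Whitney exact p matches hand enumeration and wilcox.test", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(mw$method, "exact")
  # same multiset: p = 1
  expect_equal(mann_whitney(c(5, 7, 9), c(9, 5, 7), method = "normal")$p_value, 1)
  # cross-oracle against wilcox.test (exact, no ties)
  set.seed(96)
  for (rep in 1:20) {
    a <- sample(1:1000, sample(2:8, 1))
    b <- sample(2000:3000, sample(2:8, 1))
    ref <- wilcox.test(a, b, exact = TRUE)
    mw <- mann_whitney(a, b)
    expect_equal(mw$U, unname(ref$statistic))
    expect_equal(mw$p_value, ref$p.value, tolerance = 1e-12)
    # one-sided agreement too
    expect_equal(mann_whitney(a, b, alternative = "a_greater")$p_value,
                 wilcox.test(a, b, alternative = "greater", exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney normal approximation matches wilcox.test with ties", {
  set.seed(97)
  for (rep in 1:10) {
    a <- sample(1:10, 20, replace = TRUE)
    b <- sample(3:12, 25, replace = TRUE)
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    mw <- mann_whitney(a, b, method = "normal")
    expect_equal(mw$U, unname(ref$statistic))
    expect_equal(mw$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney U stays within [0, n_a * n_b] and errors on empty input", {
  set.seed(98)
  for (rep in 1:20) {
    a <- rnorm(sample(1:10, 1)); b <- rnorm(sample(1:10, 1))
    mw <- mann_whitney(a, b, method = "normal")
    expect_gte(mw$U, 0); expect_lte(mw$U, mw$n_a * mw$n_b)
  }
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("ortholog filtering applies type, confidence and identity rules", {
  pairs <- data.frame(
    gene_a = sprintf("a%d", 1:4), gene_b = sprintf("b%d", 1:4),
    species = c("agossypii", "agossypii", "spombe", "spombe"),
    orthology_type = c("one-to-one", "one-to-one", "one-to-many", "one-to-one"),
    confidence = c(1, 1, 1, 0.5),
    percent_identity = c(59, 61, 80, 80),
    group_label = "initiation")
  thr <- c(agossypii = 60, .default = 30)
  kept <- filter_orthologs(pairs, thr)
  expect_equal(kept$gene_a, "a2")  # 59% identity, one-to-many and conf 0.5 all excluded
  # relaxing the rules readmits pairs
  kept2 <- filter_orthologs(pairs, thr, require_one_to_one = FALSE,
                            confidence_min = 0.5)
  expect_setequal(kept2$gene_a, c("a2", "a3", "a4"))
  expect_error(filter_orthologs(pairs, c(agossypii = 60)), "no identity threshold")
  bad <- pairs; bad$percent_identity[1] <- 105
  expect_error(filter_orthologs(bad, thr), "\\[0, 100\\]")
})

test_that("phase comparison recovers a planted omega difference", {
  make_phase <- function(omega, n, seed0) {
    data.frame(species = "sp1",
               omega = vapply(seq_len(n), function(i) {
                 ng86_pair(simulate_codon_pair(150, omega, 0.6, seed = seed0 + i)$pair)$omega
               }, 1),
               prob = 0.001)
  }
  init <- make_phase(0.3, 20, 1000)
  commit <- make_phase(0.1, 20, 2000)
  cmp <- compare_phase_evolution(init, commit, alpha = 0.05)
  expect_equal(nrow(cmp), 1)
  expect_lt(cmp$median_omega_commit, cmp$median_omega_init)
  expect_lt(cmp$p_value, 0.05)
  expect_true(cmp$U >= 0 && cmp$U <= cmp$n_init * cmp$n_commit)
})

test_that("phase comparison screens non-significant and undefined pairs", {
  init <- data.frame(species = c("sp1", "sp1", "sp1", "sp2"),
                     omega = c(0.2, NA, 0.3, 0.25),
                     prob = c(0.01, 0.01, 0.5, 0.01))
  commit <- data.frame(species = c("sp1", "sp1"),
                       omega = c(0.1, 0.15), prob = c(0.01, 0.02))
  # sp2 has no commitment pairs -> skipped with warning
  expect_warning(cmp <- compare_phase_evolution(init, commit), "skipped")
  expect_equal(cmp$species, "sp1")
  expect_equal(cmp$n_init, 1)  # NA omega and prob=0.5 rows dropped
  # disabling the significance screen readmits the prob=0.5 pair
  cmp2 <- suppressWarnings(compare_phase_evolution(init, commit,
                                                   require_significant = FALSE))
  expect_equal(cmp2$n_init[cmp2$species == "sp1"], 2)
  expect_error(compare_phase_evolution(init[0, ], commit), "nonempty")
})
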