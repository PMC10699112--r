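# Pairwise molecular-evolution statistics: NG86 dN/dS, codon-based
# Z-test for purifying selection, Rosner's GESD outlier scan and the
# Mann-Whitney rank comparison used to contrast the two meiotic phases.

#' Construct a codon alignment pair
#'
#' Wraps two gap-aligned, in-frame coding sequences.  Columns where
#' either sequence carries a gap or an ambiguity code are tolerated here
#' and skipped codon-wise by the estimators; internal stop codons in
#' gap-free columns are rejected.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length, length
#'   divisible by 3; gaps as `"-"`.
#' @param meta Optional named list of pair metadata (species, ids, ...).
#' @return An object of class `codon_alignment_pair`.
#' @export
codon_alignment_pair <- function(seq_a, seq_b, meta = list()) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("aligned sequences must have equal length (", nchar(seq_a), " vs ", nchar(seq_b), ")")
  if (nchar(seq_a) %% 3L != 0L)
    stop("alignment length ", nchar(seq_a), " is not divisible by 3")
  obj <- structure(list(seq_a = seq_a, seq_b = seq_b, meta = meta),
                   class = "codon_alignment_pair")
  cc <- codon_columns(obj)
  aa <- genetic_code_vector()
  usable <- !is.na(cc$idx_a) & !is.na(cc$idx_b)
  if (any(usable) &&
      (any(aa[cc$idx_a[usable]] == "*") || any(aa[cc$idx_b[usable]] == "*")))
    stop("internal stop codon in alignment")
  obj
}

#' @export
print.codon_alignment_pair <- function(x, ...) {
  cat("codon alignment pair:", nchar(x$seq_a) / 3, "codon columns\n")
  if (length(x$meta)) utils::str(x$meta, give.head = FALSE)
  invisible(x)
}

# Split both sequences into codon columns and map to codon indices;
# NA index for codons containing gaps or ambiguity characters (or stops,
# which the estimators skip after load-time validation).
codon_columns <- function(pair) {
  n <- nchar(pair$seq_a) %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  ca <- substring(pair$seq_a, starts, starts + 2L)
  cb <- substring(pair$seq_b, starts, starts + 2L)
  clean <- function(v) {
    ok <- !grepl("[^ACGT]", v)
    idx <- rep(NA_integer_, length(v))
    idx[ok] <- codon_index(v[ok])
    idx
  }
  list(codon_a = ca, codon_b = cb, idx_a = clean(ca), idx_b = clean(cb))
}

# Per-codon-column contributions (sites and pathway-averaged
# differences) for the usable columns of a pair.  Shared by ng86_pair()
# and the bootstrap in codon_z_test().
ng86_column_stats <- function(pair) {
  cc <- codon_columns(pair)
  aa <- genetic_code_vector()
  use <- !is.na(cc$idx_a) & !is.na(cc$idx_b)
  use[use] <- aa[cc$idx_a[use]] != "*" & aa[cc$idx_b[use]] != "*"
  ia <- cc$idx_a[use]; ib <- cc$idx_b[use]
  sites <- ng86_site_table()
  tabs <- ng86_diff_tables()
  s_col <- (sites[ia] + sites[ib]) / 2
  data.frame(
    s  = s_col,
    n  = 3 - s_col,
    sd = tabs$sd[cbind(ia, ib)],
    nd = tabs$nd[cbind(ia, ib)],
    blocked = tabs$blocked[cbind(ia, ib)]
  )
}

jukes_cantor <- function(p) {
  ifelse(p == 0, 0, -0.75 * log(1 - 4 * p / 3))
}

#' NG86 dN/dS for one aligned ortholog pair
#'
#' Estimates synonymous and nonsynonymous substitution rates by the
#' Nei-Gojobori (1986) counting method: fractional site counts per
#' codon (stop-creating changes excluded from the denominators),
#' differences attributed by averaging over all stop-free mutational
#' pathways between the observed codons, proportions corrected for
#' multiple hits with the Jukes-Cantor formula, and `omega = dN/dS`.
#'
#' @param pair A [codon_alignment_pair], or a nucleotide string (with
#'   `seq_b` supplied).
#' @param seq_b Second sequence when `pair` is given as a string.
#' @return An object of class `dnds_estimate`: a list with `S`, `N`,
#'   `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega` (NA when `dS == 0`:
#'   the ratio is undefined, not zero), `n_codons` (usable columns) and
#'   `n_blocked` (columns whose every pathway crosses a stop codon).
#' @examples
#' est <- ng86_pair(codon_alignment_pair("TTTGGG", "TTCGGG"))
#' est$Sd  # 1: TTT->TTC is one synonymous difference
#' @export
ng86_pair <- function(pair, seq_b = NULL) {
  if (!inherits(pair, "codon_alignment_pair")) {
    pair <- codon_alignment_pair(pair, seq_b)
  }
  cs <- ng86_column_stats(pair)
  if (nrow(cs) == 0L) stop("no usable codon columns in alignment")
  if (any(cs$blocked))
    warning(sum(cs$blocked), " codon column(s) had all mutational pathways ",
            "blocked by stop codons; averaged over all pathways")
  est <- ng86_from_columns(cs)
  if (est$pS >= 0.75 || est$pN >= 0.75)
    stop(errorCondition(
      sprintf("substitution saturation (pS = %.3f, pN = %.3f >= 0.75): Jukes-Cantor correction undefined",
              est$pS, est$pN),
      class = c("meiocascade_saturation", "error")))
  est$n_codons <- nrow(cs)
  est$n_blocked <- sum(cs$blocked)
  structure(est, class = "dnds_estimate")
}

# Sums column contributions into a dN/dS estimate.  Distances (and
# omega) are NA when a proportion is saturated (pX >= 0.75, where the
# Jukes-Cantor correction is undefined); the caller decides whether
# that is an error.
ng86_from_columns <- function(cs) {
  S <- sum(cs$s); N <- sum(cs$n)
  Sd <- sum(cs$sd); Nd <- sum(cs$nd)
  pS <- Sd / S; pN <- Nd / N
  sat <- pS >= 0.75 || pN >= 0.75
  dS <- if (sat) NA_real_ else jukes_cantor(pS)
  dN <- if (sat) NA_real_ else jukes_cantor(pN)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = dS, dN = dN,
       omega = if (sat || dS == 0) NA_real_ else dN / dS)
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("NG86 estimate over %d codons: S=%.2f N=%.2f Sd=%.2f Nd=%.2f\n",
              x$n_codons, x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  dS=%.4f dN=%.4f omega=%s\n", x$dS, x$dN,
              if (is.na(x$omega)) "undefined (dS = 0)" else sprintf("%.4f", x$omega)))
  invisible(x)
}

#' Codon-based Z-test for purifying selection
#'
#' Tests the alternative dN < dS (negative selection) for one pair.
#' The variance of `dS - dN` is estimated by bootstrap over codon
#' columns; `Z = (dS - dN) / SE` and the p-value is the upper normal
#' tail.
#'
#' @param pair A [codon_alignment_pair].
#' @param n_boot Number of bootstrap resamples (>= 200).
#' @param seed Integer seed for the resampling.
#' @return Object of class `selection_test`: list with `Z`, `prob`,
#'   `se`, `n_boot`, `seed` and the underlying `estimate`.
#' @export
codon_z_test <- function(pair, n_boot = 1000L, seed = NULL) {
  if (n_boot < 200L) stop("n_boot must be >= 200")
  cs <- ng86_column_stats(pair)
  if (nrow(cs) == 0L) stop("no usable codon columns in alignment")
  est <- ng86_pair(pair)
  if (est$Sd == 0 && est$Nd == 0) {
    warning("identical sequences: no substitution signal, prob = 1")
    return(structure(list(Z = 0, prob = 1, se = NA_real_, n_boot = n_boot,
                          seed = seed, estimate = est), class = "selection_test"))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cs)
  # column bootstrap as multinomial column weights
  counts <- stats::rmultinom(n_boot, n, rep.int(1 / n, n))
  m <- as.matrix(cs[, c("s", "n", "sd", "nd")])
  sums <- t(m) %*% counts                       # 4 x n_boot
  pS <- sums["sd", ] / sums["s", ]
  pN <- sums["nd", ] / sums["n", ]
  valid <- pS < 0.75 & pN < 0.75 & sums["s", ] > 0 & sums["n", ] > 0
  d <- jukes_cantor(pS[valid]) - jukes_cantor(pN[valid])
  se <- stats::sd(d)
  if (!is.finite(se) || se == 0) {
    warning("degenerate bootstrap resamples; prob = 1")
    return(structure(list(Z = 0, prob = 1, se = se, n_boot = n_boot,
                          seed = seed, estimate = est), class = "selection_test"))
  }
  Z <- (est$dS - est$dN) / se
  structure(list(Z = Z, prob = stats::pnorm(Z, lower.tail = FALSE), se = se,
                 n_boot = n_boot, seed = seed, estimate = est),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat(sprintf("codon-based Z-test (alternative dN < dS): Z = %.3f, prob = %.4g (%d bootstraps)\n",
              x$Z, x$prob, x$n_boot))
  invisible(x)
}

#' Rosner's generalized extreme Studentized deviate outlier scan
#'
#' Detects up to `k_max` outliers in approximately normal data.  At step
#' i the extreme Studentized deviate `R_i = max|x - mean(x)| / sd(x)` is
#' computed on the remaining data and the extreme point removed; the
#' critical value is
#' `lambda_i = (n - i) * t / sqrt((n - i - 1 + t^2) * (n - i + 1))`
#' with `t` the `1 - alpha / (2 (n - i + 1))` quantile of Student's t on
#' `n - i - 1` degrees of freedom.  The number of outliers is the
#' largest i with `R_i > lambda_i`.
#'
#' @param values Numeric vector, finite, length >= `k_max + 3`.
#' @param alpha Significance level (default 0.05).
#' @param k_max Maximum number of outliers to test for.
#' @return Object of class `outlier_scan`: list with `R_stats`,
#'   `lambdas`, `n_outliers`, `outlier_idx` (indices into `values`),
#'   `alpha` and `k_max`.
#' @export
gesd_outliers <- function(values, alpha = 0.05, k_max = 5L) {
  if (!all(is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (n < k_max + 3L) stop("need at least k_max + 3 observations (n = ", n, ")")
  if (stats::sd(values) == 0) {
    warning("zero variance: no outliers detectable")
    return(structure(list(R_stats = numeric(0), lambdas = numeric(0),
                          n_outliers = 0L, outlier_idx = integer(0),
                          alpha = alpha, k_max = k_max), class = "outlier_scan"))
  }
  remaining <- seq_len(n)
  R <- lam <- numeric(k_max)
  removed <- integer(k_max)
  for (i in seq_len(k_max)) {
    x <- values[remaining]
    s <- stats::sd(x)
    if (s == 0) { k_max <- i - 1L; R <- R[seq_len(k_max)]; lam <- lam[seq_len(k_max)]; removed <- removed[seq_len(k_max)]; break }
    dev <- abs(x - mean(x))
    j <- which.max(dev)
    R[i] <- dev[j] / s
    p <- 1 - alpha / (2 * (n - i + 1))
    tcrit <- stats::qt(p, df = n - i - 1)
    lam[i] <- (n - i) * tcrit / sqrt((n - i - 1 + tcrit^2) * (n - i + 1))
    removed[i] <- remaining[j]
    remaining <- remaining[-j]
  }
  hits <- which(R > lam)
  n_out <- if (length(hits)) max(hits) else 0L
  structure(list(R_stats = R, lambdas = lam, n_outliers = n_out,
                 outlier_idx = removed[seq_len(n_out)],
                 alpha = alpha, k_max = k_max), class = "outlier_scan")
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat("GESD outlier scan: ", x$n_outliers, " outlier(s) at alpha = ", x$alpha,
      " (k_max = ", x$k_max, ")\n", sep = "")
  invisible(x)
}

#' Mann-Whitney U rank comparison
#'
#' U is computed from rank sums with midranks for ties.  For samples
#' with `n_a, n_b <= 8` and no ties the p-value is exact, by
#' enumeration of all rank assignments; otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param a,b Numeric samples.
#' @param alternative `"two_sided"`, `"a_less"` or `"a_greater"`
#'   (location of `a` relative to `b`).
#' @param method `"auto"` (exact where available), `"exact"` or
#'   `"normal"`.
#' @return Object of class `rank_comparison`: list with `U` (for sample
#'   `a`), `p_value`, `method`, sample sizes, medians and means.
#' @export
mann_whitney <- function(a, b,
                         alternative = c("two_sided", "a_less", "a_greater"),
                         method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  ties <- any(duplicated(c(a, b)))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (method == "auto") {
    method <- if (!ties && na <= 8L && nb <= 8L) "exact" else "normal"
  }
  if (method == "exact") {
    if (ties) stop("exact p-value unavailable with ties")
    p <- mw_exact_p(U, na, nb, alternative)
  } else {
    mu <- na * nb / 2
    tie_tab <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    if (sigma == 0) {
      p <- 1
    } else if (alternative == "two_sided") {
      z <- max(0, abs(U - mu) - 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(-z))
    } else if (alternative == "a_greater") {
      p <- stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE)
    } else {
      p <- stats::pnorm((U - mu + 0.5) / sigma)
    }
  }
  structure(list(U = U, p_value = p, method = method, alternative = alternative,
                 n_a = na, n_b = nb,
                 median_a = stats::median(a), median_b = stats::median(b),
                 mean_a = mean(a), mean_b = mean(b)),
            class = "rank_comparison")
}

# Exact null distribution of U by enumeration of rank assignments.
mw_exact_p <- function(U, na, nb, alternative) {
  n <- na + nb
  combs <- utils::combn(n, na)
  Us <- colSums(combs) - na * (na + 1) / 2
  mu <- na * nb / 2
  switch(alternative,
         two_sided = mean(abs(Us - mu) >= abs(U - mu)),
         a_greater = mean(Us >= U),
         a_less = mean(Us <= U))
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n_a = %d, n_b = %d), p = %.4g [%s, %s]\n",
              x$U, x$n_a, x$n_b, x$p_value, x$method, x$alternative))
  cat(sprintf("  median a = %.4g, median b = %.4g\n", x$median_a, x$median_b))
  invisible(x)
}

#' Filter ortholog pairs by type, confidence and percent identity
#'
#' Applies the study's ortholog-screening rules: one-to-one orthology,
#' a minimum confidence score, and a species-specific percent-identity
#' floor (e.g. 60 for \emph{A. gossypii}, 30 for the remaining Ensembl
#' species, 70 for blastp-derived pairs).
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`, `species`,
#'   `orthology_type`, `confidence`, `percent_identity` and optionally
#'   `group_label`.
#' @param identity_min_by_species Named numeric vector of per-species
#'   identity thresholds; a `.default` entry covers unnamed species.
#' @param require_one_to_one Keep only `"one-to-one"` pairs.
#' @param confidence_min Minimum confidence score (default 1).
#' @return The retained rows of `pairs`.
#' @export
filter_orthologs <- function(pairs, identity_min_by_species,
                             require_one_to_one = TRUE, confidence_min = 1) {
  req <- c("gene_a", "gene_b", "species", "orthology_type", "confidence", "percent_identity")
  if (!all(req %in% names(pairs)))
    stop("pairs must have columns: ", paste(req, collapse = ", "))
  if (any(pairs$percent_identity < 0 | pairs$percent_identity > 100))
    stop("percent_identity must lie in [0, 100]")
  sp <- unique(pairs$species)
  missing_sp <- setdiff(sp, names(identity_min_by_species))
  if (length(missing_sp) && !".default" %in% names(identity_min_by_species))
    stop("no identity threshold for species: ", paste(missing_sp, collapse = ", "),
         " (and no .default given)")
  thr <- identity_min_by_species[pairs$species]
  thr[is.na(thr)] <- identity_min_by_species[".default"]
  keep <- pairs$confidence >= confidence_min &
    pairs$percent_identity >= unname(thr)
  if (require_one_to_one) keep <- keep & pairs$orthology_type == "one-to-one"
  pairs[keep, , drop = FALSE]
}

#' Compare purifying selection between two phase cascades
#'
#' For each species: keep pairs with a defined, unsaturated omega and
#' (by default) a significant codon Z-test; remove within-phase
#' outliers with [gesd_outliers]; then compare the omega distributions
#' of the two phases with [mann_whitney].
#'
#' @param pairs_init,pairs_commit Data frames with columns `species`,
#'   `omega`, `prob` (codon Z-test p) and optionally `pair_id`.
#' @param alpha Significance level for the comparison and the Z-test
#'   filter.
#' @param require_significant Drop pairs whose selection test is not
#'   significant at `alpha` (mirrors keeping only pairs with a
#'   significant dN/dS).
#' @param gesd_alpha,k_max Parameters passed to [gesd_outliers]; GESD is
#'   skipped for phases with fewer than `k_max + 3` pairs.
#' @param alternative Sidedness of the Mann-Whitney test.
#' @return Data frame, one row per species retained: sample sizes,
#'   mean/median omega per phase, `U` and `p_value`.
#' @export
compare_phase_evolution <- function(pairs_init, pairs_commit, alpha = 0.05,
                                    require_significant = TRUE,
                                    gesd_alpha = 0.05, k_max = 5L,
                                    alternative = "two_sided") {
  if (nrow(pairs_init) == 0L || nrow(pairs_commit) == 0L)
    stop("both phase tables must be nonempty")
  screen <- function(df) {
    keep <- is.finite(df$omega)
    if (require_significant) keep <- keep & df$prob < alpha
    df[keep, , drop = FALSE]
  }
  pairs_init <- screen(pairs_init); pairs_commit <- screen(pairs_commit)
  species <- sort(union(unique(pairs_init$species), unique(pairs_commit$species)))
  out <- list()
  for (sp in species) {
    oi <- pairs_init$omega[pairs_init$species == sp]
    oc <- pairs_commit$omega[pairs_commit$species == sp]
    if (length(oi) == 0L || length(oc) == 0L) {
      warning("species ", sp, " skipped: one phase has no usable pairs")
      next
    }
    degsd <- function(x) {
      if (length(x) >= k_max + 3L) {
        scan <- gesd_outliers(x, alpha = gesd_alpha, k_max = k_max)
        if (scan$n_outliers > 0L) x <- x[-scan$outlier_idx]
      }
      x
    }
    oi <- degsd(oi); oc <- degsd(oc)
    mw <- mann_whitney(oi, oc, alternative = alternative)
    out[[sp]] <- data.frame(
      species = sp, n_init = length(oi), n_commit = length(oc),
      mean_omega_init = mean(oi), mean_omega_commit = mean(oc),
      median_omega_init = stats::median(oi), median_omega_commit = stats::median(oc),
      U = mw$U, p_value = mw$p_value, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no species with usable pairs in both phases")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
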