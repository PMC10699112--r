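# Differential-expression screening: quantile normalization, a
# moderated Welch t-test on log2 intensities, BH adjustment, and the
# phase-specific gene-set logic (intersection across datasets for
# initiation; up-minus-reverted for commitment).

#' Quantile-normalize an expression matrix
#'
#' Forces every column to share the same distribution: the vector of
#' row means of the column-sorted matrix.  Ties within a column are
#' resolved by averaging the reference values across the tied ranks,
#' so the operation is deterministic and idempotent.
#'
#' @param mat Numeric matrix (genes x samples), no missing values,
#'   >= 2 columns.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("mat must be a numeric matrix")
  if (anyNA(mat)) stop("missing values are not supported")
  if (ncol(mat) < 2L) stop("quantile normalization needs >= 2 columns")
  ref <- rowMeans(apply(mat, 2L, sort))
  out <- apply(mat, 2L, function(col) {
    rk <- rank(col, ties.method = "average")
    (ref[floor(rk)] + ref[ceiling(rk)]) / 2
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output positions match
#' input positions.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, each in `[p_i, 1]`, monotone nondecreasing
#'   in sorted order.
#' @export
adjust_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
}

#' Moderated Welch test for differential expression
#'
#' Log2-transforms and quantile-normalizes the intensity matrix, then
#' tests each gene with a Welch two-sample t-statistic.  Per-group
#' variances are optionally shrunk toward the across-gene mean variance
#' with `d0` pseudo-degrees of freedom (a lightweight stand-in for
#' empirical-Bayes moderation, which keeps small-n behaviour sane
#' without changing the thresholds-and-set-logic character of the
#' screen).
#'
#' @param dataset An `expression_dataset` (see [simulate_expression]),
#'   or any list with `matrix` (linear scale, positive) and
#'   `condition_of`.
#' @param control,treatment Condition labels.
#' @param alpha Adjusted-p cutoff for a direction call (default 0.05).
#' @param lfc_min Minimum |log2 FC| for a direction call (default 1).
#' @param d0 Moderation weight in pseudo-degrees of freedom; 0 disables
#'   moderation (default 4).
#' @return Data frame of class `deg_table`, one row per gene:
#'   `gene_id`, `log2FC` (treatment minus control on the log2 scale),
#'   `p_raw`, `p_adj`, `direction` in `{"up", "down", "ns"}`.
#' @export
test_differential <- function(dataset, control = "control", treatment = "treatment",
                              alpha = 0.05, lfc_min = 1, d0 = 4) {
  mat <- dataset$matrix
  cond <- dataset$condition_of[colnames(mat)]
  if (!all(c(control, treatment) %in% cond))
    stop("both condition labels must be present among the samples")
  if (anyNA(mat)) stop("missing values are not supported")
  if (any(mat <= 0)) stop("intensities must be positive before log transform")
  sel <- cond %in% c(control, treatment)
  mat <- mat[, sel, drop = FALSE]
  cond <- cond[sel]
  if (sum(cond == control) < 2L || sum(cond == treatment) < 2L)
    stop("each condition needs >= 2 samples")
  lmat <- quantile_normalize(log2(mat))
  x <- lmat[, cond == treatment, drop = FALSE]
  y <- lmat[, cond == control, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  dfx <- nx - 1; dfy <- ny - 1
  if (d0 > 0) {
    v0 <- mean(c(vx, vy))
    vx <- (d0 * v0 + dfx * vx) / (d0 + dfx)
    vy <- (d0 * v0 + dfy * vy) / (d0 + dfy)
    dfx <- dfx + d0; dfy <- dfy + d0
  }
  se2x <- vx / nx; se2y <- vy / ny
  tstat <- (mx - my) / sqrt(se2x + se2y)
  df <- (se2x + se2y)^2 / (se2x^2 / dfx + se2y^2 / dfy)
  p_raw <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  p_adj <- adjust_bh(p_raw)
  lfc <- mx - my
  direction <- rep("ns", length(lfc))
  direction[p_adj < alpha & lfc > lfc_min] <- "up"
  direction[p_adj < alpha & lfc < -lfc_min] <- "down"
  res <- data.frame(gene_id = rownames(lmat), log2FC = lfc, p_raw = p_raw,
                    p_adj = p_adj, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("deg_table", "data.frame")
  res
}

deg_up <- function(deg) deg$gene_id[deg$direction == "up"]
deg_down <- function(deg) deg$gene_id[deg$direction == "down"]

#' Initiation gene set: common up-regulated genes across datasets
#'
#' Intersects the up-regulated genes of two or more differential runs
#' of the same contrast design (the study's "common upregulated genes"
#' step).
#'
#' @param deg_runs List of `deg_table`s (or of character vectors of
#'   up-regulated gene ids).
#' @return Sorted character vector of the common up genes.
#' @export
initiation_gene_set <- function(deg_runs) {
  if (length(deg_runs) == 0L) stop("need at least one DEG run")
  if (length(deg_runs) < 2L) warning("only one run supplied; intersection is trivial")
  sets <- lapply(deg_runs, function(r) if (is.character(r)) r else deg_up(r))
  common <- Reduce(intersect, sets)
  if (length(common) == 0L) warning("up-regulated sets are disjoint: empty intersection")
  sort(common)
}

#' Commitment gene set: up at commitment minus reverted on return
#'
#' Removes from the genes up-regulated at the committed stage those
#' that are down-regulated when committed cells are returned to growth
#' medium, leaving the genes whose induction survives the return —
#' the commitment signature.
#'
#' @param up_committed Genes up-regulated at commitment.
#' @param down_on_return Genes down-regulated on return to growth.
#' @return Sorted character vector `up_committed \ down_on_return`,
#'   with attribute `counts` = c(n_up, n_down, n_overlap).
#' @export
commitment_gene_set <- function(up_committed, down_on_return) {
  overlap <- intersect(up_committed, down_on_return)
  res <- sort(setdiff(up_committed, down_on_return))
  message(sprintf("commitment set: %d up, %d down-on-return, %d overlap -> %d retained",
                  length(unique(up_committed)), length(unique(down_on_return)),
                  length(overlap), length(res)))
  attr(res, "counts") <- c(n_up = length(unique(up_committed)),
                           n_down = length(unique(down_on_return)),
                           n_overlap = length(overlap))
  res
}
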