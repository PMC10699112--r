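# Phase-cascade comparison: role-wise unique and common members of two
# phase cascades (master regulators, top TFs, target genes).

#' Summarize one phase cascade into role sets
#'
#' A gene takes its highest role within the phase: MR > TF > TG, so the
#' three sets are disjoint.
#'
#' @param phase Phase label (e.g. `"initiation"`).
#' @param mr_ids,tf_ids,tg_ids Character vectors of gene ids; lower
#'   roles are stripped of genes already holding a higher one.
#' @param cascade Optionally, an [integrated_cascade] from which the
#'   role sets are read directly (overrides the id arguments).
#' @return Object of class `phase_cascade_summary`.
#' @export
phase_cascade_summary <- function(phase, mr_ids = character(0),
                                  tf_ids = character(0), tg_ids = character(0),
                                  cascade = NULL) {
  if (!is.null(cascade)) {
    stopifnot(inherits(cascade, "integrated_cascade"))
    mr_ids <- cascade$nodes$gene_id[cascade$nodes$role == "MR"]
    tf_ids <- cascade$nodes$gene_id[cascade$nodes$role == "TF"]
    tg_ids <- cascade$nodes$gene_id[cascade$nodes$role == "TG"]
  }
  mr_ids <- sort(unique(mr_ids))
  tf_ids <- sort(setdiff(unique(tf_ids), mr_ids))
  tg_ids <- sort(setdiff(unique(tg_ids), c(mr_ids, tf_ids)))
  structure(list(phase = phase, mr_ids = mr_ids, tf_ids = tf_ids, tg_ids = tg_ids),
            class = "phase_cascade_summary")
}

#' @export
print.phase_cascade_summary <- function(x, ...) {
  cat(sprintf("phase '%s': %d MRs, %d TFs, %d TGs (%d genes)\n", x$phase,
              length(x$mr_ids), length(x$tf_ids), length(x$tg_ids),
              length(x$mr_ids) + length(x$tf_ids) + length(x$tg_ids)))
  invisible(x)
}

#' Compare two phase cascades role-wise
#'
#' For each role (MR, TF, TG) computes the members unique to each phase
#' and common to both.  Roles are compared per phase, not per gene: a
#' gene may legitimately be a unique TF of one phase and a unique TG of
#' the other.
#'
#' @param a,b `phase_cascade_summary` objects with distinct phase
#'   labels.
#' @return Object of class `cascade_comparison`: list with `unique_a`,
#'   `unique_b`, `common` (each a list of `mr`, `tf`, `tg` sets),
#'   phase labels, and `counts` (role-wise sizes incl. per-phase unique
#'   totals).
#' @export
compare_cascades <- function(a, b) {
  stopifnot(inherits(a, "phase_cascade_summary"), inherits(b, "phase_cascade_summary"))
  if (identical(a$phase, b$phase)) stop("phase labels must differ")
  roles <- c(mr = "mr_ids", tf = "tf_ids", tg = "tg_ids")
  unique_a <- unique_b <- common <- list()
  for (r in names(roles)) {
    sa <- a[[roles[[r]]]]; sb <- b[[roles[[r]]]]
    unique_a[[r]] <- sort(setdiff(sa, sb))
    unique_b[[r]] <- sort(setdiff(sb, sa))
    common[[r]] <- sort(intersect(sa, sb))
  }
  counts <- data.frame(
    role = names(roles),
    unique_a = vapply(unique_a, length, 1L),
    unique_b = vapply(unique_b, length, 1L),
    common = vapply(common, length, 1L), row.names = NULL)
  structure(list(phase_a = a$phase, phase_b = b$phase,
                 unique_a = unique_a, unique_b = unique_b, common = common,
                 counts = counts,
                 total_unique_a = sum(counts$unique_a),
                 total_unique_b = sum(counts$unique_b)),
            class = "cascade_comparison")
}

#' @export
print.cascade_comparison <- function(x, ...) {
  cat(sprintf("cascade comparison: %s vs %s\n", x$phase_a, x$phase_b))
  print(x$counts)
  cat(sprintf("total unique: %d (%s), %d (%s)\n", x$total_unique_a, x$phase_a,
              x$total_unique_b, x$phase_b))
  invisible(x)
}

#' Flatten a cascade comparison into a gene table
#'
#' @param comparison A `cascade_comparison`.
#' @return Data frame with `gene_id`, `role_in_a`, `role_in_b`,
#'   `partition` (`unique_a` / `unique_b` / `common`), one row per
#'   (gene, role-partition) assignment.
#' @export
comparison_table <- function(comparison) {
  rows <- list()
  add <- function(ids, role, part, ra, rb) {
    if (length(ids))
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = ids, role_in_a = ra, role_in_b = rb, partition = part,
        stringsAsFactors = FALSE)
  }
  for (r in c("mr", "tf", "tg")) {
    up <- toupper(r)
    add(comparison$unique_a[[r]], r, "unique_a", up, "-")
    add(comparison$unique_b[[r]], r, "unique_b", "-", up)
    add(comparison$common[[r]], r, "common", up, up)
  }
  out <- do.call(rbind, rows)
  out[order(out$partition, out$gene_id), , drop = FALSE]
}
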