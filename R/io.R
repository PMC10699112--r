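# Readers and writers for the flat formats the pipeline consumes and
# emits: TSV tables, paired FASTA alignments, GMT annotation files,
# SIF/GraphML network exports, JSON reports.  All tables are UTF-8 TSV
# with header rows; gene ids are opaque strings.

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required) && !all(required %in% names(df)))
    stop(path, " must have columns: ", paste(required, collapse = ", "))
  df
}

#' Write / read an expression dataset
#'
#' The matrix TSV has genes as rows (first column `gene_id`) and sample
#' ids as the remaining column names; the condition map TSV has columns
#' `sample_id`, `condition`.
#'
#' @param dataset An `expression_dataset`.
#' @param matrix_path,conditions_path Output (or input) file paths.
#' @return `write_expression`: invisibly, the paths.
#'   `read_expression`: an `expression_dataset`.
#' @export
write_expression <- function(dataset, matrix_path, conditions_path) {
  df <- data.frame(gene_id = dataset$gene_ids, dataset$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, matrix_path)
  write_tsv_file(data.frame(sample_id = dataset$sample_ids,
                            condition = unname(dataset$condition_of[dataset$sample_ids])),
                 conditions_path)
  invisible(c(matrix_path, conditions_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(matrix_path, conditions_path) {
  df <- read_tsv_file(matrix_path, required = "gene_id")
  cond <- read_tsv_file(conditions_path, required = c("sample_id", "condition"))
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  if (!all(colnames(mat) %in% cond$sample_id))
    stop("condition map does not cover all samples")
  structure(list(matrix = mat,
                 condition_of = stats::setNames(cond$condition, cond$sample_id)[colnames(mat)],
                 gene_ids = rownames(mat), sample_ids = colnames(mat),
                 contrast_label = basename(matrix_path)),
            class = "expression_dataset")
}

#' Read a two-record aligned FASTA into a codon alignment pair
#'
#' @param path FASTA file with exactly two gap-aligned, in-frame
#'   records (gaps as `-`); record ids conventionally
#'   `<species>|<gene>`.
#' @return A [codon_alignment_pair] with `meta$id_a`, `meta$id_b`.
#' @export
read_fasta_pair <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2L)
    stop("expected exactly two records in ", path, ", found ", length(recs))
  codon_alignment_pair(as.character(recs[[1]]), as.character(recs[[2]]),
                       meta = list(id_a = names(recs)[1], id_b = names(recs)[2],
                                   path = path))
}

#' Write a codon alignment pair as FASTA
#'
#' @param pair A [codon_alignment_pair].
#' @param path Output path.
#' @param ids Record ids (default from `pair$meta`, else `seq_a` /
#'   `seq_b`).
#' @export
write_fasta_pair <- function(pair, path, ids = NULL) {
  if (is.null(ids)) {
    ids <- c(pair$meta$id_a %||% "seq_a", pair$meta$id_b %||% "seq_b")
  }
  set <- Biostrings::BStringSet(c(pair$seq_a, pair$seq_b))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write GMT annotation files
#'
#' GMT: one term per line, tab-separated: term id, description, then
#' member gene ids.  Duplicate term ids and malformed lines are
#' rejected with the offending line number.
#'
#' @param path GMT file path.
#' @return `read_gmt`: an [annotation_set] whose universe is the union
#'   of all members.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], " in ", path, " (need >= 3 tab-separated fields)")
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id in ", path, ": ", ids[duplicated(ids)][1])
  terms <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  desc <- stats::setNames(vapply(parts, `[[`, "", 2L), ids)
  annotation_set(terms, descriptions = desc)
}

#' @rdname read_gmt
#' @param annotations An [annotation_set] to write.
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  lines <- vapply(names(annotations$terms), function(id) {
    paste(c(id, annotations$descriptions[[id]], annotations$terms[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export an integrated cascade
#'
#' `cascade_to_igraph` builds a directed igraph with node attributes
#' `role`, `v`, `in_deg`, `out_deg` and edge attribute `layer`;
#' `write_cascade_graphml` / `write_cascade_sif` serialize it for
#' external network viewers.
#'
#' @param cascade An [integrated_cascade].
#' @return An igraph object.
#' @export
cascade_to_igraph <- function(cascade) {
  stopifnot(inherits(cascade, "integrated_cascade"))
  g <- igraph::graph_from_data_frame(cascade$edges, directed = TRUE,
                                     vertices = cascade$nodes)
  g
}

#' @rdname cascade_to_igraph
#' @param path Output path.
#' @export
write_cascade_graphml <- function(cascade, path) {
  igraph::write_graph(cascade_to_igraph(cascade), path, format = "graphml")
  invisible(path)
}

#' @rdname cascade_to_igraph
#' @export
write_cascade_sif <- function(cascade, path) {
  writeLines(sprintf("%s\t%s\t%s", cascade$edges$source, cascade$edges$layer,
                     cascade$edges$target), path)
  invisible(path)
}

#' Write a DEG table / cascade node table / gene set
#' @param deg A `deg_table` from [test_differential].
#' @param path Output path.
#' @export
write_deg_table <- function(deg, path) write_tsv_file(deg, path)

#' @rdname write_deg_table
#' @param cascade An [integrated_cascade].
#' @export
write_cascade_nodes <- function(cascade, path) write_tsv_file(cascade$nodes, path)

#' @rdname write_deg_table
#' @param genes Character vector, one id per line.
#' @export
write_gene_set <- function(genes, path) { writeLines(genes, path); invisible(path) }

#' @rdname write_deg_table
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x[nzchar(x)]
}

#' Read an ortholog metadata table
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `species`,
#'   `orthology_type`, `confidence`, `percent_identity`, `group_label`
#'   and optionally `alignment_file`.
#' @return Data frame.
#' @export
read_ortholog_table <- function(path) {
  read_tsv_file(path, required = c("gene_a", "gene_b", "species", "orthology_type",
                                   "confidence", "percent_identity", "group_label"))
}
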