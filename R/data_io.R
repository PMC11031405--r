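#' Construct a peptide-level intensity table
#'
#' Container for a peptide x sample intensity matrix together with the
#' peptide-to-protein map and the scale the values are on. Missing values
#' are encoded as `NA`, never as 0.
#'
#' @param values numeric matrix, peptides x samples; `NA` marks missing.
#' @param peptide_id,protein_id character vectors parallel to the rows.
#' @param scale `"raw"` (nonnegative intensities) or `"log2"`.
#' @return An object of class `peptide_table`: a list with elements
#'   `values`, `peptide_id`, `protein_id`, `scale`.
#' @export
peptide_table <- function(values, peptide_id, protein_id,
                          scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_that(length(peptide_id) == nrow(values) &&
                length(protein_id) == nrow(values),
              "peptide_id/protein_id must match the number of rows")
  dup <- peptide_id[duplicated(peptide_id)]
  if (length(dup)) {
    abort_ctx("duplicate peptide_id: ", paste(unique(dup), collapse = ", "))
  }
  if (scale == "raw" && any(values < 0, na.rm = TRUE)) {
    abort_ctx("negative raw intensities found")
  }
  rownames(values) <- peptide_id
  structure(list(values = values,
                 peptide_id = as.character(peptide_id),
                 protein_id = as.character(protein_id),
                 scale = scale),
            class = "peptide_table")
}

#' @export
print.peptide_table <- function(x, ...) {
  cat(sprintf("peptide_table: %d peptides (%d proteins) x %d samples [%s], %d missing\n",
              nrow(x$values), length(unique(x$protein_id)), ncol(x$values),
              x$scale, sum(is.na(x$values))))
  invisible(x)
}

#' Read a peptide intensity table from TSV
#'
#' Expects a header row; the first two columns are `peptide_id` and
#' `protein_id`, the remaining columns are per-sample intensities. Empty
#' cells and `NA` are read as missing. Peptides mapped to a protein group
#' (`"A;B"`) are dropped with a message, since group ambiguity must not
#' leak into protein-level quantification.
#'
#' @param path TSV file path.
#' @param scale scale of the stored values, `"raw"` or `"log2"`.
#' @return A [peptide_table()]; attribute `n_shared_dropped` counts dropped
#'   shared peptides.
#' @export
read_intensity_table <- function(path, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  assert_that(ncol(df) >= 3, "intensity table needs peptide_id, protein_id and >=1 sample column")
  names(df)[1:2] <- c("peptide_id", "protein_id")
  shared <- grepl(";", df$protein_id, fixed = TRUE)
  n_shared <- sum(shared)
  if (n_shared > 0) {
    message(n_shared, " shared peptide(s) mapping to protein groups dropped")
    df <- df[!shared, , drop = FALSE]
  }
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(vals)) abort_ctx("non-numeric intensity column in ", path)
  tab <- peptide_table(vals, df$peptide_id, df$protein_id, scale = scale)
  attr(tab, "n_shared_dropped") <- n_shared
  tab
}

#' Read a sample design table
#'
#' Required columns: `sample_id`, `age`, `drug`, `induction`, `replicate`,
#' `batch`, `dataset_id`. Factor levels are inferred from the data; the
#' cell counts of the age x drug x induction layout are attached as
#' attribute `cell_counts` for validation reporting.
#'
#' @param path TSV file path.
#' @return A `data.frame` of class `sample_design`.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_design(df)
}

#' @rdname read_design
#' @param df data.frame with the required design columns.
#' @export
sample_design <- function(df) {
  req <- c("sample_id", "age", "drug", "induction", "replicate", "batch",
           "dataset_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort_ctx("design is missing required column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) abort_ctx("duplicated sample_id: ", paste(dup, collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  assert_that(all(df$replicate >= 1), "replicate must be a positive integer")
  for (f in c("age", "drug", "induction", "batch", "dataset_id")) {
    df[[f]] <- as.character(df[[f]])
  }
  cells <- table(design_cells(df))
  attr(df, "cell_counts") <- cells
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Read a STRING-style interaction edge list
#'
#' Whitespace- or tab-delimited rows `protein1 protein2 combined_score`
#' (integer scores, 0-999). An optional header line is detected and
#' skipped. Edges are kept only if `combined_score > score_threshold`
#' (strict, matching the high-confidence cut ">899"); self-loops are
#' dropped and duplicate/reciprocal edges merged keeping the maximum
#' score.
#'
#' @param path edge list file.
#' @param score_threshold integer; strict lower bound on retained scores.
#' @return An `interaction_graph` (see [interaction_graph()]).
#' @export
read_network_edges <- function(path, score_threshold = 899) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("combined_score|protein1", first)
  df <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE,
                          col.names = c("protein1", "protein2", "combined_score"))
  if (!is.numeric(df$combined_score) ||
      any(df$combined_score != round(df$combined_score))) {
    abort_ctx("combined_score must be integer-valued")
  }
  interaction_graph(df$protein1, df$protein2, as.integer(df$combined_score),
                    score_threshold = score_threshold)
}

#' Construct an interaction graph from an edge list
#'
#' @param protein1,protein2 character endpoint vectors.
#' @param combined_score integer confidence scores (STRING convention,
#'   0-999).
#' @param score_threshold strict threshold; only `score > threshold` edges
#'   are retained. Use `-1` to keep everything.
#' @return `interaction_graph`: list with `edges` (data.frame `protein1`,
#'   `protein2`, `combined_score`, endpoints ordered so protein1 < protein2),
#'   and `nodes` (sorted unique ids).
#' @export
interaction_graph <- function(protein1, protein2, combined_score,
                              score_threshold = -1L) {
  keep <- combined_score > score_threshold & protein1 != protein2
  if (!any(keep)) abort_ctx("no edges survive the score threshold")
  p1 <- as.character(protein1[keep])
  p2 <- as.character(protein2[keep])
  sc <- as.integer(combined_score[keep])
  lo <- pmin(p1, p2)
  hi <- pmax(p1, p2)
  key <- paste(lo, hi, sep = "\r")
  # reciprocal/duplicate rows collapse to one undirected edge, max score
  agg <- tapply(sc, key, max)
  keys <- names(agg)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(protein1 = vapply(parts, `[`, "", 1L),
                      protein2 = vapply(parts, `[`, "", 2L),
                      combined_score = as.integer(agg),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$protein1, edges$protein2), , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0L) abort_ctx("no edges survive the score threshold")
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$protein1, edges$protein2)))),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node degrees of an interaction graph
#'
#' Number of interaction partners per node (binary degree, independent of
#' edge scores).
#' @param graph an `interaction_graph`.
#' @return named integer vector over `graph$nodes`.
#' @export
graph_degree <- function(graph) {
  tab <- table(factor(c(graph$edges$protein1, graph$edges$protein2),
                      levels = graph$nodes))
  out <- as.integer(tab)
  names(out) <- graph$nodes
  out
}

#' Read term-to-gene annotations
#'
#' Two formats: `two_column` (TSV `term_id<TAB>gene_id`, optional header)
#' and `gaf` (GAF 2.x: gene id in column 2, qualifier in column 4, term in
#' column 5; `!` comment lines and NOT-qualified lines are excluded,
#' malformed lines are skipped with a logged count).
#'
#' @param path annotation file.
#' @param format `"two_column"` or `"gaf"`.
#' @return An `annotation_set` (see [annotation_set()]); attribute
#'   `n_skipped` counts skipped malformed lines.
#' @export
read_annotations <- function(path, format = c("two_column", "gaf")) {
  format <- match.arg(format)
  n_skipped <- 0L
  if (format == "two_column") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) && grepl("^term_id\t", lines[1])) lines <- lines[-1]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(parts) >= 2L
    n_skipped <- sum(!ok)
    parts <- parts[ok]
    term <- vapply(parts, `[`, "", 1L)
    gene <- vapply(parts, `[`, "", 2L)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(parts) >= 5L
    n_skipped <- sum(!ok)
    parts <- parts[ok]
    qualifier <- vapply(parts, `[`, "", 4L)
    not <- grepl("(^|\\|)NOT($|\\|)", qualifier)
    parts <- parts[!not]
    gene <- vapply(parts, `[`, "", 2L)
    term <- vapply(parts, `[`, "", 5L)
  }
  if (n_skipped > 0) message(n_skipped, " malformed annotation line(s) skipped")
  ann <- annotation_set(term, gene)
  attr(ann, "n_skipped") <- n_skipped
  ann
}

#' Construct an annotation set
#'
#' @param term_id,gene_id parallel character vectors (one pair per
#'   annotation; duplicates removed).
#' @param parents optional named list mapping a term id to its parent term
#'   ids (used by [close_annotations()]).
#' @return `annotation_set`: list with `terms` (named list term ->
#'   character vector of genes) and `parents`.
#' @export
annotation_set <- function(term_id, gene_id, parents = NULL) {
  assert_that(length(term_id) == length(gene_id),
              "term_id and gene_id must have equal length")
  if (length(term_id) == 0L) abort_ctx("empty annotation set")
  pairs <- unique(data.frame(term = as.character(term_id),
                             gene = as.character(gene_id),
                             stringsAsFactors = FALSE))
  terms <- split(pairs$gene, pairs$term)
  terms <- terms[order(names(terms))]
  structure(list(terms = terms, parents = parents), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d terms, %d annotation pairs\n",
              length(x$terms), sum(lengths(x$terms))))
  invisible(x)
}

#' Read a gene set (one id per line)
#'
#' @param path file with one gene/protein id per line; blank lines ignored.
#' @param name optional set name (defaults to the file name).
#' @return `gene_set`: list with `name` and `members`.
#' @export
read_gene_set <- function(path, name = NULL) {
  ids <- readLines(path)
  ids <- ids[nzchar(trimws(ids))]
  gene_set(name %||% basename(path), ids)
}

#' @rdname read_gene_set
#' @param members character vector of member ids.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  assert_that(length(members) > 0, "gene set must be nonempty")
  structure(list(name = name, members = members), class = "gene_set")
}

#' Write a pipeline table to TSV
#'
#' Deterministic output: stable column order, rows sorted on the id-like
#' columns, missing written as `NA`, floating point at 6 significant
#' digits. Matrix-backed types (protein tables) are written with their ids
#' in the first column.
#'
#' @param x a data.frame, matrix, `peptide_table` or `protein_table`.
#' @param path output file.
#' @export
write_table <- function(x, path) UseMethod("write_table")

#' @export
write_table.data.frame <- function(x, path) {
  sort_cols <- intersect(c("protein_id", "peptide_id", "term_id", "gene_id",
                           "sample_id", "node", "contrast", "direction"),
                         names(x))
  if (length(sort_cols)) {
    x <- x[do.call(order, x[sort_cols]), , drop = FALSE]
  }
  out <- as.data.frame(lapply(x, format_col), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(x)
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' @export
write_table.matrix <- function(x, path) {
  df <- data.frame(id = rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- df[order(df$id), , drop = FALSE]
  write_table.data.frame(df, path)
}

#' @export
write_table.protein_table <- function(x, path) {
  m <- unclass(x)
  df <- data.frame(protein_id = rownames(m),
                   as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table.data.frame(df, path)
}

#' @export
write_table.peptide_table <- function(x, path) {
  df <- data.frame(peptide_id = x$peptide_id, protein_id = x$protein_id,
                   as.data.frame(x$values, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table.data.frame(df, path)
}

#' Read a protein table written by [write_table()]
#'
#' @param path TSV with `protein_id` first column, one column per sample.
#' @return a `protein_table` (log2-scale matrix with `NA` for missing).
#' @export
read_protein_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  protein_table(m)
}

#' Construct a protein-level table
#'
#' @param values numeric matrix proteins x samples, log2 scale, `NA`
#'   missing.
#' @return object of class `protein_table` (a matrix).
#' @export
protein_table <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_that(nrow(values) == 0L || !is.null(rownames(values)),
              "protein_table needs protein ids as rownames")
  assert_that(!anyDuplicated(rownames(values)), "duplicate protein ids")
  structure(values, class = c("protein_table", "matrix", "array"))
}
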