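#' Read a gene-by-sample read-count table
#'
#' Ingests a headered TSV whose first column holds gene identifiers and whose
#' remaining columns hold non-negative integer read counts, one column per
#' sample (the layout produced by per-gene counting tools such as HTSeq).
#'
#' @param path path to the TSV file.
#' @return An integer matrix with gene ids as row names and sample ids as
#'   column names, validated by [validate_counts()].
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("count table must have a gene-id column and at least one sample column")
  gene_ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  validate_counts(m, source = path)
}

#' Validate a count matrix
#'
#' Checks the contract shared by every selection operation: unique gene and
#' sample ids, no missing values, and non-negative integral counts.
#'
#' @param counts numeric matrix, genes in rows, samples in columns.
#' @param source label used in error messages.
#' @return The validated matrix with integer storage mode.
#' @export
validate_counts <- function(counts, source = "count matrix") {
  if (is.null(colnames(counts)) ||
      (nrow(counts) > 0L && is.null(rownames(counts))))
    stop(source, ": gene (row) and sample (column) names are required")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop(source, ": duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop(source, ": duplicate sample id(s): ",
         paste(unique(dup), collapse = ", "))
  na_idx <- which(is.na(counts), arr.ind = TRUE)
  if (nrow(na_idx))
    stop(source, ": missing value at gene '",
         rownames(counts)[na_idx[1L, 1L]], "', sample '",
         colnames(counts)[na_idx[1L, 2L]], "'")
  if (any(counts < 0))
    stop(source, ": negative count(s), first at gene '",
         rownames(counts)[which(counts < 0, arr.ind = TRUE)[1L, 1L]], "'")
  if (any(counts != floor(counts)))
    stop(source, ": non-integer count(s), first at gene '",
         rownames(counts)[which(counts != floor(counts),
                                arr.ind = TRUE)[1L, 1L]], "'")
  storage.mode(counts) <- "integer"
  counts
}

#' Write a count matrix as TSV
#'
#' @param counts validated count matrix.
#' @param path output path. First column `gene_id`, then one column per sample.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
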