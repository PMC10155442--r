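#' Selection parameters for the top-fraction screen
#'
#' @param top_fraction fraction of genes kept per sample (default 0.03, the
#'   "top 3 percent" cutoff).
#' @param min_samples number of samples a gene must qualify in to enter the
#'   intersection; `NULL` (default) means all samples.
#' @param aggregation how replicate columns mapped to the same condition are
#'   combined before ranking: `"sum"` (default), `"mean"`, or `"none"`.
#' @param boundary_mode `"truncate"` keeps exactly the first k genes of the
#'   ranking (k = ceiling(top_fraction * n_genes)); `"ties"` additionally
#'   keeps every gene tied with the count at rank k.
#' @param normalize `"none"` ranks raw read counts (the default — rankings
#'   follow raw counts, not length-normalised values); `"cpm"` ranks counts
#'   per million library reads instead.
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(top_fraction = 0.03, min_samples = NULL,
                             aggregation = c("sum", "mean", "none"),
                             boundary_mode = c("truncate", "ties"),
                             normalize = c("none", "cpm")) {
  stopifnot_scalar_number(top_fraction, "top_fraction")
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must satisfy 0 < top_fraction <= 1")
  if (!is.null(min_samples)) {
    stopifnot_scalar_number(min_samples, "min_samples", positive = TRUE)
    min_samples <- as.integer(min_samples)
  }
  structure(list(top_fraction = top_fraction, min_samples = min_samples,
                 aggregation = match.arg(aggregation),
                 boundary_mode = match.arg(boundary_mode),
                 normalize = match.arg(normalize)),
            class = "selection_params")
}

# Collapse replicate columns of one condition into a single column.
# sample_groups: named character vector, names = column names of counts,
# values = condition labels. NULL leaves the matrix untouched.
aggregate_replicates <- function(counts, sample_groups = NULL,
                                 aggregation = "sum") {
  if (is.null(sample_groups) || aggregation == "none") return(counts)
  missing_cols <- setdiff(colnames(counts), names(sample_groups))
  if (length(missing_cols))
    stop("sample_groups does not cover column(s): ",
         paste(missing_cols, collapse = ", "))
  groups <- sample_groups[colnames(counts)]
  out <- vapply(unique(groups), function(g) {
    sub <- counts[, groups == g, drop = FALSE]
    v <- rowSums(sub)
    if (aggregation == "mean") v <- v / ncol(sub)
    v
  }, numeric(nrow(counts)))
  out <- round(out)
  rownames(out) <- rownames(counts)
  storage.mode(out) <- "integer"
  out
}

ranking_values <- function(counts, normalize) {
  if (normalize == "cpm") {
    libsize <- colSums(counts)
    libsize[libsize == 0] <- 1
    sweep(counts, 2L, libsize, "/") * 1e6
  } else counts
}

#' Rank genes within one sample by read count
#'
#' Genes are ordered from the highest to the lowest count; rank 1 is the most
#' highly expressed gene. Ties are broken deterministically by ascending gene
#' id so that repeated runs give identical rankings.
#'
#' @param counts validated count matrix.
#' @param sample sample (column) id.
#' @param normalize `"none"` or `"cpm"`, see [selection_params()].
#' @return Character vector of gene ids, highest expression first.
#' @export
rank_genes <- function(counts, sample, normalize = "none") {
  if (!sample %in% colnames(counts))
    stop("unknown sample: '", sample, "'")
  v <- ranking_values(counts, normalize)[, sample]
  rownames(counts)[order(-v, rownames(counts), method = "radix")]
}

#' Top-fraction gene set of one sample
#'
#' Keeps the first k genes of the per-sample ranking with
#' k = ceiling(top_fraction * n_genes); with `boundary_mode = "ties"` every
#' gene whose count ties the count at rank k is kept as well.
#'
#' @inheritParams rank_genes
#' @param params a [selection_params()].
#' @return Character vector of gene ids (ordered by rank).
#' @export
top_fraction_set <- function(counts, sample, params = selection_params()) {
  n <- nrow(counts)
  k <- as.integer(ceiling(params$top_fraction * n))
  if (k == 0L) {
    warning("empty count matrix: top set is empty")
    return(character())
  }
  ranked <- rank_genes(counts, sample, params$normalize)
  if (params$boundary_mode == "ties" && k < n) {
    v <- ranking_values(counts, params$normalize)[, sample]
    cutoff_value <- v[ranked[k]]
    k <- max(which(v[ranked] >= cutoff_value))
  }
  ranked[seq_len(k)]
}

#' Intersect per-sample top sets across conditions
#'
#' The screen's core set operation: a gene is nominated as a constitutive
#' high-expresser when it sits in the top fraction of at least `min_samples`
#' samples (by default, of every sample).
#'
#' @inheritParams top_fraction_set
#' @param sample_groups optional named vector mapping replicate columns to
#'   condition labels; replicates are combined per `params$aggregation`
#'   before ranking.
#' @return An object of class `selection_result` with elements
#'   `per_sample_top` (named list, ordered gene vectors), `intersection`
#'   (character), `cutoff_size_per_sample` (named integer),
#'   `ranking_table` (data frame of per-sample ranks plus qualifying flags),
#'   and `params`.
#' @export
intersect_top_sets <- function(counts, params = selection_params(),
                               sample_groups = NULL) {
  counts <- aggregate_replicates(counts, sample_groups, params$aggregation)
  if (ncol(counts) < 1L) stop("at least one sample is required")
  samples <- colnames(counts)
  per_sample_top <- lapply(samples, function(s)
    top_fraction_set(counts, s, params))
  names(per_sample_top) <- samples
  min_samples <- params$min_samples %||% length(samples)
  if (min_samples > length(samples))
    stop("min_samples (", min_samples, ") exceeds the number of samples (",
         length(samples), ")")
  qualifies <- vapply(per_sample_top, function(s)
    rownames(counts) %in% s, logical(nrow(counts)))
  if (nrow(counts) == 1L) qualifies <- matrix(qualifies, nrow = 1L)
  n_qual <- rowSums(qualifies)
  intersection <- rownames(counts)[n_qual >= min_samples]
  ranks <- vapply(samples, function(s) {
    ranked <- rank_genes(counts, s, params$normalize)
    match(rownames(counts), ranked)
  }, integer(nrow(counts)))
  if (nrow(counts) == 1L) ranks <- matrix(ranks, nrow = 1L)
  colnames(ranks) <- paste0("rank_", samples)
  qcols <- qualifies
  colnames(qcols) <- paste0("top_", samples)
  ranking_table <- data.frame(gene_id = rownames(counts), ranks, qcols,
                              in_intersection = rownames(counts) %in%
                                intersection,
                              check.names = FALSE, stringsAsFactors = FALSE)
  structure(
    list(per_sample_top = per_sample_top,
         intersection = intersection,
         cutoff_size_per_sample = vapply(per_sample_top, length, integer(1)),
         ranking_table = ranking_table,
         params = params),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d samples, top fraction %.3g, intersection: %d genes\n",
    length(x$per_sample_top), x$params$top_fraction, length(x$intersection)))
  cat("per-sample top-set sizes:",
      paste(sprintf("%s=%d", names(x$cutoff_size_per_sample),
                    x$cutoff_size_per_sample), collapse = ", "), "\n")
  invisible(x)
}

#' Write a selection report
#'
#' Writes the per-gene ranking/qualification table as TSV and the per-sample
#' top sets as JSON (for Venn-style reporting).
#'
#' @param result a `selection_result`.
#' @param tsv_path output TSV path.
#' @param json_path optional JSON path for the per-sample sets.
#' @return Invisibly, the paths written.
#' @export
write_selection_report <- function(result, tsv_path, json_path = NULL) {
  utils::write.table(result$ranking_table, tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out <- tsv_path
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_sample_top = result$per_sample_top,
           intersection = result$intersection),
      json_path, pretty = TRUE)
    out <- c(out, json_path)
  }
  invisible(out)
}
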