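#' Screen a genome for strong constitutive promoters
#'
#' The package's central operation. Genes are ranked within each sample by
#' raw read count; the top fraction of every sample is intersected across
#' samples to nominate constitutive high-expressers; for each nominated gene
#' the strand-aware upstream intergenic region is computed from the
#' annotation and filtered by a minimum length. Genes present in the count
#' table but absent from the annotation are carried through selection and
#' reported separately, never dropped silently.
#'
#' @param counts validated count matrix (see [read_count_table()]).
#' @param annotation a [genome_annotation()].
#' @param params a [selection_params()].
#' @param min_length minimum promoter length in bp (default 100).
#' @param sample_groups optional named vector mapping replicate columns to
#'   conditions (see [intersect_top_sets()]).
#' @return Object of class `promoter_screen` with elements `selection`
#'   (the `selection_result`), `regions` (all candidate regions),
#'   `retained`, `excluded` (the length-filter partition), `unannotated`
#'   (intersection genes missing from the annotation), `min_length`,
#'   and `counts_summary` (stage-by-stage counts).
#' @export
promoter_screen <- function(counts, annotation,
                            params = selection_params(),
                            min_length = 100, sample_groups = NULL) {
  counts <- validate_counts(counts)
  if (nrow(counts) == 0L) stop("empty count table: no genes to screen")
  stopifnot(inherits(annotation, "genome_annotation"))
  selection <- intersect_top_sets(counts, params, sample_groups)
  candidates <- selection$intersection
  annotated <- intersect(candidates, annotation$genes$gene_id)
  unannotated <- setdiff(candidates, annotation$genes$gene_id)
  regions <- if (length(annotated)) extract_promoters(annotation, annotated)
             else NULL
  flt <- filter_promoters(regions, min_length)
  counts_summary <- c(
    n_genes = nrow(counts),
    n_samples = length(selection$per_sample_top),
    intersection = length(candidates),
    annotated = length(annotated),
    unannotated = length(unannotated),
    excluded_short = if (is.null(flt$excluded)) 0L else nrow(flt$excluded),
    retained = if (is.null(flt$retained)) 0L else nrow(flt$retained))
  structure(list(selection = selection, regions = regions,
                 retained = flt$retained, excluded = flt$excluded,
                 unannotated = unannotated, min_length = min_length,
                 params = params, counts_summary = counts_summary),
            class = "promoter_screen")
}

#' @export
print.promoter_screen <- function(x, ...) {
  cs <- x$counts_summary
  cat("<promoter_screen>\n")
  cat(sprintf("  %d genes x %d samples, top fraction %.3g (%s boundary)\n",
              cs[["n_genes"]], cs[["n_samples"]], x$params$top_fraction,
              x$params$boundary_mode))
  cat(sprintf("  intersection across samples: %d genes (%d unannotated)\n",
              cs[["intersection"]], cs[["unannotated"]]))
  cat(sprintf("  upstream regions >= %d bp: %d retained, %d excluded\n",
              x$min_length, cs[["retained"]], cs[["excluded_short"]]))
  invisible(x)
}

#' @export
summary.promoter_screen <- function(object, ...) {
  cs <- object$counts_summary
  out <- list(
    counts = cs,
    per_sample_top_sizes = object$selection$cutoff_size_per_sample,
    retained = if (!is.null(object$retained))
      object$retained[, c("promoter_id", "gene_id", "length", "strand")]
      else NULL,
    excluded = if (!is.null(object$excluded))
      object$excluded[, c("promoter_id", "gene_id", "length", "strand")]
      else NULL,
    unannotated = object$unannotated)
  class(out) <- "summary.promoter_screen"
  out
}

#' @export
print.summary.promoter_screen <- function(x, ...) {
  cat("promoter screen summary\n")
  cat("stage counts:\n")
  print(x$counts)
  if (!is.null(x$retained) && nrow(x$retained)) {
    cat("retained promoter regions:\n")
    print(x$retained, row.names = FALSE)
  }
  if (!is.null(x$excluded) && nrow(x$excluded)) {
    cat("excluded (too short):\n")
    print(x$excluded, row.names = FALSE)
  }
  if (length(x$unannotated))
    cat("in intersection but unannotated:",
        paste(x$unannotated, collapse = ", "), "\n")
  invisible(x)
}
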