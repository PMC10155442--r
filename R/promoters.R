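#' Upstream intergenic region of one gene
#'
#' Computes the strand-aware upstream intergenic region of a gene: the span
#' between the gene's 5' boundary and the nearest annotated feature boundary
#' on its 5' side, irrespective of that neighbour's strand. For a `+` strand
#' gene this walks left from the gene start; for a `-` strand gene it walks
#' right from the gene end. On circular replicons the walk wraps across the
#' origin. A neighbour overlapping the gene's 5' boundary yields length 0
#' (never a negative length). On a linear replicon with no feature on the 5'
#' side the region is truncated at the replicon edge and flagged.
#'
#' @param annotation a [genome_annotation()].
#' @param gene_id id of the candidate gene.
#' @return A one-row data frame (a promoter-region record) with columns
#'   `replicon_id`, `promoter_id`, `gene_id`, `locus_tag`, `product`,
#'   `upstream_feature_id`, `upstream_feature_strand`, `start`, `end`,
#'   `strand`, `length`, `truncated`, `sequence`. Coordinates are 0-based
#'   half-open on the forward strand; `start > end` encodes an interval
#'   wrapping the origin of a circular replicon. `sequence` is oriented
#'   5'-to-3' relative to the gene (reverse-complemented for `-` strand
#'   genes) and `NA` when the annotation has no sequence.
#' @export
upstream_intergenic <- function(annotation, gene_id) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  idx <- match(gene_id, g$gene_id)
  if (is.na(idx)) stop("unknown gene id: '", gene_id, "'")
  L <- annotation$length
  circular <- annotation$circular
  s <- g$start[idx]; e <- g$end[idx]; strand <- g$strand[idx]
  others <- g[-idx, , drop = FALSE]

  # anchor: the gene's 5' boundary; probe: the base immediately upstream of it
  # (on linear replicons the probe may fall off the edge, matching no feature)
  if (strand == "+") {
    anchor <- s
    probe <- if (circular) (s - 1L) %% L else s - 1L
  } else {
    anchor <- if (circular) e %% L else e
    probe <- anchor
  }

  truncated <- FALSE
  if (nrow(others) == 0L) {
    if (circular) {
      # only boundary on the circle is the gene's own far end
      gap <- if (strand == "+") circ_dist(e %% L, s, L)
             else circ_dist(e %% L, s, L)
      up_id <- gene_id
      up_strand <- strand
    } else {
      gap <- if (strand == "+") s else L - e
      up_id <- NA_character_
      up_strand <- NA_character_
      truncated <- TRUE
    }
  } else {
    overlaps <- vapply(seq_len(nrow(others)), function(i)
      interval_contains(others$start[i], others$end[i], probe, L,
                        circular = FALSE),  # stored intervals never wrap
      logical(1))
    if (strand == "+") {
      gaps <- circ_dist(others$end %% L, s, L)
    } else {
      gaps <- circ_dist(e %% L, others$start, L)
    }
    gaps[overlaps] <- 0L
    if (!circular) {
      # only neighbours genuinely on the 5' side count on a linear replicon
      feasible <- if (strand == "+") (others$end <= s) | overlaps
                  else (others$start >= e) | overlaps
      if (!any(feasible)) {
        gap <- if (strand == "+") s else L - e
        up_id <- NA_character_
        up_strand <- NA_character_
        truncated <- TRUE
      } else {
        gaps[!feasible] <- NA
        j <- which.min(gaps)
        gap <- gaps[j]; up_id <- others$gene_id[j]
        up_strand <- others$strand[j]
      }
    } else {
      # cap at the gene's own far boundary so the region never overlaps
      # the gene's own span when it is the only feature in the way
      own_gap <- circ_dist(e %% L, s, L)
      j <- which.min(gaps)
      if (gaps[j] <= own_gap) {
        gap <- gaps[j]; up_id <- others$gene_id[j]
        up_strand <- others$strand[j]
      } else {
        gap <- own_gap; up_id <- gene_id; up_strand <- strand
      }
    }
  }
  gap <- as.integer(max(0L, gap))

  if (strand == "+") {
    r_start <- if (circular) (s - gap) %% L else s - gap
    r_end <- s
  } else {
    r_start <- anchor
    r_end <- if (circular) (e + gap) %% L else e + gap
  }
  if (gap == 0L) { r_start <- anchor; r_end <- anchor }

  seq_out <- NA_character_
  if (!is.null(annotation$sequence) && gap > 0L) {
    fwd <- slice_sequence(annotation$sequence, r_start, r_end,
                          circular = circular)
    seq_out <- if (strand == "-") reverse_complement(fwd) else fwd
  } else if (!is.null(annotation$sequence)) {
    seq_out <- ""
  }

  data.frame(
    replicon_id = annotation$replicon_id,
    promoter_id = promoter_id_for(gene_id, g$locus_tag[idx]),
    gene_id = gene_id,
    locus_tag = g$locus_tag[idx],
    product = g$product[idx],
    upstream_feature_id = up_id,
    upstream_feature_strand = up_strand,
    start = r_start, end = r_end, strand = strand,
    length = gap, truncated = truncated,
    sequence = seq_out,
    stringsAsFactors = FALSE)
}

#' Upstream intergenic regions for a set of genes
#'
#' @inheritParams upstream_intergenic
#' @param gene_ids gene ids to process; default all genes of the annotation.
#' @return Data frame of promoter-region records, one row per gene.
#' @export
extract_promoters <- function(annotation, gene_ids = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (is.null(gene_ids)) gene_ids <- annotation$genes$gene_id
  unknown <- setdiff(gene_ids, annotation$genes$gene_id)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  do.call(rbind, lapply(gene_ids, function(id)
    upstream_intergenic(annotation, id)))
}

#' Minimum-length filter for promoter regions
#'
#' Partitions regions into retained (length >= `min_length`) and excluded
#' (strictly shorter). A region of exactly `min_length` bp is retained: the
#' exclusion rule is "shorter than the threshold".
#'
#' @param regions data frame of promoter-region records.
#' @param min_length minimum region length in bp (default 100).
#' @return List with elements `retained` and `excluded`, each a data frame
#'   carrying a `passed_filter` column; together they partition the input.
#' @export
filter_promoters <- function(regions, min_length = 100) {
  if (is.null(regions) || nrow(regions) == 0L) {
    empty <- regions
    if (!is.null(empty)) empty$passed_filter <- logical(0)
    return(list(retained = empty, excluded = empty))
  }
  regions$passed_filter <- regions$length >= min_length
  list(retained = regions[regions$passed_filter, , drop = FALSE],
       excluded = regions[!regions$passed_filter, , drop = FALSE])
}

#' Export promoter regions as BED, FASTA and a summary TSV
#'
#' Writes `<out_prefix>.bed` (0-based half-open, strand column carries the
#' downstream gene's strand; a region wrapping a circular origin is split
#' into two lines sharing the promoter id), `<out_prefix>.fa` (ids are
#' promoter ids; sequences oriented 5'-to-3' relative to the gene), and
#' `<out_prefix>.tsv` (promoter id, gene id, locus tag, product, length,
#' filter flag).
#'
#' @param regions data frame of promoter-region records.
#' @param out_prefix path prefix for the three output files.
#' @param formats subset of `c("bed", "fasta", "tsv")`.
#' @return Invisibly, the paths written.
#' @export
export_promoters <- function(regions, out_prefix,
                             formats = c("bed", "fasta", "tsv")) {
  formats <- match.arg(formats, several.ok = TRUE)
  if (is.null(regions)) stop("regions must be a data frame")
  if (nrow(regions) == 0L)
    warning("no promoter regions to export; writing empty files")
  if (!"passed_filter" %in% names(regions))
    regions$passed_filter <- NA
  paths <- character()
  if ("bed" %in% formats) {
    bed <- file(paste0(out_prefix, ".bed"), "w")
    if (nrow(regions)) for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      segs <- if (r$start <= r$end) list(c(r$start, r$end))
              else list(c(r$start, NA), c(0L, r$end))
      for (sg in segs) {
        end_ <- if (is.na(sg[2L])) r$start + (r$length - r$end) else sg[2L]
        cat(sprintf("%s\t%d\t%d\t%s\t.\t%s\n", r$replicon_id, sg[1L], end_,
                    r$promoter_id, r$strand), file = bed)
      }
    }
    close(bed)
    paths <- c(paths, paste0(out_prefix, ".bed"))
  }
  if ("fasta" %in% formats) {
    if (nrow(regions) && anyNA(regions$sequence))
      stop("FASTA export requested but region(s) lack sequence: ",
           paste(regions$promoter_id[is.na(regions$sequence)], collapse = ", "))
    ss <- Biostrings::DNAStringSet(
      if (nrow(regions)) regions$sequence else character())
    names(ss) <- regions$promoter_id
    Biostrings::writeXStringSet(ss, paste0(out_prefix, ".fa"))
    paths <- c(paths, paste0(out_prefix, ".fa"))
  }
  if ("tsv" %in% formats) {
    cols <- c("promoter_id", "gene_id", "locus_tag", "product", "length",
              "passed_filter")
    utils::write.table(regions[, cols, drop = FALSE],
                       paste0(out_prefix, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, paste0(out_prefix, ".tsv"))
  }
  invisible(paths)
}
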