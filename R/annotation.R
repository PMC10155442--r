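#' Genome annotation container
#'
#' Holds the ordered, strand-annotated gene intervals of one replicon together
#' with (optionally) its nucleotide sequence. Coordinates are stored in the
#' 0-based half-open convention throughout the package; conversion from the
#' 1-based inclusive conventions of GFF3 and GenBank happens at read time only.
#'
#' @param replicon_id character scalar naming the replicon.
#' @param length replicon length in bp.
#' @param genes data frame with columns `gene_id`, `locus_tag`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `feature_type`, `product`. `start`/`end`
#'   are 0-based half-open with `0 <= start < end <= length`.
#' @param circular logical; is the replicon circular?
#' @param sequence nucleotide string of length `length`, or `NULL` for
#'   interval-only use.
#'
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(replicon_id, length, genes,
                              circular = TRUE, sequence = NULL) {
  stopifnot_scalar_number(length, "length", positive = TRUE)
  length <- as.integer(length)
  if (is.null(genes) || nrow(genes) == 0L) {
    genes <- data.frame(gene_id = character(), locus_tag = character(),
                        start = integer(), end = integer(),
                        strand = character(), feature_type = character(),
                        product = character(), stringsAsFactors = FALSE)
  }
  required <- c("gene_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols))
    stop("genes is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"locus_tag" %in% names(genes)) genes$locus_tag <- NA_character_
  if (!"feature_type" %in% names(genes)) genes$feature_type <- "gene"
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  bad <- which(!(genes$start >= 0L & genes$start < genes$end &
                   genes$end <= length))
  if (length(bad))
    stop("malformed coordinates for gene(s): ",
         paste(genes$gene_id[bad], collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene id(s): ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != length)
      stop("sequence length (", nchar(sequence),
           ") does not match replicon length (", length, ")")
  }
  genes <- genes[order(genes$start, genes$end, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(
    list(replicon_id = as.character(replicon_id), length = length,
         circular = isTRUE(circular), genes = genes, sequence = sequence),
    class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d bp, %s, %d genes%s\n",
              x$replicon_id, x$length,
              if (x$circular) "circular" else "linear",
              nrow(x$genes),
              if (is.null(x$sequence)) " (no sequence)" else ""))
  if (nrow(x$genes)) {
    show <- utils::head(x$genes[, c("gene_id", "start", "end", "strand")], 5L)
    print(show)
    if (nrow(x$genes) > 5L) cat("... and", nrow(x$genes) - 5L, "more\n")
  }
  invisible(x)
}

FEATURE_CLASSES <- c("gene", "CDS", "rRNA", "tRNA", "tmRNA")

#' Read a genome annotation from GFF3 or GenBank
#'
#' Reads gene-level features (gene, CDS, rRNA, tRNA, tmRNA) from a GFF3 file
#' (optionally with a companion FASTA for the sequence) or a GenBank flat
#' file, converting the 1-based inclusive coordinates of both formats to the
#' internal 0-based half-open convention.
#'
#' @param path path to the annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"genbank"`.
#' @param fasta optional FASTA path supplying the replicon sequence (GFF3).
#' @param circular logical or `NA`; `NA` means detect from the file (GFF3
#'   `Is_circular` region attribute, GenBank LOCUS line) and default to
#'   `FALSE` when undeclared.
#'
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "genbank"),
                            fasta = NULL, circular = NA) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gb", "gbk", "gbff", "genbank")) "genbank"
              else "gff3"
  }
  if (format == "genbank") read_genbank(path, circular = circular)
  else read_gff3(path, fasta = fasta, circular = circular)
}

read_gff3 <- function(path, fasta = NULL, circular = NA) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  region <- gr[meta$type %in% c("region", "chromosome")]
  keep <- meta$type %in% FEATURE_CLASSES
  feats <- gr[keep]
  fm <- S4Vectors::mcols(feats)
  pick <- function(col) {
    if (col %in% names(fm)) {
      v <- fm[[col]]
      if (is.list(v) || inherits(v, "List")) v <- vapply(
        v, function(z) if (length(z)) z[[1L]] else NA_character_, character(1))
      as.character(v)
    } else rep(NA_character_, length(feats))
  }
  ids <- pick("ID")
  locus <- pick("locus_tag")
  nm <- pick("Name")
  gene_id <- ifelse(!is.na(ids), ids, ifelse(!is.na(locus), locus, nm))
  if (anyNA(gene_id))
    stop("GFF3 feature without ID/locus_tag/Name at record ",
         paste(which(is.na(gene_id)), collapse = ", "))
  genes <- data.frame(
    gene_id = gene_id, locus_tag = locus,
    start = GenomicRanges::start(feats) - 1L,  # 1-based -> 0-based half-open
    end = GenomicRanges::end(feats),
    strand = as.character(GenomicRanges::strand(feats)),
    feature_type = as.character(fm$type),
    product = pick("product"),
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  # collapse gene + CDS records sharing an id: prefer the gene record
  genes <- genes[!duplicated(genes$gene_id), , drop = FALSE]
  replicon_id <- as.character(GenomicRanges::seqnames(gr))[1L] %||% "replicon"
  sequence <- NULL
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    sequence <- as.character(ss[[1L]])
  }
  len <- if (length(region)) max(GenomicRanges::end(region))
         else if (!is.null(sequence)) nchar(sequence)
         else max(genes$end)
  if (is.na(circular)) {
    circular <- FALSE
    if (length(region)) {
      rm_ <- S4Vectors::mcols(region)
      if ("Is_circular" %in% names(rm_))
        circular <- isTRUE(tolower(as.character(rm_$Is_circular[1L])) == "true")
    }
  }
  genome_annotation(replicon_id, len, genes, circular = circular,
                    sequence = sequence)
}

# Minimal GenBank flat-file reader: LOCUS line, simple and complement()
# feature locations for gene/CDS/rRNA/tRNA/tmRNA, /locus_tag /gene /product
# qualifiers, and the ORIGIN sequence block. join() locations are rejected.
read_genbank <- function(path, circular = NA) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file: no LOCUS line")
  toks <- strsplit(trimws(locus[1L]), "\\s+")[[1L]]
  replicon_id <- toks[2L]
  len <- as.integer(toks[which(toks == "bp") - 1L][1L])
  if (is.na(circular))
    circular <- any(grepl("\\bcircular\\b", locus[1L], ignore.case = TRUE))

  fstart <- grep("^FEATURES", lines)[1L]
  ostart <- grep("^ORIGIN", lines)[1L]
  if (is.na(fstart)) stop("no FEATURES table in ", path)
  fend <- if (!is.na(ostart)) ostart - 1L else length(lines)
  flines <- lines[(fstart + 1L):fend]

  recs <- list()
  cur <- NULL
  for (ln in flines) {
    if (grepl("^ {5}\\S", ln)) {  # new feature line: 5 spaces + key
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
      key <- sub("^ {5}(\\S+).*", "\\1", ln)
      loc <- trimws(sub("^ {5}\\S+\\s+", "", ln))
      cur <- list(key = key, loc = loc, quals = character())
    } else if (!is.null(cur)) {
      cur$quals <- c(cur$quals, trimws(ln))
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
  recs <- Filter(function(r) r$key %in% FEATURE_CLASSES, recs)

  parse_loc <- function(loc) {
    if (grepl("join|order", loc))
      stop("compound GenBank location not supported: ", loc)
    strand <- if (grepl("^complement\\(", loc)) "-" else "+"
    core <- gsub("complement\\(|\\)|<|>", "", loc)
    m <- regmatches(core, regexec("^([0-9]+)\\.\\.([0-9]+)$", core))[[1L]]
    if (length(m) != 3L) stop("malformed GenBank location: ", loc)
    # 1-based inclusive -> 0-based half-open
    list(start = as.integer(m[2L]) - 1L, end = as.integer(m[3L]),
         strand = strand)
  }
  get_qual <- function(r, name) {
    pat <- paste0("^/", name, "=")
    hits <- grep(pat, r$quals, value = TRUE)
    if (!length(hits)) return(NA_character_)
    gsub('^"|"$', "", sub(pat, "", hits[1L]))
  }
  rows <- lapply(recs, function(r) {
    lc <- parse_loc(r$loc)
    data.frame(gene_id = get_qual(r, "gene") %||% NA_character_,
               locus_tag = get_qual(r, "locus_tag"),
               start = lc$start, end = lc$end, strand = lc$strand,
               feature_type = r$key, product = get_qual(r, "product"),
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  if (is.null(genes)) genes <- NULL
  else {
    genes$gene_id <- ifelse(!is.na(genes$gene_id), genes$gene_id,
                            genes$locus_tag)
    if (anyNA(genes$gene_id))
      stop("GenBank feature without /gene or /locus_tag qualifier")
    # gene + CDS pairs share an id: keep the first (gene) record
    genes <- genes[!duplicated(genes$gene_id), , drop = FALSE]
  }

  sequence <- NULL
  if (!is.na(ostart)) {
    send <- grep("^//", lines)
    send <- send[send > ostart][1L]
    if (is.na(send)) send <- length(lines) + 1L
    seqlines <- lines[(ostart + 1L):(send - 1L)]
    sequence <- toupper(gsub("[^a-zA-Z]", "", paste(seqlines, collapse = "")))
    if (!nchar(sequence)) sequence <- NULL
  }
  if (is.na(len) || !length(len)) {
    len <- if (!is.null(sequence)) nchar(sequence) else max(genes$end)
  }
  genome_annotation(replicon_id, len, genes, circular = circular,
                    sequence = sequence)
}

#' Write an annotation as GFF3 (+ optional FASTA)
#'
#' Internal 0-based half-open intervals are converted back to GFF3's 1-based
#' inclusive convention on write, so a write/read round trip is lossless.
#'
#' @param annotation a [genome_annotation()].
#' @param gff_path output GFF3 path.
#' @param fasta_path optional FASTA output path for the sequence.
#' @return Invisibly, the paths written.
#' @export
write_annotation <- function(annotation, gff_path, fasta_path = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", annotation$replicon_id,
                     annotation$length),
             sprintf("%s\tpromscreen\tregion\t1\t%d\t.\t+\t.\tID=%s;Is_circular=%s",
                     annotation$replicon_id, annotation$length,
                     annotation$replicon_id,
                     if (annotation$circular) "true" else "false"))
  if (nrow(g)) {
    attr_str <- sprintf("ID=%s%s%s", g$gene_id,
                        ifelse(is.na(g$locus_tag), "",
                               paste0(";locus_tag=", g$locus_tag)),
                        ifelse(is.na(g$product), "",
                               paste0(";product=", g$product)))
    lines <- c(lines, sprintf("%s\tpromscreen\t%s\t%d\t%d\t.\t%s\t.\t%s",
                              annotation$replicon_id, g$feature_type,
                              g$start + 1L, g$end, g$strand, attr_str))
  }
  writeLines(lines, gff_path)
  out <- gff_path
  if (!is.null(fasta_path)) {
    if (is.null(annotation$sequence))
      stop("annotation carries no sequence; cannot write FASTA")
    ss <- Biostrings::DNAStringSet(annotation$sequence)
    names(ss) <- annotation$replicon_id
    Biostrings::writeXStringSet(ss, fasta_path)
    out <- c(out, fasta_path)
  }
  invisible(out)
}
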