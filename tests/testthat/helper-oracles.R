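# Independent oracles and fixture builders used across the suite.

# Exhaustive top-fraction intersection using full per-sample sorts.
oracle_intersection <- function(counts, top_fraction = 0.03) {
  k <- ceiling(top_fraction * nrow(counts))
  sets <- lapply(colnames(counts), function(s) {
    ord <- order(-counts[, s], rownames(counts), method = "radix")
    rownames(counts)[ord][seq_len(k)]
  })
  sort(Reduce(intersect, sets))
}

# Base-by-base interval walk from a gene's 5' boundary to the nearest
# annotated base of any other feature. O(genome length); toy genomes only.
oracle_upstream_gap <- function(ann, gene_id) {
  g <- ann$genes
  i <- match(gene_id, g$gene_id)
  L <- ann$length
  own <- rep(FALSE, L)
  own[seq(g$start[i] + 1L, g$end[i])] <- TRUE
  other <- rep(FALSE, L)
  for (j in seq_len(nrow(g))[-i])
    other[seq(g$start[j] + 1L, g$end[j])] <- TRUE
  strand <- g$strand[i]
  p <- if (strand == "+") g$start[i] - 1L else g$end[i]
  gap <- 0L
  repeat {
    if (ann$circular) p <- p %% L
    if (p < 0L || p >= L) break       # linear replicon edge
    if (other[p + 1L] || own[p + 1L]) break
    gap <- gap + 1L
    p <- if (strand == "+") p - 1L else p + 1L
    if (gap > L) break
  }
  gap
}

# Closed-form simple-regression coefficients.
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# Permutation p-value for a two-group mean difference.
oracle_permutation_p <- function(a, b, n_perm = 1e5, seed = 42) {
  set.seed(seed)
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12)
      hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# Compact toy annotation builder: genes as list of c(start, end, strand).
toy_annotation <- function(genes, length = 1000L, circular = FALSE,
                           sequence = NULL, ids = NULL) {
  if (length(genes) == 0L)
    return(genome_annotation("toy", length, NULL, circular, sequence))
  df <- do.call(rbind, lapply(seq_along(genes), function(i) {
    data.frame(gene_id = if (is.null(ids)) sprintf("g%02d", i) else ids[i],
               locus_tag = sprintf("TAG_%04d", i),
               start = as.integer(genes[[i]][[1L]]),
               end = as.integer(genes[[i]][[2L]]),
               strand = genes[[i]][[3L]],
               feature_type = "gene", product = NA_character_,
               stringsAsFactors = FALSE)
  }))
  genome_annotation("toy", length, df, circular = circular,
                    sequence = sequence)
}

# Random non-overlapping toy annotation on a small replicon.
random_toy_annotation <- function(n_genes, seed, circular = TRUE,
                                  with_sequence = FALSE) {
  set.seed(seed)
  lens <- sample(20:60, n_genes, replace = TRUE)
  gaps <- sample(0:80, n_genes, replace = TRUE)
  L <- sum(lens) + sum(gaps) + sample(50:200, 1L)
  pos <- 0L
  genes <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    pos <- pos + gaps[i]
    genes[[i]] <- list(pos, pos + lens[i], sample(c("+", "-"), 1L))
    pos <- pos + lens[i]
  }
  seqchr <- if (with_sequence)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    else NULL
  toy_annotation(genes, length = L, circular = circular, sequence = seqchr)
}

random_count_matrix <- function(n_genes, n_samples, seed, max_count = 30L) {
  set.seed(seed)
  m <- matrix(sample(0:max_count, n_genes * n_samples, replace = TRUE),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

write_counts_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
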