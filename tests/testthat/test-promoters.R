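test_that("upstream region of a + strand gene spans from the previous feature", {
  ann <- toy_annotation(list(list(0, 100, "+"), list(250, 400, "+")),
                        length = 500, circular = FALSE)
  r <- upstream_intergenic(ann, "g02")
  expect_identical(r$start, 100L)
  expect_identical(r$end, 250L)
  expect_identical(r$length, 150L)
  expect_identical(r$upstream_feature_id, "g01")
  expect_false(r$truncated)
})

test_that("abutting upstream gene gives a zero-length region", {
  ann <- toy_annotation(list(list(0, 100, "+"), list(100, 300, "+")),
                        length = 400, circular = FALSE)
  r <- upstream_intergenic(ann, "g02")
  expect_identical(r$length, 0L)
  expect_identical(filter_promoters(r)$retained |> nrow(), 0L)
})

test_that("overlapping upstream neighbour is reported as length 0, not negative", {
  ann <- toy_annotation(list(list(0, 120, "+"), list(100, 300, "+")),
                        length = 400, circular = FALSE)
  r <- upstream_intergenic(ann, "g02")
  expect_identical(r$length, 0L)
})

test_that("- strand regions sit 3' of the gene and are reverse-complemented", {
  # 696 bp toy replicon; gene B(50,200,-) with next feature C(450,600,+):
  # upstream region is (200,450) on the forward strand
  seqchr <- paste(rep("ACGTGC", 116), collapse = "")
  ann <- toy_annotation(list(list(50, 200, "-"), list(450, 600, "+")),
                        length = 696, circular = FALSE, sequence = seqchr)
  r <- upstream_intergenic(ann, "g01")
  expect_identical(c(r$start, r$end), c(200L, 450L))
  expect_identical(r$length, 250L)
  fwd <- substr(seqchr, 201, 450)
  expect_identical(
    r$sequence,
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd))))

  # hand-checked toy: forward slice ACGTGC -> revcomp GCACGT
  ann2 <- toy_annotation(list(list(0, 6, "-"), list(12, 18, "+")),
                         length = 24, circular = FALSE,
                         sequence = "AAAAAAACGTGCAAAAAATTTTTT")
  r2 <- upstream_intergenic(ann2, "g01")
  expect_identical(c(r2$start, r2$end), c(6L, 12L))
  expect_identical(r2$sequence, "GCACGT")
})

test_that("linear replicon edges truncate the region and flag it", {
  ann <- toy_annotation(list(list(200, 300, "+")), length = 400,
                        circular = FALSE)
  r <- upstream_intergenic(ann, "g01")
  expect_identical(c(r$start, r$end), c(0L, 200L))
  expect_true(r$truncated)
  rminus <- upstream_intergenic(
    toy_annotation(list(list(100, 250, "-")), length = 400,
                   circular = FALSE), "g01")
  expect_identical(c(rminus$start, rminus$end), c(250L, 400L))
  expect_true(rminus$truncated)
  expect_error(upstream_intergenic(ann, "nope"), "unknown gene id")
})

test_that("circular replicons wrap the upstream walk across the origin", {
  # + gene near the origin; upstream neighbour is the last gene on the circle
  ann <- toy_annotation(list(list(10, 100, "+"), list(800, 950, "+")),
                        length = 1000, circular = TRUE)
  r <- upstream_intergenic(ann, "g01")
  expect_identical(r$length, 60L)  # 950 -> 1000 wraps -> 10
  expect_identical(r$upstream_feature_id, "g02")
  expect_identical(c(r$start, r$end), c(950L, 10L))  # wrapping interval

  # sequence extraction across the origin
  seqchr <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                  collapse = "")
  ann2 <- toy_annotation(list(list(10, 100, "+"), list(800, 950, "+")),
                         length = 1000, circular = TRUE, sequence = seqchr)
  r2 <- upstream_intergenic(ann2, "g01")
  expect_identical(r2$sequence,
                   paste0(substr(seqchr, 951, 1000), substr(seqchr, 1, 10)))
})

test_that("length filter partitions exhaustively with >= boundary semantics", {
  regions <- data.frame(promoter_id = c("P1", "P2", "P3"),
                        gene_id = c("a", "b", "c"),
                        length = c(120L, 99L, 100L),
                        stringsAsFactors = FALSE)
  flt <- filter_promoters(regions, min_length = 100)
  expect_setequal(flt$retained$promoter_id, c("P1", "P3"))
  expect_identical(flt$excluded$promoter_id, "P2")
  expect_identical(nrow(flt$retained) + nrow(flt$excluded), nrow(regions))
  # min_length 0 retains everything
  flt0 <- filter_promoters(regions, min_length = 0)
  expect_identical(nrow(flt0$retained), 3L)
  expect_identical(nrow(flt0$excluded), 0L)
})

test_that("the region never overlaps its own gene and conservation holds", {
  for (seed in 1:8) {
    ann <- random_toy_annotation(sample(3:20, 1), seed = seed,
                                 circular = sample(c(TRUE, FALSE), 1))
    regions <- extract_promoters(ann)
    flt <- filter_promoters(regions, 100)
    expect_identical(nrow(flt$retained) + nrow(flt$excluded), nrow(regions))
    for (i in seq_len(nrow(regions))) {
      g <- ann$genes[ann$genes$gene_id == regions$gene_id[i], ]
      if (regions$length[i] == 0L) next
      # walk every base of the reported region; none may fall in the gene
      pos <- regions$start[i]
      for (step in seq_len(regions$length[i])) {
        expect_false(pos >= g$start && pos < g$end,
                     info = sprintf("seed %d gene %s pos %d", seed,
                                    g$gene_id, pos))
        pos <- if (ann$circular) (pos + 1L) %% ann$length else pos + 1L
      }
    }
  }
})

test_that("upstream gaps match the base-by-base interval-walk oracle", {
  for (seed in 1:12) {
    ann <- random_toy_annotation(sample(2:30, 1), seed = 100 + seed,
                                 circular = seed %% 2 == 0)
    for (id in ann$genes$gene_id) {
      expect_identical(upstream_intergenic(ann, id)$length,
                       oracle_upstream_gap(ann, id),
                       info = sprintf("seed %d gene %s circular %s",
                                      seed, id, ann$circular))
    }
  }
})

test_that("rotating a circular annotation leaves promoter lengths unchanged", {
  ann <- random_toy_annotation(12, seed = 9, circular = TRUE)
  base_lengths <- extract_promoters(ann)$length
  names(base_lengths) <- extract_promoters(ann)$gene_id
  L <- ann$length
  for (offset in c(7L, 153L, L - 31L)) {
    g <- ann$genes
    g$start <- (g$start + offset) %% L
    g$end <- (g$end + offset) %% L
    if (any(g$start >= g$end)) next  # offset would split a gene at the origin
    rot <- genome_annotation("toy", L, g, circular = TRUE)
    lens <- extract_promoters(rot, names(base_lengths))$length
    expect_identical(lens, unname(base_lengths[names(base_lengths)]))
  }
})

test_that("exports write BED, gene-oriented FASTA and a summary TSV", {
  seqchr <- paste(rep("ACGT", 250), collapse = "")
  ann <- toy_annotation(list(list(0, 100, "+"), list(250, 400, "-")),
                        length = 1000, circular = FALSE, sequence = seqchr)
  regions <- extract_promoters(ann, "g02")
  regions$passed_filter <- TRUE
  prefix <- tempfile()
  export_promoters(regions, prefix)
  bed <- readLines(paste0(prefix, ".bed"))
  expect_identical(bed, sprintf("toy\t%d\t%d\t%s\t.\t-", regions$start,
                                regions$end, regions$promoter_id))
  fa <- Biostrings::readDNAStringSet(paste0(prefix, ".fa"))
  expect_identical(names(fa), regions$promoter_id)
  fwd <- substr(seqchr, regions$start + 1, regions$end)
  expect_identical(
    as.character(fa[[1]]),
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd))))
  tsv <- read.delim(paste0(prefix, ".tsv"))
  expect_identical(tsv$promoter_id, regions$promoter_id)

  # empty region set writes valid empty files with a warning
  expect_warning(export_promoters(regions[0, ], tempfile()), "no promoter")
  # missing sequence with FASTA requested errors
  r2 <- regions; r2$sequence <- NA_character_
  expect_error(export_promoters(r2, tempfile(), formats = "fasta"),
               "lack sequence")
})

test_that("promoter ids follow the P + trailing-digits convention", {
  expect_identical(promscreen:::promoter_id_for("PSTAA_RS12445", "PSTAA_2489"),
                   "P12445")
  expect_identical(promscreen:::promoter_id_for("SYN_0042", NA), "P0042")
})
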