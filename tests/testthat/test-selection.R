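test_that("read_count_table round-trips a well-formed TSV and rejects bad ones", {
  path <- write_counts_tsv(data.frame(gene_id = c("a", "b", "c"),
                                      s1 = c(10L, 5L, 1L),
                                      s2 = c(3L, 8L, 2L)))
  m <- read_count_table(path)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("a", "b", "c"))
  expect_identical(m["b", "s2"], 8L)

  neg <- write_counts_tsv(data.frame(gene_id = c("a", "b"),
                                     s1 = c(1L, -2L)))
  expect_error(read_count_table(neg), "negative")

  dup <- write_counts_tsv(data.frame(gene_id = c("a", "a"), s1 = c(1L, 2L)))
  expect_error(read_count_table(dup), "duplicate gene id.*a")

  frac <- write_counts_tsv(data.frame(gene_id = c("a", "b"),
                                      s1 = c(1.5, 2)))
  expect_error(read_count_table(frac), "non-integer")

  nas <- write_counts_tsv(data.frame(gene_id = c("a", "b"),
                                     s1 = c(1L, NA)))
  expect_error(read_count_table(nas), "missing value.*gene 'b'.*sample 's1'")
})

test_that("rank_genes orders by descending count with lexicographic ties", {
  m <- matrix(c(10L, 5L, 1L), ncol = 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  expect_identical(rank_genes(m, "s1"), c("a", "b", "c"))

  tie <- matrix(c(7L, 7L), ncol = 1, dimnames = list(c("b", "a"), "s1"))
  expect_identical(rank_genes(tie, "s1"), c("a", "b"))

  allsame <- matrix(rep(3L, 4), ncol = 1,
                    dimnames = list(c("d", "b", "c", "a"), "s1"))
  expect_identical(rank_genes(allsame, "s1"), c("a", "b", "c", "d"))

  expect_error(rank_genes(m, "nope"), "unknown sample")
})

test_that("top-fraction cutoff size is ceiling(top_fraction * n_genes)", {
  m100 <- random_count_matrix(100, 1, seed = 1)
  expect_length(top_fraction_set(m100, "s1"), 3L)   # ceiling(3)
  # 4427 genes at 3 percent: ceiling(132.81) = 133
  m4427 <- matrix(seq_len(4427), ncol = 1,
                  dimnames = list(sprintf("g%05d", 1:4427), "s1"))
  storage.mode(m4427) <- "integer"
  expect_length(top_fraction_set(m4427, "s1"), 133L)
  # identity at top_fraction = 1
  expect_setequal(
    top_fraction_set(m100, "s1", selection_params(top_fraction = 1)),
    rownames(m100))
})

test_that("boundary tie mode keeps every gene tied at the cutoff", {
  # 10 genes: ranks 1-2 forced, then an 8-way tie spanning the k=3 boundary
  m <- matrix(c(50L, 40L, rep(30L, 8L)), ncol = 1,
              dimnames = list(sprintf("g%02d", 1:10), "s1"))
  trunc <- top_fraction_set(m, "s1", selection_params(top_fraction = 0.3))
  ties <- top_fraction_set(m, "s1", selection_params(top_fraction = 0.3,
                                                     boundary_mode = "ties"))
  expect_length(trunc, 3L)
  expect_length(ties, 10L)
  expect_true(all(trunc %in% ties))
})

test_that("intersection keeps genes top-ranked in all required samples", {
  # single sample: intersection is that sample's top set
  m <- random_count_matrix(50, 1, seed = 3)
  res <- intersect_top_sets(m, selection_params(top_fraction = 0.1))
  expect_setequal(res$intersection, res$per_sample_top$s1)

  # a gene top in 3 of 4 samples is excluded when all samples are required
  m <- matrix(rep(1:20, 4), nrow = 20,  # distinct low background counts
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:4)))
  m["g01", c("s1", "s2", "s3")] <- 1000L  # misses s4
  m["g02", ] <- 900L                       # top everywhere
  storage.mode(m) <- "integer"
  res <- intersect_top_sets(m, selection_params(top_fraction = 0.1))  # k = 2
  expect_identical(res$intersection, "g02")
  # ... but qualifies with min_samples = 3
  res3 <- intersect_top_sets(m, selection_params(top_fraction = 0.1,
                                                 min_samples = 3))
  expect_setequal(res3$intersection, c("g01", "g02"))

  # planted constitutive genes among background are recovered exactly
  set.seed(11)
  bg <- matrix(rpois(200 * 4, 20), nrow = 200,
               dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  planted <- c("g010", "g050", "g100", "g150", "g199")
  bg[planted, ] <- bg[planted, ] + 5000L
  storage.mode(bg) <- "integer"
  res <- intersect_top_sets(bg, selection_params(top_fraction = 0.03))
  expect_setequal(res$intersection, planted)
  expect_setequal(res$intersection, oracle_intersection(bg, 0.03))
})

test_that("per-sample top-set sizes and ranking table honour the contract", {
  m <- random_count_matrix(60, 3, seed = 5)
  res <- intersect_top_sets(m, selection_params(top_fraction = 0.1))
  expect_true(all(res$cutoff_size_per_sample == ceiling(0.1 * 60)))
  rt <- res$ranking_table
  expect_setequal(rt$gene_id[rt$in_intersection], res$intersection)
  # rank columns are permutations of 1..n
  for (s in colnames(m))
    expect_setequal(rt[[paste0("rank_", s)]], seq_len(60))
})

test_that("intersection is monotone in top_fraction and row-order invariant", {
  for (seed in 1:5) {
    m <- random_count_matrix(40, 4, seed = seed)
    prev <- character()
    for (f in c(0.05, 0.1, 0.25, 0.5, 1)) {
      cur <- intersect_top_sets(m, selection_params(top_fraction = f))$intersection
      expect_true(all(prev %in% cur),
                  info = sprintf("seed %d fraction %g", seed, f))
      prev <- cur
    }
    shuffled <- m[sample(nrow(m)), , drop = FALSE]
    expect_setequal(
      intersect_top_sets(m, selection_params(top_fraction = 0.1))$intersection,
      intersect_top_sets(shuffled,
                         selection_params(top_fraction = 0.1))$intersection)
  }
})

test_that("selection matches the exhaustive full-sort oracle on random matrices", {
  for (seed in 1:10) {
    n <- sample(5:50, 1)
    m <- random_count_matrix(n, 4, seed = seed, max_count = 15L)
    f <- sample(c(0.03, 0.1, 0.3), 1)
    expect_identical(
      sort(intersect_top_sets(m, selection_params(top_fraction = f))$intersection),
      oracle_intersection(m, f),
      info = sprintf("seed %d n %d f %g", seed, n, f))
  }
})

test_that("replicate columns are aggregated before ranking", {
  m <- matrix(c(10L, 1L, 1L,   2L, 1L, 30L,    # cond A replicates
                9L, 2L, 1L,    3L, 2L, 28L),   # cond B replicates
              nrow = 3,
              dimnames = list(c("g1", "g2", "g3"),
                              c("A_r1", "A_r2", "B_r1", "B_r2")))
  groups <- c(A_r1 = "A", A_r2 = "A", B_r1 = "B", B_r2 = "B")
  res <- intersect_top_sets(m, selection_params(top_fraction = 0.3),
                            sample_groups = groups)
  # summed: A: g1=12, g3=31 -> top1 g3; B: g3=58 top1 -> intersection g3
  expect_identical(names(res$per_sample_top), c("A", "B"))
  expect_identical(res$intersection, "g3")
})

test_that("cpm mode reranks by library-size-normalised counts", {
  # g1 wins on raw counts in s2 only because s2 is sequenced deeper
  m <- matrix(c(100L, 90L, 8L, 1000L, 950L, 600L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  raw <- rank_genes(m, "s2")
  cpm <- rank_genes(m, "s2", normalize = "cpm")
  expect_identical(raw[1], "g1")
  expect_identical(cpm[1], "g1")  # same leader here, but ordering is by CPM
  expect_identical(
    cpm, rownames(m)[order(-(m[, "s2"] / sum(m[, "s2"])), rownames(m))])
})
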