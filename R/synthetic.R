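#' Specification for synthetic screening data
#'
#' Bundles the parameters of the synthetic-data generator: an annotated
#' circular genome with strand-mixed genes and a realistic mixture of
#' intergenic gap lengths, plus count matrices in which a planted subset of
#' genes is uniformly top-ranked in every sample (constitutive) while decoy
#' genes are top-ranked only in a strict subset of samples
#' (condition-specific).
#'
#' Defaults emulate the screening study design: four samples (two time points
#' in each of two media, replicates pooled into one column per condition),
#' a top-3-percent cutoff, and a 100 bp minimum promoter length. Intergenic
#' gaps are drawn from a two-component mixture — uniform 10-99 bp ("short",
#' below the filter threshold) with probability `frac_short_gap`, uniform
#' 100-600 bp otherwise — so the length filter's behaviour is controllable.
#'
#' @param genome_length replicon length in bp.
#' @param n_genes number of non-overlapping genes to place.
#' @param n_samples number of count columns (conditions).
#' @param n_constitutive number of planted always-top genes.
#' @param n_conditional number of decoy genes, high only in a strict subset
#'   of samples.
#' @param frac_short_gap fraction of intergenic gaps drawn below 100 bp.
#' @param nb_dispersion negative-binomial overdispersion alpha of counts
#'   (variance = mu + alpha * mu^2).
#' @param background_mean mean background read count.
#' @param constitutive_fc fold-change of planted constitutive genes over
#'   background (1000x separates them from every decoy and background gene
#'   in essentially every draw).
#' @param conditional_fc fold-change of decoy genes over background within
#'   their assigned samples.
#' @param gene_length_range integer range gene lengths are drawn from.
#' @param n_replicates replicate columns per condition (default 1: one pooled
#'   column per condition; >1 exercises the replicate-aggregation path).
#' @param seed random seed making every generated artefact reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome_length = 300000L, n_genes = 200L,
                           n_samples = 4L, n_constitutive = 5L,
                           n_conditional = 5L, frac_short_gap = 0.2,
                           nb_dispersion = 0.1, background_mean = 50,
                           constitutive_fc = 1000, conditional_fc = 100,
                           gene_length_range = c(300L, 1500L),
                           n_replicates = 1L, seed = 1L) {
  if (n_constitutive + n_conditional >= n_genes && n_genes > 0L)
    stop("n_constitutive + n_conditional must be smaller than n_genes")
  if (frac_short_gap < 0 || frac_short_gap > 1)
    stop("frac_short_gap must lie in [0, 1]")
  stopifnot_scalar_number(genome_length, "genome_length", positive = TRUE)
  structure(list(genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_constitutive = as.integer(n_constitutive),
                 n_conditional = as.integer(n_conditional),
                 frac_short_gap = frac_short_gap,
                 nb_dispersion = nb_dispersion,
                 background_mean = background_mean,
                 constitutive_fc = constitutive_fc,
                 conditional_fc = conditional_fc,
                 gene_length_range = as.integer(gene_length_range),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic circular genome annotation
#'
#' Places `n_genes` non-overlapping genes with random strands on a circular
#' replicon with a random nucleotide sequence. The gap preceding each gene is
#' drawn from the short/long gap mixture defined by `spec`; space left after the
#' last gene extends the gap that wraps the origin.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `annotation` (a [genome_annotation()]) and
#'   `truth` (ground truth: `constitutive_ids`, `conditional_ids`,
#'   `short_gap_ids`, and the realised strand-aware upstream gap of every
#'   gene in `upstream_gap`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  L <- spec$genome_length
  n <- spec$n_genes
  sequence <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = "")
  if (n == 0L) {
    ann <- genome_annotation("synth_replicon", L, NULL, circular = TRUE,
                             sequence = sequence)
    truth <- list(constitutive_ids = character(),
                  conditional_ids = character(),
                  short_gap_ids = character(),
                  upstream_gap = integer())
    return(list(annotation = ann, truth = truth))
  }
  lens <- sample(seq(spec$gene_length_range[1L], spec$gene_length_range[2L]),
                 n, replace = TRUE)
  if (sum(lens) >= L)
    stop("infeasible packing: total gene span (", sum(lens),
         " bp) is not smaller than genome_length (", L, " bp)")
  short <- stats::runif(n) < spec$frac_short_gap
  gaps <- ifelse(short, sample(10:99, n, replace = TRUE),
                 sample(100:600, n, replace = TRUE))
  if (sum(lens) + sum(gaps) > L)
    stop("infeasible packing: genes plus drawn gaps (", sum(lens) + sum(gaps),
         " bp) exceed genome_length (", L, " bp); increase genome_length")
  strands <- sample(c("+", "-"), n, replace = TRUE)
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lens[i]
    ends[i] <- pos
  }
  leftover <- L - pos  # extends the gap wrapping the origin
  ids <- sprintf("SYN_%04d", seq_len(n))
  genes <- data.frame(gene_id = ids,
                      locus_tag = sprintf("SYNTAG_%04d", seq_len(n)),
                      start = starts, end = ends, strand = strands,
                      feature_type = "gene",
                      product = "synthetic protein",
                      stringsAsFactors = FALSE)
  ann <- genome_annotation("synth_replicon", L, genes, circular = TRUE,
                           sequence = sequence)

  # realised strand-aware upstream gap: left gap for + genes, right gap for -
  left_gap <- gaps
  left_gap[1L] <- gaps[1L] + leftover
  right_gap <- c(gaps[-1L], gaps[1L] + leftover)
  upstream_gap <- ifelse(strands == "+", left_gap, right_gap)
  names(upstream_gap) <- ids

  planted <- sample(ids, spec$n_constitutive + spec$n_conditional)
  constitutive_ids <- sort(utils::head(planted, spec$n_constitutive))
  conditional_ids <- sort(utils::tail(planted, spec$n_conditional))
  truth <- list(
    constitutive_ids = constitutive_ids,
    conditional_ids = conditional_ids,
    short_gap_ids = sort(constitutive_ids[
      upstream_gap[constitutive_ids] < 100L]),
    upstream_gap = upstream_gap)
  list(annotation = ann, truth = truth)
}

#' Generate a synthetic count matrix with planted high-expressers
#'
#' Background genes receive negative-binomial counts around a low mean;
#' planted constitutive genes receive a mean `constitutive_fc` times higher
#' in every sample; decoy genes receive a mean `conditional_fc` times higher
#' only within a random strict, non-empty subset of samples. Reproducible
#' for a fixed spec seed.
#'
#' @param annotation a [genome_annotation()] whose genes the matrix covers.
#' @param spec a [synthetic_spec()].
#' @param truth ground-truth list from [generate_genome()]; its planted ids
#'   must be genes of `annotation`.
#' @return A list with the integer count matrix `counts` (columns `S1..Sn`,
#'   or `S<i>_R<j>` when `n_replicates > 1`), `sample_groups` (named vector
#'   mapping columns to conditions, `NULL` for one column per condition) and
#'   `truth` extended with the per-decoy sample subsets
#'   (`conditional_samples`).
#' @export
generate_counts <- function(annotation, spec, truth) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(spec, "synthetic_spec"))
  ids <- annotation$genes$gene_id
  bad <- setdiff(c(truth$constitutive_ids, truth$conditional_ids), ids)
  if (length(bad))
    stop("truth ids absent from annotation: ", paste(bad, collapse = ", "))
  set.seed(spec$seed + 1L)  # distinct stream from genome generation
  n <- length(ids)
  n_cond <- spec$n_samples
  conditions <- paste0("S", seq_len(n_cond))
  mu <- matrix(spec$background_mean, nrow = n, ncol = n_cond,
               dimnames = list(ids, conditions))
  mu[truth$constitutive_ids, ] <-
    spec$background_mean * spec$constitutive_fc
  conditional_samples <- list()
  if (length(truth$conditional_ids) && n_cond >= 2L) {
    for (id in truth$conditional_ids) {
      size <- sample(seq_len(n_cond - 1L), 1L)  # strict, non-empty subset
      subset <- sort(sample(conditions, size))
      conditional_samples[[id]] <- subset
      mu[id, subset] <- spec$background_mean * spec$conditional_fc
    }
  }
  nrep <- max(1L, spec$n_replicates)
  cols <- if (nrep == 1L) conditions
          else as.vector(t(outer(conditions, paste0("_R", seq_len(nrep)),
                                 paste0)))
  size_param <- 1 / spec$nb_dispersion
  counts <- matrix(0L, nrow = n, ncol = length(cols),
                   dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    cond_idx <- if (nrep == 1L) j else ((j - 1L) %/% nrep) + 1L
    counts[, j] <- stats::rnbinom(n, mu = mu[, cond_idx], size = size_param)
  }
  storage.mode(counts) <- "integer"
  sample_groups <- NULL
  if (nrep > 1L) {
    sample_groups <- rep(conditions, each = nrep)
    names(sample_groups) <- cols
  }
  truth$conditional_samples <- conditional_samples
  list(counts = counts, sample_groups = sample_groups, truth = truth)
}

#' Default ground-truth parameters for synthetic assay tables
#'
#' Strengths span the observed dynamic range of endogenous promoters
#' (17-959 percent of the reference); activities sit at the magnitude of
#' wild-type and overexpression strains; ammonium concentrations and nif-gene
#' fold-changes likewise mirror the magnitudes the quantitation formulas are
#' used on.
#'
#' @return A list understood by [generate_assay_tables()].
#' @export
default_assay_truth <- function() {
  list(
    promoter_strengths = c(P22180 = 17, P17270 = 60, Pgenta = 100,
                           P11670 = 400, P12445 = 959),
    reference_promoter = "Pgenta",
    blank_luminescence = 200,
    reference_luminescence = 10000,
    activities = c(WT = 70, P11670_nifA = 126, P12445_nifA = 287),
    total_protein_mg = c(WT = 0.2, P11670_nifA = 0.2, P12445_nifA = 0.2),
    peak_area_standard_1nmol = 1e4,
    ammonium_uM = c(WT = 14, P11670_nifA = 22.4, P12445_nifA = 359.1),
    ammonium_curve = list(slope = 0.002, intercept = 0.05,
                          standards_uM = c(0, 50, 100, 200, 400)),
    qpcr_folds = c(nifH = 127, nifD = 80, nifK = 25),
    qpcr_calibrator = "WT",
    qpcr_base_ct = list(target = 28, control = 18))
}

#' Generate synthetic assay measurement tables
#'
#' Emits luminescence, gas-chromatography peak-area, absorbance-standard and
#' Ct tables constructed so that the assay quantitation formulas recover the
#' supplied ground truth exactly in zero-noise mode, and up to the injected
#' noise otherwise.
#'
#' @param true_params ground-truth list, see [default_assay_truth()].
#' @param noise_sd relative (multiplicative) noise standard deviation for
#'   luminescence, peak areas and absorbances; additive cycles for Ct values.
#'   `0` gives exactly invertible tables.
#' @param n_replicates replicate measurements per record.
#' @param seed random seed.
#' @return A list of class `assay_tables` with data frames `luciferase`,
#'   `acetylene`, `ammonium_standards`, `ammonium_samples`, `qpcr`, and the
#'   `truth` used to build them.
#' @export
generate_assay_tables <- function(true_params = default_assay_truth(),
                                  noise_sd = 0, n_replicates = 3L,
                                  seed = 1L) {
  set.seed(seed)
  tp <- true_params
  jitter_mult <- function(x) x * (1 + stats::rnorm(length(x), 0, noise_sd))
  reps <- seq_len(n_replicates)

  ref <- tp$reference_promoter
  lum_mean <- function(strength)
    tp$blank_luminescence + strength / 100 *
      (tp$reference_luminescence - tp$blank_luminescence)
  lum_rows <- lapply(names(tp$promoter_strengths), function(p)
    data.frame(strain_id = paste0("DSM_", p), promoter_id = p,
               replicate = reps,
               luminescence = jitter_mult(
                 rep(lum_mean(tp$promoter_strengths[[p]]), n_replicates)),
               stringsAsFactors = FALSE))
  lum_rows[[length(lum_rows) + 1L]] <- data.frame(
    strain_id = "DSM_vector", promoter_id = "vector", replicate = reps,
    luminescence = jitter_mult(rep(tp$blank_luminescence, n_replicates)),
    stringsAsFactors = FALSE)
  luciferase <- do.call(rbind, lum_rows)

  # invert the activity formula to get the experimental peak area
  strains <- names(tp$activities)
  peak_exp <- tp$activities * tp$total_protein_mg[strains] * 4 / 100 *
    tp$peak_area_standard_1nmol
  acetylene <- data.frame(
    strain_id = rep(strains, each = n_replicates),
    replicate = rep(reps, times = length(strains)),
    peak_area_experimental = jitter_mult(rep(peak_exp, each = n_replicates)),
    peak_area_standard_1nmol = tp$peak_area_standard_1nmol,
    headspace_volume = 100, injected_volume = 1,
    total_protein = rep(tp$total_protein_mg[strains], each = n_replicates),
    incubation_time = 4, stringsAsFactors = FALSE)

  curve <- tp$ammonium_curve
  ammonium_standards <- data.frame(
    concentration = curve$standards_uM,
    absorbance = jitter_mult(curve$intercept +
                               curve$slope * curve$standards_uM),
    stringsAsFactors = FALSE)
  amm_strains <- names(tp$ammonium_uM)
  ammonium_samples <- data.frame(
    strain_id = rep(amm_strains, each = n_replicates),
    replicate = rep(reps, times = length(amm_strains)),
    absorbance = jitter_mult(rep(curve$intercept +
                                   curve$slope * tp$ammonium_uM,
                                 each = n_replicates)),
    stringsAsFactors = FALSE)

  base_t <- tp$qpcr_base_ct$target
  base_c <- tp$qpcr_base_ct$control
  jitter_ct <- function(x) x + stats::rnorm(length(x), 0, noise_sd)
  qpcr_rows <- lapply(names(tp$qpcr_folds), function(gene) {
    # sample ct_target drops by log2(fold) relative to the calibrator
    rbind(
      data.frame(strain_id = tp$qpcr_calibrator, gene_id = gene,
                 replicate = reps,
                 ct_target = jitter_ct(rep(base_t, n_replicates)),
                 ct_control = jitter_ct(rep(base_c, n_replicates)),
                 stringsAsFactors = FALSE),
      data.frame(strain_id = "overexpression", gene_id = gene,
                 replicate = reps,
                 ct_target = jitter_ct(
                   rep(base_t - log2(tp$qpcr_folds[[gene]]), n_replicates)),
                 ct_control = jitter_ct(rep(base_c, n_replicates)),
                 stringsAsFactors = FALSE))
  })
  qpcr <- do.call(rbind, qpcr_rows)

  structure(list(luciferase = luciferase, acetylene = acetylene,
                 ammonium_standards = ammonium_standards,
                 ammonium_samples = ammonium_samples, qpcr = qpcr,
                 truth = tp),
            class = "assay_tables")
}

#' Write a synthetic screening bundle to disk
#'
#' Writes the genome as GFF3 + FASTA, counts as TSV, and the ground truth as
#' a JSON sidecar, giving a complete on-disk input set for [run_screen()].
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list: paths `gff`, `fasta`, `counts_path`,
#'   `truth_path`, plus the in-memory `annotation`, `counts`,
#'   `sample_groups` and `truth`.
#' @export
write_synthetic_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(spec)
  cm <- generate_counts(gen$annotation, spec, gen$truth)
  paths <- list(gff = file.path(dir, "genome.gff3"),
                fasta = file.path(dir, "genome.fa"),
                counts = file.path(dir, "counts.tsv"),
                truth = file.path(dir, "truth.json"))
  write_annotation(gen$annotation, paths$gff, paths$fasta)
  write_count_table(cm$counts, paths$counts)
  truth <- cm$truth
  truth$upstream_gap <- as.list(truth$upstream_gap)
  jsonlite::write_json(truth, paths$truth, auto_unbox = FALSE, pretty = TRUE)
  invisible(list(gff = paths$gff, fasta = paths$fasta,
                 counts_path = paths$counts, truth_path = paths$truth,
                 annotation = gen$annotation, counts = cm$counts,
                 sample_groups = cm$sample_groups, truth = cm$truth))
}

#' Write assay tables as TSV files
#'
#' @param tables an `assay_tables` list from [generate_assay_tables()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_assay_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "assay_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- c("luciferase", "acetylene", "ammonium_standards",
          "ammonium_samples", "qpcr")
  paths <- vapply(nm, function(x) file.path(dir, paste0(x, ".tsv")),
                  character(1))
  for (x in nm)
    utils::write.table(tables[[x]], paths[[x]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(paths)
}
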