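#' Pipeline configuration
#'
#' A single serialisable configuration object driving end-to-end runs, so a
#' run is a citable artefact: write it next to the outputs and the run can
#' be reproduced exactly.
#'
#' @param annotation_path path to the genome annotation (GFF3 or GenBank).
#' @param counts_path path to the read-count TSV.
#' @param fasta_path optional companion FASTA for a GFF3 annotation.
#' @param assay_dir optional directory of assay TSVs (`luciferase.tsv`,
#'   `acetylene.tsv`, `ammonium_standards.tsv`, `ammonium_samples.tsv`,
#'   `qpcr.tsv`); absent tables are skipped with a log line.
#' @param out_dir output directory.
#' @param top_fraction,min_samples,boundary_mode,normalize see
#'   [selection_params()].
#' @param min_promoter_length minimum promoter length in bp.
#' @param reference_promoter,blank reference and blank ids for the
#'   luciferase table.
#' @param seed integer seed recorded in the run report.
#' @param verbose print log lines to the console as well as the run log.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation_path = NULL, counts_path = NULL,
                            fasta_path = NULL, assay_dir = NULL,
                            out_dir = "promscreen_out",
                            top_fraction = 0.03, min_samples = NULL,
                            boundary_mode = "truncate", normalize = "none",
                            min_promoter_length = 100,
                            reference_promoter = "Pgenta",
                            blank = "vector", seed = 1L, verbose = TRUE) {
  structure(list(annotation_path = annotation_path,
                 counts_path = counts_path, fasta_path = fasta_path,
                 assay_dir = assay_dir, out_dir = out_dir,
                 top_fraction = top_fraction, min_samples = min_samples,
                 boundary_mode = boundary_mode, normalize = normalize,
                 min_promoter_length = min_promoter_length,
                 reference_promoter = reference_promoter, blank = blank,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

log_lines <- function(config, log_path, ...) {
  msg <- paste0(...)
  if (config$verbose) message(msg)
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  invisible(msg)
}

check_exists <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(what, " not found: ", path %||% "<unset>")
  path
}

#' Run the promoter screen end to end
#'
#' Reads the annotation and count table named in the config, runs
#' [promoter_screen()], and writes the selection report, the promoter
#' exports (BED/FASTA/TSV), the run log, and a JSON run report recording the
#' counts at every stage, all parameters, and md5 checksums of the inputs.
#' Identical config and inputs give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the run report list.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  check_exists(config$annotation_path, "annotation")
  check_exists(config$counts_path, "count table")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)  # truncate
  stage <- "read_annotation"
  report <- tryCatch({
    log_lines(config, log_path, "[screen] reading annotation: ",
              config$annotation_path)
    annotation <- read_annotation(config$annotation_path,
                                  fasta = config$fasta_path)
    stage <- "read_counts"
    log_lines(config, log_path, "[screen] reading counts: ",
              config$counts_path)
    counts <- read_count_table(config$counts_path)
    stage <- "selection_extraction"
    params <- selection_params(top_fraction = config$top_fraction,
                               min_samples = config$min_samples,
                               boundary_mode = config$boundary_mode,
                               normalize = config$normalize)
    scr <- promoter_screen(counts, annotation, params,
                           min_length = config$min_promoter_length)
    stage <- "export"
    write_selection_report(scr$selection,
                           file.path(config$out_dir, "selection.tsv"),
                           file.path(config$out_dir, "top_sets.json"))
    regions <- scr$regions
    if (!is.null(regions)) {
      regions$passed_filter <- regions$length >= config$min_promoter_length
      fmts <- if (is.null(annotation$sequence)) c("bed", "tsv")
              else c("bed", "fasta", "tsv")
      suppressWarnings(export_promoters(
        regions, file.path(config$out_dir, "promoters"), formats = fmts))
    }
    cs <- scr$counts_summary
    log_lines(config, log_path, sprintf(
      "[screen] %d genes, intersection %d, excluded %d short, retained %d",
      cs[["n_genes"]], cs[["intersection"]], cs[["excluded_short"]],
      cs[["retained"]]))
    checksums <- tools::md5sum(c(config$annotation_path, config$counts_path))
    report <- list(
      stage_counts = as.list(cs),
      per_sample_top_sizes =
        as.list(scr$selection$cutoff_size_per_sample),
      unannotated = scr$unannotated,
      retained_promoters = if (!is.null(scr$retained))
        scr$retained$promoter_id else character(),
      excluded_promoters = if (!is.null(scr$excluded))
        scr$excluded$promoter_id else character(),
      parameters = unclass(config)[c(
        "top_fraction", "min_samples", "boundary_mode", "normalize",
        "min_promoter_length", "seed")],
      input_checksums = as.list(checksums))
    jsonlite::write_json(report,
                         file.path(config$out_dir, "screen_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    report
  }, error = function(e) {
    stop("screen failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(report)
}

#' Run the assay quantitation pipeline
#'
#' Processes whichever assay tables are present under `config$assay_dir`:
#' relative luciferase strengths, acetylene-reduction nitrogenase
#' activities, standard-curve ammonium concentrations, and 2^-ddCt relative
#' expression. Absent tables are skipped with a log line; at least one must
#' be present. Per-assay TSVs and a combined JSON summary are written to
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the quantitation report list.
#' @export
run_assays <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$assay_dir) || !dir.exists(config$assay_dir))
    stop("assay directory not found: ", config$assay_dir %||% "<unset>")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "assays.log")
  cat("", file = log_path)
  tsv <- function(name) file.path(config$assay_dir, paste0(name, ".tsv"))
  read_tsv <- function(path) {
    df <- tryCatch(
      utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE),
      error = function(e) stop("malformed table '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    na_row <- which(rowSums(is.na(df)) > 0)
    if (length(na_row))
      stop("malformed table '", path, "': missing value in row ", na_row[1L])
    df
  }
  report <- list()
  ran_any <- FALSE

  if (file.exists(tsv("luciferase"))) {
    ran_any <- TRUE
    lum <- read_tsv(tsv("luciferase"))
    strengths <- relative_strength(lum, config$reference_promoter,
                                   config$blank)
    utils::write.table(strengths,
                       file.path(config$out_dir, "promoter_strengths.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$promoter_strengths <- strengths
    log_lines(config, log_path, "[assays] luciferase: ",
              nrow(strengths), " promoters quantified")
  } else log_lines(config, log_path, "[assays] luciferase.tsv absent; skipped")

  if (file.exists(tsv("acetylene"))) {
    ran_any <- TRUE
    ac <- read_tsv(tsv("acetylene"))
    ac$activity <- nitrogenase_activity(
      ac$peak_area_experimental, ac$peak_area_standard_1nmol,
      ac$total_protein, ac$headspace_volume, ac$incubation_time)
    per_strain <- stats::aggregate(activity ~ strain_id, data = ac, mean)
    names(per_strain)[2L] <- "mean_activity"
    per_strain$sd_activity <-
      stats::aggregate(activity ~ strain_id, data = ac, stats::sd)$activity
    utils::write.table(per_strain,
                       file.path(config$out_dir,
                                 "nitrogenase_activity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$nitrogenase_activity <- per_strain
    log_lines(config, log_path, "[assays] acetylene: ",
              nrow(per_strain), " strains quantified")
  } else log_lines(config, log_path, "[assays] acetylene.tsv absent; skipped")

  if (file.exists(tsv("ammonium_standards")) &&
      file.exists(tsv("ammonium_samples"))) {
    ran_any <- TRUE
    std <- read_tsv(tsv("ammonium_standards"))
    smp <- read_tsv(tsv("ammonium_samples"))
    curve <- fit_standard_curve(std$concentration, std$absorbance)
    inv <- invert_standard_curve(curve, smp$absorbance)
    smp$concentration <- inv$concentration
    smp$extrapolated <- inv$extrapolated
    per_strain <- stats::aggregate(concentration ~ strain_id, data = smp,
                                   mean)
    names(per_strain)[2L] <- "mean_concentration_uM"
    utils::write.table(per_strain,
                       file.path(config$out_dir, "ammonium.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$ammonium <- per_strain
    report$ammonium_curve <- list(slope = curve$slope,
                                  intercept = curve$intercept,
                                  r_squared = curve$r_squared)
    log_lines(config, log_path, "[assays] ammonium: ",
              nrow(per_strain), " strains quantified (r^2 = ",
              sprintf("%.4f", curve$r_squared), ")")
  } else log_lines(config, log_path,
                   "[assays] ammonium tables absent; skipped")

  if (file.exists(tsv("qpcr"))) {
    ran_any <- TRUE
    q <- read_tsv(tsv("qpcr"))
    agg <- stats::aggregate(cbind(ct_target, ct_control) ~
                              strain_id + gene_id, data = q, mean)
    cal_id <- unique(agg$strain_id)
    # calibrator: the reference strain; default to the first strain present
    calibrator <- if ("WT" %in% cal_id) "WT" else cal_id[1L]
    rows <- lapply(unique(agg$gene_id), function(g) {
      sub <- agg[agg$gene_id == g, ]
      cal <- sub[sub$strain_id == calibrator, ]
      others <- sub[sub$strain_id != calibrator, ]
      if (!nrow(cal) || !nrow(others)) return(NULL)
      do.call(rbind, lapply(seq_len(nrow(others)), function(i)
        data.frame(gene_id = g, strain_id = others$strain_id[i],
                   calibrator = calibrator,
                   fold_change = relative_expression(
                     others$ct_target[i], others$ct_control[i],
                     cal$ct_target, cal$ct_control),
                   stringsAsFactors = FALSE)))
    })
    folds <- do.call(rbind, rows)
    utils::write.table(folds,
                       file.path(config$out_dir, "relative_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$relative_expression <- folds
    log_lines(config, log_path, "[assays] qpcr: ", nrow(folds),
              " gene/strain fold-changes")
  } else log_lines(config, log_path, "[assays] qpcr.tsv absent; skipped")

  if (!ran_any) stop("no assay table present in ", config$assay_dir)
  jsonlite::write_json(report,
                       file.path(config$out_dir, "assay_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  invisible(report)
}
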