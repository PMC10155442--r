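#' Relative promoter strength from reporter luminescence
#'
#' Expresses each promoter's blank-subtracted mean luminescence as a
#' percentage of a reference promoter's blank-subtracted mean:
#' `100 * (mean(L_p) - mean(L_blank)) / (mean(L_ref) - mean(L_blank))`.
#' Readings are taken on cells at a common density (OD600 = 1.0), so no
#' further normalisation is applied. Negative blank-subtracted signals are
#' clamped to 0 with a warning. Blank subtraction can be disabled.
#'
#' @param records data frame with columns `promoter_id` and `luminescence`
#'   (one row per replicate reading).
#' @param reference_promoter id of the reference (100 percent) promoter.
#' @param blank id of the promoterless blank (default `"vector"`); `NULL`
#'   disables blank subtraction.
#' @return Data frame with one row per promoter: `promoter_id`,
#'   `mean_luminescence`, `sd_luminescence`, `n`, `strength_pct`,
#'   `strength_sd_pct` (ratio-of-means approximation).
#' @export
relative_strength <- function(records, reference_promoter,
                              blank = "vector") {
  stopifnot(all(c("promoter_id", "luminescence") %in% names(records)))
  if (any(records$luminescence < 0))
    stop("negative luminescence reading(s)")
  if (!reference_promoter %in% records$promoter_id)
    stop("reference promoter '", reference_promoter, "' has no records")
  agg <- function(p) {
    v <- records$luminescence[records$promoter_id == p]
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  blank_mean <- 0
  if (!is.null(blank)) {
    if (!blank %in% records$promoter_id)
      stop("blank '", blank, "' has no records")
    blank_mean <- agg(blank)[["mean"]]
  }
  ref_net <- agg(reference_promoter)[["mean"]] - blank_mean
  if (ref_net <= 0)
    stop("assay invalid: reference signal does not exceed the blank")
  proms <- setdiff(unique(records$promoter_id), blank)
  rows <- lapply(proms, function(p) {
    a <- agg(p)
    net <- a[["mean"]] - blank_mean
    if (net < 0) {
      warning("blank-subtracted signal negative for '", p,
              "'; clamped to 0")
      net <- 0
    }
    data.frame(promoter_id = p, mean_luminescence = a[["mean"]],
               sd_luminescence = a[["sd"]], n = as.integer(a[["n"]]),
               strength_pct = 100 * net / ref_net,
               strength_sd_pct = 100 * a[["sd"]] / ref_net,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nitrogenase activity from an acetylene reduction measurement
#'
#' Converts a gas-chromatography ethylene peak area into specific nitrogenase
#' activity in nmol ethylene per hour per mg total protein:
#' `(peak_area_experimental / peak_area_standard_1nmol * headspace_volume) /
#' (total_protein * incubation_time)`. The defaults reproduce the standard
#' assay set-up: a 100 mL serum bottle, 1 mL injected, 4 h incubation.
#'
#' @param peak_area_experimental ethylene peak area of the sample.
#' @param peak_area_standard_1nmol peak area corresponding to 1 nmol
#'   ethylene.
#' @param total_protein total protein in the bottle, mg.
#' @param headspace_volume bottle headspace volume, mL (default 100).
#' @param incubation_time incubation time, h (default 4).
#' @return Activity in nmol ethylene h^-1 (mg protein)^-1.
#' @export
nitrogenase_activity <- function(peak_area_experimental,
                                 peak_area_standard_1nmol,
                                 total_protein,
                                 headspace_volume = 100,
                                 incubation_time = 4) {
  if (any(peak_area_standard_1nmol <= 0))
    stop("standard peak area must be positive")
  if (any(total_protein <= 0)) stop("total protein must be positive")
  if (any(incubation_time <= 0)) stop("incubation time must be positive")
  if (any(peak_area_experimental < 0))
    stop("experimental peak area must be non-negative")
  (peak_area_experimental / peak_area_standard_1nmol * headspace_volume) /
    (total_protein * incubation_time)
}

#' Fit a linear standard curve
#'
#' Ordinary least-squares line `response = slope * concentration +
#' intercept`, as used for colorimetric ammonium quantitation against an
#' ammonium chloride dilution series. A warning is issued when r-squared
#' falls below 0.98 (a poorly linear standard series).
#'
#' @param concentrations standard concentrations (e.g. micromolar).
#' @param responses measured responses (e.g. absorbance).
#' @return Object of class `standard_curve` wrapping the `lm` fit, with
#'   `slope`, `intercept`, `r_squared` and the standard range.
#' @export
fit_standard_curve <- function(concentrations, responses) {
  if (length(concentrations) != length(responses))
    stop("concentrations and responses differ in length")
  if (length(unique(concentrations)) < 2L)
    stop("at least two distinct standard concentrations are required")
  fit <- stats::lm(responses ~ concentrations)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) ||
      abs(slope) < 1e-12 * max(abs(responses), 1) / max(abs(concentrations)))
    stop("standard curve has zero or non-finite slope")
  # summary.lm warns on an exactly collinear (noise-free) standard series;
  # that case is legitimate here
  r2 <- withCallingHandlers(
    summary(fit)$r.squared,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (is.nan(r2)) r2 <- 1  # zero residual and zero total variance
  if (r2 < 0.98)
    warning(sprintf("standard curve r-squared = %.4f (< 0.98)", r2))
  structure(list(fit = fit, slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 range = range(concentrations),
                 response_range = range(responses)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> response = %.6g * conc + %.6g (r^2 = %.4f), range %g-%g\n",
    x$slope, x$intercept, x$r_squared, x$range[1L], x$range[2L]))
  invisible(x)
}

#' @export
predict.standard_curve <- function(object, concentrations, ...) {
  object$slope * concentrations + object$intercept
}

#' Invert a standard curve
#'
#' Maps measured responses back to concentrations:
#' `(response - intercept) / slope`. Values outside the fitted standard range
#' are returned with `extrapolated = TRUE`.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param responses measured responses.
#' @return Data frame with `response`, `concentration`, `extrapolated`.
#' @export
invert_standard_curve <- function(curve, responses) {
  stopifnot(inherits(curve, "standard_curve"))
  conc <- (responses - curve$intercept) / curve$slope
  data.frame(response = responses, concentration = conc,
             extrapolated = conc < curve$range[1L] | conc > curve$range[2L])
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes the fold-change of a target gene between a sample and a
#' calibrator, each normalised to an internal-control gene (e.g. gapdh):
#' `dCt = ct_target - ct_control` per record, `ddCt = dCt_sample -
#' dCt_calibrator`, `fold = 2^-ddCt`. Amplification efficiency is fixed at 2
#' (perfect doubling per cycle).
#'
#' @param ct_target_sample,ct_control_sample Ct values of the target and
#'   internal-control gene in the sample.
#' @param ct_target_calibrator,ct_control_calibrator same for the
#'   calibrator.
#' @return Fold-change (1 means no change).
#' @export
relative_expression <- function(ct_target_sample, ct_control_sample,
                                ct_target_calibrator,
                                ct_control_calibrator) {
  cts <- c(ct_target_sample, ct_control_sample, ct_target_calibrator,
           ct_control_calibrator)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("Ct values must be positive and finite")
  d_sample <- ct_target_sample - ct_control_sample
  d_cal <- ct_target_calibrator - ct_control_calibrator
  2^-(d_sample - d_cal)
}

#' Fold-change ratio and its rounded report value
#'
#' `fold_change` is the plain ratio `value_a / value_b`; `ratio_rounded`
#' rounds it half-away-from-zero to the nearest integer, the convention used
#' when reporting "n times more" statements.
#'
#' @param value_a numerator.
#' @param value_b denominator (must be nonzero).
#' @return The ratio (or its rounded value).
#' @export
fold_change <- function(value_a, value_b) {
  if (any(value_b == 0)) stop("division by zero in fold change")
  value_a / value_b
}

#' @rdname fold_change
#' @export
ratio_rounded <- function(value_a, value_b) {
  round_half_away(fold_change(value_a, value_b))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Classical one-way analysis of variance across replicate groups followed by
#' Tukey's honest significant difference on the studentized-range
#' distribution, with significance stars at P < 0.05 (*), < 0.01 (**) and
#' < 0.001 (***).
#'
#' @param groups named list, one numeric vector of replicate values per
#'   group label.
#' @param alpha family-wise confidence level parameter passed to
#'   `TukeyHSD` (default 0.05).
#' @return List of class `anova_tukey`: `f_statistic`, `p_value`, `df`,
#'   `table` (the aov summary), `pairwise` (data frame with `comparison`,
#'   `diff`, `lwr`, `upr`, `p_adj`, `stars`).
#' @export
one_way_anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("at least two groups are required")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least two replicates")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  fit <- stats::aov(value ~ group, data = df)
  smry <- summary(fit)[[1L]]
  f_stat <- smry[["F value"]][1L]
  p_val <- smry[["Pr(>F)"]][1L]
  group_means <- vapply(groups, mean, numeric(1))
  within_var <- vapply(groups, stats::var, numeric(1))
  # exact zero within-group variance: F is ill-defined (or numerically
  # inflated); report a p below the machine floor when means differ
  degenerate <- all(within_var == 0)
  if (degenerate) {
    if (stats::var(group_means) > 0) {
      f_stat <- Inf
      p_val <- .Machine$double.xmin
    } else {
      f_stat <- 0
      p_val <- 1
      degenerate <- FALSE
    }
  }
  stars_for <- function(p) {
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                    ifelse(p < 0.05, "*", "ns")))
  }
  pairwise <- NULL
  if (!degenerate && stats::var(df$value) > 0) {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    pairwise <- data.frame(comparison = rownames(tk),
                           diff = tk[, "diff"], lwr = tk[, "lwr"],
                           upr = tk[, "upr"], p_adj = tk[, "p adj"],
                           stars = stars_for(tk[, "p adj"]),
                           stringsAsFactors = FALSE)
    rownames(pairwise) <- NULL
  } else if (degenerate) {
    combs <- utils::combn(names(groups), 2L)
    group_means <- vapply(groups, mean, numeric(1))
    d <- group_means[combs[2L, ]] - group_means[combs[1L, ]]
    p_adj <- ifelse(d == 0, 1, .Machine$double.xmin)
    pairwise <- data.frame(
      comparison = paste(combs[2L, ], combs[1L, ], sep = "-"),
      diff = unname(d), lwr = unname(d), upr = unname(d),
      p_adj = p_adj, stars = stars_for(p_adj), stringsAsFactors = FALSE)
  }
  structure(list(f_statistic = f_stat, p_value = p_val,
                 df = c(between = smry$Df[1L], within = smry$Df[2L]),
                 table = smry, pairwise = pairwise, degenerate = degenerate),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("<anova_tukey> F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df[["between"]], x$df[["within"]], x$f_statistic, x$p_value,
              if (x$degenerate) " (zero within-group variance)" else ""))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Tukey HSD):\n")
    print(x$pairwise[, c("comparison", "diff", "p_adj", "stars")],
          row.names = FALSE)
  }
  invisible(x)
}
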