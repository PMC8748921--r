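#' Per-afferent, per-condition metrics for one recording
#' @keywords internal
characterize_recording <- function(recording, linear_model = NULL,
                                   fit_ln = TRUE, epsilon = 0.5,
                                   sin_freq = 1) {
  stim <- recording$stimulus
  rate <- estimate_firing_rate(recording$spike_times, stim$t)
  organ <- recording$truth$organ
  out <- list(
    mean_rate = mean(rate$rate),
    p_zero = zero_rate_probability(rate, epsilon),
    modulation = NA_real_,
    vaf_linear_pred = NA_real_,
    ln = NULL
  )
  if (stim$condition %in% c("passive_sinusoid_translation", "passive_sinusoid_pitch")) {
    cyc <- tryCatch(cycle_modulation(rate, frequency = sin_freq, folded = TRUE),
                    error = function(e) NULL)
    if (!is.null(cyc)) out$modulation <- cyc$modulation
  }
  if (!is.null(linear_model)) {
    pred <- predict_linear_rate(linear_model, stim, rectify = FALSE)
    out$vaf_linear_pred <- tryCatch(vaf(rate$rate, pred), error = function(e) NA_real_)
  }
  if (fit_ln) {
    out$ln <- tryCatch(fit_ln_model(rate, stim, organ), error = function(e) NULL)
  }
  out
}

#' Run the full study workflow on a synthetic cohort
#'
#' For every afferent: resting-discharge regularity classification (CV*),
#' a least-squares linear rate model fitted on the walking-matched passive
#' condition, linear predictions of every other condition with their VAF,
#' an LN cascade fit per naturalistic condition, and mean-rate /
#' zero-rate-probability statistics. Per-class summaries and standard group
#' contrasts (paired t-tests of mean rate against resting discharge;
#' active-vs-passive regressions of LN bias and modulation) are reported.
#' Deterministic given the seed.
#'
#' @param config a [cohort_config()]
#' @param seed integer seed for the cohort
#' @param out_dir optional directory; when given, per-afferent and summary
#'   tables are written as CSV and the report as JSON
#' @param ln_conditions conditions for which the LN cascade is fitted
#' @return `condition_comparison_report`: list(per_afferent, class_summary,
#'   contrasts, seed)
#' @export
run_analysis <- function(config = cohort_config(), seed = 1, out_dir = NULL,
                         ln_conditions = c("passive_low", "passive_high",
                                           "walking", "running")) {
  cohort <- generate_cohort(config, seed)
  rows <- list()
  for (id in names(cohort$recordings)) {
    truth <- cohort$truths[[id]]
    cls <- paste(truth$regularity, truth$organ, sep = "_")
    rest_rec <- cohort$rest[[id]]
    reg <- tryCatch(interspike_regularity(rest_rec$spike_times),
                    error = function(e) NULL)
    rest_rate <- length(rest_rec$spike_times) /
      (length(rest_rec$stimulus$t) / rest_rec$stimulus$sample_rate)
    lin_model <- NULL
    if ("passive_low" %in% names(cohort$recordings[[id]])) {
      pl <- cohort$recordings[[id]][["passive_low"]]
      pl_rate <- estimate_firing_rate(pl$spike_times, pl$stimulus$t)
      lin_model <- tryCatch(
        fit_linear_rate_model(pl_rate, pl$stimulus, truth$organ),
        error = function(e) NULL
      )
    }
    for (cond in names(cohort$recordings[[id]])) {
      met <- characterize_recording(cohort$recordings[[id]][[cond]], lin_model,
                                    fit_ln = cond %in% ln_conditions,
                                    sin_freq = config$params$sin_freq_hz)
      rows[[length(rows) + 1]] <- data.frame(
        afferent_id = id, class = cls, organ = truth$organ,
        regularity = truth$regularity, condition = cond,
        cv = if (is.null(reg)) NA_real_ else reg$cv,
        cv_star = if (is.null(reg)) NA_real_ else reg$cv_star,
        class_label = if (is.null(reg)) NA_character_ else reg$class_label,
        resting_rate = rest_rate,
        mean_rate = met$mean_rate, modulation = met$modulation,
        p_zero = met$p_zero,
        b = if (is.null(lin_model)) NA_real_ else lin_model$b,
        coef1 = if (is.null(lin_model)) NA_real_ else lin_model$coef[[1]],
        coef2 = if (is.null(lin_model)) NA_real_ else lin_model$coef[[2]],
        vif_max = if (is.null(lin_model)) NA_real_ else max(lin_model$vif),
        vaf_linear_pred = met$vaf_linear_pred,
        ln_st = if (is.null(met$ln)) NA_real_ else met$ln$st,
        ln_r0 = if (is.null(met$ln)) NA_real_ else met$ln$r0,
        ln_c1 = if (is.null(met$ln)) NA_real_ else met$ln$sigmoid$c1,
        ln_c2 = if (is.null(met$ln)) NA_real_ else met$ln$sigmoid$c2,
        ln_c3 = if (is.null(met$ln)) NA_real_ else met$ln$sigmoid$c3,
        ln_bias = if (is.null(met$ln)) NA_real_ else met$ln$bias,
        ln_modulation = if (is.null(met$ln)) NA_real_ else met$ln$modulation_slope,
        vaf_ln = if (is.null(met$ln)) NA_real_ else met$ln$vaf
      )
    }
  }
  per_afferent <- do.call(rbind, rows)
  class_summary <- stats::aggregate(
    per_afferent[, c("mean_rate", "resting_rate", "p_zero",
                     "vaf_linear_pred", "vaf_ln", "ln_bias", "ln_modulation")],
    by = list(class = per_afferent$class, condition = per_afferent$condition),
    FUN = function(v) mean(v, na.rm = TRUE)
  )
  contrasts <- compute_contrasts(per_afferent)
  report <- structure(list(per_afferent = per_afferent,
                           class_summary = class_summary,
                           contrasts = contrasts, seed = seed),
                      class = "condition_comparison_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Standard group contrasts on the per-afferent table
#'
#' Delegates to base statistical routines: per class and condition, a paired
#' t-test of mean firing rate against resting discharge; and, for the LN
#' bias and modulation, identity-line regressions of the locomotion value on
#' the walking-matched passive value across afferents (slope with 95% CI).
#' @keywords internal
compute_contrasts <- function(per_afferent) {
  out <- list()
  for (cl in unique(per_afferent$class)) {
    sub <- per_afferent[per_afferent$class == cl, ]
    for (cond in unique(sub$condition)) {
      d <- sub[sub$condition == cond, ]
      if (nrow(d) >= 3 && stats::sd(d$mean_rate - d$resting_rate) > 0) {
        tt <- stats::t.test(d$mean_rate, d$resting_rate, paired = TRUE)
        out[[length(out) + 1]] <- data.frame(
          test = "mean_rate_vs_resting", class = cl, condition = cond,
          estimate = unname(tt$estimate), statistic = unname(tt$statistic),
          p_value = tt$p.value, ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2]
        )
      }
    }
    for (metric in c("ln_bias", "ln_modulation")) {
      base <- sub[sub$condition == "passive_low", c("afferent_id", metric)]
      for (cond in c("walking", "running")) {
        act <- sub[sub$condition == cond, c("afferent_id", metric)]
        m <- merge(base, act, by = "afferent_id", suffixes = c("_passive", "_active"))
        m <- m[stats::complete.cases(m), ]
        if (nrow(m) >= 3 && stats::sd(m[[2]]) > 0) {
          fit <- stats::lm(m[[3]] ~ m[[2]])
          ci <- tryCatch(stats::confint(fit)[2, ], error = function(e) c(NA, NA))
          out[[length(out) + 1]] <- data.frame(
            test = paste0(metric, "_active_vs_passive"), class = cl,
            condition = cond, estimate = unname(stats::coef(fit)[2]),
            statistic = summary(fit)$coefficients[2, "t value"],
            p_value = summary(fit)$coefficients[2, "Pr(>|t|)"],
            ci_lo = ci[1], ci_hi = ci[2]
          )
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Serialize a comparison report
#' @param report a `condition_comparison_report`
#' @param out_dir output directory (created if absent)
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_afferent, file.path(out_dir, "per_afferent.csv"),
                   row.names = FALSE)
  utils::write.csv(report$class_summary, file.path(out_dir, "class_summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$contrasts)) {
    utils::write.csv(report$contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = report$seed,
         class_summary = report$class_summary,
         contrasts = report$contrasts),
    file.path(out_dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}

#' @export
print.condition_comparison_report <- function(x, ...) {
  cat(sprintf("condition_comparison_report: %d afferents x %d conditions (seed %d)\n",
              length(unique(x$per_afferent$afferent_id)),
              length(unique(x$per_afferent$condition)), x$seed))
  print(utils::head(x$class_summary, 12))
  invisible(x)
}
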