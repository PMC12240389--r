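# The screening pipeline: one entry point tying bioactivity, exposure,
# calibration, thresholds, classification and prioritization together.

#' Screening run configuration
#'
#' All defaults are the published constants of the framework, so a run with
#' no overrides reproduces the reference threshold arithmetic exactly.
#'
#' @param auc_cutoff Pathway-model AUC at or below which assay-active
#'   chemicals are excluded (default 0.01).
#' @param percentile_q ACC aggregation percentile (default 0.05).
#' @param site_q Site-level EAR_mix percentile (default 0.95).
#' @param excluded_flags Assay data-quality flags to exclude.
#' @param roster Assay roster.
#' @param bile_sex Sex retained for bile samples (default \code{"male"};
#'   \code{NULL} disables the filter).
#' @param use_highest_loec Sensitivity mode: judge bile samples against the
#'   highest LOEC_bEAR instead of the lowest (default \code{FALSE}).
#' @param recompute_ratio Recompute the EAR/EEQ calibration ratio from the
#'   supplied data (bile samples, EEF-bearing chemicals) instead of using
#'   the configured constant (default \code{FALSE}).
#' @param ratio_restrict_to_eef_chemicals Restrict the EAR side of the
#'   calibration ratio to EEF-bearing chemicals (default \code{FALSE}).
#' @param site_matrix Matrix whose samples drive site classification
#'   (default \code{"bile"}; falls back to all samples when absent).
#' @param benchmarks A [benchmark_config()].
#' @return List of class \code{"screen_config"}.
#' @export
screen_config <- function(auc_cutoff = 0.01,
                          percentile_q = 0.05,
                          site_q = 0.95,
                          excluded_flags = default_excluded_flags(),
                          roster = default_assay_roster(),
                          bile_sex = "male",
                          use_highest_loec = FALSE,
                          recompute_ratio = FALSE,
                          ratio_restrict_to_eef_chemicals = FALSE,
                          site_matrix = "bile",
                          benchmarks = benchmark_config()) {
  structure(as.list(environment()), class = "screen_config")
}

#' Screen a monitoring campaign for estrogenic mixture activity
#'
#' Runs the full pipeline: quality-flag filtering and estrogenicity calls,
#' ACC5 potency aggregation, water-equivalent conversion and per-sample
#' mixture EARs, threshold derivation (optionally calibrating the EAR/EEQ
#' ratio from the data), site and sample classification, chemical role
#' assignment and priority resolution, and summary statistics.
#'
#' @param chemicals Chemical registry (data frame or CSV path).
#' @param assays Assay bioactivity table (data frame or CSV path).
#' @param samples Monitoring sample table (data frame or CSV path).
#' @param config A [screen_config()].
#' @param field Optional field-response table (\code{site_id},
#'   \code{pct_male_vtg}, \code{pct_female_altered_timing}) for the
#'   qualitative concordance join.
#' @return Object of class \code{"ear_screen"}: a list with elements
#'   \code{statuses}, \code{acc5}, \code{ear}, \code{calibration},
#'   \code{thresholds}, \code{sites}, \code{sample_activity}, \code{roles},
#'   \code{priorities}, \code{drivers}, \code{detection},
#'   \code{concordance}, \code{config}, \code{call}.
#' @seealso [print.ear_screen()], [summary.ear_screen()],
#'   [plot.ear_screen()], [run_pipeline()]
#' @export
ear_screen <- function(chemicals, assays, samples,
                       config = screen_config(), field = NULL) {
  cl <- match.call()
  stopifnot(inherits(config, "screen_config"))
  if (is.character(chemicals)) chemicals <- read_chemical_table(chemicals)
  if (is.character(assays)) assays <- read_assay_table(assays)
  if (is.character(samples)) samples <- read_sample_table(samples)
  chemicals <- chemical_registry(chemicals)
  assays <- assay_table(assays)
  samples <- sample_table(samples)
  if (nrow(samples) == 0L)
    warning("empty sample table: reports will be empty", call. = FALSE)

  assays_f <- filter_assay_results(assays, config$excluded_flags)
  statuses <- identify_eedcs(chemicals, assays_f,
                             auc_cutoff = config$auc_cutoff,
                             roster = config$roster)
  acc5 <- acc5_table(chemicals, assays_f, statuses,
                     percentile_q = config$percentile_q,
                     roster = config$roster)
  if (!is.null(config$bile_sex))
    samples <- filter_bile_sex(samples, config$bile_sex)
  ear <- compute_ear_table(samples, chemicals, acc5, statuses)

  benchmarks <- config$benchmarks
  calibration <- list(ratio = benchmarks$calibration_ratio,
                      source = "configured", n = NA_integer_,
                      spearman_rho = NA_real_)
  if (config$recompute_ratio) {
    cal_samples <- samples[samples$matrix == "bile", , drop = FALSE]
    if (nrow(cal_samples) == 0L) cal_samples <- samples
    eeq <- compute_eeq_table(cal_samples, chemicals)
    cal_ear <- ear
    cal_ear$by_sample <- ear$by_sample[
      ear$by_sample$sample_id %in% cal_samples$sample_id, , drop = FALSE]
    r <- median_ear_eeq_ratio(
      cal_ear, eeq,
      restrict_to_eef_chemicals = config$ratio_restrict_to_eef_chemicals,
      chemicals = chemicals)
    rho <- tryCatch(
      spearman_rho(r$per_sample$ear_mix, r$per_sample$eeq_mix),
      error = function(e) NA_real_)
    calibration <- list(ratio = r$median_ratio, source = "recomputed",
                        n = r$n, spearman_rho = rho,
                        per_sample = r$per_sample)
    benchmarks <- benchmark_config(
      noec_ug_L = benchmarks$noec_ug_L, loec_ug_L = benchmarks$loec_ug_L,
      calibration_ratio = r$median_ratio,
      bcf_bw_low = benchmarks$bcf_bw_low,
      bcf_bw_high = benchmarks$bcf_bw_high)
  }
  thresholds <- derive_thresholds(benchmarks)

  site_rows <- ear$by_sample[ear$by_sample$matrix == config$site_matrix, ,
                             drop = FALSE]
  if (nrow(site_rows) == 0L) site_rows <- ear$by_sample
  sites <- classify_sites(site_rows, thresholds, q = config$site_q)

  sample_activity <- sample_activity_table(
    ear$by_sample, thresholds, use_highest_loec = config$use_highest_loec)
  roles <- chemical_roles(sample_activity, ear)
  priorities <- resolve_categories(roles, statuses, samples)
  drivers <- driver_fraction(sample_activity, ear)
  detection <- detection_frequency(samples)
  concordance <- if (!is.null(field)) concordance_table(sites, field) else NULL

  structure(list(statuses = statuses, acc5 = acc5, ear = ear,
                 calibration = calibration, thresholds = thresholds,
                 sites = sites, sample_activity = sample_activity,
                 roles = roles, priorities = priorities, drivers = drivers,
                 detection = detection, concordance = concordance,
                 config = config, call = cl),
            class = "ear_screen")
}

#' @export
print.ear_screen <- function(x, ...) {
  cat("Estrogenic mixture screen (exposure-activity ratios)\n")
  st <- table(x$statuses$status)
  cat(sprintf("  chemicals: %d (%d active e-EDCs, %d inactive, %d excluded low-AUC, %d insufficient info)\n",
              nrow(x$statuses), st[["active_eedc"]], st[["inactive"]],
              st[["excluded_low_auc"]], st[["insufficient_information"]]))
  act <- table(x$sample_activity$activity)
  cat(sprintf("  samples:   %d (%d high, %d medium, %d low estrogenic activity)\n",
              nrow(x$sample_activity), act[["high"]], act[["medium"]],
              act[["low"]]))
  sc <- table(x$sites$site_class)
  cat(sprintf("  sites:     %d (%d low / %d medium / %d high-low-certainty / %d high-high-certainty)\n",
              nrow(x$sites), sc[["low"]], sc[["medium"]],
              sc[["high_low_certainty"]], sc[["high_high_certainty"]]))
  cat(sprintf("  calibration ratio: %.4g (%s)\n",
              x$calibration$ratio, x$calibration$source))
  pr <- x$priorities$priorities
  if (nrow(pr) > 0L) {
    tp <- table(pr$category)
    cat(sprintf("  priorities: %d high priority, %d watch list, %d low priority, %d insufficient information\n",
                tp[["high_priority"]], tp[["watch_list"]],
                tp[["low_priority"]], tp[["insufficient_information"]]))
  }
  invisible(x)
}

#' Summarize a screening run
#'
#' @param object An \code{"ear_screen"} object.
#' @param ... Unused.
#' @return The object, invisibly, after printing thresholds, the site
#'   classification, the priority table, and driver statistics.
#' @export
summary.ear_screen <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$thresholds)
  cat("\nSite classification:\n")
  print(object$sites, row.names = FALSE)
  cat("\nChemical priorities:\n")
  print(object$priorities$priorities, row.names = FALSE)
  d <- object$drivers
  cat(sprintf("\nSingle-chemical exceedance: %.0f%% of %d samples above NOEC; %.0f%% of %d above LOEC\n",
              100 * d$frac_single_above_noec, d$n_above_noec,
              100 * d$frac_single_above_loec, d$n_above_loec))
  invisible(object)
}

#' Plot per-site mixture EAR distributions
#'
#' Box plots of log10 EAR_mix by site for the site-classification matrix,
#' the site-level upper percentile overlaid as points, and the bile
#' threshold bounds as horizontal lines.
#'
#' @param x An \code{"ear_screen"} object.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.ear_screen <- function(x, ...) {
  rows <- x$ear$by_sample[x$ear$by_sample$matrix == x$config$site_matrix, ,
                          drop = FALSE]
  if (nrow(rows) == 0L) rows <- x$ear$by_sample
  v <- pmax(rows$ear_mix, min(rows$ear_mix[rows$ear_mix > 0], 1e-6) / 10)
  ord <- order(x$sites$p95_ear_mix)
  f <- factor(rows$site_id, levels = x$sites$site_id[ord])
  graphics::boxplot(log10(v) ~ f, las = 2, xlab = "",
                    ylab = "log10 EAR_mix", ...)
  graphics::points(seq_along(levels(f)), log10(sort(x$sites$p95_ear_mix)),
                   pch = 17, col = "red")
  t <- x$thresholds
  graphics::abline(h = log10(c(t$noec_bear_low, t$loec_bear_low,
                               t$loec_bear_high)),
                   lty = c(3, 2, 1), col = "grey40")
  invisible(x)
}

#' Run the pipeline from files and write the report bundle
#'
#' Reads the three input tables, runs [ear_screen()], and writes the report
#' CSVs (thresholds, site report, sample report, chemical priorities,
#' detection frequencies, per-chemical EARs) plus a provenance log capturing
#' the configuration, constants, and package version, to \code{out_dir}.
#'
#' @param chemical_path,assay_path,sample_path CSV paths.
#' @param out_dir Output directory (created if needed).
#' @param config A [screen_config()].
#' @param field Optional field-response table or CSV path.
#' @return The \code{"ear_screen"} object, invisibly.
#' @export
run_pipeline <- function(chemical_path, assay_path, sample_path, out_dir,
                         config = screen_config(), field = NULL) {
  if (is.character(field) && length(field) == 1L)
    field <- utils::read.csv(field, stringsAsFactors = FALSE)
  res <- ear_screen(chemical_path, assay_path, sample_path,
                    config = config, field = field)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(report_rounded(res$thresholds),
                  file.path(out_dir, "thresholds.csv"))
  write_table_csv(res$sites, file.path(out_dir, "site_report.csv"))
  write_table_csv(res$sample_activity,
                  file.path(out_dir, "sample_report.csv"))
  write_table_csv(res$priorities$priorities,
                  file.path(out_dir, "priority_report.csv"))
  write_table_csv(res$detection,
                  file.path(out_dir, "detection_frequency.csv"))
  write_table_csv(res$ear$by_chemical,
                  file.path(out_dir, "ear_by_chemical.csv"))
  if (!is.null(res$concordance))
    write_table_csv(res$concordance, file.path(out_dir, "concordance.csv"))
  prov <- c(
    sprintf("earscreen %s | R %s", as.character(utils::packageVersion("earscreen")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("inputs: %s | %s | %s", chemical_path, assay_path, sample_path),
    sprintf("calibration ratio: %.6g (%s)", res$calibration$ratio,
            res$calibration$source),
    sprintf("benchmarks: NOEC %g LOEC %g ug/L; BCF_bw %g-%g",
            res$thresholds$config$noec_ug_L, res$thresholds$config$loec_ug_L,
            res$thresholds$config$bcf_bw_low,
            res$thresholds$config$bcf_bw_high),
    sprintf("thresholds (unrounded): noec_ear %.6g loec_ear %.6g noec_bear %.6g-%.6g loec_bear %.6g-%.6g",
            res$thresholds$noec_ear, res$thresholds$loec_ear,
            res$thresholds$noec_bear_low, res$thresholds$noec_bear_high,
            res$thresholds$loec_bear_low, res$thresholds$loec_bear_high),
    sprintf("config: auc_cutoff %g; percentile_q %g; site_q %g; bile_sex %s; use_highest_loec %s; recompute_ratio %s; excluded_flags [%s]",
            config$auc_cutoff, config$percentile_q, config$site_q,
            config$bile_sex %||% "none", config$use_highest_loec,
            config$recompute_ratio,
            paste(config$excluded_flags, collapse = ",")))
  writeLines(prov, file.path(out_dir, "provenance.log"))
  invisible(res)
}
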