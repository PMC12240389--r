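# Effect thresholds: estradiol benchmarks translated onto the EAR scale for
# water, then into bile-concentration space through bile-water accumulation
# factors.

#' Effect benchmark configuration
#'
#' Defaults are the vitellogenin-induction benchmarks for 17beta-estradiol
#' in adult male zebrafish (NOEC 0.005 ug/L, LOEC 0.025 ug/L), the median
#' EAR/EEQ translation ratio of 27 observed in male fish bile, and the
#' published range of bile-water bioaccumulation factors for estradiol in
#' juvenile rainbow trout (4000-13000).
#'
#' @param noec_ug_L No-observed-effect concentration, ug/L (> 0).
#' @param loec_ug_L Lowest-observed-effect concentration, ug/L (> noec).
#' @param calibration_ratio Unitless EAR/EEQ translation ratio (> 0); may be
#'   recomputed from data with [median_ear_eeq_ratio()].
#' @param bcf_bw_low,bcf_bw_high Bile-water bioaccumulation factor bounds
#'   (unitless, low <= high).
#' @return A list of class \code{"benchmark_config"}.
#' @export
benchmark_config <- function(noec_ug_L = 0.005, loec_ug_L = 0.025,
                             calibration_ratio = 27,
                             bcf_bw_low = 4000, bcf_bw_high = 13000) {
  if (!is.finite(noec_ug_L) || noec_ug_L <= 0)
    stopf("noec_ug_L must be > 0")
  if (!is.finite(loec_ug_L) || loec_ug_L <= noec_ug_L)
    stopf("loec_ug_L must exceed noec_ug_L")
  if (!is.finite(calibration_ratio) || calibration_ratio <= 0)
    stopf("calibration_ratio must be > 0")
  if (!is.finite(bcf_bw_low) || !is.finite(bcf_bw_high) ||
      bcf_bw_low <= 0 || bcf_bw_low > bcf_bw_high)
    stopf("need 0 < bcf_bw_low <= bcf_bw_high")
  structure(list(noec_ug_L = noec_ug_L, loec_ug_L = loec_ug_L,
                 calibration_ratio = calibration_ratio,
                 bcf_bw_low = bcf_bw_low, bcf_bw_high = bcf_bw_high),
            class = "benchmark_config")
}

#' Derive water- and bile-based EAR thresholds
#'
#' Water thresholds translate the estradiol benchmarks onto the EAR scale:
#' \code{noec_ear = NOEC x ratio}, \code{loec_ear = LOEC x ratio}. Bile
#' thresholds multiply the water thresholds by each bound of the bile-water
#' bioaccumulation factor range, yielding low/high pairs. All values are
#' stored unrounded; classification always uses the unrounded values, and
#' [report_rounded()] handles presentation.
#'
#' @param cfg A [benchmark_config()].
#' @return List of class \code{"threshold_set"} with elements
#'   \code{noec_ear}, \code{loec_ear}, \code{noec_bear_low},
#'   \code{noec_bear_high}, \code{loec_bear_low}, \code{loec_bear_high},
#'   and the generating \code{config}.
#' @export
#' @examples
#' derive_thresholds(benchmark_config())
derive_thresholds <- function(cfg = benchmark_config()) {
  if (!inherits(cfg, "benchmark_config")) cfg <- do.call(benchmark_config, cfg)
  noec_ear <- cfg$noec_ug_L * cfg$calibration_ratio
  loec_ear <- cfg$loec_ug_L * cfg$calibration_ratio
  ts <- structure(list(noec_ear = noec_ear,
                       loec_ear = loec_ear,
                       noec_bear_low = noec_ear * cfg$bcf_bw_low,
                       noec_bear_high = noec_ear * cfg$bcf_bw_high,
                       loec_bear_low = loec_ear * cfg$bcf_bw_low,
                       loec_bear_high = loec_ear * cfg$bcf_bw_high,
                       config = cfg),
                  class = "threshold_set")
  stopifnot(ts$noec_ear < ts$loec_ear,
            ts$noec_bear_low < ts$loec_bear_low,
            ts$noec_bear_high < ts$loec_bear_high)
  ts
}

#' Threshold report at a fixed number of significant figures
#'
#' Presentation-only rounding (half away from zero); the unrounded values are
#' kept alongside and remain the ones used for any classification.
#'
#' @param t A \code{"threshold_set"}.
#' @param sig_figs Significant figures (default 2).
#' @return Data frame with columns \code{threshold}, \code{unrounded},
#'   \code{rounded}.
#' @export
report_rounded <- function(t, sig_figs = 2L) {
  stopifnot(inherits(t, "threshold_set"))
  nm <- c("noec_ear", "loec_ear", "noec_bear_low", "noec_bear_high",
          "loec_bear_low", "loec_bear_high")
  v <- unlist(t[nm])
  data.frame(threshold = nm, unrounded = unname(v),
             rounded = unname(signif_half_up(v, sig_figs)),
             stringsAsFactors = FALSE)
}

#' @export
print.threshold_set <- function(x, ...) {
  r <- report_rounded(x)
  cat("EAR effect thresholds (unrounded; 2-sig-fig report in parentheses)\n")
  cat(sprintf("  water: NOEC_EAR %.4g (%.3g)  LOEC_EAR %.4g (%.3g)\n",
              x$noec_ear, r$rounded[1], x$loec_ear, r$rounded[2]))
  cat(sprintf("  bile:  NOEC_bEAR %.4g-%.4g (%.3g-%.3g)\n",
              x$noec_bear_low, x$noec_bear_high, r$rounded[3], r$rounded[4]))
  cat(sprintf("         LOEC_bEAR %.4g-%.4g (%.3g-%.3g)\n",
              x$loec_bear_low, x$loec_bear_high, r$rounded[5], r$rounded[6]))
  cat(sprintf("  benchmarks: NOEC %g, LOEC %g ug/L; ratio %g; BCF_bw %g-%g\n",
              x$config$noec_ug_L, x$config$loec_ug_L,
              x$config$calibration_ratio, x$config$bcf_bw_low,
              x$config$bcf_bw_high))
  invisible(x)
}
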