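# Shared internal helpers: vocabularies, validation, percentiles, rounding.

# Matrix vocabulary and the concentration unit each matrix reports in.
MATRIX_LEVELS <- c("marine_water", "wwtp_effluent", "mussel_tissue",
                   "fish_tissue", "bile")
MATRIX_UNIT <- c(marine_water = "ng_per_L",
                 wwtp_effluent = "ng_per_L",
                 mussel_tissue = "ng_per_g",
                 fish_tissue = "ng_per_g",
                 bile = "ng_per_mL")
TISSUE_MATRICES <- c("mussel_tissue", "fish_tissue")

STATUS_LEVELS <- c("active_eedc", "inactive", "excluded_low_auc",
                   "insufficient_information")
SITE_CLASS_LEVELS <- c("low", "medium", "high_low_certainty",
                       "high_high_certainty")
ACTIVITY_LEVELS <- c("low", "medium", "high")
ROLE_LEVELS <- c("minor_contributor", "major_contributor", "driver")
PRIORITY_LEVELS <- c("insufficient_information", "low_priority",
                     "watch_list", "high_priority")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(df)
}

#' Linear-interpolation percentile
#'
#' The percentile convention used throughout the package (ACC5 aggregation and
#' site-level 95th percentiles): linear interpolation between the closest order
#' statistics at position \code{q * (n - 1)}, i.e. the type-7 quantile.
#'
#' @param x Numeric vector with at least one finite value.
#' @param q Fraction in \code{[0, 1]}.
#' @return The interpolated percentile as a single number.
#' @export
#' @examples
#' percentile_interp(c(-2, -1, 0, 1, 2), 0.05)  # -1.8
percentile_interp <- function(x, q) {
  if (length(x) == 0L) stopf("percentile of an empty vector is undefined")
  if (any(!is.finite(x))) stopf("percentile input must be finite")
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stopf("q must be a single fraction in [0, 1]")
  unname(stats::quantile(x, probs = q, type = 7, names = FALSE))
}

#' Round to significant figures, half away from zero
#'
#' Display rounding for threshold reports. Classification always uses
#' unrounded values; this affects presentation only.
#'
#' @param x Numeric vector.
#' @param sig_figs Number of significant figures (>= 1).
#' @return Rounded numeric vector.
#' @export
signif_half_up <- function(x, sig_figs = 2L) {
  if (sig_figs < 1L) stopf("sig_figs must be >= 1")
  out <- x
  nz <- is.finite(x) & x != 0
  mag <- floor(log10(abs(x[nz])))
  f <- 10^(sig_figs - 1 - mag)
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) * f + 0.5) / f
  out
}
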