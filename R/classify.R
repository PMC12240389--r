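# Site and sample classification against the EAR thresholds, and the
# qualitative concordance join with field measures of organism response.

#' Site-level upper-percentile EAR_mix
#'
#' The site statistic is an upper percentile (default 95th) of the site's
#' per-sample mixture EARs, representing the upper end of the exposure
#' distribution; same interpolation convention as ACC5.
#'
#' @param ear_mix_values Numeric vector (>= 1 value).
#' @param q Percentile fraction (default 0.95).
#' @return The percentile value.
#' @export
site_percentile <- function(ear_mix_values, q = 0.95) {
  percentile_interp(ear_mix_values, q)
}

#' Classify sites from the upper-percentile EAR_mix
#'
#' Regions partition \code{[0, Inf)} using the bile threshold ranges (lower
#' bounds inclusive, upper bounds exclusive):
#' \itemize{
#'   \item \code{p95 >= loec_bear_high}: high potential, high certainty;
#'   \item \code{loec_bear_low <= p95 < loec_bear_high}: high potential,
#'     low certainty (within the threshold range, so the call depends on
#'     which accumulation factor applies);
#'   \item \code{noec_bear_low <= p95 < loec_bear_low}: medium potential;
#'   \item \code{p95 < noec_bear_low}: low potential.
#' }
#'
#' @param p95 Numeric vector of site-level percentile EAR_mix values.
#' @param t A \code{"threshold_set"}.
#' @return Factor over \code{low < medium < high_low_certainty <
#'   high_high_certainty}.
#' @export
classify_site <- function(p95, t) {
  stopifnot(inherits(t, "threshold_set"))
  cls <- ifelse(p95 >= t$loec_bear_high, "high_high_certainty",
         ifelse(p95 >= t$loec_bear_low, "high_low_certainty",
         ifelse(p95 >= t$noec_bear_low, "medium", "low")))
  factor(cls, levels = SITE_CLASS_LEVELS, ordered = TRUE)
}

#' Site classification table from per-sample mixture EARs
#'
#' Groups the per-sample EAR table by site, takes the upper percentile, and
#' classifies each site.
#'
#' @param ear_by_sample The \code{by_sample} element of an
#'   \code{"ear_table"} (or any data frame with \code{site_id} and
#'   \code{ear_mix}).
#' @param t A \code{"threshold_set"}.
#' @param q Site percentile fraction (default 0.95).
#' @return Data frame with \code{site_id}, \code{n_samples},
#'   \code{p95_ear_mix}, \code{site_class}.
#' @export
classify_sites <- function(ear_by_sample, t, q = 0.95) {
  assert_columns(ear_by_sample, c("site_id", "ear_mix"), "per-sample EAR table")
  sites <- unique(ear_by_sample$site_id)
  p95 <- vapply(sites, function(s)
    site_percentile(ear_by_sample$ear_mix[ear_by_sample$site_id == s], q),
    numeric(1L))
  n <- vapply(sites, function(s)
    sum(ear_by_sample$site_id == s), integer(1L))
  out <- data.frame(site_id = sites, n_samples = unname(n),
                    p95_ear_mix = unname(p95),
                    site_class = classify_site(unname(p95), t),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify a sample's estrogenic activity
#'
#' Bile samples are judged against the lowest bile thresholds
#' (\code{noec_bear_low}, \code{loec_bear_low}) as the conservative choice
#' consistent with single-valued water thresholds; in sensitivity mode
#' (\code{use_highest_loec = TRUE}) the highest LOEC_bEAR replaces the
#' lowest. All other matrices use the water thresholds. Activity is
#' \code{low} below the NOEC threshold, \code{medium} in
#' \code{[NOEC, LOEC)}, \code{high} at or above the LOEC threshold.
#'
#' @param ear_mix Numeric vector of per-sample mixture EARs.
#' @param matrix Matrix of each sample (recycled).
#' @param t A \code{"threshold_set"}.
#' @param use_highest_loec Sensitivity mode for bile (default \code{FALSE}).
#' @return Data frame with \code{activity} (ordered factor low < medium <
#'   high) and the governing \code{noec}, \code{loec} actually applied.
#' @export
classify_sample <- function(ear_mix, matrix, t, use_highest_loec = FALSE) {
  stopifnot(inherits(t, "threshold_set"))
  n <- length(ear_mix)
  matrix <- rep_len(matrix, n)
  bad <- setdiff(unique(matrix), MATRIX_LEVELS)
  if (length(bad) > 0L)
    stopf("unknown matrix value(s): %s", paste(bad, collapse = ", "))
  bile <- matrix == "bile"
  noec <- ifelse(bile, t$noec_bear_low, t$noec_ear)
  loec <- ifelse(bile,
                 if (use_highest_loec) t$loec_bear_high else t$loec_bear_low,
                 t$loec_ear)
  act <- ifelse(ear_mix >= loec, "high",
         ifelse(ear_mix >= noec, "medium", "low"))
  data.frame(activity = factor(act, levels = ACTIVITY_LEVELS, ordered = TRUE),
             noec = noec, loec = loec)
}

#' Sample activity table
#'
#' [classify_sample()] applied to every row of a per-sample EAR table.
#'
#' @inheritParams classify_sites
#' @inheritParams classify_sample
#' @return The per-sample table with \code{activity}, \code{noec},
#'   \code{loec} columns appended.
#' @export
sample_activity_table <- function(ear_by_sample, t, use_highest_loec = FALSE) {
  assert_columns(ear_by_sample, c("sample_id", "matrix", "ear_mix"),
                 "per-sample EAR table")
  cbind(ear_by_sample,
        classify_sample(ear_by_sample$ear_mix, ear_by_sample$matrix, t,
                        use_highest_loec = use_highest_loec))
}

#' Join site classes with field measures of organism response
#'
#' Left-joins the site classification with field response data (percent male
#' vitellogenin induction, percent females with altered reproductive timing)
#' and adds a qualitative alignment flag. A site is flagged aligned when its
#' class rank and its male-Vtg response fall on the same side of their
#' respective medians (computed over sites with field data); a site sitting
#' exactly at the median class rank is counted aligned, since a mid-range
#' classification is consistent with any response level. The flag is a
#' reported diagnostic only and never feeds back into classification.
#'
#' @param classes Site classification table from [classify_sites()].
#' @param field Data frame with \code{site_id}, \code{pct_male_vtg},
#'   optionally \code{pct_female_altered_timing} (may be empty).
#' @return One row per classified site with field columns (NA where absent)
#'   and a logical \code{aligned} (NA without field data).
#' @export
concordance_table <- function(classes, field) {
  assert_columns(classes, c("site_id", "p95_ear_mix", "site_class"),
                 "site classification table")
  if (is.null(field) || nrow(field) == 0L) {
    field <- data.frame(site_id = character(), pct_male_vtg = numeric(),
                        pct_female_altered_timing = numeric(),
                        stringsAsFactors = FALSE)
  }
  assert_columns(field, c("site_id", "pct_male_vtg"), "field response table")
  if (is.null(field$pct_female_altered_timing))
    field$pct_female_altered_timing <- NA_real_
  pct <- c(field$pct_male_vtg, field$pct_female_altered_timing)
  if (any(!is.na(pct) & (pct < 0 | pct > 100)))
    stopf("field response percentages must lie in [0, 100]")
  out <- merge(classes, field, by = "site_id", all.x = TRUE, sort = FALSE)
  rank <- as.integer(out$site_class)
  has <- !is.na(out$pct_male_vtg)
  out$aligned <- NA
  if (sum(has) > 0L) {
    med_rank <- stats::median(rank[has])
    med_vtg <- stats::median(out$pct_male_vtg[has])
    out$aligned[has] <- rank[has] == med_rank |
      ((rank[has] > med_rank) == (out$pct_male_vtg[has] > med_vtg))
  }
  rownames(out) <- NULL
  out
}
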