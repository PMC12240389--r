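# Calibration: estradiol equivalency quotients and the EAR/EEQ translation
# ratio that anchors the effect thresholds.

#' Estradiol equivalency quotients per sample
#'
#' For each detected chemical with an estradiol equivalency factor (EEF),
#' EEQ = concentration x EEF; the per-sample \code{eeq_mix} is their sum.
#' Chemicals without an EEF contribute nothing. Concentrations enter on the
#' same water-equivalent scale used for EARs (bile ng/mL is numerically
#' ug/L, so bile EEQs are in ng/mL estradiol equivalents).
#'
#' @param samples Validated sample table.
#' @param chemicals Validated chemical registry carrying \code{eef}.
#' @return List with \code{by_chemical} (\code{sample_id}, \code{cas},
#'   \code{eeq}) and \code{by_sample} (\code{sample_id}, \code{eeq_mix}; one
#'   row per sample).
#' @export
compute_eeq_table <- function(samples, chemicals) {
  samples <- sample_table(samples)
  chemicals <- chemical_registry(chemicals)
  has_eef <- chemicals$cas[!is.na(chemicals$eef)]
  det <- samples[samples$detected & samples$cas %in% has_eef, , drop = FALSE]
  if (nrow(det) > 0L) {
    ci <- match(det$cas, chemicals$cas)
    conc <- to_water_equivalent(det$value, det$unit,
                                bcf = chemicals$bcf_l_per_kg[ci],
                                cas = det$cas)
    eeq <- conc * chemicals$eef[ci]
  } else {
    eeq <- numeric(0)
  }
  by_chemical <- data.frame(sample_id = det$sample_id, cas = det$cas,
                            eeq = eeq, stringsAsFactors = FALSE)
  sample_ids <- unique(samples$sample_id)
  mix <- vapply(sample_ids,
                function(id) sum(eeq[det$sample_id == id]), numeric(1L))
  by_sample <- data.frame(sample_id = sample_ids, eeq_mix = unname(mix),
                          stringsAsFactors = FALSE)
  rownames(by_chemical) <- rownames(by_sample) <- NULL
  list(by_chemical = by_chemical, by_sample = by_sample)
}

#' Median EAR/EEQ translation ratio
#'
#' Computes \code{ear_mix / eeq_mix} per sample and returns the median over
#' samples with \code{eeq_mix > 0}. This ratio translates estradiol-based
#' effect benchmarks onto the EAR scale when deriving thresholds.
#'
#' By default \code{ear_mix} covers all active estrogenic chemicals in each
#' sample while \code{eeq_mix} covers only EEF-bearing chemicals; setting
#' \code{restrict_to_eef_chemicals = TRUE} restricts the EAR side to the same
#' EEF-bearing set before forming ratios (an alternative reading of the
#' calibration; see the methods vignette).
#'
#' @param ear \code{"ear_table"} from [compute_ear_table()].
#' @param eeq Output of [compute_eeq_table()].
#' @param restrict_to_eef_chemicals Logical (default \code{FALSE}).
#' @param chemicals Chemical registry; required when
#'   \code{restrict_to_eef_chemicals} is \code{TRUE}.
#' @return List with \code{median_ratio}, \code{n} (samples used), and
#'   \code{per_sample} (data frame \code{sample_id}, \code{ear_mix},
#'   \code{eeq_mix}, \code{ratio}).
#' @export
median_ear_eeq_ratio <- function(ear, eeq, restrict_to_eef_chemicals = FALSE,
                                 chemicals = NULL) {
  ear_by_sample <- ear$by_sample
  if (restrict_to_eef_chemicals) {
    if (is.null(chemicals))
      stopf("restrict_to_eef_chemicals requires the chemical registry")
    chemicals <- chemical_registry(chemicals)
    has_eef <- chemicals$cas[!is.na(chemicals$eef)]
    bc <- ear$by_chemical
    bc <- bc[bc$cas %in% has_eef, , drop = FALSE]
    mix <- vapply(ear_by_sample$sample_id,
                  function(id) sum(bc$ear_acc5[bc$sample_id == id]),
                  numeric(1L))
    ear_by_sample$ear_mix <- unname(mix)
  }
  m <- merge(ear_by_sample[, c("sample_id", "ear_mix")], eeq$by_sample,
             by = "sample_id")
  m <- m[m$eeq_mix > 0, , drop = FALSE]
  if (nrow(m) == 0L)
    stopf("no samples with eeq_mix > 0; cannot form the translation ratio")
  m$ratio <- m$ear_mix / m$eeq_mix
  rownames(m) <- NULL
  list(median_ratio = stats::median(m$ratio), n = nrow(m), per_sample = m)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked vectors (ties receive their mean
#' rank). Used to verify that EAR-based and EEQ-based mixture scores agree
#' in rank order.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return Correlation in \code{[-1, 1]}.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("Spearman correlation is undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}
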