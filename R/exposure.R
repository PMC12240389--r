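# Exposure: water-equivalent conversion and exposure-activity ratios.

#' Convert a measurement to a water-equivalent concentration (ug/L)
#'
#' Water and effluent concentrations (ng/L) convert by unit only. Tissue
#' concentrations (ng/g wet weight, numerically ug/kg) are back-calculated to
#' water with a chemical-specific bioconcentration factor (L/kg). Bile
#' concentrations (ng/mL) are used directly: ng/mL is numerically identical
#' to ug/L, and comparability with effect levels is restored downstream by
#' the bile-specific thresholds rather than by a BCF translation.
#'
#' @param value Measured concentration(s) in the native unit.
#' @param unit One of \code{"ng_per_L"}, \code{"ng_per_g"},
#'   \code{"ng_per_mL"} (recycled to the length of \code{value}).
#' @param bcf Tissue-water bioconcentration factor in L/kg; required (and
#'   > 0) for \code{ng_per_g}.
#' @param cas Chemical identifier(s) used in error messages.
#' @return Concentration(s) in ug/L (bile: ug/L-equivalent bile units).
#' @export
#' @examples
#' to_water_equivalent(1000, "ng_per_L")        # 1 ug/L
#' to_water_equivalent(10, "ng_per_g", bcf = 100)  # 0.1 ug/L
to_water_equivalent <- function(value, unit, bcf = NA_real_, cas = "") {
  n <- length(value)
  unit <- rep_len(unit, n)
  bcf <- rep_len(bcf, n)
  cas <- rep_len(cas, n)
  bad <- setdiff(unique(unit), c("ng_per_L", "ng_per_g", "ng_per_mL"))
  if (length(bad) > 0L)
    stopf("unknown concentration unit(s): %s", paste(bad, collapse = ", "))
  tissue <- unit == "ng_per_g"
  nobcf <- tissue & (!is.finite(bcf) | bcf <= 0)
  if (any(nobcf))
    stopf("tissue measurement(s) without a usable BCF for chemical(s): %s",
          paste(unique(cas[nobcf]), collapse = ", "))
  out <- numeric(n)
  out[unit == "ng_per_L"] <- value[unit == "ng_per_L"] / 1000
  out[unit == "ng_per_mL"] <- value[unit == "ng_per_mL"]
  out[tissue] <- value[tissue] / bcf[tissue]
  out
}

#' Exposure-activity ratio for one chemical
#'
#' The ratio of the (water-equivalent) environmental concentration to the
#' chemical's ACC5 potency, both in ug/L.
#'
#' @param conc_ug_L Concentration in ug/L (>= 0).
#' @param acc5_ug_L ACC5 in ug/L (> 0).
#' @return The dimensionless EAR.
#' @export
compute_ear <- function(conc_ug_L, acc5_ug_L) {
  if (any(!is.finite(acc5_ug_L) | acc5_ug_L <= 0))
    stopf("ACC5 must be > 0")
  if (any(!is.finite(conc_ug_L) | conc_ug_L < 0))
    stopf("concentration must be >= 0")
  conc_ug_L / acc5_ug_L
}

#' Drop female (or unknown-sex) bile samples
#'
#' Endogenous steroidal estrogens in reproductively active females confound
#' the interpretation of exogenous exposure, so bile-based mixture screening
#' runs on male fish only by default. Non-bile samples pass through.
#'
#' @param samples Validated sample table.
#' @param sex Sex retained for bile samples (default \code{"male"}).
#' @return The filtered sample table.
#' @export
filter_bile_sex <- function(samples, sex = "male") {
  samples <- sample_table(samples)
  keep <- samples$matrix != "bile" |
    (!is.na(samples$sex) & samples$sex == sex)
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-chemical EARs and per-sample mixture EARs
#'
#' For every sample, computes the EAR of each detected chemical classified
#' \code{active_eedc} and sums them under concentration addition into an
#' \code{ear_mix}. Non-detects and non-active chemicals contribute zero (no
#' substitution at the quantification limit). Samples with no detected
#' active chemical get \code{ear_mix = 0} and no contribution rows.
#'
#' @param samples Validated sample table.
#' @param chemicals Validated chemical registry (for molecular weights and
#'   BCFs).
#' @param acc5 ACC5 table from [acc5_table()].
#' @param statuses Status table from [identify_eedcs()].
#' @return List of class \code{"ear_table"} with elements
#'   \describe{
#'     \item{by_chemical}{data frame \code{sample_id}, \code{cas},
#'       \code{conc_ug_L}, \code{ear_acc5}, \code{pct_contribution};}
#'     \item{by_sample}{data frame \code{sample_id}, \code{site_id},
#'       \code{matrix}, \code{n_eedcs_detected}, \code{ear_mix} (one row per
#'       sample, including all-zero samples).}
#'   }
#' @export
compute_ear_table <- function(samples, chemicals, acc5, statuses) {
  samples <- sample_table(samples)
  chemicals <- chemical_registry(chemicals)
  active <- statuses$cas[statuses$status == "active_eedc"]

  det <- samples[samples$detected & samples$cas %in% active, , drop = FALSE]
  missing_acc5 <- setdiff(unique(det$cas), acc5$cas)
  if (length(missing_acc5) > 0L)
    stopf("detected active chemical(s) without an ACC5 record: %s",
          paste(missing_acc5, collapse = ", "))

  if (nrow(det) > 0L) {
    ci <- match(det$cas, chemicals$cas)
    det$conc_ug_L <- to_water_equivalent(det$value, det$unit,
                                         bcf = chemicals$bcf_l_per_kg[ci],
                                         cas = det$cas)
    det$ear_acc5 <- compute_ear(det$conc_ug_L,
                                acc5$acc5_ug_per_L[match(det$cas, acc5$cas)])
  } else {
    det$conc_ug_L <- numeric(0)
    det$ear_acc5 <- numeric(0)
  }

  sample_ids <- unique(samples$sample_id)
  first <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]
  mix <- vapply(sample_ids,
                function(id) sum(det$ear_acc5[det$sample_id == id]),
                numeric(1L))
  n_det <- vapply(sample_ids,
                  function(id) sum(det$sample_id == id), integer(1L))
  by_sample <- data.frame(sample_id = sample_ids,
                          site_id = first$site_id,
                          matrix = first$matrix,
                          n_eedcs_detected = n_det,
                          ear_mix = unname(mix),
                          stringsAsFactors = FALSE)
  rownames(by_sample) <- NULL

  by_chemical <- det[, c("sample_id", "cas", "conc_ug_L", "ear_acc5")]
  mix_of <- by_sample$ear_mix[match(by_chemical$sample_id, by_sample$sample_id)]
  by_chemical$pct_contribution <-
    ifelse(mix_of > 0, 100 * by_chemical$ear_acc5 / mix_of, NA_real_)
  rownames(by_chemical) <- NULL

  structure(list(by_chemical = by_chemical, by_sample = by_sample),
            class = "ear_table")
}
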