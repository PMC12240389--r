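# Bundled published data.

#' Published Salish Sea bile site summary
#'
#' Site-level summary of the English sole bile monitoring campaign (male
#' fish, 2011-2019): the 95th-percentile mixture EAR at each of 18 sites,
#' sample counts, and, for the ten sites with biological surveys (1997-2001),
#' the percentage of males expressing vitellogenin and of females with
#' altered reproductive timing (NA where not surveyed).
#'
#' These are the published site statistics, shipped so the site
#' classification and concordance exercise can be reproduced without the
#' underlying per-fish chemistry deposit.
#'
#' @return Data frame with columns \code{site_id}, \code{n_samples},
#'   \code{p95_ear_mix}, \code{pct_male_vtg},
#'   \code{pct_female_altered_timing}.
#' @export
#' @examples
#' s <- salish_site_summary()
#' table(classify_site(s$p95_ear_mix, derive_thresholds()))
salish_site_summary <- function() {
  path <- system.file("extdata", "salish_site_summary.csv",
                      package = "earscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
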