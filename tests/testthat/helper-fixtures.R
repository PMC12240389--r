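# Fixture builders and independent oracles shared across the suite.

# Independent sort-and-interpolate percentile: enumerate order statistics,
# interpolate linearly at position q*(n-1). Kept free of stats::quantile so
# it can serve as an oracle for the package's percentile convention.
oracle_percentile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  if (n == 1L) return(s)
  h <- q * (n - 1)
  lo <- floor(h)
  hi <- min(lo + 1, n - 1)
  s[lo + 1] + (h - lo) * (s[hi + 1] - s[lo + 1])
}

# Independent average-rank assignment (ties get the mean of their positions).
oracle_avg_rank <- function(x) {
  s <- sort(unique(x))
  out <- numeric(length(x))
  for (v in s) {
    idx <- which(x == v)
    pos <- which(sort(x) == v)
    out[idx] <- mean(pos)
  }
  out
}

make_chemicals <- function(cas, mw = 100, auc = 0.9, eef = NA_real_,
                           bcf = NA_real_, override = NA_character_) {
  n <- length(cas)
  data.frame(cas = cas, name = paste0("chem-", cas), chem_class = "Test",
             molecular_weight_g_mol = rep_len(mw, n),
             auc = rep_len(auc, n), eef = rep_len(eef, n),
             bcf_l_per_kg = rep_len(bcf, n),
             override = rep_len(override, n), stringsAsFactors = FALSE)
}

make_assays <- function(cas, acc, assay_id = NULL, active = TRUE,
                        flags = "") {
  n <- max(length(cas), length(acc))
  if (is.null(assay_id))
    assay_id <- default_assay_roster()[seq_len(n)]
  data.frame(cas = rep_len(cas, n), assay_id = rep_len(assay_id, n),
             acc_log10_uM = rep_len(acc, n), active = rep_len(active, n),
             flags = rep_len(flags, n), stringsAsFactors = FALSE)
}

make_samples <- function(sample_id, cas, value, matrix = "bile",
                         site_id = "site_A", detected = TRUE,
                         sex = "male", loq = NA_real_) {
  n <- max(length(sample_id), length(cas), length(value))
  matrix <- rep_len(matrix, n)
  data.frame(sample_id = rep_len(sample_id, n),
             site_id = rep_len(site_id, n), matrix = matrix,
             species = "test-fish", sex = rep_len(sex, n), year = 2015L,
             cas = rep_len(cas, n), value = rep_len(value, n),
             unit = c(marine_water = "ng_per_L", wwtp_effluent = "ng_per_L",
                      mussel_tissue = "ng_per_g", fish_tissue = "ng_per_g",
                      bile = "ng_per_mL")[matrix],
             detected = rep_len(detected, n), loq = rep_len(loq, n),
             stringsAsFactors = FALSE)
}

# Statuses / ACC5 tables built directly, for exposure-layer tests that do not
# need the bioactivity layer.
make_statuses <- function(cas, status = "active_eedc") {
  data.frame(cas = cas, status = rep_len(status, length(cas)),
             stringsAsFactors = FALSE)
}

make_acc5 <- function(cas, acc5_ug_per_L) {
  data.frame(cas = cas, acc5_log10_uM = log10(acc5_ug_per_L / 100),
             acc5_ug_per_L = acc5_ug_per_L,
             n_assays_used = 1L, stringsAsFactors = FALSE)
}

default_ts <- function() derive_thresholds(benchmark_config())
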