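# Bioactivity: quality-flag filtering, estrogenicity calls, ACC5 aggregation.

#' Default estrogen-receptor agonist assay roster
#'
#' Names for the 18 receptor-agonism assays spanning the signaling pathway
#' (binding, dimerization, transactivation, proliferation). The roster is a
#' configuration item: supply your own ids when working from a different
#' assay extraction.
#'
#' @return Character vector of 18 assay ids.
#' @export
default_assay_roster <- function() {
  c("ER_binding_1", "ER_binding_2", "ER_binding_3", "ER_binding_4",
    "ER_dimer_agonist_1", "ER_dimer_agonist_2", "ER_dimer_agonist_3",
    "ER_dimer_agonist_4", "ER_dna_binding_1", "ER_dna_binding_2",
    "ER_transactivation_1", "ER_transactivation_2", "ER_transactivation_3",
    "ER_transactivation_4", "ER_transactivation_5", "ER_proliferation_1",
    "ER_agonist_extra_1", "ER_agonist_extra_2")
}

#' Default data-quality flags excluded from ACC aggregation
#'
#' Assay results carrying any of these flags are dropped before potency
#' aggregation, to limit false positives/negatives from borderline responses,
#' single-concentration hits, extrapolated potencies, or cell-free artifacts.
#' This list is a documented configuration default, not a fixed vocabulary.
#'
#' @return Character vector of flag tokens.
#' @export
default_excluded_flags <- function() {
  c("Borderline", "OnlyHighestConcActive", "GainAC50BelowLowest",
    "BiochemicalNoCell", "LessThan50PctEfficacy")
}

#' Filter assay results on data-quality flags
#'
#' Removes rows whose flag set intersects the excluded set; all other rows
#' are retained in their original order.
#'
#' @param assays Validated assay table (see [assay_table()]); the
#'   \code{flags} column is semicolon-delimited.
#' @param excluded_flags Character vector of flags to exclude (may be empty).
#' @return The filtered assay table.
#' @export
filter_assay_results <- function(assays, excluded_flags = default_excluded_flags()) {
  assays <- assay_table(assays)
  if (nrow(assays) == 0L || length(excluded_flags) == 0L) return(assays)
  flag_sets <- strsplit(assays$flags, ";", fixed = TRUE)
  drop <- vapply(flag_sets,
                 function(f) any(trimws(f) %in% excluded_flags),
                 logical(1L))
  out <- assays[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify chemicals by estrogenicity
#'
#' Partitions a chemical registry into exactly one status each, from the
#' flag-filtered assay table:
#' \itemize{
#'   \item no assay rows in the roster: \code{insufficient_information};
#'   \item assay rows but none active: \code{inactive};
#'   \item at least one active assay and pathway AUC above the cutoff:
#'     \code{active_eedc};
#'   \item at least one active assay and AUC at or below the cutoff (a likely
#'     assay-interference false positive): \code{excluded_low_auc}.
#' }
#' A manual \code{override} in the registry (\code{force_active} /
#' \code{force_inactive}), representing expert evaluation of chemicals the
#' pathway model does not cover, takes precedence over the AUC rule. An
#' assay-active chemical with neither an AUC score nor an override is an
#' error: such chemicals must be resolved explicitly, never guessed.
#'
#' @param chemicals Validated chemical registry.
#' @param assays Flag-filtered assay table.
#' @param auc_cutoff AUC at or below which an assay-active chemical is
#'   considered non-estrogenic (default 0.01).
#' @param roster Assay roster; rows outside it are ignored.
#' @return Data frame with columns \code{cas}, \code{status} (factor over the
#'   four statuses).
#' @export
identify_eedcs <- function(chemicals, assays, auc_cutoff = 0.01,
                           roster = default_assay_roster()) {
  chemicals <- chemical_registry(chemicals)
  assays <- assay_table(assays)
  if (!is.null(roster))
    assays <- assays[assays$assay_id %in% roster, , drop = FALSE]
  has_rows <- chemicals$cas %in% assays$cas
  active_cas <- unique(assays$cas[assays$active])
  status <- character(nrow(chemicals))
  for (i in seq_len(nrow(chemicals))) {
    cas <- chemicals$cas[i]
    if (!has_rows[i]) {
      status[i] <- "insufficient_information"
    } else if (!cas %in% active_cas) {
      status[i] <- "inactive"
    } else {
      ov <- chemicals$override[i]
      if (!is.na(ov)) {
        status[i] <- if (ov == "force_active") "active_eedc" else "inactive"
      } else if (is.na(chemicals$auc[i])) {
        stopf("chemical %s (%s) is active in ER agonist assays but has no AUC score and no override; resolve it explicitly",
              cas, chemicals$name[i])
      } else if (chemicals$auc[i] > auc_cutoff) {
        status[i] <- "active_eedc"
      } else {
        status[i] <- "excluded_low_auc"
      }
    }
  }
  data.frame(cas = chemicals$cas,
             status = factor(status, levels = STATUS_LEVELS),
             stringsAsFactors = FALSE)
}

#' Aggregate a chemical's assay potencies into an ACC5
#'
#' The per-chemical potency is the q-th percentile (default 5th) of the
#' log10 micromolar ACC values across the chemical's \emph{active} assays,
#' interpolated linearly between order statistics, then converted to a mass
#' concentration: 1 uM of a chemical with molecular weight MW g/mol is
#' MW ug/L, so \code{acc5_ug_per_L = 10^acc5_log10_uM * MW}.
#'
#' @param acc_log10_uM Numeric vector of log10 uM ACC values from active
#'   assay rows (length >= 1, finite).
#' @param molecular_weight Molecular weight in g/mol (> 0).
#' @param percentile_q Percentile as a fraction (default 0.05).
#' @return List with \code{acc5_log10_uM}, \code{acc5_ug_per_L},
#'   \code{n_assays_used}.
#' @export
#' @examples
#' compute_acc5(c(-2, -1, 0, 1, 2), 100)  # acc5_log10_uM = -1.8
compute_acc5 <- function(acc_log10_uM, molecular_weight, percentile_q = 0.05) {
  if (length(acc_log10_uM) == 0L)
    stopf("ACC5 requires at least one active assay result")
  if (any(!is.finite(acc_log10_uM)))
    stopf("ACC values must be finite")
  if (!is.finite(molecular_weight) || molecular_weight <= 0)
    stopf("molecular weight must be a positive number (g/mol)")
  a5 <- percentile_interp(acc_log10_uM, percentile_q)
  list(acc5_log10_uM = a5,
       acc5_ug_per_L = 10^a5 * molecular_weight,
       n_assays_used = length(acc_log10_uM))
}

#' ACC5 table for all active estrogenic chemicals
#'
#' Runs [compute_acc5()] for every chemical classified \code{active_eedc},
#' using its active, flag-filtered assay rows.
#'
#' @param chemicals Validated chemical registry.
#' @param assays Flag-filtered assay table.
#' @param statuses Output of [identify_eedcs()].
#' @param percentile_q Percentile fraction (default 0.05).
#' @param roster Assay roster; rows outside it are ignored.
#' @return Data frame with columns \code{cas}, \code{acc5_log10_uM},
#'   \code{acc5_ug_per_L}, \code{n_assays_used}.
#' @export
acc5_table <- function(chemicals, assays, statuses, percentile_q = 0.05,
                       roster = default_assay_roster()) {
  chemicals <- chemical_registry(chemicals)
  assays <- assay_table(assays)
  if (!is.null(roster))
    assays <- assays[assays$assay_id %in% roster, , drop = FALSE]
  active <- statuses$cas[statuses$status == "active_eedc"]
  rows <- lapply(active, function(cas) {
    acc <- assays$acc_log10_uM[assays$cas == cas & assays$active]
    mw <- chemicals$molecular_weight_g_mol[chemicals$cas == cas]
    if (length(acc) == 0L)
      stopf("chemical %s is classified active but has no active assay rows", cas)
    if (length(mw) != 1L || is.na(mw))
      stopf("chemical %s has assay data but no molecular weight", cas)
    r <- compute_acc5(acc, mw, percentile_q)
    data.frame(cas = cas, acc5_log10_uM = r$acc5_log10_uM,
               acc5_ug_per_L = r$acc5_ug_per_L,
               n_assays_used = r$n_assays_used, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cas = character(), acc5_log10_uM = numeric(),
               acc5_ug_per_L = numeric(), n_assays_used = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
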