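# Synthetic monitoring campaigns with known ground truth.
#
# The generator emulates an opportunistic multi-matrix monitoring compilation:
# censored lognormal concentrations, multiplicative site-level exposure
# effects, a small set of high-potency steroid-like drivers, decoy chemicals
# that are assay-active but fail the pathway-model screen, assay-inactive
# chemicals, and chemicals never tested in the assay roster.

#' Synthetic campaign configuration
#'
#' Defaults emulate the structure of a regional bile-focused monitoring
#' compilation: 18 sites, ~20 samples per site, a bile-dominated matrix mix,
#' a 30-chemical roster with 6 true estrogenic chemicals among decoys,
#' inactives, and untested chemicals.
#'
#' @param n_sites Number of sites (>= 1).
#' @param samples_per_site Samples per site (>= 1).
#' @param matrix_mix Named probability weights over matrices.
#' @param n_chemicals Total chemical roster size.
#' @param n_true_eedcs True estrogenic chemicals (assay-active, AUC > 0.01).
#' @param n_decoys Assay-active chemicals with AUC <= 0.01 (pathway-model
#'   false positives).
#' @param n_untested Chemicals with no rows in the assay roster.
#' @param acc_center_range_log10 Range (log10 uM) for per-chemical potency
#'   centers, drawn log-uniformly.
#' @param acc_assay_sd Between-assay spread of log10 ACC around the center.
#' @param conc_median_log10_range Range (log10 ug/L) for per-chemical median
#'   concentrations on the water-equivalent scale.
#' @param conc_sdlog Lognormal sigma (natural log) of within-chemical
#'   concentration variation.
#' @param site_sdlog Lognormal sigma of multiplicative site exposure effects.
#' @param loq_factor Quantification limit as a multiple of each chemical's
#'   median concentration.
#' @param flag_frac Fraction of assay rows carrying an excluded quality flag.
#' @param female_frac Fraction of bile samples from female fish.
#' @param eef_mode \code{"noisy"} (EEF tracks 1/ACC5 with lognormal noise),
#'   \code{"proportional"} (EEF exactly \code{1/(proportional_k * ACC5)}, so
#'   the EAR/EEQ ratio is exactly \code{proportional_k}), or \code{"none"}.
#' @param proportional_k Target EAR/EEQ ratio for the EEF scale (default 27).
#' @param eef_noise_sdlog Lognormal sigma of EEF noise in \code{"noisy"} mode.
#' @param driver_spec Optional list of \code{list(cas = , median_ear = )}
#'   entries forcing a chemical's median concentration to a target median
#'   EAR (dominant-driver scenarios).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return List of class \code{"campaign_config"}.
#' @export
campaign_config <- function(n_sites = 18L,
                            samples_per_site = 20L,
                            matrix_mix = c(bile = 0.6, marine_water = 0.2,
                                           fish_tissue = 0.1,
                                           wwtp_effluent = 0.1),
                            n_chemicals = 30L,
                            n_true_eedcs = 6L,
                            n_decoys = 4L,
                            n_untested = 4L,
                            acc_center_range_log10 = c(-3, 1),
                            acc_assay_sd = 0.2,
                            conc_median_log10_range = c(-3, 0),
                            conc_sdlog = 1.0,
                            site_sdlog = 0.5,
                            loq_factor = 0.2,
                            flag_frac = 0.1,
                            female_frac = 0.1,
                            eef_mode = c("noisy", "proportional", "none"),
                            proportional_k = 27,
                            eef_noise_sdlog = 0.3,
                            driver_spec = NULL,
                            seed = 1L) {
  eef_mode <- match.arg(eef_mode)
  if (n_sites < 1L || samples_per_site < 1L || n_chemicals < 1L)
    stopf("all counts must be >= 1")
  if (n_true_eedcs + n_decoys + n_untested > n_chemicals)
    stopf("chemical role counts exceed n_chemicals")
  if (conc_sdlog < 0 || site_sdlog < 0 || acc_assay_sd < 0 ||
      eef_noise_sdlog < 0)
    stopf("sigmas must be >= 0")
  if (is.null(names(matrix_mix)) ||
      !all(names(matrix_mix) %in% MATRIX_LEVELS) || any(matrix_mix < 0) ||
      sum(matrix_mix) <= 0)
    stopf("matrix_mix must be non-negative weights named by matrix")
  if (loq_factor < 0) stopf("loq_factor must be >= 0")
  if (flag_frac < 0 || flag_frac > 1 || female_frac < 0 || female_frac > 1)
    stopf("fractions must lie in [0, 1]")
  if (length(seed) != 1L || is.na(seed)) stopf("an explicit seed is required")
  structure(as.list(environment()), class = "campaign_config")
}

# Independent sort-and-interpolate percentile used for the generator's own
# ground-truth arithmetic (kept separate from percentile_interp on purpose).
truth_percentile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  if (n == 1L) return(s)
  h <- q * (n - 1)
  lo <- floor(h)
  s[lo + 1L] + (h - lo) * (s[min(lo + 2L, n)] - s[lo + 1L])
}

#' Generate a synthetic monitoring campaign
#'
#' Deterministic given the configured seed. Emits the three tables the
#' pipeline consumes (chemical registry, assay table, long-format sample
#' table) plus a ground-truth ledger computed by the generator's own
#' arithmetic, for parameter-recovery checks.
#'
#' Concentrations below a chemical's quantification limit are flagged
#' non-detect with the value withheld and the LOQ recorded.
#'
#' @param cfg A [campaign_config()].
#' @return List of class \code{"ear_campaign"}: \code{chemicals},
#'   \code{assays}, \code{samples}, \code{truth}. \code{truth} carries
#'   per-chemical true status / ACC5 / EEF, per-sample true \code{ear_mix},
#'   per-site exposure multipliers, and the intended driver list.
#' @export
generate_campaign <- function(cfg = campaign_config()) {
  stopifnot(inherits(cfg, "campaign_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(as.integer(cfg$seed))
  roster <- default_assay_roster()

  # --- chemical roster ------------------------------------------------------
  n <- cfg$n_chemicals
  cas <- sprintf("SYN-%03d", seq_len(n))
  kind <- rep("inactive", n)
  kind[seq_len(cfg$n_true_eedcs)] <- "true_eedc"
  if (cfg$n_decoys > 0L)
    kind[cfg$n_true_eedcs + seq_len(cfg$n_decoys)] <- "decoy"
  if (cfg$n_untested > 0L)
    kind[cfg$n_true_eedcs + cfg$n_decoys + seq_len(cfg$n_untested)] <- "untested"
  chem_class <- ifelse(kind == "true_eedc", "Hormones", "Industrial")
  mw <- round(stats::runif(n, 150, 450), 2)
  auc <- rep(NA_real_, n)
  auc[kind == "true_eedc"] <- round(stats::runif(cfg$n_true_eedcs, 0.1, 1), 3)
  auc[kind == "decoy"] <- round(stats::runif(cfg$n_decoys, 0.001, 0.01), 4)
  auc[kind == "inactive"] <- round(stats::runif(sum(kind == "inactive"),
                                                0, 0.5), 3)
  bcf <- round(10^stats::runif(n, 1, 4), 1)
  chemicals <- data.frame(cas = cas, name = paste0("synthetic-", cas),
                          chem_class = chem_class,
                          molecular_weight_g_mol = mw, auc = auc,
                          eef = NA_real_, bcf_l_per_kg = bcf,
                          override = NA_character_, stringsAsFactors = FALSE)

  # --- assay table ----------------------------------------------------------
  tested <- which(kind != "untested")
  centers <- stats::runif(n, cfg$acc_center_range_log10[1L],
                          cfg$acc_center_range_log10[2L])
  # steroid-like true chemicals sit at the potent end of the range
  centers[kind == "true_eedc"] <-
    stats::runif(cfg$n_true_eedcs, cfg$acc_center_range_log10[1L],
                 mean(cfg$acc_center_range_log10))
  assay_rows <- lapply(tested, function(i) {
    k <- sample(3:length(roster), 1L)
    ids <- sample(roster, k)
    act <- kind[i] %in% c("true_eedc", "decoy")
    acc <- if (act) centers[i] + stats::rnorm(k, 0, cfg$acc_assay_sd)
           else rep(NA_real_, k)
    flags <- ifelse(stats::runif(k) < cfg$flag_frac, "Borderline", "")
    data.frame(cas = cas[i], assay_id = ids, acc_log10_uM = acc,
               active = act, flags = flags, stringsAsFactors = FALSE)
  })
  assays <- do.call(rbind, assay_rows)
  rownames(assays) <- NULL
  # guarantee every assay-active chemical keeps >= 1 unflagged active row
  for (i in which(kind %in% c("true_eedc", "decoy"))) {
    rows <- which(assays$cas == cas[i] & assays$active)
    if (all(assays$flags[rows] != "")) assays$flags[rows[1L]] <- ""
  }

  # --- ground-truth potency and status (generator's own arithmetic) ---------
  true_status <- character(n)
  true_acc5_ug_L <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    unflagged <- assays[assays$cas == cas[i] & assays$flags == "", ,
                        drop = FALSE]
    rows <- unflagged[unflagged$active, , drop = FALSE]
    if (kind[i] == "untested" || nrow(unflagged) == 0L) {
      true_status[i] <- "insufficient_information"
    } else if (nrow(rows) == 0L) {
      true_status[i] <- "inactive"
    } else if (auc[i] <= 0.01) {
      true_status[i] <- "excluded_low_auc"
    } else {
      true_status[i] <- "active_eedc"
    }
    if (nrow(rows) > 0L)
      true_acc5_ug_L[i] <- 10^truth_percentile(rows$acc_log10_uM, 0.05) * mw[i]
  }

  # --- EEFs -----------------------------------------------------------------
  if (cfg$eef_mode != "none") {
    act <- which(true_status == "active_eedc")
    base <- 1 / (cfg$proportional_k * true_acc5_ug_L[act])
    if (cfg$eef_mode == "noisy")
      base <- base * exp(stats::rnorm(length(act), 0, cfg$eef_noise_sdlog))
    chemicals$eef[act] <- base
  }

  # --- concentration model --------------------------------------------------
  med_we <- 10^stats::runif(n, cfg$conc_median_log10_range[1L],
                            cfg$conc_median_log10_range[2L])
  intended_drivers <- character(0)
  if (!is.null(cfg$driver_spec)) {
    for (d in cfg$driver_spec) {
      i <- match(d$cas, cas)
      if (is.na(i)) stopf("driver_spec names unknown chemical %s", d$cas)
      if (is.na(true_acc5_ug_L[i]))
        stopf("driver_spec chemical %s has no assay potency", d$cas)
      med_we[i] <- d$median_ear * true_acc5_ug_L[i]
      intended_drivers <- c(intended_drivers, d$cas)
    }
  }

  sites <- sprintf("site_%02d", seq_len(cfg$n_sites))
  site_mult <- stats::setNames(
    exp(stats::rnorm(cfg$n_sites, 0, cfg$site_sdlog)), sites)
  mm <- cfg$matrix_mix / sum(cfg$matrix_mix)

  n_samples <- cfg$n_sites * cfg$samples_per_site
  samp_site <- rep(sites, each = cfg$samples_per_site)
  samp_id <- sprintf("%s_s%03d", samp_site,
                     rep(seq_len(cfg$samples_per_site), cfg$n_sites))
  samp_matrix <- sample(names(mm), n_samples, replace = TRUE, prob = mm)
  samp_sex <- ifelse(samp_matrix == "bile",
                     ifelse(stats::runif(n_samples) < cfg$female_frac,
                            "female", "male"),
                     "unknown")
  samp_year <- sample(2011:2019, n_samples, replace = TRUE)

  meas <- vector("list", n_samples)
  true_ear_mix <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    conc_we <- med_we * exp(stats::rnorm(n, 0, cfg$conc_sdlog)) *
      site_mult[[samp_site[s]]]
    m <- samp_matrix[s]
    native <- switch(m,
                     marine_water = conc_we * 1000,
                     wwtp_effluent = conc_we * 1000,
                     bile = conc_we,
                     mussel_tissue = conc_we * bcf,
                     fish_tissue = conc_we * bcf)
    loq_we <- cfg$loq_factor * med_we
    loq_native <- switch(m,
                         marine_water = loq_we * 1000,
                         wwtp_effluent = loq_we * 1000,
                         bile = loq_we,
                         mussel_tissue = loq_we * bcf,
                         fish_tissue = loq_we * bcf)
    det <- native >= loq_native
    meas[[s]] <- data.frame(sample_id = samp_id[s], site_id = samp_site[s],
                            matrix = m, species = "synthetic-fish",
                            sex = samp_sex[s], year = samp_year[s],
                            cas = cas,
                            value = ifelse(det, native, NA_real_),
                            unit = MATRIX_UNIT[[m]],
                            detected = det, loq = loq_native,
                            stringsAsFactors = FALSE)
    eligible <- det & true_status == "active_eedc"
    true_ear_mix[s] <- sum(conc_we[eligible] / true_acc5_ug_L[eligible])
  }
  samples <- do.call(rbind, meas)
  rownames(samples) <- NULL

  truth <- list(
    chemicals = data.frame(cas = cas, kind = kind, true_status = true_status,
                           true_acc5_ug_per_L = true_acc5_ug_L,
                           eef = chemicals$eef,
                           median_conc_we = med_we, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = samp_id, site_id = samp_site,
                         matrix = samp_matrix, sex = samp_sex,
                         true_ear_mix = true_ear_mix,
                         stringsAsFactors = FALSE),
    site_multipliers = site_mult,
    intended_drivers = intended_drivers,
    config = cfg)

  structure(list(chemicals = chemical_registry(chemicals),
                 assays = assay_table(assays),
                 samples = sample_table(samples),
                 truth = truth),
            class = "ear_campaign")
}

#' Compare pipeline output with the generator's ground truth
#'
#' @param result An \code{"ear_screen"} object fitted on the campaign's
#'   tables.
#' @param truth The \code{truth} element of an \code{"ear_campaign"}.
#' @return List with \code{status_confusion} (contingency table of true vs
#'   estimated status), \code{acc5_relative_error} (per-chemical relative
#'   error of the estimated ACC5 in ug/L), and \code{driver_recovery}
#'   (final category and driver-role rate per intended driver, NULL when the
#'   campaign has no forced drivers).
#' @export
recover_parameters <- function(result, truth) {
  stopifnot(inherits(result, "ear_screen"))
  est <- result$statuses
  tr <- truth$chemicals
  m <- merge(tr, est, by = "cas")
  confusion <- table(true = m$true_status, estimated = as.character(m$status))

  a <- merge(tr[!is.na(tr$true_acc5_ug_per_L) &
                  tr$true_status == "active_eedc", ],
             result$acc5, by = "cas")
  rel_err <- stats::setNames(
    abs(a$acc5_ug_per_L - a$true_acc5_ug_per_L) / a$true_acc5_ug_per_L,
    a$cas)

  driver_recovery <- NULL
  if (length(truth$intended_drivers) > 0L) {
    driver_recovery <- lapply(truth$intended_drivers, function(cas) {
      cat_ <- result$priorities$priorities$category[
        result$priorities$priorities$cas == cas]
      high_ids <- result$sample_activity$sample_id[
        result$sample_activity$activity == "high"]
      rl <- result$roles[result$roles$sample_id %in% high_ids &
                           result$roles$cas == cas, , drop = FALSE]
      list(cas = cas,
           final_category = if (length(cat_)) as.character(cat_) else NA,
           n_high_samples = length(high_ids),
           driver_rate_in_high = if (length(high_ids))
             sum(rl$role == "driver") / length(high_ids) else NA_real_)
    })
  }
  list(status_confusion = confusion,
       acc5_relative_error = rel_err,
       driver_recovery = driver_recovery)
}
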