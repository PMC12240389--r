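# Table readers/writers and schema validation.
#
# All tables are long-format CSV. Long format was chosen over wide because
# analyte panels differ between monitoring studies: a chemical simply has no
# row in a sample where it was not analyzed.

#' Validate and normalize a chemical registry table
#'
#' The registry carries one row per chemical: identity, molecular weight,
#' the estrogen-receptor pathway AUC score, an optional estradiol equivalency
#' factor (EEF), an optional tissue-water bioconcentration factor (BCF), and
#' an optional manual override of the AUC-based estrogenicity call.
#'
#' @param df Data frame with columns \code{cas}, \code{name}, \code{chem_class},
#'   \code{molecular_weight_g_mol}, and optionally \code{auc}, \code{eef},
#'   \code{bcf_l_per_kg}, \code{override} (\code{"force_active"},
#'   \code{"force_inactive"} or empty/NA).
#' @return The validated data frame (optional columns filled with NA).
#' @export
chemical_registry <- function(df) {
  df <- as.data.frame(df)
  assert_columns(df, c("cas", "name", "chem_class", "molecular_weight_g_mol"),
                 "chemical table")
  for (opt in c("auc", "eef", "bcf_l_per_kg"))
    if (is.null(df[[opt]])) df[[opt]] <- NA_real_
  if (is.null(df$override)) df$override <- NA_character_
  df$cas <- as.character(df$cas)
  df$override <- as.character(df$override)
  df$override[!is.na(df$override) & df$override == ""] <- NA_character_
  if (anyDuplicated(df$cas))
    stopf("duplicate CAS in chemical table: %s",
          paste(unique(df$cas[duplicated(df$cas)]), collapse = ", "))
  bad <- !is.na(df$override) &
    !df$override %in% c("force_active", "force_inactive")
  if (any(bad))
    stopf("invalid override value(s): %s",
          paste(unique(df$override[bad]), collapse = ", "))
  mw <- df$molecular_weight_g_mol
  if (any(!is.na(mw) & mw <= 0))
    stopf("molecular_weight_g_mol must be > 0")
  if (any(!is.na(df$eef) & df$eef < 0)) stopf("eef must be >= 0")
  df
}

#' Validate an assay bioactivity table
#'
#' One row per (chemical, assay): the log10 micromolar activity concentration
#' at cutoff (ACC), an active flag, and semicolon-delimited data-quality flags.
#'
#' @param df Data frame with columns \code{cas}, \code{assay_id},
#'   \code{acc_log10_uM}, \code{active} (0/1 or logical), optional
#'   \code{flags}.
#' @param roster Character vector of permitted assay ids; \code{NULL} to skip
#'   the roster check.
#' @return Validated data frame with \code{active} as logical and
#'   \code{flags} as character (empty string when none).
#' @export
assay_table <- function(df, roster = NULL) {
  df <- as.data.frame(df)
  assert_columns(df, c("cas", "assay_id", "acc_log10_uM", "active"),
                 "assay table")
  df$cas <- as.character(df$cas)
  df$assay_id <- as.character(df$assay_id)
  df$active <- as.logical(df$active)
  if (is.null(df$flags)) df$flags <- ""
  df$flags <- ifelse(is.na(df$flags), "", as.character(df$flags))
  if (!is.null(roster)) {
    bad <- setdiff(unique(df$assay_id), roster)
    if (length(bad) > 0L)
      stopf("assay_id not in roster: %s", paste(bad, collapse = ", "))
  }
  bad <- df$active & !is.finite(df$acc_log10_uM)
  if (any(bad))
    stopf("active assay rows must carry a finite acc_log10_uM (cas %s)",
          paste(unique(df$cas[bad]), collapse = ", "))
  df
}

#' Validate a monitoring sample table
#'
#' Long format: one row per (sample, chemical) observation. The matrix fixes
#' the permissible unit (water/effluent ng/L, tissues ng/g, bile ng/mL).
#'
#' @param df Data frame with columns \code{sample_id}, \code{site_id},
#'   \code{matrix}, \code{cas}, \code{value}, \code{unit}, \code{detected},
#'   optional \code{species}, \code{sex}, \code{year}, \code{loq}.
#' @return Validated data frame.
#' @export
sample_table <- function(df) {
  df <- as.data.frame(df)
  assert_columns(df, c("sample_id", "site_id", "matrix", "cas", "value",
                       "unit", "detected"), "sample table")
  df$sample_id <- as.character(df$sample_id)
  df$site_id <- as.character(df$site_id)
  df$cas <- as.character(df$cas)
  df$detected <- as.logical(df$detected)
  if (is.null(df$species)) df$species <- NA_character_
  if (is.null(df$sex)) df$sex <- NA_character_
  if (is.null(df$year)) df$year <- NA_integer_
  if (is.null(df$loq)) df$loq <- NA_real_
  bad <- setdiff(unique(df$matrix), MATRIX_LEVELS)
  if (length(bad) > 0L)
    stopf("unknown matrix value(s): %s", paste(bad, collapse = ", "))
  want <- MATRIX_UNIT[df$matrix]
  bad <- which(df$unit != want)
  if (length(bad) > 0L) {
    i <- bad[1L]
    stopf("unit '%s' not permitted in matrix '%s' (row %d, sample %s, cas %s); expected '%s'",
          df$unit[i], df$matrix[i], i, df$sample_id[i], df$cas[i], want[i])
  }
  key <- paste(df$sample_id, df$cas, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    pair <- strsplit(d, "\r", fixed = TRUE)[[1L]]
    stopf("duplicated (sample_id, cas) pair: (%s, %s)", pair[1L], pair[2L])
  }
  if (any(df$detected & (is.na(df$value) | df$value < 0)))
    stopf("detected measurements must carry a non-negative value")
  # One sample id must not span sites or matrices.
  for (col in c("site_id", "matrix")) {
    n <- tapply(df[[col]], df$sample_id, function(v) length(unique(v)))
    if (any(n > 1L))
      stopf("sample_id %s maps to multiple %s values",
            names(n)[which(n > 1L)[1L]], col)
  }
  df
}

#' @rdname chemical_registry
#' @param path Path to a CSV file.
#' @export
read_chemical_table <- function(path) {
  chemical_registry(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname assay_table
#' @param path Path to a CSV file.
#' @export
read_assay_table <- function(path, roster = NULL) {
  assay_table(utils::read.csv(path, stringsAsFactors = FALSE), roster = roster)
}

#' @rdname sample_table
#' @param path Path to a CSV file.
#' @export
read_sample_table <- function(path) {
  sample_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a table to CSV
#'
#' Plain CSV without row names; the exact inverse of the \code{read_*_table}
#' readers, so write-then-read round-trips are lossless.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-matrix detection frequency summary
#'
#' For every (chemical, matrix) pair where the chemical was analyzed, reports
#' the number of samples analyzed, the number with detections, the detection
#' frequency in percent, and the min-max of detected concentrations in the
#' matrix's native unit. Matrices where a chemical was never analyzed get no
#' row (the "-" convention of monitoring summary tables).
#'
#' @param samples Validated sample table.
#' @return Data frame with columns \code{cas}, \code{matrix},
#'   \code{n_analyzed}, \code{n_detected}, \code{df_pct}, \code{min_detected},
#'   \code{max_detected}, \code{unit}.
#' @export
detection_frequency <- function(samples) {
  samples <- sample_table(samples)
  if (nrow(samples) == 0L)
    return(data.frame(cas = character(), matrix = character(),
                      n_analyzed = integer(), n_detected = integer(),
                      df_pct = numeric(), min_detected = numeric(),
                      max_detected = numeric(), unit = character(),
                      stringsAsFactors = FALSE))
  split_key <- interaction(samples$cas, samples$matrix, drop = TRUE)
  rows <- lapply(split(samples, split_key), function(g) {
    det <- g$value[g$detected]
    data.frame(cas = g$cas[1L], matrix = g$matrix[1L],
               n_analyzed = nrow(g), n_detected = sum(g$detected),
               df_pct = 100 * sum(g$detected) / nrow(g),
               min_detected = if (length(det)) min(det) else NA_real_,
               max_detected = if (length(det)) max(det) else NA_real_,
               unit = g$unit[1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cas, out$matrix), , drop = FALSE]
}

#' Read a screening run configuration from a YAML file
#'
#' Keys mirror the arguments of [screen_config()]; a `benchmarks` section
#' mirrors [benchmark_config()]. Absent keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `screen_config` object.
#' @export
read_screen_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("reading config files requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  bm <- do.call(benchmark_config, raw$benchmarks %||% list())
  raw$benchmarks <- NULL
  do.call(screen_config, c(raw, list(benchmarks = bm)))
}
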