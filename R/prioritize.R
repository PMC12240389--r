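# Chemical prioritization: the per-sample decision tree assigning
# driver / major / minor contributor roles, and cross-sample resolution into
# final priority categories.

#' Assign chemical roles within one medium- or high-activity sample
#'
#' Walks the prioritization decision tree for each chemical contributing to
#' the sample's mixture EAR, with tests applied in order (driver first, then
#' the 1\% contribution test, then the NOEC test):
#' \describe{
#'   \item{high-activity sample (governing LOEC L, NOEC N)}{EAR >= L:
#'     driver, high priority; else \% contribution >= 1: major contributor,
#'     high priority; else EAR >= N: minor contributor, watch list; else
#'     minor contributor, low priority.}
#'   \item{medium-activity sample}{EAR >= N: driver, watch list; else \% >=
#'     1: major contributor, watch list; else minor contributor, low
#'     priority.}
#' }
#' "Exceed" is inclusive at the threshold. Roles are only defined for
#' samples of at least medium activity; a low-activity sample is an error.
#'
#' @param activity One of \code{"medium"}, \code{"high"}.
#' @param ear_rows Data frame for the sample's chemicals: \code{cas},
#'   \code{ear_acc5}, \code{pct_contribution}.
#' @param noec,loec The governing thresholds actually applied to the sample
#'   (as returned by [classify_sample()]).
#' @return \code{ear_rows} with \code{role} (factor) and
#'   \code{provisional_category} (ordered factor) appended.
#' @export
assign_roles <- function(activity, ear_rows, noec, loec) {
  activity <- as.character(activity)
  if (!activity %in% c("medium", "high"))
    stopf("roles are only assigned in medium- or high-activity samples (got '%s')",
          activity)
  assert_columns(ear_rows, c("cas", "ear_acc5", "pct_contribution"),
                 "per-chemical EAR rows")
  ear <- ear_rows$ear_acc5
  pct <- ear_rows$pct_contribution
  if (activity == "high") {
    role <- ifelse(ear >= loec, "driver",
            ifelse(pct >= 1, "major_contributor", "minor_contributor"))
    cat_ <- ifelse(ear >= loec | pct >= 1, "high_priority",
            ifelse(ear >= noec, "watch_list", "low_priority"))
  } else {
    role <- ifelse(ear >= noec, "driver",
            ifelse(pct >= 1, "major_contributor", "minor_contributor"))
    cat_ <- ifelse(ear >= noec | pct >= 1, "watch_list", "low_priority")
  }
  ear_rows$role <- factor(role, levels = ROLE_LEVELS)
  ear_rows$provisional_category <- factor(cat_, levels = PRIORITY_LEVELS,
                                          ordered = TRUE)
  ear_rows
}

#' Chemical roles across all medium/high samples
#'
#' Applies [assign_roles()] to every sample of at least medium activity.
#'
#' @param sample_activity Output of [sample_activity_table()].
#' @param ear An \code{"ear_table"}.
#' @return Data frame with \code{sample_id}, \code{cas}, \code{ear_acc5},
#'   \code{pct_contribution}, \code{activity}, \code{role},
#'   \code{provisional_category} (zero rows if no sample qualifies).
#' @export
chemical_roles <- function(sample_activity, ear) {
  el <- sample_activity[sample_activity$activity >= "medium", , drop = FALSE]
  rows <- lapply(seq_len(nrow(el)), function(i) {
    rws <- ear$by_chemical[ear$by_chemical$sample_id == el$sample_id[i], ,
                           drop = FALSE]
    if (nrow(rws) == 0L) return(NULL)
    r <- assign_roles(el$activity[i],
                      rws[, c("cas", "ear_acc5", "pct_contribution")],
                      noec = el$noec[i], loec = el$loec[i])
    cbind(sample_id = el$sample_id[i], r,
          activity = el$activity[i], stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), cas = character(),
               ear_acc5 = numeric(), pct_contribution = numeric(),
               role = factor(character(), levels = ROLE_LEVELS),
               provisional_category = factor(character(),
                                             levels = PRIORITY_LEVELS,
                                             ordered = TRUE),
               activity = factor(character(), levels = ACTIVITY_LEVELS,
                                 ordered = TRUE),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Resolve per-sample assignments into final priority categories
#'
#' A chemical's final category is the maximum of its provisional categories
#' across samples (conflicting assignments resolve upward). Detected active
#' estrogenic chemicals that never reach a medium/high sample are low
#' priority; detected chemicals never tested in the assay roster carry
#' insufficient information. Chemicals analyzed but never detected are not
#' categorized here (see the \code{not_detected} element).
#'
#' @param roles Output of [chemical_roles()].
#' @param statuses Status table from [identify_eedcs()].
#' @param samples Validated sample table (supplies detection presence).
#' @return List with \code{priorities} (data frame \code{cas},
#'   \code{category}, \code{roles_seen}, \code{n_supporting_samples}) and
#'   \code{not_detected} (character vector of analyzed-only chemicals).
#' @export
resolve_categories <- function(roles, statuses, samples) {
  samples <- sample_table(samples)
  detected_cas <- unique(samples$cas[samples$detected])
  analyzed_cas <- unique(samples$cas)
  rows <- lapply(detected_cas, function(cas) {
    st <- statuses$status[statuses$cas == cas]
    rl <- roles[roles$cas == cas, , drop = FALSE]
    if (length(st) == 1L && st == "insufficient_information") {
      cat_ <- "insufficient_information"
    } else if (length(st) == 1L && st == "active_eedc") {
      cat_ <- if (nrow(rl) > 0L)
        as.character(max(rl$provisional_category)) else "low_priority"
    } else {
      return(NULL)  # inactive / excluded chemicals are not prioritized
    }
    data.frame(cas = cas,
               category = cat_,
               roles_seen = paste(sort(unique(as.character(rl$role))),
                                  collapse = ";"),
               n_supporting_samples = length(unique(rl$sample_id)),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  priorities <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cas = character(), category = character(),
               roles_seen = character(), n_supporting_samples = integer(),
               stringsAsFactors = FALSE)
  priorities$category <- factor(priorities$category,
                                levels = PRIORITY_LEVELS, ordered = TRUE)
  priorities <- priorities[order(priorities$category,
                                 decreasing = TRUE), , drop = FALSE]
  rownames(priorities) <- NULL
  list(priorities = priorities,
       not_detected = setdiff(analyzed_cas, detected_cas))
}

#' Single-chemical exceedance and driver-count summaries
#'
#' Reports, over samples above the governing NOEC threshold and above the
#' governing LOEC threshold, the fraction whose exceedance is attributable
#' to a single chemical alone (some chemical's individual EAR at or above
#' that threshold), and the distribution of driver counts among
#' high-activity samples.
#'
#' @param sample_activity Output of [sample_activity_table()].
#' @param ear An \code{"ear_table"}.
#' @return List with \code{frac_single_above_noec},
#'   \code{frac_single_above_loec}, \code{n_above_noec},
#'   \code{n_above_loec}, and \code{driver_counts} (table of drivers per
#'   high sample).
#' @export
driver_fraction <- function(sample_activity, ear) {
  bc <- ear$by_chemical
  max_ear <- vapply(sample_activity$sample_id, function(id) {
    v <- bc$ear_acc5[bc$sample_id == id]
    if (length(v)) max(v) else 0
  }, numeric(1L))
  above_noec <- sample_activity$ear_mix >= sample_activity$noec
  above_loec <- sample_activity$ear_mix >= sample_activity$loec
  frac <- function(above, thr) {
    if (!any(above)) return(NA_real_)
    mean(max_ear[above] >= thr[above])
  }
  high <- which(above_loec)
  driver_counts <- vapply(sample_activity$sample_id[high], function(id) {
    i <- match(id, sample_activity$sample_id)
    sum(bc$ear_acc5[bc$sample_id == id] >= sample_activity$loec[i])
  }, integer(1L))
  list(frac_single_above_noec = frac(above_noec, sample_activity$noec),
       frac_single_above_loec = frac(above_loec, sample_activity$loec),
       n_above_noec = sum(above_noec),
       n_above_loec = sum(above_loec),
       driver_counts = table(driver_counts))
}
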