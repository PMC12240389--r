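# The chemical prioritization decision tree and cross-sample resolution.

test_that("roles in a high bile sample follow the decision tree", {
  ts <- default_ts()  # governing bile thresholds 540 / 2700
  rows <- data.frame(cas = c("A", "B", "C", "D"),
                     ear_acc5 = c(2800, 150, 30, 20),
                     pct_contribution = 100 * c(2800, 150, 30, 20) / 3000,
                     stringsAsFactors = FALSE)
  out <- assign_roles("high", rows, noec = ts$noec_bear_low,
                      loec = ts$loec_bear_low)
  expect_equal(as.character(out$role),
               c("driver", "major_contributor", "major_contributor",
                 "minor_contributor"))
  expect_equal(as.character(out$provisional_category),
               c("high_priority", "high_priority", "high_priority",
                 "low_priority"))

  # above NOEC but under 1%: the watch-list minor-contributor branch
  wl <- assign_roles("high",
                     data.frame(cas = "E", ear_acc5 = 550,
                                pct_contribution = 100 * 550 / 60000),
                     noec = 540, loec = 2700)
  expect_equal(as.character(wl$role), "minor_contributor")
  expect_equal(as.character(wl$provisional_category), "watch_list")
})

test_that("roles in a medium sample use the NOEC as the driver bar", {
  med <- assign_roles("medium",
                      data.frame(cas = c("A", "B", "C"),
                                 ear_acc5 = c(600, 350, 5),
                                 pct_contribution = c(60, 35, 0.5)),
                      noec = 540, loec = 2700)
  expect_equal(as.character(med$role),
               c("driver", "major_contributor", "minor_contributor"))
  expect_equal(as.character(med$provisional_category),
               c("watch_list", "watch_list", "low_priority"))
  expect_error(assign_roles("low", med[, 1:3], 540, 2700), "low")
})

test_that("roles partition chemicals and a lone chemical is a 100% driver", {
  ts <- default_ts()
  out <- assign_roles("high",
                      data.frame(cas = "solo", ear_acc5 = 3000,
                                 pct_contribution = 100),
                      noec = ts$noec_bear_low, loec = ts$loec_bear_low)
  expect_equal(as.character(out$role), "driver")
  expect_equal(out$pct_contribution, 100)
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    ear <- 10^stats::runif(n, 0, 4)
    rows <- data.frame(cas = paste0("c", 1:n), ear_acc5 = ear,
                       pct_contribution = 100 * ear / sum(ear))
    out <- assign_roles(sample(c("medium", "high"), 1), rows, 540, 2700)
    expect_false(any(is.na(out$role)))  # every chemical gets exactly one role
  }
})

test_that("conflicting per-sample categories resolve upward, others by status", {
  roles <- data.frame(
    sample_id = c("s1", "s2"), cas = "bpa",
    ear_acc5 = c(600, 100), pct_contribution = c(60, 5),
    role = factor(c("driver", "major_contributor"),
                  levels = c("minor_contributor", "major_contributor",
                             "driver")),
    provisional_category = factor(c("watch_list", "high_priority"),
                                  levels = c("insufficient_information",
                                             "low_priority", "watch_list",
                                             "high_priority"),
                                  ordered = TRUE),
    stringsAsFactors = FALSE)
  statuses <- make_statuses(c("bpa", "quiet", "unknown"),
                            c("active_eedc", "active_eedc",
                              "insufficient_information"))
  samples <- make_samples(paste0("s", 1:3), c("bpa", "quiet", "unknown"),
                          value = c(1, 1, 1))
  out <- resolve_categories(roles, statuses, samples)
  got <- setNames(as.character(out$priorities$category), out$priorities$cas)
  expect_equal(got[["bpa"]], "high_priority")      # max over samples
  expect_equal(got[["quiet"]], "low_priority")     # never in a medium/high sample
  expect_equal(got[["unknown"]], "insufficient_information")

  # resolution is order-independent and idempotent over samples
  out2 <- resolve_categories(roles[2:1, ], statuses, samples)
  expect_equal(out2$priorities[order(out2$priorities$cas), ],
               out$priorities[order(out$priorities$cas), ],
               ignore_attr = TRUE)

  # analyzed-but-never-detected chemicals land in the not-detected report
  samples2 <- rbind(samples,
                    make_samples("s4", "ghost", NA_real_, detected = FALSE,
                                 loq = 1))
  out3 <- resolve_categories(roles, statuses, samples2)
  expect_equal(out3$not_detected, "ghost")
  expect_false("ghost" %in% out3$priorities$cas)
})

test_that("raising a chemical's concentration never demotes its category", {
  cas <- c("target", "other")
  chems <- make_chemicals(cas)
  acc5 <- make_acc5(cas, c(1, 1))
  st <- make_statuses(cas)
  ts <- default_ts()
  rank_of <- function(value, other) {
    s <- make_samples("s1", cas, value = c(value, other))
    ear <- compute_ear_table(s, chems, acc5, st)
    act <- sample_activity_table(ear$by_sample, ts)
    roles <- chemical_roles(act, ear)
    pri <- resolve_categories(roles, st, s)$priorities
    r <- roles[roles$cas == "target", ]
    c(role = if (nrow(r)) as.integer(r$role) else 0L,
      category = as.integer(pri$category[pri$cas == "target"]))
  }
  # sweep crossing low -> medium -> high activity: the final category is
  # monotone even where the governing driver bar jumps from NOEC to LOEC
  # at the medium/high transition
  values <- c(1, 200, 600, 2500, 5000, 50000)
  ranks <- t(vapply(values, rank_of, c(role = 0L, category = 0L),
                    other = 400))
  expect_true(all(diff(ranks[, "category"]) >= 0))
  # within a fixed activity class the role is monotone too
  high_ranks <- t(vapply(c(1, 100, 600, 2800, 10000), rank_of,
                         c(role = 0L, category = 0L), other = 5000))
  expect_true(all(diff(high_ranks[, "role"]) >= 0))
  expect_true(all(diff(high_ranks[, "category"]) >= 0))
})

test_that("single-chemical exceedance fractions hit both extremes", {
  cas <- c("big", "small")
  chems <- make_chemicals(cas)
  acc5 <- make_acc5(cas, c(1, 1))
  st <- make_statuses(cas)
  ts <- default_ts()
  run <- function(values) {
    s <- do.call(rbind, lapply(seq_along(values), function(i)
      make_samples(paste0("s", i), cas, value = values[[i]])))
    ear <- compute_ear_table(s, chems, acc5, st)
    act <- sample_activity_table(ear$by_sample, ts)
    driver_fraction(act, ear)
  }
  # every high sample carried by one chemical alone
  d1 <- run(list(c(2800, 10), c(5000, 100)))
  expect_equal(d1$frac_single_above_loec, 1.0)
  expect_equal(as.integer(names(d1$driver_counts)), 1L)
  # exceedances only as a mixture: no single chemical at the threshold
  d2 <- run(list(c(1500, 1500), c(2000, 1000)))
  expect_equal(d2$frac_single_above_loec, 0.0)
  expect_equal(d2$n_above_loec, 2L)
})
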