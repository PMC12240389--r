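# Quality-flag filtering, estrogenicity status calls, ACC5 aggregation.

test_that("flag filtering removes exactly the flagged rows, preserving order", {
  a <- make_assays(cas = c("c1", "c2", "c3", "c4", "c5"), acc = -1,
                   flags = c("Borderline", "", "Borderline;Other", "Other", ""))
  out <- filter_assay_results(a, excluded_flags = "Borderline")
  expect_equal(out$cas, c("c2", "c4", "c5"))

  # empty flag set retains everything; empty input stays empty
  expect_equal(nrow(filter_assay_results(a, character(0))), 5L)
  expect_equal(nrow(filter_assay_results(a[0, ], "Borderline")), 0L)

  # a record with no flags survives any exclusion list
  b <- make_assays("c1", -1, flags = "")
  expect_equal(nrow(filter_assay_results(b, c("Borderline", "X"))), 1L)
})

test_that("estrogenicity statuses partition the registry by the AUC rule", {
  chems <- make_chemicals(c("e2", "cutoff", "decoy", "silent", "untested"),
                          auc = c(0.94, 0.01, 0.005, 0.3, NA))
  assays <- rbind(make_assays("e2", c(-2, -1), active = TRUE),
                  make_assays("cutoff", -1, active = TRUE),
                  make_assays("decoy", 0, active = TRUE),
                  make_assays("silent", NA_real_, active = FALSE))
  st <- identify_eedcs(chems, assays)
  got <- setNames(as.character(st$status), st$cas)
  expect_equal(got[["e2"]], "active_eedc")
  expect_equal(got[["cutoff"]], "excluded_low_auc")  # AUC <= cutoff excluded
  expect_equal(got[["decoy"]], "excluded_low_auc")
  expect_equal(got[["silent"]], "inactive")
  expect_equal(got[["untested"]], "insufficient_information")
  # partition: exactly one status per chemical
  expect_equal(sort(st$cas), sort(chems$cas))
  expect_false(any(is.na(st$status)))
})

test_that("manual overrides beat the AUC rule; unresolvable chemicals error", {
  chems <- make_chemicals(c("forced_on", "forced_off", "orphan"),
                          auc = c(0.001, 0.9, NA),
                          override = c("force_active", "force_inactive", NA))
  assays <- rbind(make_assays("forced_on", -1), make_assays("forced_off", -1),
                  make_assays("orphan", -1))
  st <- identify_eedcs(chems[1:2, ], assays)
  expect_equal(as.character(st$status),
               c("active_eedc", "inactive"))
  expect_error(identify_eedcs(chems, assays), "orphan")
})

test_that("ACC5 matches the stated examples and the unit conversion", {
  # single assay: percentile of one value is itself; 1 uM x MW g/mol = MW ug/L
  r <- compute_acc5(0, 272.38)
  expect_equal(r$acc5_ug_per_L, 272.38)

  # five assays: 5th percentile at rank 0.05*(n-1) = -1.8
  r <- compute_acc5(c(-2, -1, 0, 1, 2), 100)
  expect_equal(r$acc5_log10_uM, -1.8)
  expect_equal(r$acc5_ug_per_L, 10^-1.8 * 100)
  expect_equal(r$n_assays_used, 5L)

  # constant vector
  expect_equal(compute_acc5(rep(-1, 4), 100)$acc5_ug_per_L, 10)

  expect_error(compute_acc5(numeric(0), 100))
  expect_error(compute_acc5(-1, 0))
  expect_error(compute_acc5(-1, -5))
})

test_that("percentile agrees with the brute-force oracle for all n <= 8", {
  set.seed(42)
  for (n in 1:8) {
    for (rep in 1:20) {
      x <- round(stats::rnorm(n, 0, 2), 3)
      for (q in c(0.05, 0.5, 0.95)) {
        expect_equal(percentile_interp(x, q), oracle_percentile(x, q),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("ACC5 is permutation-invariant, monotone, and linear in MW", {
  set.seed(7)
  for (rep in 1:25) {
    x <- stats::rnorm(sample(2:10, 1))
    p <- sample(x)
    expect_equal(compute_acc5(x, 100)$acc5_log10_uM,
                 compute_acc5(p, 100)$acc5_log10_uM)
    # raising any one ACC never lowers the aggregate
    i <- sample(length(x), 1)
    y <- x
    y[i] <- y[i] + abs(stats::rnorm(1))
    expect_gte(compute_acc5(y, 100)$acc5_log10_uM,
               compute_acc5(x, 100)$acc5_log10_uM)
    # mass-unit potency scales linearly with molecular weight
    expect_equal(compute_acc5(x, 250)$acc5_ug_per_L,
                 2.5 * compute_acc5(x, 100)$acc5_ug_per_L)
  }
})

test_that("acc5_table aggregates only active assay rows of active chemicals", {
  chems <- make_chemicals(c("a", "b"), mw = c(100, 200), auc = 0.9)
  assays <- rbind(
    make_assays("a", c(-2, -1, 0, 1, 2), active = TRUE),
    make_assays("a", -10, assay_id = "ER_agonist_extra_2", active = FALSE),
    make_assays("b", 0, active = TRUE))
  st <- identify_eedcs(chems, assays)
  t <- acc5_table(chems, assays, st)
  expect_equal(t$acc5_ug_per_L[t$cas == "a"], 10^-1.8 * 100)  # inactive row ignored
  expect_equal(t$acc5_ug_per_L[t$cas == "b"], 200)
  expect_equal(t$n_assays_used, c(5L, 1L))
})
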