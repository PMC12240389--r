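# Estradiol equivalency quotients, the EAR/EEQ translation ratio, and the
# rank-correlation check.

test_that("EEQs multiply concentration by EEF and sum per sample", {
  # identity potency: EEF 1 at 5 ng/mL bile -> eeq_mix 5
  chems <- make_chemicals("e2", eef = 1)
  s <- make_samples("s1", "e2", value = 5)
  eq <- compute_eeq_table(s, chems)
  expect_equal(eq$by_sample$eeq_mix, 5)

  # hand sum: (10 x 0.1) + (2 x 2) = 5
  chems2 <- make_chemicals(c("a", "b"), eef = c(0.1, 2))
  s2 <- make_samples("s1", c("a", "b"), value = c(10, 2))
  expect_equal(compute_eeq_table(s2, chems2)$by_sample$eeq_mix, 5)

  # chemicals lacking an EEF contribute nothing; none detected -> 0
  chems3 <- make_chemicals(c("a", "b"), eef = c(0.1, NA))
  s3 <- make_samples("s1", c("a", "b"), value = c(10, 1000))
  expect_equal(compute_eeq_table(s3, chems3)$by_sample$eeq_mix, 1)
  s4 <- make_samples("s1", "a", value = NA_real_, detected = FALSE, loq = 1)
  expect_equal(compute_eeq_table(s4, chems3)$by_sample$eeq_mix, 0)
})

test_that("the translation ratio is the median of per-sample EAR/EEQ ratios", {
  fake_ear <- function(ids, mix) {
    structure(list(by_chemical = data.frame(sample_id = character(),
                                            cas = character(),
                                            ear_acc5 = numeric(),
                                            pct_contribution = numeric()),
                   by_sample = data.frame(sample_id = ids, site_id = "x",
                                          matrix = "bile", ear_mix = mix,
                                          stringsAsFactors = FALSE)),
              class = "ear_table")
  }
  fake_eeq <- function(ids, mix)
    list(by_sample = data.frame(sample_id = ids, eeq_mix = mix,
                                stringsAsFactors = FALSE))
  ids <- paste0("s", 1:4)

  # all per-sample ratios 27 -> 27
  r <- median_ear_eeq_ratio(fake_ear(ids, 27 * c(1, 2, 3, 4)),
                            fake_eeq(ids, c(1, 2, 3, 4)))
  expect_equal(r$median_ratio, 27)
  expect_equal(r$n, 4L)

  # odd- and even-length medians
  expect_equal(median_ear_eeq_ratio(fake_ear(ids[1:3], c(10, 20, 30)),
                                    fake_eeq(ids[1:3], c(1, 1, 1)))$median_ratio,
               20)
  expect_equal(median_ear_eeq_ratio(fake_ear(ids, c(10, 20, 30, 40)),
                                    fake_eeq(ids, c(1, 1, 1, 1)))$median_ratio,
               25)

  # zero-EEQ samples are excluded; none eligible errors
  r2 <- median_ear_eeq_ratio(fake_ear(ids, c(10, 20, 30, 999)),
                             fake_eeq(ids, c(1, 1, 1, 0)))
  expect_equal(r2$median_ratio, 20)
  expect_error(median_ear_eeq_ratio(fake_ear(ids[1], 5), fake_eeq(ids[1], 0)))
})

test_that("spearman_rho matches a rank-then-Pearson oracle, ties included", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1.0)
  expect_equal(spearman_rho(1:3, c(30, 20, 10)), -1.0)

  x <- c(1, 1, 2, 3)
  y <- c(5, 6, 7, 8)
  expect_equal(spearman_rho(x, y),
               stats::cor(oracle_avg_rank(x), oracle_avg_rank(y)))

  set.seed(3)
  for (rep in 1:10) {
    x <- sample(1:5, 8, replace = TRUE)
    y <- stats::rnorm(8)
    expect_equal(spearman_rho(x, y),
                 stats::cor(oracle_avg_rank(x), oracle_avg_rank(y)))
    # invariance under strictly increasing transforms
    expect_equal(spearman_rho(exp(y), x), spearman_rho(y, x))
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2))
  expect_error(spearman_rho(1:3, 1:4))
})

test_that("proportional potency makes every sample ratio k and rho 1", {
  # if each chemical's EEF is exactly 1/(k * ACC5), then per-chemical
  # eeq = ear/k, so every sample ratio is k and the two mixture scores are
  # perfectly rank-correlated: the closed-form consistency check of the
  # whole calibration path.
  k <- 27
  cas <- paste0("c", 1:4)
  acc5_val <- c(0.5, 2, 10, 80)
  chems <- make_chemicals(cas, eef = 1 / (k * acc5_val))
  acc5 <- make_acc5(cas, acc5_val)
  st <- make_statuses(cas)
  set.seed(9)
  s <- do.call(rbind, lapply(1:6, function(i)
    make_samples(paste0("s", i), cas, value = stats::runif(4, 0.1, 100))))
  ear <- compute_ear_table(s, chems, acc5, st)
  eeq <- compute_eeq_table(s, chems)
  r <- median_ear_eeq_ratio(ear, eeq)
  expect_equal(r$per_sample$ratio, rep(k, 6), tolerance = 1e-12)
  expect_equal(r$median_ratio, k, tolerance = 1e-12)
  expect_equal(spearman_rho(r$per_sample$ear_mix, r$per_sample$eeq_mix), 1.0)
})

test_that("restricting the EAR side to EEF-bearing chemicals changes the ratio", {
  cas <- c("with_eef", "without_eef")
  chems <- make_chemicals(cas, eef = c(1, NA))
  acc5 <- make_acc5(cas, c(1, 1))
  st <- make_statuses(cas)
  s <- make_samples("s1", cas, value = c(10, 30))
  ear <- compute_ear_table(s, chems, acc5, st)
  eeq <- compute_eeq_table(s, chems)
  full <- median_ear_eeq_ratio(ear, eeq)
  restricted <- median_ear_eeq_ratio(ear, eeq,
                                     restrict_to_eef_chemicals = TRUE,
                                     chemicals = chems)
  expect_equal(full$median_ratio, 4)        # (10 + 30) / 10
  expect_equal(restricted$median_ratio, 1)  # 10 / 10
})
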