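make_records <- function(values, subject = "s1", measure = "orbital_height",
                         side = "right") {
  stopifnot(length(values) == 6)
  tibble::tibble(
    subject = subject, measure = measure, side = side,
    rater = rep(1:2, each = 3), replicate = rep(1:3, 2), value = values
  )
}

test_that("replicate collapse averages within rater then across raters", {
  expect_equal(collapse_replicates(make_records(rep(7.5, 6)))$value, 7.5)
  rec <- make_records(c(9, 10, 11, 11, 12, 13))  # rater means 10 and 12
  expect_equal(collapse_replicates(rec)$value, 11)
  # random records against the direct grand-mean-of-rater-means oracle
  set.seed(8)
  for (i in 1:10) {
    v <- rnorm(6, 30, 2)
    expect_equal(collapse_replicates(make_records(v))$value,
                 mean(c(mean(v[1:3]), mean(v[4:6]))))
  }
})

test_that("replicate collapse ignores row order and rater relabeling", {
  set.seed(9)
  v <- rnorm(6, 50, 3)
  rec <- make_records(v)
  shuffled <- rec[sample(6), ]
  expect_equal(collapse_replicates(shuffled)$value, collapse_replicates(rec)$value)
  relabeled <- rec
  relabeled$rater <- 3 - relabeled$rater
  expect_equal(collapse_replicates(relabeled)$value, collapse_replicates(rec)$value)
})

test_that("incomplete replicate sets raise missing-replicate errors", {
  rec <- make_records(rnorm(6))[-2, ]
  expect_error(collapse_replicates(rec), "missing-replicate")
  one_rater <- make_records(rnorm(6))
  one_rater$rater <- 1
  one_rater$replicate <- rep(1:3, 2)
  expect_error(collapse_replicates(one_rater), "replicate")
})

test_that("two-sample t-test matches the textbook pooled formula", {
  expect_equal(ttest_two_sample(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(ttest_two_sample(c(1, 2, 3), c(1, 2, 3))$p, 1)
  sep <- ttest_two_sample(c(1, 2, 3), c(1, 2, 3) + 100)
  expect_lt(sep$p, 0.001)
  set.seed(10)
  for (i in 1:10) {
    xs <- rnorm(7, 10, 2); ys <- rnorm(9, 11, 3)
    tt <- ttest_two_sample(xs, ys)
    sp2 <- ((6) * var(xs) + (8) * var(ys)) / 14
    t_ref <- (mean(xs) - mean(ys)) / sqrt(sp2 * (1 / 7 + 1 / 9))
    expect_equal(tt$t, t_ref, tolerance = 1e-10)
    expect_equal(tt$df, 14)
    expect_equal(tt$p, 2 * pt(-abs(t_ref), 14), tolerance = 1e-12)
    swap <- ttest_two_sample(ys, xs)
    expect_equal(swap$t, -tt$t, tolerance = 1e-12)
    expect_equal(swap$p, tt$p, tolerance = 1e-12)
  }
})

test_that("summary-statistic t-test equals the raw-data test on matched moments", {
  expect_equal(ttest_from_summary(5, 2, 10, 5, 3, 12)$t, 0)
  expect_equal(ttest_from_summary(5, 2, 10, 5, 3, 12)$p, 1)
  set.seed(12)
  for (i in 1:10) {
    xs <- rnorm(8); ys <- rnorm(11)
    # engineer samples with exact target moments
    xs <- 20 + 3 * (xs - mean(xs)) / sd(xs)
    ys <- 22 + 4 * (ys - mean(ys)) / sd(ys)
    a <- ttest_two_sample(xs, ys)
    b <- ttest_from_summary(mean(xs), sd(xs), 8, mean(ys), sd(ys), 11)
    expect_equal(a$t, b$t, tolerance = 1e-10)
    expect_equal(a$p, b$p, tolerance = 1e-10)
    expect_equal(a$df, b$df)
  }
})

test_that("tidy and glance methods summarise test objects", {
  td <- tidy(ttest_from_summary(30, 2, 30, 28, 2, 30))
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate, 2)
  expect_true(td$p.value < 0.05)
})

test_that("zero-variance groups follow the documented edge contract", {
  same <- ttest_two_sample(rep(5, 3), rep(5, 4))
  expect_equal(same$p, 1)
  diff <- ttest_two_sample(rep(5, 3), rep(9, 4))
  expect_equal(diff$p, 0)
})

test_that("comparison table has the study layout and group structure", {
  set.seed(14)
  sim <- simulate_cohort(cohort_spec(n_uls = 6, n_control = 5,
                                     laterality = c(right = 4, left = 2)), seed = 5)
  tbl <- build_comparison_table(sim$measurements)
  n_bil <- length(bilateral_measures()) + length(volume_measures())
  tests <- tbl[tbl$comparison != "deviation", ]
  expect_equal(nrow(tests), 3 * n_bil)
  expect_equal(sort(unique(tests$comparison)),
               sort(c("ipsilateral_vs_contralateral", "ipsilateral_vs_control",
                      "contralateral_vs_control")))
  expect_equal(sum(tbl$comparison == "deviation"), 2)
  expect_true(all(tbl$facial_third %in% c("upper", "middle", "lower")))
  expect_true(all(tests$p >= 0 & tests$p <= 1))
  expect_equal(tests$significant, tests$p < 0.05)
  gl <- glance(tbl)
  expect_equal(gl$n_comparisons, 3 * n_bil)
})

test_that("identical groups yield p = 1 everywhere", {
  lms <- inverse_place_landmarks(table1_targets(), affected_side = "right")
  mt_u <- dplyr::bind_rows(lapply(1:3, function(i) {
    measure_all(lms, sprintf("u%d", i), "ULS", "right")
  }))
  # controls carrying the same per-side values as the affected subjects
  mt_c <- suppressWarnings(dplyr::bind_rows(lapply(1:3, function(i) {
    measure_all(lms, sprintf("c%d", i), "control", "none")  # deviations unsigned
  })))
  tbl <- build_comparison_table(dplyr::bind_rows(mt_u, mt_c),
                                control_sides = "pooled")
  ic <- tbl[tbl$comparison == "ipsilateral_vs_contralateral", ]
  expect_true(all(ic$p[ic$mean1 == ic$mean2] == 1))
})
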