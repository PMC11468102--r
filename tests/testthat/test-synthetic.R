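test_that("inverse placement realizes every craniometric target exactly", {
  tg <- table1_targets("right")
  lms <- inverse_place_landmarks(tg, affected_side = "right")
  mt <- measure_all(lms, "p", "ULS", "right")
  tg$lab <- dplyr::case_when(tg$side == "right" ~ "ipsilateral",
                             tg$side == "left" ~ "contralateral",
                             TRUE ~ "midline")
  j <- dplyr::inner_join(mt, tg, by = c("measure", "side" = "lab"))
  expect_equal(nrow(j), 28)  # 13 bilateral x 2 + 2 deviations
  expect_equal(j$value.x, j$value.y, tolerance = 1e-6)
})

test_that("single-measure targets behave like direct construction", {
  h <- 31.7
  lms <- inverse_place_landmarks(
    tibble::tibble(measure = "orbital_height", side = "right", value = h)
  )
  expect_equal(point_point_distance(lm_point(lms, "zm", "right"),
                                    lm_point(lms, "sn", "right")), h, tolerance = 1e-9)
  ang <- inverse_place_landmarks(
    tibble::tibble(measure = "mandibular_angle", side = "left", value = 102.51)
  )
  mm <- measure_mandible(ang)
  expect_equal(mm$value[mm$measure == "mandibular_angle" & mm$side == "left"],
               102.51, tolerance = 1e-9)
})

test_that("simultaneous zygomatic length and angle targets are both satisfied", {
  tg <- tibble::tibble(measure = c("zygomatic_length", "zygomatic_angle"),
                       side = "right", value = c(51.01, 45.17))
  lms <- inverse_place_landmarks(tg)
  z <- measure_zygoma(lms)
  expect_equal(z$value[z$measure == "zygomatic_length" & z$side == "right"],
               51.01, tolerance = 1e-9)
  expect_equal(z$value[z$measure == "zygomatic_angle" & z$side == "right"],
               45.17, tolerance = 1e-9)
})

test_that("infeasible or conflicting targets raise construction errors", {
  bad <- tibble::tibble(measure = c("orbital_height", "vertical_orbital_angle"),
                        side = "right", value = c(5, 80))
  expect_error(inverse_place_landmarks(bad), "constructibility")
  dup <- tibble::tibble(measure = "orbital_height", side = c("right", "right"),
                        value = c(30, 31))
  expect_error(inverse_place_landmarks(dup), "duplicate targets")
  unknown <- tibble::tibble(measure = "skull_girth", side = "right", value = 1)
  expect_error(inverse_place_landmarks(unknown), "unknown measure")
})

test_that("an undeformed phantom is bilaterally symmetric end to end", {
  ph <- make_phantom(phantom_spec(affected_side = "none"))
  mt <- measure_all(ph$landmarks, "p", "control")
  wide <- tidyr::pivot_wider(mt[mt$side != "midline", c("measure", "side", "value")],
                             names_from = "side", values_from = "value")
  expect_equal(wide$left, wide$right, tolerance = 1e-9)
  expect_equal(mt$value[mt$side == "midline"], c(0, 0), tolerance = 1e-12)
  expect_true(is_watertight(ph$surface))
  expect_true(all(vapply(ph$regions, is_watertight, logical(1))))
})

test_that("cohort simulation is deterministic and honors the laterality mix", {
  spec <- cohort_spec(n_uls = 4, n_control = 2, laterality = c(right = 3, left = 1))
  a <- simulate_cohort(spec, seed = 3)
  b <- simulate_cohort(spec, seed = 3)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$records, b$records)
  aff <- dplyr::distinct(a$measurements[a$measurements$group == "ULS", ],
                         subject, affected_side)
  expect_equal(sum(aff$affected_side == "right"), 3)
  expect_equal(sum(aff$affected_side == "left"), 1)
})

test_that("degenerate spec (zero SDs, zero noise) reproduces the means exactly", {
  mom <- uls_table1()$moments
  mom[, c("sd_ipsi", "sd_contra", "sd_control")] <- 0
  spec <- cohort_spec(moments = mom, n_uls = 3, n_control = 2,
                      laterality = c(right = 2, left = 1),
                      replicate_sd = 0, rater_bias_sd = 0)
  sim <- simulate_cohort(spec, seed = 99)
  m <- sim$measurements
  oh <- m$value[m$measure == "orbital_height" & m$side == "ipsilateral"]
  expect_equal(oh, rep(30.05, 3), tolerance = 1e-9)
  ma <- m$value[m$measure == "mandibular_angle" & m$side == "contralateral"]
  expect_equal(ma, rep(102.51, 3), tolerance = 1e-9)
  col <- collapse_replicates(sim$records)
  expect_equal(col$value[col$measure == "nasal_deviation" & col$group == "ULS"],
               rep(3.57, 3), tolerance = 1e-9)
})

test_that("laterality does not leak into ipsi/contra tables", {
  spec_mix <- cohort_spec(n_uls = 4, n_control = 2,
                          laterality = c(right = 2, left = 2))
  spec_all_r <- cohort_spec(n_uls = 4, n_control = 2,
                            laterality = c(right = 4, left = 0))
  a <- simulate_cohort(spec_mix, seed = 17)
  b <- simulate_cohort(spec_all_r, seed = 17)
  cols <- c("subject", "measure", "side", "value")
  expect_equal(
    dplyr::arrange(a$measurements[a$measurements$group == "ULS", cols],
                   subject, measure, side),
    dplyr::arrange(b$measurements[b$measurements$group == "ULS", cols],
                   subject, measure, side),
    tolerance = 1e-9
  )
})

test_that("cohort at the study moments recovers group means within 2 SE", {
  sim <- simulate_cohort(cohort_spec(), seed = 2)
  ps <- collapse_replicates(sim$records)
  mom <- uls_table1()$moments
  for (ms in c("orbital_height", "fossa_angle", "mandibular_angle")) {
    row <- mom[mom$measure == ms, ]
    est_i <- mean(ps$value[ps$measure == ms & ps$side == "ipsilateral"])
    est_c <- mean(ps$value[ps$measure == ms & ps$side == "contralateral"])
    expect_lt(abs(est_i - row$mean_ipsi), 2 * row$sd_ipsi / sqrt(30) + 0.25)
    expect_lt(abs(est_c - row$mean_contra), 2 * row$sd_contra / sqrt(30) + 0.25)
  }
})
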