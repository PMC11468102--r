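# shared fixtures, all generated in code

# full craniometric target table at the study's group means
table1_targets <- function(affected = "right") {
  mom <- uls_table1()$moments
  bil <- mom[!mom$measure %in% c(volume_measures(), "nasal_deviation", "chin_deviation"), ]
  ipsi_side <- affected
  contra_side <- if (affected == "right") "left" else "right"
  dplyr::bind_rows(
    tibble::tibble(measure = bil$measure, side = ipsi_side, value = bil$mean_ipsi),
    tibble::tibble(measure = bil$measure, side = contra_side, value = bil$mean_contra),
    tibble::tibble(measure = c("nasal_deviation", "chin_deviation"),
                   side = "midline", value = c(3.57, 1.04))
  )
}

# deterministic "random" rigid transform
random_rigid <- function(seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0.3, 2.5)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  list(rotation = R, translation = rnorm(3, sd = 20))
}

transform_landmarks <- function(lms, tf) {
  p <- as.matrix(lms[, c("x", "y", "z")]) %*% t(tf$rotation)
  p <- sweep(p, 2, tf$translation, "+")
  lms$x <- p[, 1]; lms$y <- p[, 2]; lms$z <- p[, 3]
  lms
}

expect_tables_equal <- function(a, b, tol = 1e-9) {
  a <- dplyr::arrange(tibble::as_tibble(a), measure, side)
  b <- dplyr::arrange(tibble::as_tibble(b), measure, side)
  expect_equal(a$measure, b$measure)
  expect_equal(a$side, b$side)
  expect_equal(a$value, b$value, tolerance = tol)
}
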