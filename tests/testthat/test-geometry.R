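test_that("midsagittal plane passes through the three midline points", {
  lms <- landmark_set(tibble::tibble(
    name = c("nasion", "sella", "basion"), side = "midline",
    x = 0, y = c(100, 0, -40), z = c(0, 0, -20)
  ))
  pl <- build_midsagittal_plane(lms)
  expect_equal(abs(pl$normal), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(plane_distance(c(0, 5, 7), pl), 0, tolerance = 1e-12)
})

test_that("fallback symmetry fit recovers the mirror plane of bilateral pairs", {
  base <- default_landmarks()
  no_mid <- base[!(base$name %in% c("nasion", "sella", "basion")), ]
  class(no_mid) <- class(base)
  pl <- build_midsagittal_plane(no_mid)
  expect_equal(pl$normal, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(abs(plane_distance(c(0, 10, -4), pl)), 0, tolerance = 1e-9)

  # same configuration under a rigid transform: the fitted plane moves with it
  tf <- random_rigid(4)
  moved <- transform_landmarks(no_mid, tf)
  pl2 <- build_midsagittal_plane(moved)
  n_expect <- as.numeric(tf$rotation %*% c(1, 0, 0))
  expect_equal(abs(sum(pl2$normal * n_expect)), 1, tolerance = 1e-9)
  p_on <- as.numeric(tf$rotation %*% c(0, 30, 10) + tf$translation)
  expect_equal(plane_distance(p_on, pl2), 0, tolerance = 1e-6)
})

test_that("midsagittal plane requires enough landmarks", {
  lms <- landmark_set(tibble::tibble(name = "nasion", side = "midline",
                                     x = 0, y = 45, z = 18))
  expect_error(build_midsagittal_plane(lms), "bilateral landmark pairs")
})

test_that("distances and vertex angles follow the closed forms", {
  expect_equal(point_point_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(point_point_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(3, sd = 30); b <- rnorm(3, sd = 30); v <- rnorm(3, sd = 30)
    expect_equal(point_point_distance(a, b), sqrt(sum((a - b)^2)))
    u1 <- (a - v) / sqrt(sum((a - v)^2)); u2 <- (b - v) / sqrt(sum((b - v)^2))
    expect_equal(three_point_angle(a, v, b),
                 acos(max(-1, min(1, sum(u1 * u2)))) * 180 / pi, tolerance = 1e-10)
  }
  expect_equal(three_point_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  # collinear rays: acos amplifies rounding near 1, so allow microdegrees
  expect_lt(three_point_angle(c(1, 1, 0), c(0, 0, 0), c(2, 2, 0)), 1e-5)
  expect_error(three_point_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("line-plane angle handles parallel, normal, and constructed cases", {
  pl <- plane(c(0, 0, 0), c(0, 0, 1))
  expect_equal(line_plane_angle(c(0, 0, 0), c(5, 3, 0), pl), 0)
  expect_equal(line_plane_angle(c(1, 1, 0), c(1, 1, 7), pl), 90)
  # 30 degree elevation built by rotation out of the plane
  p2 <- c(cos(pi / 6), 0, sin(pi / 6))
  expect_equal(line_plane_angle(c(0, 0, 0), p2, pl), 30, tolerance = 1e-10)
  # angle to plane and angle to normal are complementary
  set.seed(3)
  for (i in 1:10) {
    q <- rnorm(3)
    a_pl <- line_plane_angle(c(0, 0, 0), q, pl)
    a_n <- three_point_angle(q, c(0, 0, 0), c(0, 0, 1))
    expect_equal(a_pl + min(a_n, 180 - a_n), 90, tolerance = 1e-9)
  }
})

test_that("axial-projected angle spans the full anterior-posterior range", {
  lms <- default_landmarks()
  midsag <- build_midsagittal_plane(lms)
  axial <- build_axial_plane(lms, midsag)
  ant <- cranioshape:::anterior_axis(lms, midsag, axial)
  s0 <- lm_point(lms, "sella")
  expect_lt(axial_projected_angle(s0, s0 + 50 * ant, midsag, axial, ant), 1e-5)
  lat <- cranioshape:::cross3(ant, axial$normal)
  expect_equal(axial_projected_angle(s0, s0 + 40 * lat, midsag, axial, ant), 90,
               tolerance = 1e-9)
  # posterior-lateral target constructed at 102.51 degrees
  th <- 102.51 * pi / 180
  tgt <- s0 + 60 * (cos(th) * ant + sin(th) * lat) + 12 * axial$normal
  expect_equal(axial_projected_angle(s0, tgt, midsag, axial, ant), 102.51,
               tolerance = 1e-9)
  expect_error(axial_projected_angle(s0, s0 + 5 * axial$normal, midsag, axial, ant),
               "degenerate")
})

test_that("mirroring is an involution that swaps sides and fixes the midline", {
  lms <- inverse_place_landmarks(table1_targets(), affected_side = "right")
  pl <- build_midsagittal_plane(lms)
  m1 <- mirror_subject(lms, pl)
  # midline landmarks keep |x| but flip across the plane; on-plane points fixed
  expect_equal(lm_point(m1, "sella"), lm_point(lms, "sella"), tolerance = 1e-12)
  expect_equal(lm_point(m1, "zm", "right"), lm_point(lms, "zm", "left") * c(-1, 1, 1),
               tolerance = 1e-12)
  m2 <- mirror_subject(m1, pl)
  expect_equal(as.matrix(m2[, c("x", "y", "z")]), as.matrix(lms[, c("x", "y", "z")]),
               tolerance = 1e-9)
  expect_equal(m2$side, lms$side)
})

test_that("a mirrored surface keeps outward orientation and volume", {
  ell <- make_ellipsoid(c(30, 40, 25), center = c(5, -3, 8))
  res <- mirror_subject(default_landmarks(), plane(c(0, 0, 0), c(1, 0, 0)), ell)
  expect_true(is_watertight(res$surface))
  expect_equal(mesh_volume(res$surface), mesh_volume(ell), tolerance = 1e-12)
})

test_that("rigid alignment recovers known transforms and matches procrustes", {
  lms <- default_landmarks()
  tf0 <- rigid_align_landmarks(lms, lms)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tf0$rmsd, 0, tolerance = 1e-10)

  tf <- random_rigid(9)
  moved <- transform_landmarks(lms, tf)
  est <- rigid_align_landmarks(lms, moved)
  expect_equal(est$rotation, tf$rotation, tolerance = 1e-6)
  expect_equal(est$translation, tf$translation, tolerance = 1e-6)
  back <- apply_rigid_transform(lms, est)
  expect_equal(as.matrix(back[, c("x", "y", "z")]),
               as.matrix(moved[, c("x", "y", "z")]), tolerance = 1e-9)

  # independent oracle: vegan's procrustes with scaling off, on noisy pairs
  skip_if_not_installed("vegan")
  set.seed(11)
  noisy <- moved
  noisy$x <- noisy$x + rnorm(nrow(noisy), sd = 0.5)
  noisy$y <- noisy$y + rnorm(nrow(noisy), sd = 0.5)
  noisy$z <- noisy$z + rnorm(nrow(noisy), sd = 0.5)
  est2 <- rigid_align_landmarks(lms, noisy)
  X <- as.matrix(lms[, c("x", "y", "z")])
  Y <- as.matrix(noisy[, c("x", "y", "z")])
  pr <- vegan::procrustes(Y, X, scale = FALSE)
  expect_equal(est2$rotation, t(pr$rotation), tolerance = 1e-8)
})

test_that("alignment errors on insufficient or collinear landmarks", {
  lms <- default_landmarks()
  two <- lms[lms$name %in% c("nasion", "sella"), ]
  class(two) <- class(lms)
  expect_error(rigid_align_landmarks(two, two), "fewer than 3")
  col <- landmark_set(tibble::tibble(
    name = c("nasion", "sella", "basion"), side = "midline",
    x = 0, y = c(0, 10, 20), z = 0
  ))
  expect_error(rigid_align_landmarks(col, col), "collinear")
})
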