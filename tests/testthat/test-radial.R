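# a landmark set whose inter-tragi midpoint sits at a chosen center
tragi_at <- function(center) {
  lms <- default_landmarks()
  i_l <- which(lms$name == "tragus" & lms$side == "left")
  i_r <- which(lms$name == "tragus" & lms$side == "right")
  lms$x[i_l] <- center[1] - 50; lms$x[i_r] <- center[1] + 50
  lms$y[c(i_l, i_r)] <- center[2]; lms$z[c(i_l, i_r)] <- center[3]
  lms
}

# direction grid aimed exactly at a subset of mesh vertices
vertex_grid <- function(surf, center, n = 150) {
  set.seed(21)
  v <- surf$vertices[sample(nrow(surf$vertices), n), ]
  d <- sweep(v, 2, center)
  r <- sqrt(rowSums(d^2))
  u <- d / r
  tibble::tibble(
    azimuth_deg = (atan2(u[, 1], u[, 2]) * 180 / pi) %% 360,
    elevation_deg = asin(pmin(1, pmax(-1, u[, 3]))) * 180 / pi,
    ux = u[, 1], uy = u[, 2], uz = u[, 3]
  )
}

test_that("radial grid has the documented resolution and unit directions", {
  g <- radial_grid(2)
  expect_equal(nrow(g), 180 * 90)
  expect_equal(g$ux^2 + g$uy^2 + g$uz^2, rep(1, nrow(g)), tolerance = 1e-12)
  # azimuth 0 = anterior (+y), 90 = right (+x)
  first <- radial_grid(90)
  expect_equal(first$uy[first$azimuth_deg == 0 & first$elevation_deg == 45],
               cos(pi / 4), tolerance = 1e-12)
})

test_that("sphere about the inter-tragi center returns the exact radius at vertices", {
  ctr <- c(0, -5, -10)
  sph <- make_ellipsoid(c(80, 80, 80), center = ctr, n_lat = 24, n_lon = 48)
  lms <- tragi_at(ctr)
  rm_v <- radial_map(sph, lms, vertex_grid(sph, ctr, 100))
  expect_true(all(rm_v$hit))
  expect_equal(rm_v$radius_mm, rep(80, 100), tolerance = 1e-9)
  # interior chords on a regular grid stay within the faceting sagitta
  rm_g <- radial_map(sph, lms, radial_grid(30))
  expect_true(all(rm_g$radius_mm <= 80 + 1e-9))
  expect_true(all(rm_g$radius_mm > 80 * 0.99))
})

test_that("ellipsoid radial map matches the closed-form quadric solution", {
  semi <- c(70, 90, 60)
  ell <- make_ellipsoid(semi, n_lat = 32, n_lon = 64)
  ctr <- c(0, -5, -10)  # off-center, inside
  lms <- tragi_at(ctr)
  g <- vertex_grid(ell, ctr, 150)
  rm <- radial_map(ell, lms, g)
  dirs <- as.matrix(g[, c("ux", "uy", "uz")])
  A <- rowSums(sweep(dirs^2, 2, semi^2, "/"))
  B <- 2 * rowSums(sweep(dirs * matrix(ctr, nrow(dirs), 3, byrow = TRUE), 2, semi^2, "/"))
  C <- sum(ctr^2 / semi^2) - 1
  t_quad <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
  expect_equal(rm$radius_mm, t_quad, tolerance = 1e-6)
})

test_that("a center outside the surface is a geometry error", {
  sph <- make_ellipsoid(c(30, 30, 30), center = c(200, 0, 0))
  expect_error(radial_map(sph, tragi_at(c(0, 0, 0)), radial_grid(45)), "outside")
})

test_that("composites are idempotent, permutation-invariant, and average radii", {
  ctr <- c(0, -5, -10)
  lms <- tragi_at(ctr)
  g <- radial_grid(30)
  r70 <- radial_map(make_ellipsoid(c(70, 70, 70), center = ctr), lms, g)
  r90 <- radial_map(make_ellipsoid(c(90, 90, 90), center = ctr), lms, g)
  expect_equal(composite_map(list(r70, r70, r70))$radius_mm, r70$radius_mm)
  c1 <- composite_map(list(r70, r90)); c2 <- composite_map(list(r90, r70))
  expect_equal(c1$radius_mm, c2$radius_mm)
  expect_equal(c1$radius_mm, (r70$radius_mm + r90$radius_mm) / 2)
  expect_true(all(c1$n_subjects == 2))
})

test_that("heat maps are zero on identical groups, antisymmetric, and track offsets", {
  ctr <- c(0, -5, -10)
  lms <- tragi_at(ctr)
  g <- radial_grid(30)
  a <- radial_map(make_ellipsoid(c(80, 80, 80), center = ctr), lms, g)
  expect_equal(heat_map(list(a), list(a))$delta_mm, rep(0, nrow(a)))
  b <- a
  b$radius_mm <- b$radius_mm + 5  # uniform 5 mm inflation
  expect_equal(heat_map(list(b), list(a))$delta_mm, rep(5, nrow(a)))
  h_ab <- heat_map(list(a, b), list(b))
  h_ba <- heat_map(list(b), list(a, b))
  expect_equal(h_ab$delta_mm, -h_ba$delta_mm)
  # misses: delta defined only where both groups have coverage
  a_miss <- a; a_miss$radius_mm[3] <- NA; a_miss$hit[3] <- FALSE
  expect_true(is.na(heat_map(list(a_miss), list(b))$delta_mm[3]))
  expect_error(heat_map(list(), list(a)), "at least one subject")
  g2 <- radial_map(make_ellipsoid(c(80, 80, 80), center = ctr), lms, radial_grid(45))
  expect_error(heat_map(list(a), list(g2)), "grid")
})

test_that("synthetic bossing shows up as a positive delta in the right sector", {
  grid <- radial_grid(15)
  subj <- function(aff) {
    ph <- make_phantom(phantom_spec(affected_side = aff, n_lat = 24, n_lon = 48))
    radial_map(ph$surface, ph$landmarks, grid)
  }
  h <- heat_map(list(subj("right")), list(subj("none")))
  # contralateral (left) posterior parietal bossing: azimuth around 180-270,
  # high elevation; the peak delta should be positive and near the amplitude
  sector <- h$azimuth_deg > 190 & h$azimuth_deg < 290 & h$elevation_deg > 20
  expect_gt(max(h$delta_mm[sector]), 4)
  expect_lt(max(h$delta_mm[sector]), 8)
  # ipsilateral (right) occipital flattening: negative delta
  flat <- h$azimuth_deg > 135 & h$azimuth_deg < 180 & h$elevation_deg < 30
  expect_lt(min(h$delta_mm[flat]), -3)
})

test_that("heat map export interpolates onto a reference mesh and round-trips", {
  ctr <- c(0, -5, -10)
  lms <- tragi_at(ctr)
  g <- radial_grid(30)
  sph <- make_ellipsoid(c(80, 80, 80), center = ctr, n_lat = 16, n_lon = 32)
  a <- radial_map(sph, lms, g)
  zero <- heat_map(list(a), list(a))
  path <- withr::local_tempfile(fileext = ".ply")
  export_heatmap_mesh(zero, sph, ctr, path)
  rt <- read_ply(path)
  expect_equal(rt$scalars$delta, rep(0, nrow(sph$vertices)))
  # nonzero map: scalar at a direction equals bilinear interpolation there
  b <- a; b$radius_mm <- b$radius_mm + seq_len(nrow(b)) / nrow(b)
  h <- heat_map(list(b), list(a))
  at_nodes <- cranioshape:::interp_heatmap(h, h$azimuth_deg, h$elevation_deg)
  expect_equal(at_nodes, h$delta_mm, tolerance = 1e-9)
})
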