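#' Study-condition fixture: group moments and cohort counts
#'
#' The group means and SDs for every measure (ipsilateral / contralateral /
#' control), the cohort sizes (30 affected, 30 control), the laterality mix
#' (17 right, 13 left) and the metopic-ridge count (13 of 30) used as the
#' default conditions for [simulate_cohort()] and the phantom builders.
#'
#' @return A list with `moments` (tibble: `measure`, `unit`, `mean_ipsi`,
#'   `sd_ipsi`, `mean_contra`, `sd_contra`, `mean_control`, `sd_control`),
#'   `n_uls`, `n_control`, `laterality`, `metopic_ridge`.
#' @export
uls_table1 <- function() {
  moments <- tibble::tribble(
    ~measure, ~unit, ~mean_ipsi, ~sd_ipsi, ~mean_contra, ~sd_contra, ~mean_control, ~sd_control,
    "fossa_volume",             "cm3", 99.62, 31.13, 101.87, 35.83, 86.90, 30.25,
    "fossa_angle",              "deg", 77.76,  3.82,  73.19,  2.86, 75.22,  3.48,
    "orbital_volume",           "cm3", 14.66,  2.96,  15.09,  3.18, 13.96,  2.95,
    "orbital_height",           "mm",  30.05,  1.91,  30.30,  2.30, 28.36,  2.18,
    "orbital_width",            "mm",  30.05,  1.91,  30.52,  1.99, 30.42,  2.44,
    "orbital_depth",            "mm",  32.34,  2.72,  32.72,  2.42, 35.70,  2.66,
    "horizontal_orbital_angle", "deg", 55.74,  4.31,  57.46,  3.85, 54.67,  2.25,
    "vertical_orbital_angle",   "deg", 53.21,  2.90,  53.43,  3.10, 45.52,  2.30,
    "zygomatic_volume",         "cm3",  1.85,  0.63,   1.93,  0.70,  2.09,  0.64,
    "zygomatic_length",         "mm",  47.16,  5.31,  51.01,  5.24, 42.78,  5.17,
    "zygomatic_height",         "mm",  29.01,  4.11,  28.55,  3.90, 28.49,  4.46,
    "zygomatic_angle",          "deg", 45.78,  2.69,  45.17,  2.74, 44.42,  1.65,
    "nasal_deviation",          "deg",    NA,    NA,   3.57,  1.97,     0,     0,
    "maxillary_angle",          "deg", 32.36,  4.84,  33.21,  4.14, 30.19,  4.03,
    "mandibular_volume",        "cm3",  5.38,  1.71,   5.76,  1.77,  6.01,  1.38,
    "ramus_length",             "mm",  28.57,  3.96,  28.87,  4.75, 30.05,  4.26,
    "body_length",              "mm",  40.28,  3.41,  44.70,  4.46, 42.97,  3.19,
    "mandibular_angle",         "deg", 94.83,  4.83, 102.51,  3.72, 95.85,  6.02,
    "chin_deviation",           "deg",    NA,    NA,   1.04,  3.74,     0,     0
  )
  list(
    moments = moments,
    n_uls = 30L, n_control = 30L,
    laterality = c(right = 17L, left = 13L),
    metopic_ridge = c(present = 13L, n = 30L)
  )
}

#' Names of the region volume measures
#' @return Character vector.
#' @export
volume_measures <- function() {
  c("fossa_volume", "orbital_volume", "zygomatic_volume", "mandibular_volume")
}

#' Default (symmetric) phantom landmark set
#'
#' A bilaterally symmetric full-registry landmark set in the canonical frame
#' (midsagittal plane x = 0, sella at the origin, +y anterior, +z superior;
#' coordinates in mm, sized for an infant skull). Serves as the base that
#' [inverse_place_landmarks()] deforms to hit measure targets.
#'
#' @return A `landmark_set`.
#' @export
default_landmarks <- function() {
  mid <- tibble::tribble(
    ~name, ~x, ~y, ~z,
    "sella", 0, 0, 0,
    "nasion", 0, 45, 18,
    "basion", 0, -35, -25,
    "ans", 0, 55, -12,
    "symphysis", 0, 48, -58
  )
  bil <- tibble::tribble(
    ~name, ~x, ~y, ~z,
    "zm", 28, 40, -8,
    "sn", 26, 43, 20,
    "zf", 31, 36, 16,
    "of", 7, 24, 10,
    "zt", 46, 4, -6,
    "zygoma_lowest", 34, 26, -18,
    "lesser_wing_medial", 6, 4, 10,
    "lesser_wing_lateral", 33, -6, 10,
    "pterygoid_hamulus", 10, 22, -28,
    "mandibular_notch", 42, 2, -36,
    "gonion", 46, -4, -54,
    "parasymphysis", 16, 38, -56,
    "articular_fossa", 49, -10, -6,
    "tragus", 55, -5, -10
  )
  landmark_set(dplyr::bind_rows(
    dplyr::mutate(mid, side = "midline"),
    dplyr::mutate(bil, side = "right"),
    dplyr::mutate(bil, x = -.data$x, side = "left")
  ))
}

# canonical-frame axes used by the constructive inverse
canonical_axes <- function(base) {
  s0 <- lm_point(base, "sella"); n0 <- lm_point(base, "nasion")
  ant <- unitize(n0 - s0 - c((n0 - s0)[1], 0, 0))
  m <- cross3(c(1, 0, 0), ant)
  list(right = c(1, 0, 0), anterior = ant, axial_normal = m)
}

# place P on the cone of half-angle `ang` (deg) about axis e1 at apex, inside
# the plane spanned by e1 and the default direction, at distance `len` from
# `anchor`; closed-form quadratic in the apex distance t
solve_cone_point <- function(apex, e1, default_dir, ang_deg, anchor, len, measure) {
  d0 <- default_dir - sum(default_dir * e1) * e1
  e2 <- unitize(d0)
  q <- cos(ang_deg * pi / 180) * e1 + sin(ang_deg * pi / 180) * e2
  w <- apex - anchor
  b <- sum(w * q)
  disc <- b^2 - sum(w * w) + len^2
  if (disc < 0) {
    stop(sprintf(
      "constructibility error: %s = %.4g unreachable (needs >= %.4g at this angle)",
      measure, len, sqrt(sum(w * w) - b^2)
    ), call. = FALSE)
  }
  t <- -b + sqrt(disc)
  if (t <= 0) {
    stop(sprintf("constructibility error: %s target places point behind the apex", measure),
         call. = FALSE)
  }
  apex + t * q
}

#' Place landmarks so that measures hit exact targets
#'
#' Constructive inverse of every craniometric formula: lengths are realized by
#' scaling along the defining segment, "midsagittal plane - sella - X" angles
#' by positioning on the target ray in the axial frame, orbital angles by a
#' closed-form cone/sphere intersection (so a simultaneous angle + length pair
#' is met exactly), and the midline deviations by rotating ANS and symphysis
#' off the midsagittal plane. The base set must be in the canonical frame
#' (see [default_landmarks()]). Measures without a target keep base geometry.
#'
#' @param targets Tibble with columns `measure`, `side` (`"left"`, `"right"`,
#'   or `"midline"` for the deviations), `value`.
#' @param base Canonical-frame `landmark_set`.
#' @param affected_side `"left"`, `"right"` or `"none"`; fixes the sign
#'   convention of the deviations (positive toward the contralateral side).
#' @return A `landmark_set` whose measured values equal the targets to
#'   numerical precision.
#' @export
#' @examples
#' tg <- tibble::tibble(measure = "nasal_deviation", side = "midline", value = 3.57)
#' lms <- inverse_place_landmarks(tg, affected_side = "right")
#' measure_deviations(lms, "right")
inverse_place_landmarks <- function(targets, base = default_landmarks(),
                                    affected_side = c("none", "left", "right")) {
  affected_side <- match.arg(affected_side)
  targets <- tibble::as_tibble(targets)
  stopifnot(all(c("measure", "side", "value") %in% names(targets)))
  bad <- setdiff(targets$measure, names(measure_units()))
  if (length(bad)) {
    stop("unknown measure target(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(targets$measure, targets$side)
  if (anyDuplicated(key)) {
    stop("conflict error: duplicate targets for ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  ax <- canonical_axes(base)
  s0 <- lm_point(base, "sella"); n0 <- lm_point(base, "nasion")
  tg <- function(measure, side) {
    i <- which(targets$measure == measure & targets$side == side)
    if (length(i)) targets$value[i] else NA_real_
  }
  set_pt <- function(lms, name, side, p) {
    i <- which(lms$name == name & lms$side == side)
    lms$x[i] <- p[1]; lms$y[i] <- p[2]; lms$z[i] <- p[3]
    lms
  }
  out <- base

  # point at a given axial-projected angle from anterior, keeping the default
  # in-plane distance and off-plane offset
  place_axial <- function(default_p, ang_deg, sgn) {
    v <- default_p - s0
    h <- sum(v * ax$axial_normal)
    rho <- vnorm(v - h * ax$axial_normal)
    a <- ang_deg * pi / 180
    s0 + rho * (cos(a) * ax$anterior + sin(a) * sgn * ax$right) + h * ax$axial_normal
  }

  for (side in c("left", "right")) {
    sgn <- if (side == "right") 1 else -1
    P0 <- lm_points(base, c("zm", "sn", "zf", "of", "zt", "zygoma_lowest",
                            "lesser_wing_medial", "lesser_wing_lateral",
                            "pterygoid_hamulus", "mandibular_notch", "gonion",
                            "parasymphysis", "articular_fossa"), side)

    zm <- P0["zm", ]
    v <- tg("zygomatic_angle", side)
    if (!is.na(v)) zm <- place_axial(P0["zm", ], v, sgn)

    of <- zm + (P0["of", ] - P0["zm", ])
    v <- tg("orbital_depth", side)
    if (!is.na(v)) of <- zm + v * unitize(P0["of", ] - P0["zm", ])

    vh <- tg("orbital_height", side); va <- tg("vertical_orbital_angle", side)
    if (is.na(vh)) vh <- point_point_distance(P0["zm", ], P0["sn", ])
    if (is.na(va)) {
      sn <- zm + vh * unitize(P0["sn", ] - P0["zm", ])
    } else {
      sn <- solve_cone_point(of, unitize(zm - of), P0["sn", ] - P0["of", ],
                             va, zm, vh, "orbital_height/vertical_orbital_angle")
    }

    vw <- tg("orbital_width", side); ha <- tg("horizontal_orbital_angle", side)
    if (is.na(vw)) vw <- point_point_distance(P0["zf", ], n0)
    if (is.na(ha)) {
      zf <- n0 + vw * unitize(P0["zf", ] - n0)
    } else {
      zf <- solve_cone_point(of, unitize(n0 - of), P0["zf", ] - P0["of", ],
                             ha, n0, vw, "orbital_width/horizontal_orbital_angle")
    }

    v <- tg("zygomatic_length", side)
    zt <- if (is.na(v)) zm + (P0["zt", ] - P0["zm", ]) else
      zm + v * unitize(P0["zt", ] - P0["zm", ])

    v <- tg("zygomatic_height", side)
    low <- if (is.na(v)) zf + (P0["zygoma_lowest", ] - P0["zf", ]) else
      zf + v * unitize(P0["zygoma_lowest", ] - P0["zf", ])

    med <- P0["lesser_wing_medial", ]
    v <- tg("fossa_angle", side)
    if (is.na(v)) {
      lat <- P0["lesser_wing_lateral", ]
    } else {
      f <- v * pi / 180
      wing_len <- point_point_distance(P0["lesser_wing_medial", ],
                                       P0["lesser_wing_lateral", ])
      lat <- med + wing_len * (sin(f) * sgn * ax$right - cos(f) * ax$anterior)
    }

    ham <- P0["pterygoid_hamulus", ]
    v <- tg("maxillary_angle", side)
    if (!is.na(v)) ham <- place_axial(P0["pterygoid_hamulus", ], v, sgn)

    art <- P0["articular_fossa", ]
    v <- tg("mandibular_angle", side)
    if (!is.na(v)) art <- place_axial(P0["articular_fossa", ], v, sgn)

    gon <- P0["gonion", ]
    v <- tg("ramus_length", side)
    notch <- if (is.na(v)) P0["mandibular_notch", ] else
      gon + v * unitize(P0["mandibular_notch", ] - gon)
    v <- tg("body_length", side)
    para <- if (is.na(v)) P0["parasymphysis", ] else
      gon + v * unitize(P0["parasymphysis", ] - gon)

    pts <- list(zm = zm, sn = sn, zf = zf, of = of, zt = zt,
                zygoma_lowest = low, lesser_wing_medial = med,
                lesser_wing_lateral = lat, pterygoid_hamulus = ham,
                mandibular_notch = notch, gonion = gon, parasymphysis = para,
                articular_fossa = art)
    for (nm in names(pts)) out <- set_pt(out, nm, side, pts[[nm]])
  }

  # midline deviations: positive toward the contralateral side
  s_dir <- switch(affected_side, right = -1, left = 1, none = 1)
  ans0 <- lm_point(base, "ans"); sym0 <- lm_point(base, "symphysis")
  ans <- ans0
  v <- tg("nasal_deviation", "midline")
  if (!is.na(v)) {
    a <- v * pi / 180
    d0 <- unitize(ans0 - n0)
    ans <- n0 + vnorm(ans0 - n0) * (cos(a) * d0 + sin(a) * s_dir * ax$right)
    out <- set_pt(out, "ans", "midline", ans)
  }
  v <- tg("chin_deviation", "midline")
  if (!is.na(v)) {
    a <- v * pi / 180
    d1 <- unitize(sym0 - ans0)
    sym <- ans + vnorm(sym0 - ans0) * (cos(a) * d1 + sin(a) * s_dir * ax$right)
    out <- set_pt(out, "symphysis", "midline", sym)
  }
  validate_landmark_set(out)
  out
}

#' Phantom specification
#'
#' @param affected_side `"right"`, `"left"` or `"none"`.
#' @param head_semi_axes Length-3 base head semi-axes (mm).
#' @param deformations Named amplitudes (mm): `occipital_flattening`
#'   (ipsilateral, applied as retrusion), `occipitomastoid_bulge`
#'   (ipsilateral), `parietal_bossing` (contralateral),
#'   `frontal_bossing_ipsi`, `frontal_bossing_contra`.
#' @param measure_targets Optional tibble for [inverse_place_landmarks()].
#' @param volume_targets Optional named numeric (cm^3): any of `fossa_left`,
#'   `fossa_right`, `orbit_left`, `orbit_right`, `zygoma_left`, `zygoma_right`,
#'   `mandible_left`, `mandible_right`.
#' @param n_lat,n_lon Mesh resolution of all generated solids.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(affected_side = "right",
                         head_semi_axes = c(65, 82, 60),
                         deformations = c(occipital_flattening = 8,
                                          occipitomastoid_bulge = 6,
                                          parietal_bossing = 7,
                                          frontal_bossing_ipsi = 2,
                                          frontal_bossing_contra = 5),
                         measure_targets = NULL,
                         volume_targets = NULL,
                         n_lat = 32, n_lon = 64) {
  stopifnot(all(is.finite(head_semi_axes)), all(head_semi_axes > 0),
            all(is.finite(deformations)))
  if (!is.null(volume_targets) && any(volume_targets <= 0)) {
    stop("volume targets must be positive", call. = FALSE)
  }
  structure(list(affected_side = affected_side,
                 head_semi_axes = head_semi_axes,
                 deformations = deformations,
                 measure_targets = measure_targets,
                 volume_targets = volume_targets,
                 n_lat = n_lat, n_lon = n_lon),
            class = "phantom_spec")
}

# smooth radial bump field on an ellipsoidal head
apply_bump <- function(v, center_dir, amplitude, width = 0.55) {
  u <- v / sqrt(rowSums(v^2))
  cd <- unitize(center_dir)
  ang <- acos(pmin(1, pmax(-1, u %*% cd)))
  v + as.numeric(amplitude * exp(-ang^2 / (2 * width^2))) * u
}

# piecewise-linear scaling of the two sides of a plane so that the measured
# half volumes hit (target_pos, target_neg) exactly; exact because the base
# solid is built with a vertex ring in the plane (no face crosses it)
calibrate_halves <- function(surf, pl, target_pos, target_neg) {
  halves <- split_by_plane(surf, pl)
  vp <- mesh_volume(halves$positive); vn <- mesh_volume(halves$negative)
  d <- plane_distance(surf$vertices, pl)
  s <- ifelse(d >= 0, target_pos / vp, target_neg / vn)
  triangle_surface(surf$vertices + (s - 1) * d %o% pl$normal, surf$faces)
}

# ellipsoid solid whose x=0-equivalent vertex ring lies exactly in `pl`
oriented_ellipsoid <- function(pl, along, semi, center, n_lat, n_lon) {
  u <- unitize(along - sum(along * pl$normal) * pl$normal)
  w <- cross3(pl$normal, u)
  R <- cbind(pl$normal, u, w)
  base <- make_uv_sphere(n_lat, n_lon)
  v0 <- base$vertices
  # base sphere columns at azimuth 0 and 180 have x = 0 exactly
  v <- t(R %*% t(v0 * matrix(semi, nrow(v0), 3, byrow = TRUE)))
  ctr <- center - plane_distance(center, pl) * pl$normal
  triangle_surface(sweep(v, 2, ctr, "+"), base$faces)
}

#' Build a synthetic skull phantom
#'
#' Watertight deformed-ellipsoid head surface carrying the full landmark
#' registry, plus watertight region solids (anterior fossa, orbits, zygomas,
#' mandible). Craniometric targets are realized exactly through
#' [inverse_place_landmarks()]; volume targets are realized by scaling each
#' region solid so its discrete mesh volume equals the target (the fossa and
#' mandible solids are built with a vertex ring in their split plane and
#' scaled per half, so the plane-partitioned volumes are exact too). Fully
#' deterministic.
#'
#' @param spec A [phantom_spec()].
#' @return List with `landmarks`, `surface` (head), and `regions` (named list
#'   of `triangle_surface`s: `anterior_fossa`, `orbit_left`, `orbit_right`,
#'   `zygoma_left`, `zygoma_right`, `mandible`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  lms <- if (is.null(spec$measure_targets)) default_landmarks() else
    inverse_place_landmarks(spec$measure_targets, default_landmarks(),
                            affected_side = if (spec$affected_side == "none") "none" else spec$affected_side)

  ipsi <- if (spec$affected_side == "left") -1 else 1  # canonical build, right = +x
  dfm <- spec$deformations
  head <- make_ellipsoid(spec$head_semi_axes, n_lat = spec$n_lat, n_lon = spec$n_lon)
  v <- head$vertices
  if (spec$affected_side != "none") {
    v <- apply_bump(v, c(0.45 * ipsi, -0.80, 0.15), -abs(dfm[["occipital_flattening"]]))
    v <- apply_bump(v, c(0.80 * ipsi, -0.50, -0.30), abs(dfm[["occipitomastoid_bulge"]]))
    v <- apply_bump(v, c(-0.60 * ipsi, -0.35, 0.72), abs(dfm[["parietal_bossing"]]))
    v <- apply_bump(v, c(0.45 * ipsi, 0.82, 0.35), abs(dfm[["frontal_bossing_ipsi"]]))
    v <- apply_bump(v, c(-0.45 * ipsi, 0.82, 0.35), abs(dfm[["frontal_bossing_contra"]]))
  }
  head <- triangle_surface(v, head$faces)

  vt <- function(nm, default) {
    x <- spec$volume_targets
    if (!is.null(x) && nm %in% names(x)) x[[nm]] else default
  }

  # anterior fossa: split-plane-aligned ellipsoid, per-half calibrated (cm^3)
  fossa_pl <- ans_sella_plane(lms)
  fossa <- oriented_ellipsoid(fossa_pl, along = c(0, 1, 0), semi = c(50, 42, 28),
                              center = c(0, 30, 22), n_lat = spec$n_lat, n_lon = spec$n_lon)
  fossa <- calibrate_halves(fossa, fossa_pl,
                            target_pos = vt("fossa_right", 87),
                            target_neg = vt("fossa_left", 87))

  orbit_solid <- function(side, sgn) {
    target <- vt(paste0("orbit_", side), 14)
    s <- make_ellipsoid(c(12, 18, 14), center = c(sgn * 28, 48, 5),
                        n_lat = spec$n_lat, n_lon = spec$n_lon)
    scale_mesh(s, (target / mesh_volume(s))^(1 / 3), center = c(sgn * 28, 48, 5))
  }
  zygoma_solid <- function(side, sgn) {
    target <- vt(paste0("zygoma_", side), 2)
    s <- make_ellipsoid(c(6, 16, 5), center = c(sgn * 38, 25, -10),
                        n_lat = spec$n_lat, n_lon = spec$n_lon)
    scale_mesh(s, (target / mesh_volume(s))^(1 / 3), center = c(sgn * 38, 25, -10))
  }

  # mandible: one solid split at the symphysis plane (parallel to midsagittal)
  midsag <- build_midsagittal_plane(lms)
  mand_pl <- plane(lm_point(lms, "symphysis"), midsag$normal)
  mandible <- oriented_ellipsoid(mand_pl, along = c(0, 1, 0), semi = c(26, 21, 8),
                                 center = c(0, 18, -52), n_lat = spec$n_lat, n_lon = spec$n_lon)
  mandible <- calibrate_halves(mandible, mand_pl,
                               target_pos = vt("mandible_right", 6),
                               target_neg = vt("mandible_left", 6))

  list(
    landmarks = lms,
    surface = head,
    regions = list(
      anterior_fossa = fossa,
      orbit_left = orbit_solid("left", -1), orbit_right = orbit_solid("right", 1),
      zygoma_left = zygoma_solid("left", -1), zygoma_right = zygoma_solid("right", 1),
      mandible = mandible
    )
  )
}

#' Cohort specification
#'
#' @param moments Per-measure group moments (default [uls_table1()]).
#' @param n_uls,n_control Group sizes.
#' @param laterality Named counts `c(right=, left=)`, summing to `n_uls`.
#' @param replicate_sd Within-rater replicate noise SD (mm or degrees).
#' @param rater_bias_sd SD of the per-rater systematic offset.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(moments = uls_table1()$moments,
                        n_uls = 30L, n_control = 30L,
                        laterality = c(right = 17L, left = 13L),
                        replicate_sd = 0.4, rater_bias_sd = 0.2) {
  stopifnot(n_uls >= 2, n_control >= 2, sum(laterality) == n_uls,
            replicate_sd >= 0, rater_bias_sd >= 0,
            all(moments$sd_ipsi >= 0, na.rm = TRUE))
  structure(list(moments = moments, n_uls = as.integer(n_uls),
                 n_control = as.integer(n_control), laterality = laterality,
                 replicate_sd = replicate_sd, rater_bias_sd = rater_bias_sd),
            class = "cohort_spec")
}

# normal draw truncated at +/-4 SD (keeps targets constructible)
rnorm_trunc <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, mean - 4 * sd), mean + 4 * sd)
}

#' Simulate a full study cohort
#'
#' Draws per-subject true measure values from the group moments, realizes the
#' craniometric truths geometrically with [inverse_place_landmarks()]
#' (left-affected subjects are built in the canonical right-affected frame and
#' mirrored), re-measures every subject with [measure_all()], and generates
#' triplicate, two-rater replicate records (truth + rater bias + replicate
#' noise). Region volumes are sampled values attached to the measurement
#' table; distances and angles are the geometric round trip.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the simulation is fully reproducible.
#' @return List with `measurements` (per-subject values: `subject`, `group`,
#'   `affected_side`, `measure`, `side`, `value`, `unit`), `records`
#'   (replicate-level tibble), and `subjects` (named list of `landmark_set`s).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  set.seed(seed)
  mom <- spec$moments
  cranio <- mom[!mom$measure %in% volume_measures(), ]
  vols <- mom[mom$measure %in% volume_measures(), ]
  sides_of <- c(rep("right", spec$laterality[["right"]]),
                rep("left", spec$laterality[["left"]]))

  measurements <- list(); records <- list(); subjects <- list()

  # One subject: independent normal draws can violate the geometric triangle
  # constraints among jointly realized measures (e.g. orbital height >= depth
  # x sin(vertical angle)); such draws are rejected and the subject resampled.
  sample_subject <- function(id, group, affected) {
    for (attempt in 1:50) {
      res <- tryCatch(sample_subject_once(id, group, affected),
                      error = function(e) {
                        if (grepl("constructibility", conditionMessage(e))) NULL else stop(e)
                      })
      if (!is.null(res)) return(res)
    }
    stop("constructibility error persisted for subject ", id, call. = FALSE)
  }

  sample_subject_once <- function(id, group, affected) {
    bil <- cranio[!cranio$measure %in% c("nasal_deviation", "chin_deviation"), ]
    if (group == "ULS") {
      tg_r <- tibble::tibble(measure = bil$measure, side = "right",
                             value = rnorm_trunc(nrow(bil), bil$mean_ipsi, bil$sd_ipsi))
      tg_l <- tibble::tibble(measure = bil$measure, side = "left",
                             value = rnorm_trunc(nrow(bil), bil$mean_contra, bil$sd_contra))
      dev <- cranio[cranio$measure %in% c("nasal_deviation", "chin_deviation"), ]
      tg_d <- tibble::tibble(measure = dev$measure, side = "midline",
                             value = rnorm_trunc(nrow(dev), dev$mean_contra, dev$sd_contra))
      # canonical build is right-affected; mirror afterwards if left-affected
      lms <- inverse_place_landmarks(dplyr::bind_rows(tg_r, tg_l, tg_d),
                                     affected_side = "right")
      if (affected == "left") {
        lms <- mirror_subject(lms, plane(c(0, 0, 0), c(1, 0, 0)))
      }
      vol_vals <- tibble::tibble(
        measure = rep(vols$measure, 2),
        side = rep(c("ipsilateral", "contralateral"), each = nrow(vols)),
        value = c(rnorm_trunc(nrow(vols), vols$mean_ipsi, vols$sd_ipsi),
                  rnorm_trunc(nrow(vols), vols$mean_contra, vols$sd_contra)),
        unit = rep(vols$unit, 2)
      )
    } else {
      tg_r <- tibble::tibble(measure = bil$measure, side = "right",
                             value = rnorm_trunc(nrow(bil), bil$mean_control, bil$sd_control))
      tg_l <- tibble::tibble(measure = bil$measure, side = "left",
                             value = rnorm_trunc(nrow(bil), bil$mean_control, bil$sd_control))
      lms <- inverse_place_landmarks(dplyr::bind_rows(tg_r, tg_l),
                                     affected_side = "none")
      vol_vals <- tibble::tibble(
        measure = rep(vols$measure, 2),
        side = rep(c("left", "right"), each = nrow(vols)),
        value = c(rnorm_trunc(nrow(vols), vols$mean_control, vols$sd_control),
                  rnorm_trunc(nrow(vols), vols$mean_control, vols$sd_control)),
        unit = rep(vols$unit, 2)
      )
    }
    aff <- if (group == "ULS") affected else "none"
    mt <- measure_all(lms, subject_id = id, group = group, affected_side = aff)
    vol_vals <- dplyr::mutate(vol_vals, subject = id, group = !!group,
                              affected_side = !!aff)
    mt <- dplyr::bind_rows(mt, vol_vals)
    list(lms = lms, mt = mt)
  }

  for (i in seq_len(spec$n_uls)) {
    id <- sprintf("uls_%02d", i)
    res <- sample_subject(id, "ULS", sides_of[i])
    subjects[[id]] <- res$lms
    measurements[[id]] <- res$mt
  }
  for (i in seq_len(spec$n_control)) {
    id <- sprintf("ctl_%02d", i)
    res <- sample_subject(id, "control", "none")
    subjects[[id]] <- res$lms
    measurements[[id]] <- res$mt
  }
  measurements <- dplyr::bind_rows(measurements)

  # replicate protocol: craniometric distances/angles only
  cranio_rows <- dplyr::filter(measurements, !.data$measure %in% volume_measures())
  n <- nrow(cranio_rows)
  rec <- tidyr::expand_grid(i = seq_len(n), rater = 1:2, replicate = 1:3)
  bias_key <- paste(cranio_rows$subject[rec$i], cranio_rows$measure[rec$i],
                    cranio_rows$side[rec$i], rec$rater)
  ukey <- unique(bias_key)
  bias <- stats::setNames(stats::rnorm(length(ukey), 0, spec$rater_bias_sd), ukey)
  records <- tibble::tibble(
    subject = cranio_rows$subject[rec$i],
    group = cranio_rows$group[rec$i],
    affected_side = cranio_rows$affected_side[rec$i],
    measure = cranio_rows$measure[rec$i],
    side = cranio_rows$side[rec$i],
    unit = cranio_rows$unit[rec$i],
    rater = rec$rater, replicate = rec$replicate,
    value = cranio_rows$value[rec$i] + bias[bias_key] +
      stats::rnorm(nrow(rec), 0, spec$replicate_sd)
  )
  list(measurements = measurements, records = records, subjects = subjects)
}
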