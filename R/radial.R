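#' Equal-angle spherical direction grid
#'
#' Azimuth is measured in the axial plane from anterior (+y) toward the right
#' (+x); elevation from the axial plane toward superior (+z). The default
#' 2-degree spacing gives 180 x 90 directions.
#'
#' @param spacing_deg Angular spacing in degrees (must divide 360 and 180).
#' @return Tibble with `azimuth_deg`, `elevation_deg` and unit direction
#'   columns `ux`, `uy`, `uz`.
#' @export
radial_grid <- function(spacing_deg = 2) {
  stopifnot(spacing_deg > 0, 360 %% spacing_deg == 0, 180 %% spacing_deg == 0)
  az <- seq(0, 360 - spacing_deg, by = spacing_deg)
  el <- seq(-90 + spacing_deg / 2, 90 - spacing_deg / 2, by = spacing_deg)
  g <- tidyr::expand_grid(azimuth_deg = az, elevation_deg = el)
  a <- g$azimuth_deg * pi / 180; e <- g$elevation_deg * pi / 180
  dplyr::mutate(g, ux = cos(e) * sin(a), uy = cos(e) * cos(a), uz = sin(e))
}

# parity test: is `p` inside the closed surface? An oblique ray direction
# avoids grazing the edges of symmetric meshes; coincident hits (shared
# edges/vertices) are collapsed before counting.
point_in_mesh <- function(surf, p) {
  dir <- matrix(c(0.12793471, 0.64208966, 0.75591631), 1)
  t <- ray_mesh_intersections(surf, p, dir)[[1]]
  if (length(t) > 1) t <- t[c(TRUE, diff(t) > 1e-7 * max(t))]
  length(t) %% 2 == 1
}

# Moeller-Trumbore, vectorised over rays inside a loop over faces.
# Returns, per ray, the sorted vector of positive ray parameters t.
ray_mesh_intersections <- function(surf, origin, dirs) {
  v <- surf$vertices; f <- surf$faces
  nr <- nrow(dirs)
  hits <- vector("list", nr)
  for (i in seq_len(nr)) hits[[i]] <- numeric(0)
  eps <- 1e-12
  for (fi in seq_len(nrow(f))) {
    a <- v[f[fi, 1], ]; b <- v[f[fi, 2], ]; cc <- v[f[fi, 3], ]
    e1 <- b - a; e2 <- cc - a
    # pvec = dir x e2 for all rays
    px <- dirs[, 2] * e2[3] - dirs[, 3] * e2[2]
    py <- dirs[, 3] * e2[1] - dirs[, 1] * e2[3]
    pz <- dirs[, 1] * e2[2] - dirs[, 2] * e2[1]
    det <- e1[1] * px + e1[2] * py + e1[3] * pz
    ok <- abs(det) > eps
    if (!any(ok)) next
    tv <- origin - a
    u <- (tv[1] * px + tv[2] * py + tv[3] * pz) / det
    qx <- tv[2] * e1[3] - tv[3] * e1[2]
    qy <- tv[3] * e1[1] - tv[1] * e1[3]
    qz <- tv[1] * e1[2] - tv[2] * e1[1]
    w <- (dirs[, 1] * qx + dirs[, 2] * qy + dirs[, 3] * qz) / det
    t <- (e2[1] * qx + e2[2] * qy + e2[3] * qz) / det
    sel <- which(ok & u >= -1e-9 & w >= -1e-9 & (u + w) <= 1 + 1e-9 & t > 1e-9)
    for (i in sel) hits[[i]] <- c(hits[[i]], t[i])
  }
  lapply(hits, sort)
}

#' Tragi-centered radial distance map
#'
#' For each grid direction, the distance from the inter-tragi midpoint to the
#' surface along that direction. The default takes the first ray-surface
#' intersection; `mode = "farthest"` takes the last, for surfaces that are not
#' star-shaped about the center. Directions with no intersection are flagged
#' as misses, not zero-filled.
#'
#' @param surf Head `triangle_surface` enclosing the inter-tragi midpoint.
#' @param lms A `landmark_set` with both tragi.
#' @param grid Direction grid from [radial_grid()].
#' @param mode `"first"` or `"farthest"`.
#' @return A `radial_map` tibble: grid columns plus `radius_mm` and `hit`,
#'   with the center stored in `attr(, "center")`.
#' @export
radial_map <- function(surf, lms, grid = radial_grid(2), mode = c("first", "farthest")) {
  mode <- match.arg(mode)
  center <- (lm_point(lms, "tragus", "left") + lm_point(lms, "tragus", "right")) / 2
  if (!point_in_mesh(surf, center)) {
    stop("geometry error: inter-tragi center lies outside the surface", call. = FALSE)
  }
  dirs <- as.matrix(grid[, c("ux", "uy", "uz")])
  hits <- ray_mesh_intersections(surf, center, dirs)
  radius <- vapply(hits, function(h) {
    if (!length(h)) return(NA_real_)
    if (mode == "first") h[1] else h[length(h)]
  }, numeric(1))
  out <- dplyr::mutate(grid, radius_mm = radius, hit = !is.na(radius))
  attr(out, "center") <- center
  class(out) <- c("radial_map", class(tibble::tibble()))
  out
}

check_shared_grid <- function(maps) {
  ref <- maps[[1]][, c("azimuth_deg", "elevation_deg")]
  same <- vapply(maps, function(m) {
    nrow(m) == nrow(ref) &&
      all(m$azimuth_deg == ref$azimuth_deg) &&
      all(m$elevation_deg == ref$elevation_deg)
  }, logical(1))
  if (!all(same)) stop("radial maps do not share one direction grid", call. = FALSE)
  invisible(ref)
}

#' Composite (average) radial map
#'
#' Per-direction arithmetic mean over the subjects that have coverage there.
#' Subjects must already be in a common frame (rigid landmark registration,
#' left-affected subjects mirrored first).
#'
#' @param maps List of `radial_map`s sharing one grid.
#' @return A `radial_map` with `radius_mm` = per-direction mean, plus an
#'   `n_subjects` coverage count.
#' @export
composite_map <- function(maps) {
  stopifnot(length(maps) >= 1)
  check_shared_grid(maps)
  radii <- vapply(maps, function(m) m$radius_mm, numeric(nrow(maps[[1]])))
  radii <- matrix(radii, nrow = nrow(maps[[1]]))
  n <- rowSums(!is.na(radii))
  mean_r <- rowMeans(radii, na.rm = TRUE)
  mean_r[n == 0] <- NA_real_
  out <- maps[[1]]
  out$radius_mm <- mean_r
  out$hit <- n > 0
  out$n_subjects <- n
  out
}

#' Signed group-difference heat map
#'
#' Per-direction difference of group mean radii (A minus B): positive values
#' are projection of group A relative to B, negative retrusion. Defined only
#' where both groups have coverage.
#'
#' @param group_a,group_b Lists of `radial_map`s on one shared grid.
#' @return A `cranio_heatmap` tibble: grid columns, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`, `delta_mm`.
#' @export
heat_map <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop("heat map requires at least one subject per group", call. = FALSE)
  }
  check_shared_grid(c(group_a, group_b))
  ca <- composite_map(group_a); cb <- composite_map(group_b)
  out <- ca[, c("azimuth_deg", "elevation_deg", "ux", "uy", "uz")]
  out$mean_a <- ca$radius_mm; out$mean_b <- cb$radius_mm
  out$n_a <- ca$n_subjects; out$n_b <- cb$n_subjects
  out$delta_mm <- ifelse(ca$hit & cb$hit, ca$radius_mm - cb$radius_mm, NA_real_)
  class(out) <- c("cranio_heatmap", class(tibble::tibble()))
  out
}

# bilinear interpolation of a heat map at arbitrary (azimuth, elevation)
interp_heatmap <- function(heat, az_deg, el_deg) {
  az_lv <- sort(unique(heat$azimuth_deg))
  el_lv <- sort(unique(heat$elevation_deg))
  step_az <- az_lv[2] - az_lv[1]; step_el <- el_lv[2] - el_lv[1]
  grid <- matrix(NA_real_, length(az_lv), length(el_lv))
  grid[cbind(match(heat$azimuth_deg, az_lv), match(heat$elevation_deg, el_lv))] <- heat$delta_mm
  az <- az_deg %% 360
  ia <- floor((az - az_lv[1]) / step_az)
  fa <- (az - az_lv[1]) / step_az - ia
  i0 <- (ia %% length(az_lv)) + 1
  i1 <- ((ia + 1) %% length(az_lv)) + 1
  el <- pmin(pmax(el_deg, el_lv[1]), el_lv[length(el_lv)])
  je <- pmin(floor((el - el_lv[1]) / step_el), length(el_lv) - 2)
  fe <- (el - el_lv[1]) / step_el - je
  j0 <- je + 1; j1 <- je + 2
  g <- function(i, j) grid[cbind(i, j)]
  (1 - fa) * (1 - fe) * g(i0, j0) + fa * (1 - fe) * g(i1, j0) +
    (1 - fa) * fe * g(i0, j1) + fa * fe * g(i1, j1)
}

#' Export a heat map onto a reference mesh
#'
#' Writes an ASCII PLY whose per-vertex scalar (`delta`) is the heat-map
#' difference bilinearly interpolated at each vertex's direction from the
#' center. Colormap styling is left to the viewer.
#'
#' @param heat A `cranio_heatmap`.
#' @param reference_surf `triangle_surface` to annotate.
#' @param center Length-3 center the directions are taken from.
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
export_heatmap_mesh <- function(heat, reference_surf, center, path) {
  v <- sweep(reference_surf$vertices, 2, center)
  r_ax <- sqrt(v[, 1]^2 + v[, 2]^2)
  az <- (atan2(v[, 1], v[, 2]) * 180 / pi) %% 360
  el <- atan2(v[, 3], r_ax) * 180 / pi
  scalars <- interp_heatmap(heat, az, el)
  scalars[is.na(scalars)] <- 0
  write_ply(reference_surf, path, vertex_scalar = scalars, scalar_name = "delta")
  invisible(path)
}

#' Plot a heat map as an azimuth-elevation tile panel
#'
#' @param object A `cranio_heatmap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cranio_heatmap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$azimuth_deg, .data$elevation_deg,
                                       fill = .data$delta_mm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  name = "Δ radius (mm)") +
    ggplot2::labs(x = "azimuth (°, 0 = anterior, 90 = right)",
                  y = "elevation (°)",
                  title = "Radial difference map (projection > 0, retrusion < 0)") +
    ggplot2::theme_minimal()
}
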