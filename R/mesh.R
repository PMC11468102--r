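#' Triangle surface mesh
#'
#' Minimal mesh container: an N x 3 vertex matrix (mm) and an M x 3 face index
#' matrix (1-based). Volumetric operations additionally require the mesh to be
#' watertight (every edge shared by exactly two consistently oriented faces).
#'
#' @param vertices N x 3 numeric matrix, mm.
#' @param faces M x 3 integer matrix of vertex indices.
#' @return A `triangle_surface`.
#' @export
triangle_surface <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates", call. = FALSE)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_surface")
}

#' @export
print.triangle_surface <- function(x, ...) {
  cat(sprintf("<triangle_surface: %d vertices, %d faces, watertight: %s>\n",
              nrow(x$vertices), nrow(x$faces), is_watertight(x)))
  invisible(x)
}

# directed edge multiset; watertight iff every directed edge appears once and
# its reverse appears once
edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  list(fwd = paste(e[, 1], e[, 2]), rev = paste(e[, 2], e[, 1]))
}

#' Is a mesh watertight?
#'
#' @param surf A `triangle_surface`.
#' @return Logical.
#' @export
is_watertight <- function(surf) {
  open_edge_count(surf) == 0L
}

open_edge_count <- function(surf) {
  if (nrow(surf$faces) == 0) return(1L)
  ek <- edge_keys(surf$faces)
  if (anyDuplicated(ek$fwd)) return(sum(duplicated(ek$fwd)))
  sum(!(ek$fwd %in% ek$rev))
}

#' Enclosed volume of a watertight mesh
#'
#' Signed-tetrahedron (divergence theorem) sum; the absolute value is returned
#' so a globally inverted mesh yields the same magnitude.
#'
#' @param surf A watertight `triangle_surface` in mm.
#' @param units `"cm3"` (default) or `"mm3"`.
#' @return Volume (cm^3 by default).
#' @export
#' @examples
#' cube <- make_box(c(10, 10, 10))
#' mesh_volume(cube)  # 1 cm^3
mesh_volume <- function(surf, units = c("cm3", "mm3")) {
  units <- match.arg(units)
  oc <- open_edge_count(surf)
  if (oc > 0L) {
    stop(sprintf("volumetry error: mesh is not watertight (%d open/inconsistent edges)", oc),
         call. = FALSE)
  }
  v <- surf$vertices; f <- surf$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  # scalar triple product a . (b x c), vectorised over faces
  det6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
          a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  vol <- abs(sum(det6)) / 6
  if (units == "cm3") vol / 1000 else vol
}

#' Axis-aligned box mesh
#'
#' @param size Length-3 edge lengths (mm).
#' @param center Length-3 center (mm).
#' @return A watertight `triangle_surface` (12 triangles).
#' @export
make_box <- function(size = c(1, 1, 1), center = c(0, 0, 0)) {
  h <- size / 2
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- sweep(as.matrix(s) * matrix(h, 8, 3, byrow = TRUE), 2, center, "+")
  # outward-oriented quads of the unit cube (indices into the expand.grid order)
  quads <- rbind(
    c(1, 3, 4, 2), # z-
    c(5, 6, 8, 7), # z+
    c(1, 2, 6, 5), # y-
    c(3, 7, 8, 4), # y+
    c(1, 5, 7, 3), # x-
    c(2, 4, 8, 6)  # x+
  )
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  triangle_surface(v, f)
}

#' Unit-sphere mesh by latitude/longitude subdivision
#'
#' Longitude columns at azimuth 0 and 180 degrees lie exactly in the x = 0
#' plane, so a midsagittal cut passes through vertices, never through face
#' interiors. Used as the base shape for phantom heads and region solids.
#'
#' @param n_lat Number of latitude bands (>= 3).
#' @param n_lon Number of longitude columns (even, >= 8).
#' @return A watertight `triangle_surface` with unit radius.
#' @export
make_uv_sphere <- function(n_lat = 32, n_lon = 64) {
  stopifnot(n_lat >= 3, n_lon >= 8, n_lon %% 2 == 0)
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 1)[-c(1, n_lat + 1)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  grid <- expand.grid(lon = lon, lat = lat)
  ring <- cbind(
    x = cos(grid$lat) * sin(grid$lon),
    y = cos(grid$lat) * cos(grid$lon),
    z = sin(grid$lat)
  )
  v <- rbind(c(0, 0, -1), ring, c(0, 0, 1))
  south <- 1L
  north <- nrow(v)
  idx <- function(i_lat, j_lon) 1L + (i_lat - 1L) * n_lon + ((j_lon - 1L) %% n_lon) + 1L
  f <- vector("list", 0)
  # south cap (lat band 1)
  f[[length(f) + 1]] <- do.call(rbind, lapply(seq_len(n_lon), function(j) {
    c(south, idx(1, j + 1), idx(1, j))
  }))
  # body quads
  if (n_lat - 1 >= 2) {
    for (i in seq_len(n_lat - 2)) {
      f[[length(f) + 1]] <- do.call(rbind, lapply(seq_len(n_lon), function(j) {
        a <- idx(i, j); b <- idx(i, j + 1); cc <- idx(i + 1, j + 1); d <- idx(i + 1, j)
        rbind(c(a, b, cc), c(a, cc, d))
      }))
    }
  }
  # north cap
  f[[length(f) + 1]] <- do.call(rbind, lapply(seq_len(n_lon), function(j) {
    c(north, idx(n_lat - 1, j), idx(n_lat - 1, j + 1))
  }))
  triangle_surface(v, do.call(rbind, f))
}

#' Ellipsoid mesh
#'
#' @param semi_axes Length-3 semi-axes (mm).
#' @param center Length-3 center (mm).
#' @param n_lat,n_lon Sphere subdivision (see [make_uv_sphere()]).
#' @return A watertight `triangle_surface`.
#' @export
make_ellipsoid <- function(semi_axes, center = c(0, 0, 0), n_lat = 32, n_lon = 64) {
  s <- make_uv_sphere(n_lat, n_lon)
  v <- sweep(s$vertices * matrix(semi_axes, nrow(s$vertices), 3, byrow = TRUE),
             2, center, "+")
  triangle_surface(v, s$faces)
}

scale_mesh <- function(surf, factor, center = c(0, 0, 0)) {
  if (length(factor) == 1) factor <- rep(factor, 3)
  v <- sweep(surf$vertices, 2, center)
  v <- v * matrix(factor, nrow(v), 3, byrow = TRUE)
  triangle_surface(sweep(v, 2, center, "+"), surf$faces)
}
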