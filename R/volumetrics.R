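#' Split a watertight mesh by a plane
#'
#' Triangles crossing the plane are subdivided exactly at the intersection,
#' and each half is capped with an ear-clipped triangulation of the closed
#' intersection polygon(s), so both halves are watertight and their volumes
#' sum to the whole (the cap triangles of the two halves cancel in the signed
#' volume sum). Vertices within `eps` of the plane are treated as on-plane.
#'
#' @param surf A watertight `triangle_surface`.
#' @param pl The cutting `cranio_plane`.
#' @param eps On-plane snapping tolerance (mm); default scales with the mesh.
#' @return List with `positive` and `negative` `triangle_surface`s (sides by
#'   the plane normal). A side the plane misses comes back as an empty mesh.
#' @export
split_by_plane <- function(surf, pl, eps = NULL) {
  oc <- open_edge_count(surf)
  if (oc > 0L) {
    stop(sprintf("volumetry error: mesh is not watertight (%d open/inconsistent edges)", oc),
         call. = FALSE)
  }
  V <- surf$vertices
  if (is.null(eps)) {
    eps <- 1e-9 * max(1, vnorm(apply(V, 2, max) - apply(V, 2, min)))
  }
  d <- plane_distance(V, pl)
  d[abs(d) <= eps] <- 0

  n_orig <- nrow(V)
  extra <- list()        # new intersection vertices
  emap <- new.env(parent = emptyenv())  # edge key -> new vertex index
  edge_cut <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    key <- paste(a, b)
    hit <- emap[[key]]
    if (!is.null(hit)) return(hit)
    t <- d[a] / (d[a] - d[b])
    p <- V[a, ] + t * (V[b, ] - V[a, ])
    extra[[length(extra) + 1]] <<- p
    idx <- n_orig + length(extra)
    emap[[key]] <- idx
    idx
  }

  clip_side <- function(tri, sgn) {
    # Sutherland-Hodgman of one triangle against the half-space sgn*d >= 0
    out <- integer(0)
    for (k in 1:3) {
      a <- tri[k]; b <- tri[if (k == 3) 1 else k + 1]
      da <- sgn * d[a]; db <- sgn * d[b]
      if (da >= 0) out <- c(out, a)
      if ((da > 0 && db < 0) || (da < 0 && db > 0)) out <- c(out, edge_cut(a, b))
    }
    out[!duplicated(out)]
  }

  pos_faces <- list(); neg_faces <- list()
  add_poly <- function(poly, store) {
    if (length(poly) < 3) return(store)
    for (k in 2:(length(poly) - 1)) {
      store[[length(store) + 1]] <- c(poly[1], poly[k], poly[k + 1])
    }
    store
  }

  F <- surf$faces
  for (fi in seq_len(nrow(F))) {
    tri <- F[fi, ]
    dt <- d[tri]
    if (all(dt >= 0) && any(dt > 0)) {
      pos_faces[[length(pos_faces) + 1]] <- tri
    } else if (all(dt <= 0) && any(dt < 0)) {
      neg_faces[[length(neg_faces) + 1]] <- tri
    } else if (all(dt == 0)) {
      # degenerate: triangle lying in the cutting plane; keep with positive side
      pos_faces[[length(pos_faces) + 1]] <- tri
    } else {
      pos_faces <- add_poly(clip_side(tri, 1), pos_faces)
      neg_faces <- add_poly(clip_side(tri, -1), neg_faces)
    }
  }

  V_all <- if (length(extra)) rbind(V, do.call(rbind, extra)) else V
  pos_f <- if (length(pos_faces)) do.call(rbind, pos_faces) else matrix(integer(0), 0, 3)
  neg_f <- if (length(neg_faces)) do.call(rbind, neg_faces) else matrix(integer(0), 0, 3)

  if (nrow(pos_f) > 0 && nrow(neg_f) > 0) {
    loops <- boundary_loops(pos_f)
    caps <- cap_faces(loops, V_all, pl)
    if (nrow(caps) > 0) {
      pos_f <- rbind(pos_f, caps[, c(1, 3, 2), drop = FALSE])  # outward = -normal side
      neg_f <- rbind(neg_f, caps)
    }
  }
  list(
    positive = compact_surface(V_all, pos_f),
    negative = compact_surface(V_all, neg_f)
  )
}

compact_surface <- function(V, F) {
  if (nrow(F) == 0) {
    return(triangle_surface(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  used <- sort(unique(as.integer(F)))
  remap <- integer(nrow(V)); remap[used] <- seq_along(used)
  triangle_surface(V[used, , drop = FALSE],
                   matrix(remap[as.integer(F)], ncol = 3))
}

# closed loops of directed boundary edges (edges lacking a reverse partner)
boundary_loops <- function(F) {
  ek <- edge_keys(F)
  open <- !(ek$fwd %in% ek$rev)
  if (!any(open)) return(list())
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])[open, , drop = FALSE]
  nxt <- stats::setNames(e[, 2], as.character(e[, 1]))
  seen <- stats::setNames(rep(FALSE, nrow(e)), as.character(e[, 1]))
  loops <- list()
  for (start in as.character(e[, 1])) {
    if (seen[[start]]) next
    loop <- integer(0)
    cur <- start
    repeat {
      if (is.na(nxt[cur]) || seen[[cur]]) break
      seen[[cur]] <- TRUE
      loop <- c(loop, as.integer(cur))
      cur <- as.character(nxt[[cur]])
      if (cur == start) break
    }
    if (length(loop) >= 3 && cur == start) loops[[length(loops) + 1]] <- loop
  }
  loops
}

# triangulate each boundary loop inside the plane; triangles returned with the
# loop's winding (caller orients per side). Loops come from the positive
# piece's open boundary, traversed so the cap with reversed winding closes it.
cap_faces <- function(loops, V, pl) {
  if (!length(loops)) return(matrix(integer(0), 0, 3))
  n <- pl$normal
  e1 <- if (abs(n[1]) < 0.9) unitize(cross3(n, c(1, 0, 0))) else unitize(cross3(n, c(0, 1, 0)))
  e2 <- cross3(n, e1)
  out <- list()
  for (loop in loops) {
    pts <- V[loop, , drop = FALSE]
    p2 <- cbind(pts %*% e1, pts %*% e2)
    tri <- triangulate_polygon2d(p2)
    if (nrow(tri)) out[[length(out) + 1]] <- matrix(loop[tri], ncol = 3)
  }
  if (!length(out)) return(matrix(integer(0), 0, 3))
  do.call(rbind, out)
}

# Ear clipping of a simple polygon given as an n x 2 matrix in traversal
# order; returns index triples with the same winding as the input.
triangulate_polygon2d <- function(p) {
  n <- nrow(p)
  if (n < 3) return(matrix(integer(0), 0, 3))
  area2 <- sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])
  s <- if (area2 >= 0) 1 else -1
  idx <- seq_len(n)
  tris <- list()
  cross_z <- function(a, b, cc) {
    (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
  }
  inside <- function(a, b, cc, q) {
    d1 <- cross_z(a, b, q); d2 <- cross_z(b, cc, q); d3 <- cross_z(cc, a, q)
    (d1 * s > 0) && (d2 * s > 0) && (d3 * s > 0)
  }
  guard <- 0
  while (length(idx) > 3 && guard < 10 * n) {
    m <- length(idx)
    clipped <- FALSE
    for (k in seq_len(m)) {
      i0 <- idx[if (k == 1) m else k - 1]; i1 <- idx[k]; i2 <- idx[if (k == m) 1 else k + 1]
      a <- p[i0, ]; b <- p[i1, ]; cc <- p[i2, ]
      if (cross_z(a, b, cc) * s <= 0) next
      others <- setdiff(idx, c(i0, i1, i2))
      blocked <- FALSE
      for (q in others) {
        if (inside(a, b, cc, p[q, ])) { blocked <- TRUE; break }
      }
      if (!blocked) {
        tris[[length(tris) + 1]] <- c(i0, i1, i2)
        idx <- idx[-k]
        clipped <- TRUE
        break
      }
    }
    if (!clipped) { # numerically degenerate; clip the widest convex corner
      best <- which.max(vapply(seq_along(idx), function(k) {
        m <- length(idx)
        i0 <- idx[if (k == 1) m else k - 1]; i1 <- idx[k]; i2 <- idx[if (k == m) 1 else k + 1]
        cross_z(p[i0, ], p[i1, ], p[i2, ]) * s
      }, numeric(1)))
      m <- length(idx)
      i0 <- idx[if (best == 1) m else best - 1]; i1 <- idx[best]
      i2 <- idx[if (best == m) 1 else best + 1]
      tris[[length(tris) + 1]] <- c(i0, i1, i2)
      idx <- idx[-best]
    }
    guard <- guard + 1
  }
  tris[[length(tris) + 1]] <- idx
  do.call(rbind, tris)
}

#' Split plane through the anterior nasal spine and sella
#'
#' The left/right partition plane of the anterior fossa: it contains ANS and
#' sella, with normal equal to the midsagittal normal projected orthogonal to
#' the ANS-to-sella direction (identical to the midsagittal plane when both
#' points are midline).
#'
#' @param lms A `landmark_set` with `ans`, `sella` (and the midsagittal
#'   support points).
#' @param midsag Optional midsagittal plane; built from `lms` if omitted.
#' @return A `cranio_plane` with normal toward the anatomical right.
#' @export
ans_sella_plane <- function(lms, midsag = build_midsagittal_plane(lms)) {
  a <- lm_point(lms, "ans"); s <- lm_point(lms, "sella")
  u <- unitize(a - s)
  n <- midsag$normal - sum(midsag$normal * u) * u
  plane(s, n)
}

#' Left/right anterior fossa volumes
#'
#' Splits a watertight anterior-fossa solid along the ANS-sella plane and
#' reports both side volumes in cm^3. Sides are labeled by the sign of each
#' half's centroid against the plane normal (anatomical right is positive).
#'
#' @param fossa_surf Watertight `triangle_surface` of the anterior fossa solid.
#' @param lms A `landmark_set` with `ans`, `sella`, `nasion`, `basion`.
#' @return A tibble with columns `region`, `side`, `volume_cm3`.
#' @export
anterior_fossa_volumes <- function(fossa_surf, lms) {
  pl <- ans_sella_plane(lms)
  halves <- split_by_plane(fossa_surf, pl)
  vol_of <- function(h) if (nrow(h$faces) == 0) 0 else mesh_volume(h)
  tibble::tibble(
    region = "anterior_fossa",
    side = c("right", "left"),
    volume_cm3 = c(vol_of(halves$positive), vol_of(halves$negative))
  )
}

#' Volume of a labeled region submesh
#'
#' Region segmentation (orbital aperture, zygomatic sutures, ...) happens
#' upstream or synthetically; this computes the enclosed volume of the
#' submesh. The mandibular left/right split is done here, with a plane
#' through the symphysis parallel to the midsagittal plane.
#'
#' @param surf Watertight region `triangle_surface`.
#' @param region One of `"anterior_fossa"`, `"orbit"`, `"zygoma"`,
#'   `"mandible"`.
#' @param side `"left"`, `"right"`, or `"both"` (mandible only: splits at the
#'   symphysis and returns both rows).
#' @param lms `landmark_set`, required for the mandible split.
#' @return A tibble with columns `region`, `side`, `volume_cm3`.
#' @export
region_volume <- function(surf, region = c("anterior_fossa", "orbit", "zygoma", "mandible"),
                          side = "both", lms = NULL) {
  region <- match.arg(region)
  if (nrow(surf$faces) == 0) {
    stop("volumetry error: empty region submesh for ", region, call. = FALSE)
  }
  if (region == "mandible" && side == "both") {
    if (is.null(lms)) stop("mandible split requires a landmark set", call. = FALSE)
    midsag <- build_midsagittal_plane(lms)
    pl <- plane(lm_point(lms, "symphysis"), midsag$normal)
    halves <- split_by_plane(surf, pl)
    vol_of <- function(h) if (nrow(h$faces) == 0) 0 else mesh_volume(h)
    return(tibble::tibble(
      region = region, side = c("right", "left"),
      volume_cm3 = c(vol_of(halves$positive), vol_of(halves$negative))
    ))
  }
  tibble::tibble(region = region, side = side, volume_cm3 = mesh_volume(surf))
}
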