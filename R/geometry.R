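#' Geometric planes
#'
#' A plane is stored as an origin point plus a unit normal (mm, RAS frame).
#'
#' @param origin Length-3 point on the plane.
#' @param normal Length-3 normal; normalised internally.
#' @return A `cranio_plane` object.
#' @export
plane <- function(origin, normal) {
  origin <- as.numeric(origin); normal <- as.numeric(normal)
  stopifnot(length(origin) == 3, length(normal) == 3,
            all(is.finite(origin)), all(is.finite(normal)))
  n <- sqrt(sum(normal^2))
  if (n < 1e-12) stop("degenerate plane normal", call. = FALSE)
  structure(list(origin = origin, normal = normal / n), class = "cranio_plane")
}

#' @export
print.cranio_plane <- function(x, ...) {
  cat(sprintf("<plane: origin (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f)>\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Signed distance of points to a plane
#'
#' @param p Point (length 3) or N x 3 matrix.
#' @param pl A `cranio_plane`.
#' @return Signed distance(s) in mm, positive on the normal side.
#' @export
plane_distance <- function(p, pl) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  as.numeric((p - matrix(pl$origin, nrow(p), 3, byrow = TRUE)) %*% pl$normal)
}

vnorm <- function(v) sqrt(sum(v^2))
unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector", call. = FALSE)
  v / n
}
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Euclidean distance between two points
#'
#' @param a,b Length-3 points (mm).
#' @return Distance in mm.
#' @export
point_point_distance <- function(a, b) {
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  vnorm(as.numeric(a) - as.numeric(b))
}

#' Angle at a vertex between two rays
#'
#' The planar angle a-vertex-b, e.g. the horizontal orbital angle ZF-OF-N.
#'
#' @param a,vertex,b Length-3 points (mm).
#' @return Angle in degrees, in \[0, 180\].
#' @export
three_point_angle <- function(a, vertex, b) {
  u <- unitize(as.numeric(a) - as.numeric(vertex))
  v <- unitize(as.numeric(b) - as.numeric(vertex))
  d <- max(-1, min(1, sum(u * v)))
  acos(d) * 180 / pi
}

#' Angle between a line segment and a plane
#'
#' Used for the nasal (nasion-ANS) and chin (ANS-symphysis) deviations against
#' the midsagittal plane. The unsigned angle is in \[0, 90\]: 0 when the segment
#' lies parallel to the plane, 90 along the normal.
#'
#' @param p1,p2 Segment endpoints (mm).
#' @param pl A `cranio_plane`.
#' @param signed If `TRUE`, the sign of the normal component is kept
#'   (positive toward the plane's normal side).
#' @return Angle in degrees.
#' @export
line_plane_angle <- function(p1, p2, pl, signed = FALSE) {
  d <- unitize(as.numeric(p2) - as.numeric(p1))
  s <- sum(d * pl$normal)
  ang <- asin(min(1, abs(s))) * 180 / pi
  if (signed && s < 0) -ang else ang
}

#' Construct the midsagittal plane
#'
#' Primary rule: the plane through nasion, sella and basion. If any of the
#' three is absent, falls back to the best-fit symmetry plane of the bilateral
#' landmark pairs (normal = principal direction of the left-to-right
#' difference vectors, origin = mean of pair midpoints and midline points).
#' The normal is oriented toward the anatomical right, resolved from the
#' bilateral landmarks when present.
#'
#' @param lms A `landmark_set`.
#' @return A `cranio_plane`.
#' @export
build_midsagittal_plane <- function(lms) {
  has <- function(nm) any(lms$name == nm & lms$side == "midline")
  bil <- bilateral_pairs(lms)
  if (has("nasion") && has("sella") && has("basion")) {
    n0 <- lm_point(lms, "nasion"); s0 <- lm_point(lms, "sella")
    b0 <- lm_point(lms, "basion")
    nrm <- cross3(s0 - n0, b0 - n0)
    if (vnorm(nrm) < 1e-9) {
      stop("nasion, sella and basion are collinear; cannot build midsagittal plane",
           call. = FALSE)
    }
    pl <- plane(s0, nrm)
  } else {
    if (nrow(bil) < 3) {
      stop("landmark-completeness error: need nasion, sella and basion, or >= 3 ",
           "bilateral landmark pairs, to build the midsagittal plane", call. = FALSE)
    }
    d <- as.matrix(bil[, c("dx", "dy", "dz")])
    m <- as.matrix(bil[, c("mx", "my", "mz")])
    mid <- lms[lms$side == "midline", c("x", "y", "z")]
    ctr <- colMeans(rbind(m, as.matrix(mid)))
    ev <- eigen(crossprod(d), symmetric = TRUE)
    pl <- plane(ctr, ev$vectors[, 1])
  }
  orient_plane_right(pl, lms, bil)
}

# left->right difference and midpoint per bilateral pair present on both sides
bilateral_pairs <- function(lms) {
  wide <- dplyr::inner_join(
    dplyr::filter(lms, .data$side == "left"),
    dplyr::filter(lms, .data$side == "right"),
    by = "name", suffix = c("_l", "_r")
  )
  tibble::tibble(
    name = wide$name,
    dx = wide$x_r - wide$x_l, dy = wide$y_r - wide$y_l, dz = wide$z_r - wide$z_l,
    mx = (wide$x_r + wide$x_l) / 2, my = (wide$y_r + wide$y_l) / 2,
    mz = (wide$z_r + wide$z_l) / 2
  )
}

orient_plane_right <- function(pl, lms, bil = bilateral_pairs(lms)) {
  if (nrow(bil) > 0) {
    right_dir <- colMeans(as.matrix(bil[, c("dx", "dy", "dz")]))
    if (sum(right_dir * pl$normal) < 0) pl$normal <- -pl$normal
  } else if (pl$normal[1] < 0) {
    pl$normal <- -pl$normal
  }
  pl
}

#' Construct the axial reference plane
#'
#' Plane through sella whose normal is the cross product of the midsagittal
#' normal and the anterior direction (sella to nasion, projected off the
#' midsagittal normal). Angles of the form "midsagittal plane - sella - X"
#' are measured inside this plane.
#'
#' @param lms A `landmark_set` containing nasion and sella.
#' @param midsag Midsagittal `cranio_plane`.
#' @return A `cranio_plane`.
#' @export
build_axial_plane <- function(lms, midsag = build_midsagittal_plane(lms)) {
  s0 <- lm_point(lms, "sella"); n0 <- lm_point(lms, "nasion")
  ant <- n0 - s0
  ant <- ant - sum(ant * midsag$normal) * midsag$normal
  plane(s0, cross3(midsag$normal, unitize(ant)))
}

# anterior unit direction inside the axial plane
anterior_axis <- function(lms, midsag, axial) {
  s0 <- lm_point(lms, "sella"); n0 <- lm_point(lms, "nasion")
  ant <- n0 - s0
  ant <- ant - sum(ant * midsag$normal) * midsag$normal
  unitize(ant - sum(ant * axial$normal) * axial$normal)
}

#' Axial-projected angle from the anterior midsagittal direction
#'
#' Projects the vertex-to-target ray into the axial plane and measures its
#' angle from the anterior midsagittal direction. Values exceed 90 degrees
#' when the target lies posterior to the coronal plane through the vertex
#' (the mandibular angle does).
#'
#' @param vertex Apex point, normally sella (mm).
#' @param target Target point (mm).
#' @param midsag,axial Midsagittal and axial `cranio_plane`s.
#' @param anterior Anterior unit direction in the axial plane.
#' @return Angle in degrees, in \[0, 180\].
#' @export
axial_projected_angle <- function(vertex, target, midsag, axial, anterior) {
  v <- as.numeric(target) - as.numeric(vertex)
  v <- v - sum(v * axial$normal) * axial$normal
  if (vnorm(v) < 1e-9) {
    stop("degenerate geometry: target projects onto the vertex", call. = FALSE)
  }
  d <- max(-1, min(1, sum(unitize(v) * anterior)))
  acos(d) * 180 / pi
}

#' Reflect a subject across a plane
#'
#' Mirrors landmark positions and (optionally) a surface across the plane,
#' swapping left/right side labels and re-fixing face orientation to outward.
#' The operation is an involution.
#'
#' @param lms A `landmark_set`.
#' @param midsag The mirror `cranio_plane` (normally midsagittal).
#' @param surf Optional `triangle_surface` to mirror alongside.
#' @return The mirrored `landmark_set`, or `list(landmarks=, surface=)` when a
#'   surface is supplied.
#' @export
mirror_subject <- function(lms, midsag, surf = NULL) {
  pos <- as.matrix(lms[, c("x", "y", "z")])
  d <- plane_distance(pos, midsag)
  refl <- pos - 2 * outer(d, midsag$normal)
  out <- lms
  out$x <- refl[, 1]; out$y <- refl[, 2]; out$z <- refl[, 3]
  out$side <- ifelse(out$side == "left", "right",
                     ifelse(out$side == "right", "left", "midline"))
  if (is.null(surf)) return(out)
  v <- surf$vertices
  dv <- plane_distance(v, midsag)
  v2 <- v - 2 * outer(dv, midsag$normal)
  surf2 <- triangle_surface(v2, surf$faces[, c(1, 3, 2), drop = FALSE])
  list(landmarks = out, surface = surf2)
}

#' Least-squares rigid alignment of two landmark sets
#'
#' Kabsch algorithm: the rotation + translation (no scaling) minimising the
#' summed squared distance between shared landmarks.
#'
#' @param moving,fixed `landmark_set`s sharing at least 3 non-collinear points.
#' @param names Optional canonical names to restrict the correspondence to.
#' @return A `rigid_transform`: list with 3x3 `rotation`, length-3
#'   `translation`, and `rmsd` residual (mm). Apply with
#'   [apply_rigid_transform()].
#' @export
rigid_align_landmarks <- function(moving, fixed, names = NULL) {
  key <- function(l) paste(l$name, l$side)
  shared <- intersect(key(moving), key(fixed))
  if (!is.null(names)) {
    shared <- shared[sub(" .*", "", shared) %in% names]
  }
  if (length(shared) < 3) {
    stop("alignment error: fewer than 3 shared landmarks", call. = FALSE)
  }
  M <- as.matrix(moving[match(shared, key(moving)), c("x", "y", "z")])
  F <- as.matrix(fixed[match(shared, key(fixed)), c("x", "y", "z")])
  cm <- colMeans(M); cf <- colMeans(F)
  Mc <- sweep(M, 2, cm); Fc <- sweep(F, 2, cf)
  if (qr(Mc)$rank < 2) {
    stop("alignment error: shared landmarks are collinear", call. = FALSE)
  }
  H <- crossprod(Mc, Fc)
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- unname(cf - as.numeric(R %*% cm))
  resid <- sqrt(mean(rowSums((Fc - Mc %*% t(R))^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = resid),
            class = "rigid_transform")
}

#' Apply a rigid transform
#'
#' @param x A `landmark_set`, `triangle_surface`, or N x 3 matrix / length-3
#'   point.
#' @param tf A `rigid_transform` from [rigid_align_landmarks()].
#' @return The transformed object.
#' @export
apply_rigid_transform <- function(x, tf) {
  mv <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 3)
    sweep(p %*% t(tf$rotation), 2, tf$translation, "+")
  }
  if (inherits(x, "landmark_set")) {
    p <- mv(as.matrix(x[, c("x", "y", "z")]))
    x$x <- p[, 1]; x$y <- p[, 2]; x$z <- p[, 3]
    return(x)
  }
  if (inherits(x, "triangle_surface")) {
    return(triangle_surface(mv(x$vertices), x$faces))
  }
  out <- mv(x)
  if (length(out) == 3) as.numeric(out) else out
}
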