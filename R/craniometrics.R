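#' @keywords internal
measure_units <- function() {
  c(fossa_angle = "deg", orbital_height = "mm", orbital_width = "mm",
    orbital_depth = "mm", horizontal_orbital_angle = "deg",
    vertical_orbital_angle = "deg", zygomatic_length = "mm",
    zygomatic_height = "mm", zygomatic_angle = "deg",
    nasal_deviation = "deg", maxillary_angle = "deg", ramus_length = "mm",
    body_length = "mm", mandibular_angle = "deg", chin_deviation = "deg")
}

#' Names of the bilateral craniometric measures
#' @return Character vector (the two midline deviations excluded).
#' @export
bilateral_measures <- function() {
  setdiff(names(measure_units()), c("nasal_deviation", "chin_deviation"))
}

measure_frames <- function(lms) {
  midsag <- build_midsagittal_plane(lms)
  axial <- build_axial_plane(lms, midsag)
  list(midsag = midsag, axial = axial,
       anterior = anterior_axis(lms, midsag, axial))
}

per_side <- function(values_by_side) {
  tibble::tibble(
    side = rep(c("left", "right"), each = length(values_by_side$left)),
    measure = rep(names(values_by_side$left), 2),
    value = unname(c(unlist(values_by_side$left), unlist(values_by_side$right)))
  )
}

#' Anterior fossa angle
#'
#' Angle between the lesser-wing line (medial to lateral point of the lesser
#' sphenoid wing) and the midsagittal plane, measured in the axial-plane
#' projection. 0 degrees means the wing points straight anterior; larger
#' values indicate a more posterior sweep of the wing.
#'
#' @param lms A `landmark_set`.
#' @param frames Optional precomputed reference frames.
#' @return Tibble with `side`, `measure`, `value` (degrees).
#' @export
measure_fossa_angle <- function(lms, frames = measure_frames(lms)) {
  one <- function(side) {
    p <- lm_points(lms, c("lesser_wing_medial", "lesser_wing_lateral"), side)
    w <- p[2, ] - p[1, ]
    w <- w - sum(w * frames$axial$normal) * frames$axial$normal
    if (vnorm(w) < 1e-9) {
      stop("degenerate geometry: lesser-wing line projects to a point", call. = FALSE)
    }
    asin(min(1, abs(sum(unitize(w) * frames$midsag$normal)))) * 180 / pi
  }
  tibble::tibble(side = c("left", "right"), measure = "fossa_angle",
                 value = c(one("left"), one("right")))
}

#' Orbital measures
#'
#' Height = ZM-SN, width = ZF-nasion, depth = ZM-optic foramen (mm);
#' horizontal angle = ZF-OF-N, vertical angle = ZM-OF-SN (degrees).
#'
#' @inheritParams measure_fossa_angle
#' @return Tibble with `side`, `measure`, `value`, five measures per side.
#' @export
measure_orbit <- function(lms, frames = NULL) {
  n0 <- lm_point(lms, "nasion")
  one <- function(side) {
    p <- lm_points(lms, c("zm", "sn", "zf", "of"), side)
    list(
      orbital_height = point_point_distance(p["zm", ], p["sn", ]),
      orbital_width = point_point_distance(p["zf", ], n0),
      orbital_depth = point_point_distance(p["zm", ], p["of", ]),
      horizontal_orbital_angle = three_point_angle(p["zf", ], p["of", ], n0),
      vertical_orbital_angle = three_point_angle(p["zm", ], p["of", ], p["sn", ])
    )
  }
  per_side(list(left = one("left"), right = one("right")))
}

#' Zygomatic measures
#'
#' Length = ZM-ZT, height = ZF to lowest zygoma point (mm); angle =
#' axial-projected angle midsagittal plane - sella - ZM (degrees).
#'
#' @inheritParams measure_fossa_angle
#' @return Tibble with `side`, `measure`, `value`.
#' @export
measure_zygoma <- function(lms, frames = measure_frames(lms)) {
  s0 <- lm_point(lms, "sella")
  one <- function(side) {
    p <- lm_points(lms, c("zm", "zt", "zf", "zygoma_lowest"), side)
    list(
      zygomatic_length = point_point_distance(p["zm", ], p["zt", ]),
      zygomatic_height = point_point_distance(p["zf", ], p["zygoma_lowest", ]),
      zygomatic_angle = axial_projected_angle(s0, p["zm", ], frames$midsag,
                                              frames$axial, frames$anterior)
    )
  }
  per_side(list(left = one("left"), right = one("right")))
}

#' Maxillary angle
#'
#' Axial-projected angle midsagittal plane - sella - pterygoid hamulus.
#'
#' @inheritParams measure_fossa_angle
#' @return Tibble with `side`, `measure`, `value` (degrees).
#' @export
measure_maxilla <- function(lms, frames = measure_frames(lms)) {
  s0 <- lm_point(lms, "sella")
  one <- function(side) {
    h <- lm_point(lms, "pterygoid_hamulus", side)
    axial_projected_angle(s0, h, frames$midsag, frames$axial, frames$anterior)
  }
  tibble::tibble(side = c("left", "right"), measure = "maxillary_angle",
                 value = c(one("left"), one("right")))
}

#' Mandibular measures
#'
#' Ramus length = mandibular notch to gonion, body length = gonion to
#' parasymphysis (mm); mandibular angle = axial-projected angle midsagittal
#' plane - sella - articular fossa (degrees; exceeds 90 when the fossa lies
#' posterior to the coronal plane through sella).
#'
#' @inheritParams measure_fossa_angle
#' @return Tibble with `side`, `measure`, `value`.
#' @export
measure_mandible <- function(lms, frames = measure_frames(lms)) {
  s0 <- lm_point(lms, "sella")
  one <- function(side) {
    p <- lm_points(lms, c("mandibular_notch", "gonion", "parasymphysis",
                          "articular_fossa"), side)
    list(
      ramus_length = point_point_distance(p["mandibular_notch", ], p["gonion", ]),
      body_length = point_point_distance(p["gonion", ], p["parasymphysis", ]),
      mandibular_angle = axial_projected_angle(s0, p["articular_fossa", ],
                                               frames$midsag, frames$axial,
                                               frames$anterior)
    )
  }
  per_side(list(left = one("left"), right = one("right")))
}

#' Nasal and chin midline deviations
#'
#' Nasal deviation is the angle of the nasion-to-ANS line to the midsagittal
#' plane; chin deviation the angle of the ANS-to-symphysis line. With a known
#' affected side the sign is positive toward the contralateral side; without
#' one the unsigned magnitude is returned with a warning.
#'
#' @inheritParams measure_fossa_angle
#' @param affected_side `"left"`, `"right"`, or `"none"` (controls).
#' @return Tibble with `side = "midline"`, `measure`, `value` (degrees).
#' @export
measure_deviations <- function(lms, affected_side = c("none", "left", "right"),
                               frames = measure_frames(lms)) {
  affected_side <- match.arg(affected_side)
  n0 <- lm_point(lms, "nasion"); a0 <- lm_point(lms, "ans")
  s0 <- lm_point(lms, "symphysis")
  nasal <- line_plane_angle(n0, a0, frames$midsag, signed = TRUE)
  chin <- line_plane_angle(a0, s0, frames$midsag, signed = TRUE)
  # plane normal points right: positive-toward-contralateral means flip when
  # the affected (ipsilateral) side is left
  if (affected_side == "none") {
    if (abs(nasal) > 1e-12 || abs(chin) > 1e-12) {
      warning("no affected side given; deviations reported unsigned", call. = FALSE)
    }
    nasal <- abs(nasal); chin <- abs(chin)
  } else {
    flip <- if (affected_side == "right") -1 else 1
    nasal <- flip * nasal; chin <- flip * chin
  }
  tibble::tibble(side = "midline",
                 measure = c("nasal_deviation", "chin_deviation"),
                 value = c(nasal, chin))
}

#' All craniometric measures for one subject
#'
#' Runs every measurement and, for affected subjects, re-keys left/right to
#' ipsilateral/contralateral (ipsilateral = affected side).
#'
#' @param lms A complete `landmark_set`.
#' @param subject_id Subject identifier.
#' @param group `"ULS"` or `"control"`.
#' @param affected_side `"left"`, `"right"`, or `"none"`.
#' @return A `measurement_table` tibble: `subject`, `group`, `affected_side`,
#'   `measure`, `side` (left/right for controls, ipsilateral/contralateral for
#'   affected subjects, midline for deviations), `value`, `unit`.
#' @export
#' @examples
#' lms <- default_landmarks()
#' measure_all(lms, subject_id = "s1", group = "control")
measure_all <- function(lms, subject_id = "subject", group = "control",
                        affected_side = c("none", "left", "right")) {
  affected_side <- match.arg(affected_side)
  frames <- measure_frames(lms)
  out <- dplyr::bind_rows(
    measure_fossa_angle(lms, frames),
    measure_orbit(lms),
    measure_zygoma(lms, frames),
    measure_maxilla(lms, frames),
    measure_mandible(lms, frames),
    measure_deviations(lms, affected_side, frames)
  )
  if (affected_side %in% c("left", "right")) {
    contra <- if (affected_side == "left") "right" else "left"
    out$side <- dplyr::case_when(
      out$side == affected_side ~ "ipsilateral",
      out$side == contra ~ "contralateral",
      TRUE ~ out$side
    )
  }
  out <- dplyr::mutate(
    out,
    subject = subject_id, group = group, affected_side = affected_side,
    unit = measure_units()[.data$measure], .before = 1
  )
  out <- out[, c("subject", "group", "affected_side", "measure", "side", "value", "unit")]
  class(out) <- c("measurement_table", class(tibble::tibble()))
  out
}
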