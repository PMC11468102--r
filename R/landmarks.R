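#' Anatomical landmark registry
#'
#' Controlled vocabulary of the craniofacial landmarks used by every
#' measurement in the package. Bilateral landmarks exist as left/right pairs;
#' midline landmarks never carry a side. Basion is carried solely as a
#' midsagittal support point for plane construction and enters no measure.
#'
#' @return A tibble with columns `name`, `bilateral` (logical) and
#'   `description`.
#' @export
#' @examples
#' landmark_registry()
landmark_registry <- function() {
  tibble::tribble(
    ~name,                ~bilateral, ~description,
    "nasion",             FALSE, "midline junction of frontal and nasal bones",
    "sella",              FALSE, "center of the sella turcica",
    "basion",             FALSE, "anterior rim of the foramen magnum",
    "ans",                FALSE, "anterior nasal spine",
    "symphysis",          FALSE, "midline point of the mandibular symphysis",
    "zm",                 TRUE,  "zygomaticomaxillary suture point",
    "sn",                 TRUE,  "supraorbital notch",
    "zf",                 TRUE,  "zygomaticofrontal suture point",
    "of",                 TRUE,  "optic foramen",
    "zt",                 TRUE,  "zygomaticotemporal suture point",
    "zygoma_lowest",      TRUE,  "lowest point of the zygoma",
    "lesser_wing_medial", TRUE,  "medial point of the lesser sphenoid wing",
    "lesser_wing_lateral",TRUE,  "lateral point of the lesser sphenoid wing",
    "pterygoid_hamulus",  TRUE,  "pterygoid hamulus",
    "mandibular_notch",   TRUE,  "deepest point of the mandibular notch",
    "gonion",             TRUE,  "mandibular angle point",
    "parasymphysis",      TRUE,  "parasymphysis point of the mandibular body",
    "articular_fossa",    TRUE,  "articular (glenoid) fossa of the TMJ",
    "tragus",             TRUE,  "tragus"
  )
}

# Alias table for external files (Slicer labels, long names, case variants).
# Side suffixes (_L/_R/-left/...) are stripped before lookup.
landmark_aliases <- function() {
  c(
    "n" = "nasion", "nasion" = "nasion",
    "s" = "sella", "sella" = "sella", "sella_turcica" = "sella",
    "ba" = "basion", "basion" = "basion",
    "ans" = "ans", "anterior_nasal_spine" = "ans",
    "symphysis" = "symphysis", "menton" = "symphysis", "pog" = "symphysis",
    "zm" = "zm", "zygomaticomaxillary" = "zm",
    "sn" = "sn", "supraorbital_notch" = "sn",
    "zf" = "zf", "zygomaticofrontal" = "zf",
    "of" = "of", "optic_foramen" = "of",
    "zt" = "zt", "zygomaticotemporal" = "zt",
    "zygoma_lowest" = "zygoma_lowest", "lowest_zygoma" = "zygoma_lowest",
    "lesser_wing_medial" = "lesser_wing_medial",
    "lesser_wing_lateral" = "lesser_wing_lateral",
    "pterygoid_hamulus" = "pterygoid_hamulus", "hamulus" = "pterygoid_hamulus",
    "mandibular_notch" = "mandibular_notch", "notch" = "mandibular_notch",
    "gonion" = "gonion", "go" = "gonion", "mandibular_angle" = "gonion",
    "parasymphysis" = "parasymphysis",
    "articular_fossa" = "articular_fossa", "glenoid_fossa" = "articular_fossa",
    "tragus" = "tragus", "t" = "tragus"
  )
}

#' Resolve a landmark name against the registry
#'
#' Normalises case/separators, applies the alias table, and fails with
#' nearest-name suggestions for unknown labels.
#'
#' @param name Character label, e.g. `"Nasion"` or `"optic foramen"`.
#' @return Canonical registry name.
#' @export
resolve_landmark_name <- function(name) {
  key <- gsub("[ .-]+", "_", tolower(trimws(name)))
  al <- landmark_aliases()
  if (key %in% names(al)) return(unname(al[key]))
  reg <- landmark_registry()$name
  if (key %in% reg) return(key)
  near <- agrep(key, reg, max.distance = 0.3, value = TRUE)
  stop(sprintf(
    "unknown landmark name '%s'%s", name,
    if (length(near)) paste0("; did you mean: ", paste(near, collapse = ", "), "?") else ""
  ), call. = FALSE)
}

#' Build a landmark set
#'
#' A landmark set is a tibble with one row per named anatomical point, columns
#' `name`, `side` (`"left"`, `"right"` or `"midline"`) and coordinates
#' `x`, `y`, `z` in millimetres. The internal frame is right-handed RAS:
#' +x anatomical right, +y anterior, +z superior.
#'
#' @param df Data frame with columns `name`, `side`, `x`, `y`, `z`.
#' @return A validated `landmark_set` tibble.
#' @export
#' @examples
#' landmark_set(data.frame(
#'   name = c("nasion", "sella"), side = "midline",
#'   x = 0, y = c(45, 0), z = c(18, 0)
#' ))
landmark_set <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("name", "side", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("landmark set lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(df[need])
  out$name <- vapply(out$name, resolve_landmark_name, character(1))
  out$side <- tolower(out$side)
  validate_landmark_set(out)
  class(out) <- c("landmark_set", class(tibble::tibble()))
  out
}

validate_landmark_set <- function(lms) {
  reg <- landmark_registry()
  bad_side <- !lms$side %in% c("left", "right", "midline")
  if (any(bad_side)) {
    stop("invalid side label(s): ", paste(unique(lms$side[bad_side]), collapse = ", "),
         call. = FALSE)
  }
  bilat <- stats::setNames(reg$bilateral, reg$name)
  mism <- (lms$side == "midline") != !bilat[lms$name]
  if (any(mism)) {
    stop("side label inconsistent with registry for: ",
         paste(unique(lms$name[mism]), collapse = ", "), call. = FALSE)
  }
  key <- paste(lms$name, lms$side)
  if (anyDuplicated(key)) {
    stop("duplicate landmark(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  pos <- as.matrix(lms[, c("x", "y", "z")])
  if (!all(is.finite(pos))) stop("non-finite landmark coordinates", call. = FALSE)
  invisible(lms)
}

#' Extract one landmark position
#'
#' @param lms A `landmark_set`.
#' @param name Canonical landmark name.
#' @param side `"left"`, `"right"` or `"midline"` (default for midline points).
#' @return Numeric length-3 position (mm).
#' @export
lm_point <- function(lms, name, side = "midline") {
  i <- which(lms$name == name & lms$side == side)
  if (length(i) != 1L) {
    stop(sprintf("missing landmark: %s (%s)", name, side), call. = FALSE)
  }
  c(lms$x[i], lms$y[i], lms$z[i])
}

# Fetch several landmarks at once; error names every absent point.
lm_points <- function(lms, names, side) {
  key_have <- paste(lms$name, lms$side)
  key_want <- paste(names, side)
  absent <- which(!key_want %in% key_have)
  if (length(absent)) {
    stop("missing landmark(s): ",
         paste(sprintf("%s (%s)", names[absent], side), collapse = ", "),
         call. = FALSE)
  }
  i <- match(key_want, key_have)
  m <- as.matrix(lms[i, c("x", "y", "z")])
  rownames(m) <- names
  m
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set: %d points (mm, RAS frame)>\n", nrow(x)))
  NextMethod()
}
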