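#' Read landmarks from JSON or Slicer FCSV
#'
#' JSON files hold an array of `{name, side, x, y, z}` objects (mm, RAS).
#' Slicer fiducial FCSV files are accepted too: labels are resolved through
#' the registry alias table, side suffixes (`_L`/`_R`, `-left`/`-right`, ...)
#' are stripped to the `side` field, and LPS coordinates are converted to the
#' internal RAS frame when the file header declares LPS.
#'
#' @param path `.json` or `.fcsv` file.
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = read_landmarks_json(path),
    fcsv = read_landmarks_fcsv(path),
    stop("unsupported landmark format '.", ext, "' (use json or fcsv): ", path,
         call. = FALSE)
  )
}

read_landmarks_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  need <- c("name", "side", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("landmark JSON lacks fields: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  landmark_set(df)
}

#' Write landmarks to JSON
#'
#' @param lms A `landmark_set`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lms, path) {
  jsonlite::write_json(as.data.frame(lms[, c("name", "side", "x", "y", "z")]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

split_label_side <- function(label) {
  lab <- trimws(label)
  side <- "midline"
  m <- regexpr("[_-](l|r|left|right)$", tolower(lab))
  if (m > 0) {
    suffix <- substring(tolower(lab), m + 1)
    side <- if (suffix %in% c("l", "left")) "left" else "right"
    lab <- substring(lab, 1, m - 1)
  }
  list(name = lab, side = side)
}

read_landmarks_fcsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cs <- grep("CoordinateSystem", lines, value = TRUE)
  lps <- length(cs) > 0 && grepl("LPS|= ?0", cs[1])
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("FCSV file has no fiducial rows: ", path, call. = FALSE)
  df <- utils::read.csv(text = body, header = FALSE, stringsAsFactors = FALSE)
  # Slicer fiducial columns: id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,assoc
  if (ncol(df) < 12) stop("unrecognised FCSV layout: ", path, call. = FALSE)
  parts <- lapply(df[[12]], split_label_side)
  out <- tibble::tibble(
    name = vapply(parts, `[[`, character(1), "name"),
    side = vapply(parts, `[[`, character(1), "side"),
    x = as.numeric(df[[2]]), y = as.numeric(df[[3]]), z = as.numeric(df[[4]])
  )
  if (lps) {
    out$x <- -out$x; out$y <- -out$y
  }
  # a bilateral name with no side suffix is resolved by the sign of x
  reg <- landmark_registry()
  canon <- vapply(out$name, resolve_landmark_name, character(1))
  bilat <- stats::setNames(reg$bilateral, reg$name)[canon]
  fix <- bilat & out$side == "midline"
  out$side[fix] <- ifelse(out$x[fix] >= 0, "right", "left")
  landmark_set(out)
}
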