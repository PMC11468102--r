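#' Read a triangle mesh (STL, PLY, OBJ)
#'
#' Binary and ASCII STL, ASCII PLY, and OBJ are supported. Coordinates are
#' assumed to be millimetres; pass `scale` to convert (e.g. 1000 for metres).
#'
#' @param path Mesh file path; format inferred from the extension.
#' @param scale Multiplier applied to all coordinates on read.
#' @return A `triangle_surface`.
#' @export
read_mesh <- function(path, scale = 1) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  surf <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path)$surface,
    obj = read_obj(path),
    stop("unsupported mesh format '.", ext, "' (use stl, ply or obj): ", path,
         call. = FALSE)
  )
  if (scale != 1) surf <- triangle_surface(surf$vertices * scale, surf$faces)
  surf
}

#' Write a triangle mesh (STL, PLY, OBJ)
#'
#' @param surf A `triangle_surface` (mm).
#' @param path Output path; format from the extension. STL is written ASCII by
#'   default (`binary = TRUE` for binary STL).
#' @param binary Write binary STL.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(surf, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = if (binary) write_stl_binary(surf, path) else write_stl_ascii(surf, path),
    ply = write_ply(surf, path),
    obj = write_obj(surf, path),
    stop("unsupported mesh format '.", ext, "' (use stl, ply or obj): ", path,
         call. = FALSE)
  )
  invisible(path)
}

# STL stores loose triangles; weld identical vertices back together
weld_vertices <- function(tri_verts) {
  key <- paste(tri_verts[, 1], tri_verts[, 2], tri_verts[, 3])
  idx <- match(key, key[!duplicated(key)])
  v <- tri_verts[!duplicated(key), , drop = FALSE]
  f <- matrix(idx, ncol = 3, byrow = TRUE)
  triangle_surface(v, f)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  n_tri <- readBin(con, "integer", 1, size = 4, endian = "little")
  sz <- file.size(path)
  close(con)
  if (!is.na(n_tri) && sz == 84 + 50 * n_tri) return(read_stl_binary(path, n_tri))
  first <- tolower(trimws(readLines(path, n = 1, warn = FALSE)))
  if (startsWith(first, "solid")) return(read_stl_ascii(path))
  stop("corrupt STL file (neither valid binary nor ASCII): ", path, call. = FALSE)
}

read_stl_binary <- function(path, n_tri) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 84)
  rec <- readBin(con, "raw", 50 * n_tri)
  m <- matrix(rec, nrow = 50)
  coords <- vapply(seq_len(n_tri), function(i) {
    readBin(m[13:48, i], "numeric", 9, size = 4, endian = "little")
  }, numeric(9))
  verts <- matrix(as.numeric(coords), ncol = 3, byrow = TRUE)
  weld_vertices(verts)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4])))
  if (nrow(nums) %% 3 != 0) stop("corrupt ASCII STL: ", path, call. = FALSE)
  weld_vertices(nums)
}

write_stl_ascii <- function(surf, path) {
  v <- surf$vertices; f <- surf$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid cranioshape", con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    n <- cross3(b - a, cc - a)
    nn <- vnorm(n); if (nn > 0) n <- n / nn
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %.17g %.17g %.17g", a[1], a[2], a[3]),
      sprintf("      vertex %.17g %.17g %.17g", b[1], b[2], b[3]),
      sprintf("      vertex %.17g %.17g %.17g", cc[1], cc[2], cc[3]),
      "    endloop",
      "  endfacet"
    ), con)
  }
  writeLines("endsolid cranioshape", con)
}

write_stl_binary <- function(surf, path) {
  v <- surf$vertices; f <- surf$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; cc <- v[f[i, 3], ]
    n <- cross3(b - a, cc - a)
    nn <- vnorm(n); if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, a, b, cc)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- strsplit(trimws(grep("^v\\s", lines, value = TRUE)), "\\s+")
  v <- do.call(rbind, lapply(vl, function(x) as.numeric(x[2:4])))
  fl <- strsplit(trimws(grep("^f\\s", lines, value = TRUE)), "\\s+")
  f <- do.call(rbind, lapply(fl, function(x) {
    idx <- as.integer(sub("/.*", "", x[-1]))
    if (length(idx) != 3) stop("only triangle faces supported in OBJ", call. = FALSE)
    idx
  }))
  triangle_surface(v, f)
}

write_obj <- function(surf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", surf$vertices[, 1], surf$vertices[, 2],
                     surf$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", surf$faces[, 1], surf$faces[, 2],
                     surf$faces[, 3]), con)
}

#' Write an ASCII PLY mesh, optionally with a per-vertex scalar
#'
#' @param surf A `triangle_surface`.
#' @param path Output `.ply` path.
#' @param vertex_scalar Optional numeric per-vertex scalar.
#' @param scalar_name Property name for the scalar.
#' @return `path`, invisibly.
#' @export
write_ply <- function(surf, path, vertex_scalar = NULL, scalar_name = "quality") {
  v <- surf$vertices; f <- surf$faces
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z")
  if (!is.null(vertex_scalar)) {
    stopifnot(length(vertex_scalar) == nrow(v))
    hdr <- c(hdr, sprintf("property double %s", scalar_name))
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (is.null(vertex_scalar)) {
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  } else {
    writeLines(sprintf("%.17g %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3],
                       vertex_scalar), con)
  }
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh (with any per-vertex scalars)
#'
#' @param path `.ply` path.
#' @return List with `surface` (`triangle_surface`) and `scalars` (tibble of
#'   extra per-vertex properties, zero columns if none).
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "ply") stop("not a PLY file: ", path, call. = FALSE)
  if (!grepl("ascii", lines[2])) stop("only ASCII PLY supported: ", path, call. = FALSE)
  end <- match("end_header", lines)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vi <- grep("^element vertex", hdr)
  fi <- grep("^element face", hdr)
  vprops <- sub(".* ", "", grep("^property (double|float)", hdr[vi:fi], value = TRUE))
  vlines <- lines[(end + 1):(end + nv)]
  vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
  colnames(vm) <- vprops
  flines <- lines[(end + nv + 1):(end + nv + nf)]
  fm <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(x) as.integer(x[2:4]) + 1L))
  extra <- setdiff(vprops, c("x", "y", "z"))
  list(
    surface = triangle_surface(vm[, c("x", "y", "z"), drop = FALSE], fm),
    scalars = tibble::as_tibble(as.data.frame(vm[, extra, drop = FALSE]))
  )
}
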