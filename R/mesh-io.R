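# Mesh readers/writers for STL (ASCII and binary), OBJ and PLY (ASCII).
# All readers return geometry in metres; `units` declares the file's units.

#' Load a triangle mesh from STL, OBJ or PLY
#'
#' STL stores a triangle soup, so coincident vertices are welded on load
#' (tolerance 1e-9 m).  OBJ 1-based and PLY 0-based face indexing are both
#' normalised to the package's 1-based convention.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"obj"`, `"ply"`; guessed from the file
#'   extension when missing.
#' @param units units the file's coordinates are expressed in: `"m"`
#'   (default), `"mm"` or `"cm"`.  Coordinates are converted to metres.
#' @param name mesh identifier; defaults to the file name.
#' @return a [trimesh()].
#' @export
load_mesh <- function(path, format = NULL, units = "m", name = NULL) {
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
  }
  format <- match.arg(tolower(format), c("stl", "obj", "ply"))
  scale <- unit_scale(units)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  mesh <- switch(format,
                 stl = read_stl(path, name),
                 obj = read_obj(path, name),
                 ply = read_ply(path, name))
  if (scale != 1) mesh$vertices <- mesh$vertices * scale
  mesh
}

#' Write a triangle mesh to STL, OBJ or PLY
#'
#' @param mesh a [trimesh()].
#' @param path output file path.
#' @param format one of `"stl"`, `"obj"`, `"ply"`; guessed from the extension
#'   when missing.
#' @param units units to write the coordinates in (converted from metres).
#' @param binary write binary STL instead of ASCII (STL only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, units = "m", binary = FALSE) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("stl", "obj", "ply"))
  out <- mesh
  out$vertices <- mesh$vertices / unit_scale(units)
  switch(format,
         stl = write_stl(out, path, binary = binary),
         obj = write_obj(out, path),
         ply = write_ply(out, path))
  invisible(path)
}

# -- STL ----------------------------------------------------------------------

is_binary_stl <- function(path) {
  size <- file.info(path)$size
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  # A binary STL's size is exactly 84 + 50 * ntri.
  isTRUE(size == 84 + 50 * ntri)
}

read_stl <- function(path, name) {
  tri <- if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
  if (nrow(tri) == 0L) stopf("STL file '%s' contains no triangles", path)
  welded <- weld_soup(tri, tol = 1e-9)
  trimesh(welded$vertices, matrix(welded$index, ncol = 3L, byrow = TRUE),
          name = name)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L) {
    stopf("malformed ASCII STL file: %s", path)
  }
  nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(tok) {
    as.numeric(tok[2:4])
  })
  m <- do.call(rbind, nums)
  if (any(!is.finite(m))) stopf("malformed ASCII STL file: %s", path)
  m
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(ntri) || ntri < 1L) stopf("malformed binary STL file: %s", path)
  # Records are 50 bytes: 12 little-endian floats + a uint16 attribute.
  raw <- readBin(con, "raw", n = 50L * ntri)
  if (length(raw) < 50L * ntri) stopf("truncated binary STL file: %s", path)
  tri <- matrix(0, nrow = 3L * ntri, ncol = 3L)
  for (i in seq_len(ntri)) {
    chunk <- raw[((i - 1L) * 50L + 1L):((i - 1L) * 50L + 48L)]
    vals <- readBin(chunk, "numeric", n = 12L, size = 4L, endian = "little")
    tri[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], ncol = 3L, byrow = TRUE)
  }
  tri
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- face_normals(mesh)
  len <- row_norms(nrm)
  len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], t(v[f[i, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  } else {
    lines <- character(7L * nrow(f) + 2L)
    lines[1L] <- sprintf("solid %s", mesh$name)
    k <- 2L
    for (i in seq_len(nrow(f))) {
      lines[k] <- sprintf("  facet normal %.9e %.9e %.9e",
                          nrm[i, 1L], nrm[i, 2L], nrm[i, 3L])
      lines[k + 1L] <- "    outer loop"
      for (j in 1:3) {
        p <- v[f[i, j], ]
        lines[k + 1L + j] <- sprintf("      vertex %.9e %.9e %.9e",
                                     p[1L], p[2L], p[3L])
      }
      lines[k + 5L] <- "    endloop"
      lines[k + 6L] <- "  endfacet"
      k <- k + 7L
    }
    lines[k] <- sprintf("endsolid %s", mesh$name)
    writeLines(lines, path)
  }
  invisible(path)
}

# -- OBJ ----------------------------------------------------------------------

read_obj <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(flines) == 0L) {
    stopf("OBJ file '%s' has no usable geometry", path)
  }
  v <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(tok) {
    as.numeric(tok[2:4])
  }))
  if (any(!is.finite(v))) stopf("malformed OBJ file: %s", path)
  faces <- list()
  for (fl in flines) {
    tok <- strsplit(trimws(fl), "\\s+")[[1L]][-1L]
    idx <- as.integer(vapply(strsplit(tok, "/"), `[[`, "", 1L))
    idx[idx < 0L] <- nrow(v) + 1L + idx[idx < 0L]  # negative = relative
    if (length(idx) < 3L || any(is.na(idx))) stopf("malformed OBJ face in %s", path)
    # fan-triangulate polygons
    for (j in 2:(length(idx) - 1L)) {
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[j], idx[j + 1L])
    }
  }
  trimesh(v, do.call(rbind, faces), name = name)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  lines <- c(sprintf("o %s", mesh$name),
             sprintf("v %.9e %.9e %.9e", v[, 1L], v[, 2L], v[, 3L]),
             sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]))
  writeLines(lines, path)
  invisible(path)
}

# -- PLY (ASCII) --------------------------------------------------------------

read_ply <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L || trimws(lines[1L]) != "ply") {
    stopf("not a PLY file: %s", path)
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stopf("malformed PLY header in %s", path)
  header <- trimws(lines[seq_len(end)])
  if (any(grepl("^format\\s+binary", header))) {
    stopf("binary PLY is not supported: %s", path)
  }
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex\\s", header, value = TRUE)[1L]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face\\s", header, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf)) stopf("malformed PLY header in %s", path)
  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stopf("truncated PLY file: %s", path)
  v <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                             function(tok) as.numeric(tok[1:3])))
  faces <- list()
  for (fl in body[(nv + 1L):(nv + nf)]) {
    tok <- as.integer(strsplit(trimws(fl), "\\s+")[[1L]])
    k <- tok[1L]
    idx <- tok[2:(k + 1L)] + 1L  # PLY is 0-based
    for (j in 2:(k - 1L)) {
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[j], idx[j + 1L])
    }
  }
  trimesh(v, do.call(rbind, faces), name = name)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  header <- c("ply", "format ascii 1.0",
              sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices",
              "end_header")
  writeLines(c(header,
               sprintf("%.9e %.9e %.9e", v[, 1L], v[, 2L], v[, 3L]),
               sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)),
             path)
  invisible(path)
}

# Weld a triangle soup (3 rows per triangle) into shared vertices.
weld_soup <- function(points, tol) {
  key <- if (tol > 0) {
    apply(round(points / tol), 1L, paste, collapse = ",")
  } else {
    apply(points, 1L, paste, collapse = ",")
  }
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(vertices = points[first, , drop = FALSE], index = map)
}
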