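#' Read a triangulated surface mesh
#'
#' Supports ASCII and binary STL, ASCII PLY, and legacy ASCII VTK polydata.
#' STL files carry no shared connectivity, so coincident vertices are merged
#' on read. Non-triangular cells are rejected.
#'
#' @param path file path.
#' @param format `"auto"` (from extension/content), `"stl"`, `"ply"` or
#'   `"vtk"`.
#' @param ... passed to [surface_mesh()] (e.g. `drop_degenerate`).
#' @return a [surface_mesh()]. For VTK input, any point-data arrays are
#'   attached as the `"point_data"` attribute (a named list).
#' @export
read_surface_mesh <- function(path, format = c("auto", "stl", "ply", "vtk"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, stl = "stl", ply = "ply", vtk = "vtk",
                     stop("cannot infer mesh format from extension: ", ext))
  }
  switch(format,
         stl = read_stl(path, ...),
         ply = read_ply(path, ...),
         vtk = read_vtk_polydata(path, ...))
}

#' Write a surface mesh
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param format `"stl"` (ASCII), `"ply"` (ASCII) or `"vtk"` (legacy ASCII
#'   polydata).
#' @param point_data named list of per-vertex numeric vectors, written as
#'   VTK point-data arrays (ignored for STL/PLY).
#' @export
write_surface_mesh <- function(mesh, path, format = c("vtk", "stl", "ply"),
                               point_data = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  format <- match.arg(format)
  switch(format,
         stl = write_stl(mesh, path),
         ply = write_ply(mesh, path),
         vtk = write_vtk_polydata(mesh, path, point_data))
  invisible(path)
}

# ---- STL ----------------------------------------------------------------

read_stl <- function(path, ...) {
  # binary STL: 80-byte header + uint32 count + 50 bytes/facet
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", 84)
  is_binary <- FALSE
  if (length(head) == 84) {
    ntri <- readBin(head[81:84], "integer", 1, size = 4, endian = "little")
    if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) is_binary <- TRUE
  }
  close(con)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    coords <- matrix(NA_real_, 3 * ntri, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      coords[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      invisible(readBin(con, "raw", 2))
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3 != 0)
      stop("malformed ASCII STL: ", path)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
  }
  stl_to_mesh(coords, ...)
}

# merge coincident vertices of an unindexed triangle soup
stl_to_mesh <- function(coords, ...) {
  key <- apply(signif(coords, 12), 1, paste, collapse = "_")
  idx <- match(key, unique(key))
  verts <- coords[!duplicated(key), , drop = FALSE]
  tris <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, tris, ...)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - a
  e2 <- v[tr[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fn <- fn / pmax(sqrt(rowSums(fn^2)), 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid wallshear", con)
  for (i in seq_len(nrow(tr))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3)
      writeLines(sprintf("      vertex %.9g %.9g %.9g",
                         v[tr[i, j], 1], v[tr[i, j], 2], v[tr[i, j], 3]), con)
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid wallshear", con)
}

# ---- PLY (ASCII) --------------------------------------------------------

read_ply <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("malformed PLY header")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", hdr))) stop("only ASCII PLY supported")
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header")
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vl <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vl, function(p) as.numeric(p[1:3])))
  fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  tris <- lapply(fl, function(p) {
    n <- as.integer(p[1])
    if (n != 3L) stop("non-triangular cell in PLY file")
    as.integer(p[2:4]) + 1L
  })
  surface_mesh(verts, do.call(rbind, tris), ...)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
}

# ---- VTK legacy polydata ------------------------------------------------

read_vtk_polydata <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop("no POINTS section in VTK file")
  nv <- as.integer(toks(lines[ip])[2])
  # points may wrap across lines: read numbers until 3*nv collected
  nums <- numeric(0); i <- ip + 1
  while (length(nums) < 3 * nv) {
    nums <- c(nums, as.numeric(toks(lines[i]))); i <- i + 1
  }
  verts <- matrix(nums[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  ipoly <- grep("^(POLYGONS|CELLS)", lines)[1]
  if (is.na(ipoly)) stop("no POLYGONS section in VTK file")
  nf <- as.integer(toks(lines[ipoly])[2])
  tris <- matrix(NA_integer_, nf, 3)
  for (k in seq_len(nf)) {
    p <- as.integer(toks(lines[ipoly + k]))
    if (p[1] != 3L) stop("non-triangular cell in VTK file")
    tris[k, ] <- p[2:4] + 1L
  }
  pd <- list()
  ipd <- grep("^POINT_DATA", lines)[1]
  if (!is.na(ipd)) {
    i <- ipd + 1
    while (i <= length(lines)) {
      t <- toks(lines[i])
      if (length(t) >= 2 && t[1] == "SCALARS") {
        nm <- t[2]
        i <- i + 2  # skip LOOKUP_TABLE line
        vals <- numeric(0)
        while (length(vals) < nv && i <= length(lines)) {
          vals <- c(vals, as.numeric(toks(lines[i]))); i <- i + 1
        }
        pd[[nm]] <- vals[seq_len(nv)]
      } else i <- i + 1
    }
  }
  m <- surface_mesh(verts, tris, ...)
  if (length(pd)) attr(m, "point_data") <- pd
  m
}

write_vtk_polydata <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "wallshear surface", "ASCII",
               "DATASET POLYDATA", paste("POINTS", nv, "double")), con)
  writeLines(sprintf("%.12g %.12g %.12g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(paste("POLYGONS", nf, 4 * nf), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  if (!is.null(point_data) && length(point_data)) {
    writeLines(paste("POINT_DATA", nv), con)
    for (nm in names(point_data)) {
      x <- point_data[[nm]]
      stopifnot(length(x) == nv)
      writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.12g", as.numeric(x)), con)
    }
  }
}
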