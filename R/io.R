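#' Read a surface mesh from STL, VTK PolyData or OBJ
#'
#' Format is chosen by file extension (`.stl`, `.vtk`, `.obj`). STL files
#' (binary or ASCII, auto-detected) are vertex-deduplicated with a 1e-6 mm
#' tolerance; coordinates are taken to be millimetres.
#'
#' @param path file path.
#' @return a [trimesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         vtk = read_vtk_polydata(path),
         obj = read_obj(path),
         stop("unsupported mesh format: .", ext))
}

#' @rdname read_mesh
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  sz <- file.size(path)
  is_binary <- length(ntri) == 1L && !is.na(ntri) &&
    sz == 84 + 50 * as.numeric(ntri)
  if (is_binary) {
    raw <- readBin(con, "raw", 50L * ntri)
    m <- matrix(raw, nrow = 50L)
    tri <- t(vapply(seq_len(ntri), function(i)
      readBin(m[1:48, i], "numeric", 12L, size = 4L, endian = "little"),
      numeric(12L)))  # ntri x 12: normal, v1, v2, v3
    V <- matrix(0, 3L * ntri, 3L)
    V[seq(1L, by = 3L, length.out = ntri), ] <- tri[, 4:6, drop = FALSE]
    V[seq(2L, by = 3L, length.out = ntri), ] <- tri[, 7:9, drop = FALSE]
    V[seq(3L, by = 3L, length.out = ntri), ] <- tri[, 10:12, drop = FALSE]
    F <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  } else {
    if (!grepl("^\\s*solid", rawToChar(header[1:5])))
      stop("not a recognisable STL file: ", path)
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
    V <- do.call(rbind, nums)
    if (nrow(V) %% 3L != 0L) stop("ASCII STL vertex count not a multiple of 3")
    F <- matrix(seq_len(nrow(V)), ncol = 3L, byrow = TRUE)
  }
  merge_vertices(trimesh(V, F, clean = TRUE), tol = 1e-6)
}

#' Write a mesh as binary STL
#' @param mesh a [trimesh].
#' @param path output path.
#' @export
write_stl <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  N <- face_normals(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "spineforge binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(nrow(F)), con, size = 4L, endian = "little")
  # interleave: normal, v1, v2, v3 as float32 + attribute uint16
  dat <- cbind(N, V[F[, 1L], , drop = FALSE], V[F[, 2L], , drop = FALSE],
               V[F[, 3L], , drop = FALSE])
  for (i in seq_len(nrow(F))) {
    writeBin(as.numeric(dat[i, ]), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' @rdname read_mesh
#' @export
read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(p) as.numeric(p[2:4])))
  F <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    idx <- as.integer(sub("/.*$", "", p[-1L]))
    if (length(idx) != 3L) stop("only triangular OBJ faces are supported")
    idx
  }))
  trimesh(V, F)
}

#' Legacy ASCII VTK PolyData I/O for triangle surfaces
#' @param mesh a [trimesh].
#' @param path file path.
#' @export
write_vtk_polydata <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  lines <- c("# vtk DataFile Version 3.0",
             "spineforge surface",
             "ASCII",
             "DATASET POLYDATA",
             sprintf("POINTS %d double", nrow(V)),
             sprintf("%.12g %.12g %.12g", V[, 1L], V[, 2L], V[, 3L]),
             sprintf("POLYGONS %d %d", nrow(F), 4L * nrow(F)),
             sprintf("3 %d %d %d", F[, 1L] - 1L, F[, 2L] - 1L, F[, 3L] - 1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vtk_polydata
#' @export
read_vtk_polydata <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", txt)[1L]
  if (is.na(ip)) stop("no POINTS section in ", path)
  np <- as.integer(strsplit(txt[ip], "\\s+")[[1L]][2L])
  pts <- scan(text = txt[(ip + 1L):length(txt)], what = numeric(),
              n = 3L * np, quiet = TRUE)
  V <- matrix(pts, ncol = 3L, byrow = TRUE)
  ifc <- grep("^POLYGONS", txt)[1L]
  if (is.na(ifc)) stop("no POLYGONS section in ", path)
  nf <- as.integer(strsplit(txt[ifc], "\\s+")[[1L]][2L])
  raw <- scan(text = txt[(ifc + 1L):length(txt)], what = integer(),
              n = 4L * nf, quiet = TRUE)
  m <- matrix(raw, ncol = 4L, byrow = TRUE)
  if (any(m[, 1L] != 3L)) stop("non-triangular polygons in ", path)
  trimesh(V, m[, 2:4, drop = FALSE] + 1L, clean = FALSE)
}
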