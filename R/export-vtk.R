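#' Write a tet mesh as legacy ASCII VTK unstructured grid
#'
#' One VTK_TETRA cell per tet, with an integer `part_label` cell field.
#'
#' @param tm a [tetmesh].
#' @param path output path.
#' @param label integer part label written as CELL_DATA.
#' @export
write_vtk_unstructured <- function(tm, path, label = 1L) {
  V <- tm$vertices
  C <- tm$cells - 1L  # VTK is 0-based
  lines <- c("# vtk DataFile Version 3.0",
             "spineforge part",
             "ASCII",
             "DATASET UNSTRUCTURED_GRID",
             sprintf("POINTS %d double", nrow(V)),
             sprintf("%.12g %.12g %.12g", V[, 1L], V[, 2L], V[, 3L]),
             sprintf("CELLS %d %d", nrow(C), 5L * nrow(C)),
             sprintf("4 %d %d %d %d", C[, 1L], C[, 2L], C[, 3L], C[, 4L]),
             sprintf("CELL_TYPES %d", nrow(C)),
             rep("10", nrow(C)),
             sprintf("CELL_DATA %d", nrow(C)),
             "SCALARS part_label int 1",
             "LOOKUP_TABLE default",
             rep(sprintf("%d", as.integer(label)), nrow(C)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vtk_unstructured
#' @export
read_vtk_unstructured <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", txt)[1L]
  np <- as.integer(strsplit(txt[ip], "\\s+")[[1L]][2L])
  V <- matrix(scan(text = txt[(ip + 1L):(ip + np)], what = numeric(),
                   quiet = TRUE), ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS", txt)[1L]
  nc <- as.integer(strsplit(txt[ic], "\\s+")[[1L]][2L])
  raw <- scan(text = txt[(ic + 1L):(ic + nc)], what = integer(), quiet = TRUE)
  m <- matrix(raw, ncol = 5L, byrow = TRUE)
  il <- grep("^LOOKUP_TABLE", txt)[1L]
  lab <- if (!is.na(il))
    scan(text = txt[(il + 1L):(il + nc)], what = integer(), quiet = TRUE)
  else rep(NA_integer_, nc)
  list(vertices = V, cells = m[, 2:5, drop = FALSE] + 1L, labels = lab)
}

#' Write spring elements as a VTK polyline file
#'
#' Legacy ASCII POLYDATA: two points and one LINES entry per spring.
#'
#' @param model an `fe_model`.
#' @param path output path.
#' @export
write_vtk_springs <- function(model, path) {
  pts <- list()
  for (ss in model$springs) {
    ep <- ss$endpoints
    for (i in seq_len(nrow(ep))) {
      pu <- model$parts[[ep$part_upper[i]]]$vertices[ep$node_upper[i], ]
      pl <- model$parts[[ep$part_lower[i]]]$vertices[ep$node_lower[i], ]
      pts[[length(pts) + 1L]] <- rbind(pu, pl)
    }
  }
  P <- do.call(rbind, pts)
  n <- nrow(P) / 2L
  lines <- c("# vtk DataFile Version 3.0",
             "spineforge ligament springs",
             "ASCII",
             "DATASET POLYDATA",
             sprintf("POINTS %d double", nrow(P)),
             sprintf("%.12g %.12g %.12g", P[, 1L], P[, 2L], P[, 3L]),
             sprintf("LINES %d %d", n, 3L * n),
             sprintf("2 %d %d", 2L * seq_len(n) - 2L, 2L * seq_len(n) - 1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vtk_springs
#' @export
read_vtk_springs <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", txt)[1L]
  np <- as.integer(strsplit(txt[ip], "\\s+")[[1L]][2L])
  P <- matrix(scan(text = txt[(ip + 1L):(ip + np)], what = numeric(),
                   quiet = TRUE), ncol = 3L, byrow = TRUE)
  il <- grep("^LINES", txt)[1L]
  nl <- as.integer(strsplit(txt[il], "\\s+")[[1L]][2L])
  list(points = P, n_lines = nl)
}

#' Export every model part (and the springs) as VTK files
#'
#' Writes `<prefix><part>.vtk` per part with a part-label cell field, plus
#' `<prefix>springs.vtk` with the ligament polylines.
#'
#' @param model an `fe_model`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of the written paths, invisibly.
#' @export
export_vtk <- function(model, dir, prefix = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(model$parts)) {
    pn <- names(model$parts)[i]
    p <- file.path(dir, paste0(prefix, pn, ".vtk"))
    write_vtk_unstructured(model$parts[[i]], p, label = i)
    paths <- c(paths, p)
  }
  if (length(model$springs) > 0L) {
    p <- file.path(dir, paste0(prefix, "springs.vtk"))
    write_vtk_springs(model, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
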