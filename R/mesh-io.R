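#' Read a triangulated surface from OFF, PLY or STL
#'
#' Supports ASCII OFF, ASCII and binary little-endian PLY, and ASCII or
#' binary STL.  The vertex order of the file is preserved (STL files, which
#' store no connectivity, get vertices merged by exact coordinate match).
#' The result is validated as an oriented manifold-with-boundary surface;
#' inconsistent triangle orientation is repaired by flipping where possible.
#'
#' @param path file path.
#' @param format one of `"auto"` (default, by extension), `"off"`, `"ply"`,
#'   `"stl"`.
#' @return a [tri_surface()].
#' @export
read_triangle_surface <- function(path, format = c("auto", "off", "ply", "stl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("off", "ply", "stl")) {
      stop("cannot infer surface format from extension: ", path)
    }
  }
  raw <- switch(format,
    off = read_off(path),
    ply = read_ply(path),
    stl = read_stl(path))
  tri_surface(raw$vertices, raw$triangles)
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!identical(toupper(lines[1]), "OFF")) stop("not an OFF file: ", path)
  toks <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  nv <- as.integer(toks[1]); nf <- as.integer(toks[2])
  pos <- 4L
  V <- matrix(toks[pos:(pos + 3L * nv - 1L)], nv, 3L, byrow = TRUE)
  pos <- pos + 3L * nv
  F <- matrix(NA_integer_, nf, 3L)
  for (i in seq_len(nf)) {
    k <- as.integer(toks[pos])
    if (k != 3L) stop("OFF reader supports triangles only (face with ", k, " vertices)")
    F[i, ] <- as.integer(toks[(pos + 1L):(pos + 3L)]) + 1L
    pos <- pos + k + 1L
  }
  list(vertices = V, triangles = F)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    header <- c(header, ln)
    if (identical(trimws(ln), "end_header")) break
    if (length(header) > 500L) stop("PLY header not terminated")
  }
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  elems <- list(); cur <- NULL
  for (ln in header) {
    t <- strsplit(trimws(ln), "\\s+")[[1]]
    if (t[1] == "element") {
      cur <- t[2]
      elems[[cur]] <- list(n = as.integer(t[3]), props = list())
    } else if (t[1] == "property" && !is.null(cur)) {
      elems[[cur]]$props[[length(elems[[cur]]$props) + 1L]] <- t[-1]
    }
  }
  nv <- elems$vertex$n; nf <- elems$face$n
  vp <- elems$vertex$props
  vnames <- vapply(vp, function(p) p[length(p)], character(1))
  if (fmt == "ascii") {
    toks <- scan(con, quiet = TRUE)
    np <- length(vp)
    V <- matrix(toks[seq_len(nv * np)], nv, np, byrow = TRUE)
    colnames(V) <- vnames
    V <- V[, c("x", "y", "z"), drop = FALSE]
    pos <- nv * np + 1L
    F <- matrix(NA_integer_, nf, 3L)
    for (i in seq_len(nf)) {
      k <- as.integer(toks[pos])
      if (k != 3L) stop("PLY reader supports triangles only")
      F[i, ] <- as.integer(toks[(pos + 1L):(pos + 3L)]) + 1L
      pos <- pos + k + 1L
    }
  } else if (fmt == "binary_little_endian") {
    sz <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L, short = 2L,
            ushort = 2L, int16 = 2L, uint16 = 2L, int = 4L, uint = 4L,
            int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
            double = 8L, float64 = 8L)
    read_scalar <- function(type) {
      if (type %in% c("float", "float32", "double", "float64")) {
        readBin(con, "double", 1L, size = sz[[type]], endian = "little")
      } else {
        readBin(con, "integer", 1L, size = sz[[type]], endian = "little",
                signed = !startsWith(type, "u") || sz[[type]] >= 4L)
      }
    }
    V <- matrix(0, nv, length(vp))
    for (i in seq_len(nv)) for (j in seq_along(vp)) {
      V[i, j] <- read_scalar(vp[[j]][1])
    }
    colnames(V) <- vnames
    V <- V[, c("x", "y", "z"), drop = FALSE]
    fp <- elems$face$props[[1]]  # list <count type> <index type> name
    F <- matrix(NA_integer_, nf, 3L)
    for (i in seq_len(nf)) {
      k <- read_scalar(fp[2])
      if (k != 3L) stop("PLY reader supports triangles only")
      F[i, ] <- c(read_scalar(fp[3]), read_scalar(fp[3]), read_scalar(fp[3])) + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  list(vertices = V, triangles = F)
}

read_stl <- function(path) {
  hdr <- readBin(path, "raw", 84L)
  is_ascii <- identical(rawToChar(hdr[1:5]), "solid") &&
    !grepl("[^[:print:][:space:]]", rawToChar(readBin(path, "raw", 512L)))
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vx <- grep("^\\s*vertex", lines, value = TRUE)
    toks <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(t) {
      as.numeric(t[2:4])
    }))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80L)
    nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    toks <- matrix(0, nf * 3L, 3L)
    for (i in seq_len(nf)) {
      dat <- readBin(con, "double", 12L, size = 4L, endian = "little")
      readBin(con, "raw", 2L)
      toks[(3L * i - 2L):(3L * i), ] <- matrix(dat[4:12], 3L, 3L, byrow = TRUE)
    }
  }
  key <- apply(toks, 1L, function(p) paste(sprintf("%.9g", p), collapse = ","))
  uniq <- !duplicated(key)
  V <- toks[uniq, , drop = FALSE]
  idx <- match(key, key[uniq])
  F <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = V, triangles = F)
}

#' Write a triangulated surface to OFF or ASCII PLY
#'
#' @param surface a [tri_surface()].
#' @param path output path.
#' @param format `"off"` (default) or `"ply"`; `"auto"` infers from extension.
#' @export
write_triangle_surface <- function(surface, path, format = c("auto", "off", "ply")) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  V <- surface$vertices; F <- surface$triangles
  if (format == "off") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("OFF", sprintf("%d %d 0", nrow(V), nrow(F))), con)
    writeLines(sprintf("%.10g %.10g %.10g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  } else if (format == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(F)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.10g %.10g %.10g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  } else stop("unsupported surface output format: ", format)
  invisible(path)
}

# internal node order -> VTK order for hexes.  The internal 20-node
# (serendipity) order is: 8 corners, then mid-edge nodes of the bottom face
# (1-2,2-3,3-4,4-1), top face (5-6,6-7,7-8,8-5), vertical edges
# (1-5,2-6,3-7,4-8).  VTK_QUADRATIC_HEXAHEDRON uses the same convention.
hex_vtk_perm <- function(nen) seq_len(nen)
# Abaqus C3D20 likewise shares the corner/bottom/top/vertical convention.
hex_abaqus_perm <- function(nen) seq_len(nen)

#' Write a hexahedral mesh to VTU or Abaqus INP
#'
#' The VTU dialect emits an XML unstructured grid with cell type 12 (8-node
#' hexahedron) or 25 (20-node quadratic hexahedron) and the region label as
#' cell data.  The Abaqus dialect emits `C3D8`/`C3D20` elements, an element
#' set and solid section per region label, and (when material frames are
#' present) one orientation record per element carrying the first two frame
#' axes.
#'
#' @param mesh a [hex_mesh()].
#' @param path output path.
#' @param dialect `"vtu"` or `"inp"` (`"auto"` infers from extension).
#' @export
write_hex_mesh <- function(mesh, path, dialect = c("auto", "vtu", "inp")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext == "inp") "inp" else "vtu"
  }
  nen <- ncol(mesh$elements)
  if (!nen %in% c(8L, 20L)) stop("mixed or unsupported element order")
  if (dialect == "vtu") write_vtu(mesh, path) else write_inp(mesh, path)
  invisible(path)
}

write_vtu <- function(mesh, path) {
  N <- mesh$nodes; E <- mesh$elements
  nen <- ncol(E)
  ctype <- if (nen == 8L) 12L else 25L
  perm <- hex_vtk_perm(nen)
  conn <- t(E[, perm, drop = FALSE]) - 1L
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nrow(N), nrow(E))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(sprintf("%.12g %.12g %.12g", N[, 1], N[, 2], N[, 3]), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(paste(apply(matrix(as.vector(conn), nrow = nen), 2L, paste,
                         collapse = " ")), con)
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(nrow(E)) * nen), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(as.character(rep(ctype, nrow(E))), con)
  w('        </DataArray>')
  w('      </Cells>')
  if (!is.null(mesh$region)) {
    w('      <CellData>')
    w('        <DataArray type="Int32" Name="region" format="ascii">')
    writeLines(as.character(as.integer(factor(mesh$region))), con)
    w('        </DataArray>')
    w('      </CellData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
}

write_inp <- function(mesh, path) {
  N <- mesh$nodes; E <- mesh$elements
  nen <- ncol(E)
  etype <- if (nen == 8L) "C3D8" else "C3D20"
  perm <- hex_abaqus_perm(nen)
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("*HEADING")
  w("harmonichex shell mesh")
  w("*NODE")
  writeLines(sprintf("%d, %.12g, %.12g, %.12g",
                     seq_len(nrow(N)), N[, 1], N[, 2], N[, 3]), con)
  w("*ELEMENT, TYPE=%s", etype)
  Ep <- E[, perm, drop = FALSE]
  writeLines(vapply(seq_len(nrow(Ep)), function(i) {
    paste(c(i, Ep[i, ]), collapse = ", ")
  }, character(1)), con)
  region <- mesh$region %||% rep("ALL", nrow(E))
  for (rg in unique(region)) {
    w("*ELSET, ELSET=%s", rg)
    ids <- which(region == rg)
    writeLines(vapply(split(ids, ceiling(seq_along(ids) / 16)),
                      paste, character(1), collapse = ", "), con)
    w("*SOLID SECTION, ELSET=%s, MATERIAL=SCLERA", rg)
  }
  if (!is.null(mesh$frames)) {
    fx <- mesh$frames$x; fy <- mesh$frames$y
    w("** per-element material orientation: a-axis, b-axis")
    for (i in seq_len(nrow(E))) {
      w("*ORIENTATION, NAME=ORI_%d, DEFINITION=COORDINATES", i)
      w("%.9g, %.9g, %.9g, %.9g, %.9g, %.9g",
        fx[i, 1], fx[i, 2], fx[i, 3], fy[i, 1], fy[i, 2], fy[i, 3])
    }
  }
  w("*END")
}

#' Read back a VTU hexahedral mesh (generic reader for round-trips)
#'
#' Minimal XML unstructured-grid reader for the subset written by
#' [write_hex_mesh()].
#'
#' @param path a `.vtu` file written by this package.
#' @return a [hex_mesh()] (region labels restored as integers when present).
#' @export
read_vtu_hex <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  pts <- xml2::xml_find_first(piece, ".//Points/DataArray")
  coords <- scan(text = xml2::xml_text(pts), quiet = TRUE)
  N <- matrix(coords, ncol = 3L, byrow = TRUE)
  arrays <- xml2::xml_find_all(piece, ".//Cells/DataArray")
  names(arrays) <- xml2::xml_attr(arrays, "Name")
  conn <- as.integer(scan(text = xml2::xml_text(arrays[["connectivity"]]),
                          quiet = TRUE)) + 1L
  offs <- as.integer(scan(text = xml2::xml_text(arrays[["offsets"]]),
                          quiet = TRUE))
  nen <- offs[1]
  E <- matrix(conn, ncol = nen, byrow = TRUE)
  region <- NULL
  rg <- xml2::xml_find_first(piece, ".//CellData/DataArray[@Name='region']")
  if (!inherits(rg, "xml_missing")) {
    region <- as.integer(scan(text = xml2::xml_text(rg), quiet = TRUE))
  }
  hex_mesh(N, E, region = region, validate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
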