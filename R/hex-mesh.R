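#' Hexahedral mesh container
#'
#' Stores an 8- or 20-node hexahedral mesh.  Internal node ordering is the
#' common serendipity convention: corners 1..8 with local coordinates
#' `(-1,-1,-1),(1,-1,-1),(1,1,-1),(-1,1,-1)` then the same square at the top,
#' followed (for 20-node meshes) by the 12 mid-edge nodes in the fixed edge
#' order bottom `(1-2, 2-3, 3-4, 4-1)`, top `(5-6, 6-7, 7-8, 8-5)`, vertical
#' `(1-5, 2-6, 3-7, 4-8)`.
#'
#' @param nodes numeric n x 3 matrix (mm).
#' @param elements integer m x 8 or m x 20 connectivity (1-based).
#' @param region optional per-element region label vector (length m).
#' @param frames optional per-element material frames as returned by
#'   [assign_local_frames()].
#' @param node_sets named list of integer node-index vectors.
#' @param face_sets named list of 2-column matrices `(element, face)` where
#'   `face` is 1..6 in the package's outward-face order.
#' @param meta optional per-element metadata (data frame, m rows).
#' @param validate check scaled Jacobians are positive (default `TRUE`).
#' @return an object of class `hex_mesh`.
#' @export
hex_mesh <- function(nodes, elements, region = NULL, frames = NULL,
                     node_sets = list(), face_sets = list(), meta = NULL,
                     validate = TRUE) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  elements <- as.matrix(elements); storage.mode(elements) <- "integer"
  nen <- ncol(elements)
  if (!nen %in% c(8L, 20L)) stop("elements must have 8 or 20 nodes")
  if (any(elements < 1L) || any(elements > nrow(nodes))) {
    stop("element connectivity indices out of range")
  }
  m <- structure(
    list(nodes = nodes, elements = elements, region = region,
         frames = frames, node_sets = node_sets, face_sets = face_sets,
         meta = meta),
    class = "hex_mesh")
  if (validate) {
    sj <- scaled_jacobians(m)
    bad <- which(apply(sj, 1L, min) <= 0)
    if (length(bad)) {
      stop("inverted element (scaled Jacobian <= 0) at element(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  m
}

#' @exportS3Method base::print
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d nodes, %d elements (%d-node)\n",
              nrow(x$nodes), nrow(x$elements), ncol(x$elements)))
  if (!is.null(x$region)) {
    cat("  regions:", paste(sprintf("%s=%d", names(table(x$region)),
                                    table(x$region)), collapse = ", "), "\n")
  }
  invisible(x)
}

# outward-oriented faces of the reference hex (corner indices)
hex_faces <- function() {
  list(c(1L, 4L, 3L, 2L),   # zeta = -1 (bottom)
       c(5L, 6L, 7L, 8L),   # zeta = +1 (top)
       c(1L, 2L, 6L, 5L),   # eta  = -1
       c(2L, 3L, 7L, 6L),   # xi   = +1
       c(3L, 4L, 8L, 7L),   # eta  = +1
       c(4L, 1L, 5L, 8L))   # xi   = -1
}

# 12 hex edges in the internal serendipity order (mid node 8+k sits on edge k)
hex_edges <- function() {
  rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L),
        c(5L, 6L), c(6L, 7L), c(7L, 8L), c(8L, 5L),
        c(1L, 5L), c(2L, 6L), c(3L, 7L), c(4L, 8L))
}

# mid-edge node slots (local index in a 20-node element) for a face given by
# its corner cycle: mids between consecutive corners
hex_face_mids <- function(face_corners) {
  E <- hex_edges()
  key <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  a <- face_corners
  b <- face_corners[c(2:4, 1)]
  idx <- match(paste(pmin(a, b), pmax(a, b)), key)
  idx + 8L
}

#' Per-corner scaled Jacobians
#'
#' Scaled Jacobian of the trilinear (corner) shape at each of the 8 corners:
#' determinant of the three emanating edge vectors divided by the product of
#' their lengths.  A perfectly orthogonal corner scores 1; non-positive
#' values flag inverted elements.
#'
#' @param mesh a [hex_mesh()].
#' @return m x 8 matrix of scaled Jacobians.
#' @export
scaled_jacobians <- function(mesh) {
  E <- mesh$elements[, 1:8, drop = FALSE]
  V <- mesh$nodes
  adj_xi  <- c(2L, 1L, 4L, 3L, 6L, 5L, 8L, 7L)
  adj_eta <- c(4L, 3L, 2L, 1L, 8L, 7L, 6L, 5L)
  adj_ze  <- c(5L, 6L, 7L, 8L, 1L, 2L, 3L, 4L)
  s_xi  <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  s_eta <- c(-1, -1, 1, 1, -1, -1, 1, 1)
  s_ze  <- c(-1, -1, -1, -1, 1, 1, 1, 1)
  m <- nrow(E)
  out <- matrix(NA_real_, m, 8L)
  for (k in 1:8) {
    pk <- V[E[, k], , drop = FALSE]
    e1 <- -s_xi[k]  * (V[E[, adj_xi[k]], , drop = FALSE] - pk)
    e2 <- -s_eta[k] * (V[E[, adj_eta[k]], , drop = FALSE] - pk)
    e3 <- -s_ze[k]  * (V[E[, adj_ze[k]], , drop = FALSE] - pk)
    det3 <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
            e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
            e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
    nrm <- sqrt(rowSums(e1^2) * rowSums(e2^2) * rowSums(e3^2))
    out[, k] <- det3 / nrm
  }
  out
}

# unique (undirected) corner edges of the whole mesh; returns the pair matrix
# plus, for each element x edge-slot, the index into the unique edge list
mesh_unique_edges <- function(elements) {
  E8 <- elements[, 1:8, drop = FALSE]
  HE <- hex_edges()
  m <- nrow(E8)
  a <- as.vector(E8[, HE[, 1]])
  b <- as.vector(E8[, HE[, 2]])
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)
  uniq <- !duplicated(key)
  list(pairs = cbind(lo[uniq], hi[uniq]),
       slot = matrix(match(key, key[uniq]), m, 12L))
}
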