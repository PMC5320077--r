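#' Triangulated open surface
#'
#' Construct a `tri_surface`, the package's representation of an oriented,
#' manifold-with-boundary triangle mesh.  Coordinates are millimetres.
#' Construction validates the invariants the downstream meshing pipeline
#' relies on: every edge bounds one or two triangles, shared edges are
#' traversed in opposite directions by their two triangles (consistent
#' orientation), no triangle has zero area, and no vertex is unreferenced.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param repair_orientation if `TRUE` (default), attempt to make the
#'   triangle orientation globally consistent by flipping triangles; an
#'   error is raised if the surface is non-orientable.
#' @return An object of class `tri_surface` with elements `vertices`,
#'   `triangles` and derived per-triangle unit `normals`.
#' @export
tri_surface <- function(vertices, triangles, repair_orientation = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  nv <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > nv)) {
    stop("triangle indices out of range")
  }
  if (any(triangles[, 1] == triangles[, 2] |
          triangles[, 2] == triangles[, 3] |
          triangles[, 1] == triangles[, 3])) {
    stop("degenerate triangle: repeated vertex index")
  }
  if (!all(seq_len(nv) %in% as.vector(triangles))) {
    stop("unreferenced vertices present")
  }

  ec <- edge_counts(triangles)
  if (any(ec$count > 2L)) {
    stop("non-manifold edge: an edge bounds more than two triangles")
  }
  if (repair_orientation) {
    triangles <- orient_triangles(triangles)
  } else {
    dk <- directed_edge_keys(triangles)
    if (anyDuplicated(dk)) {
      stop("inconsistent orientation: a directed edge appears twice")
    }
  }

  nrm <- triangle_normals(vertices, triangles)
  area2 <- sqrt(rowSums(nrm$raw^2))
  if (any(area2 < 1e-14)) stop("degenerate triangle: zero area")

  structure(
    list(vertices = vertices, triangles = triangles,
         normals = nrm$unit),
    class = "tri_surface")
}

#' @exportS3Method base::print
print.tri_surface <- function(x, ...) {
  loops <- extract_boundary_loops(x)
  cat(sprintf("<tri_surface> %d vertices, %d triangles, %d boundary loop(s)\n",
              nrow(x$vertices), nrow(x$triangles), length(loops)))
  invisible(x)
}

# per-triangle raw (2*area-scaled) and unit normals
triangle_normals <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  raw <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(raw^2))
  list(raw = raw, unit = raw / pmax(len, .Machine$double.xmin))
}

triangle_areas <- function(surface) {
  a <- surface$vertices[surface$triangles[, 1], , drop = FALSE]
  e1 <- surface$vertices[surface$triangles[, 2], , drop = FALSE] - a
  e2 <- surface$vertices[surface$triangles[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# undirected edge keys "i_j" with i < j, 3 per triangle (cols 1-2, 2-3, 3-1)
undirected_edge_pairs <- function(F) {
  e <- rbind(F[, c(1, 2), drop = FALSE],
             F[, c(2, 3), drop = FALSE],
             F[, c(3, 1), drop = FALSE])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

edge_key <- function(i, j) paste(i, j, sep = "_")

edge_counts <- function(F) {
  ep <- undirected_edge_pairs(F)
  key <- edge_key(ep[, 1], ep[, 2])
  tab <- table(key)
  list(pairs = ep, keys = key, count = as.integer(tab[key]))
}

directed_edge_keys <- function(F) {
  e <- rbind(F[, c(1, 2), drop = FALSE],
             F[, c(2, 3), drop = FALSE],
             F[, c(3, 1), drop = FALSE])
  edge_key(e[, 1], e[, 2])
}

# Make orientation globally consistent by BFS over edge-adjacent triangles,
# flipping where a shared edge is traversed in the same direction.
orient_triangles <- function(F) {
  m <- nrow(F)
  ep <- undirected_edge_pairs(F)
  key <- edge_key(ep[, 1], ep[, 2])
  tri_of_edge <- split(rep(seq_len(m), 3L), key)

  adj <- vector("list", m)
  for (tris in tri_of_edge) {
    if (length(tris) == 2L) {
      adj[[tris[1]]] <- c(adj[[tris[1]]], tris[2])
      adj[[tris[2]]] <- c(adj[[tris[2]]], tris[1])
    }
  }
  flipped <- rep(FALSE, m)
  visited <- rep(FALSE, m)
  for (seed in seq_len(m)) {
    if (visited[seed]) next
    queue <- seed
    visited[seed] <- TRUE
    while (length(queue)) {
      t <- queue[[1]]; queue <- queue[-1]
      ft <- if (flipped[t]) F[t, c(1, 3, 2)] else F[t, ]
      dir_t <- edge_key(c(ft[1], ft[2], ft[3]), c(ft[2], ft[3], ft[1]))
      for (u in adj[[t]]) {
        fu <- if (flipped[u]) F[u, c(1, 3, 2)] else F[u, ]
        dir_u <- edge_key(c(fu[1], fu[2], fu[3]), c(fu[2], fu[3], fu[1]))
        same <- any(dir_u %in% dir_t)   # shared edge traversed same way
        if (!visited[u]) {
          if (same) flipped[u] <- !flipped[u]
          visited[u] <- TRUE
          queue <- c(queue, u)
        } else if (same != FALSE) {
          # already fixed: verify consistency
          if (any(dir_u %in% dir_t)) {
            stop("inconsistent orientation that cannot be repaired (non-orientable)")
          }
        }
      }
    }
  }
  F[flipped, ] <- F[flipped, c(1, 3, 2), drop = FALSE]
  dk <- directed_edge_keys(F)
  if (anyDuplicated(dk)) {
    stop("inconsistent orientation that cannot be repaired (non-orientable)")
  }
  F
}

#' Boundary loops of an open surface
#'
#' Identifies the closed boundary cycles of a manifold-with-boundary
#' triangle surface.  Each boundary edge (an edge with a single incident
#' triangle) belongs to exactly one loop.  Loops are returned sorted by
#' descending total arc length, so for a scleral shell the equator ring is
#' first and the optic-nerve-head canal ring last.  Loop vertices follow the
#' surface orientation (each consecutive pair is a directed boundary edge of
#' its triangle).
#'
#' @param surface a [tri_surface()].
#' @return A list of `boundary_loop` objects, each with `vertex_indices`
#'   (closed cycle, first vertex not repeated), `arc_length` (cumulative
#'   lengths, mm, starting at 0) and `total_length` (mm).
#' @export
extract_boundary_loops <- function(surface) {
  F <- surface$triangles
  V <- surface$vertices
  de <- rbind(F[, c(1, 2), drop = FALSE],
              F[, c(2, 3), drop = FALSE],
              F[, c(3, 1), drop = FALSE])
  ukey <- edge_key(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  cnt <- table(ukey)
  is_bnd <- as.integer(cnt[ukey]) == 1L
  bnd <- de[is_bnd, , drop = FALSE]
  if (nrow(bnd) == 0L) return(list())

  # boundary of an oriented surface: directed boundary edges run opposite to
  # their triangle's traversal so the loop keeps the surface on a fixed side;
  # we keep triangle traversal direction (deterministic, orientation-linked)
  nxt <- bnd[, 2]
  names(nxt) <- as.character(bnd[, 1])
  if (anyDuplicated(bnd[, 1]) || anyDuplicated(bnd[, 2])) {
    stop("non-simple boundary: a boundary vertex has degree != 2")
  }
  remaining <- rep(TRUE, nrow(bnd))
  names(remaining) <- as.character(bnd[, 1])
  loops <- list()
  while (any(remaining)) {
    start <- as.integer(names(remaining)[which(remaining)[1]])
    cyc <- integer(0)
    v <- start
    repeat {
      cyc <- c(cyc, v)
      remaining[as.character(v)] <- FALSE
      v <- as.integer(nxt[as.character(v)])
      if (is.na(v)) stop("non-simple boundary: open boundary chain")
      if (v == start) break
    }
    pts <- V[cyc, , drop = FALSE]
    seg <- sqrt(rowSums((pts[c(2:nrow(pts), 1), , drop = FALSE] - pts)^2))
    loops[[length(loops) + 1L]] <- structure(
      list(vertex_indices = cyc,
           arc_length = cumsum(c(0, seg[-length(seg)])),
           total_length = sum(seg)),
      class = "boundary_loop")
  }
  loops[order(vapply(loops, `[[`, numeric(1), "total_length"),
              decreasing = TRUE)]
}

#' @exportS3Method base::print
print.boundary_loop <- function(x, ...) {
  cat(sprintf("<boundary_loop> %d vertices, length %.4f mm\n",
              length(x$vertex_indices), x$total_length))
  invisible(x)
}

#' Evaluate a point on a boundary loop at a given arc length
#'
#' @param loop a `boundary_loop`.
#' @param surface the owning [tri_surface()].
#' @param s arc length (mm), wrapped modulo the loop's total length.
#' @return list with `point` (3-vector), `edge` (the two loop vertex ids
#'   bounding the segment) and `t` (parameter in `[0,1)` along that edge).
#' @keywords internal
loop_point_at <- function(loop, surface, s) {
  L <- loop$total_length
  s <- s %% L
  idx <- findInterval(s, loop$arc_length, rightmost.closed = FALSE)
  n <- length(loop$vertex_indices)
  a <- loop$vertex_indices[idx]
  b <- loop$vertex_indices[if (idx == n) 1L else idx + 1L]
  s0 <- loop$arc_length[idx]
  seg_len <- if (idx == n) L - s0 else loop$arc_length[idx + 1L] - s0
  t <- (s - s0) / seg_len
  p <- (1 - t) * surface$vertices[a, ] + t * surface$vertices[b, ]
  list(point = p, edge = c(a, b), t = t)
}

# vertex -> incident triangles map
vertex_triangle_map <- function(F) {
  split(rep(seq_len(nrow(F)), 3L), as.vector(F))
}

# triangle adjacency across edges: for triangle t, edge slot k (1:12,23,31)
# gives the neighbouring triangle or NA
triangle_edge_neighbors <- function(F) {
  m <- nrow(F)
  ep <- undirected_edge_pairs(F)
  key <- edge_key(ep[, 1], ep[, 2])
  owner <- rep(seq_len(m), 3L)
  sp <- split(owner, key)
  nb <- matrix(NA_integer_, m, 3L)
  idx <- split(seq_along(owner), key)
  for (k in seq_along(sp)) {
    tris <- sp[[k]]
    if (length(tris) == 2L) {
      pos <- idx[[k]]
      slot <- ((pos - 1L) %/% m) + 1L
      nb[tris[1], slot[1]] <- tris[2]
      nb[tris[2], slot[2]] <- tris[1]
    }
  }
  nb
}
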