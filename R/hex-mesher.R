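#' Interpolate middle grid layers between outer and inner surface grids
#'
#' @param outer,inner congruent `surface_grid`s (same `n`, `m`).
#' @param n_layers number of element layers through the thickness (default
#'   2, i.e. one interpolated node layer at the mid-surface).
#' @return list of `n_layers + 1` grids ordered inner -> outer.
#' @export
interpolate_middle_layer <- function(outer, inner, n_layers = 2L) {
  if (outer$n != inner$n || outer$m != inner$m) {
    stop("outer and inner grids must share n and m")
  }
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L) stop("need at least one element layer")
  lapply(seq(0, 1, length.out = n_layers + 1L), function(t) {
    g <- inner
    g$points <- (1 - t) * inner$points + t * outer$points
    g
  })
}

#' Assemble the 8-node hexahedral shell mesh from stacked grids
#'
#' Connects congruent node layers (inner to outer) of `n x m` structured
#' grids, periodic circumferentially, into `n x (m-1) x n_layers` hexahedra.
#' Face set `inner_surface` (pressure side) and node sets `equator_ring`,
#' `onh_ring`, `inner_surface`, `outer_surface` are populated.  Per-element
#' metadata records grid indices and the mid-level harmonic value `u` used
#' for region labelling.
#'
#' @param grids list of congruent grids ordered inner -> outer, e.g. from
#'   [interpolate_middle_layer()].
#' @return an 8-node [hex_mesh()].
#' @export
assemble_hex_mesh <- function(grids) {
  nl <- length(grids)
  n <- grids[[1]]$n; m <- grids[[1]]$m
  for (g in grids) if (g$n != n || g$m != m) stop("grids are not congruent")
  levels <- grids[[1]]$levels

  nid <- function(i, j, l) (l - 1L) * n * m + (j - 1L) * n +
    ((i - 1L) %% n) + 1L
  nodes <- matrix(NA_real_, n * m * nl, 3L)
  for (l in seq_len(nl)) {
    P <- grids[[l]]$points
    for (j in seq_len(m)) {
      nodes[nid(1:n, j, l), ] <- P[, j, ]
    }
  }

  build_elements <- function(flip) {
    elems <- matrix(NA_integer_, n * (m - 1L) * (nl - 1L), 8L)
    meta_i <- integer(nrow(elems)); meta_j <- integer(nrow(elems))
    meta_l <- integer(nrow(elems))
    row <- 0L
    for (l in seq_len(nl - 1L)) {
      for (j in seq_len(m - 1L)) {
        for (i in seq_len(n)) {
          lo <- if (flip) l + 1L else l
          hi <- if (flip) l else l + 1L
          elems[row + 1L, ] <- c(nid(i, j, lo), nid(i + 1L, j, lo),
                                 nid(i + 1L, j + 1L, lo), nid(i, j + 1L, lo),
                                 nid(i, j, hi), nid(i + 1L, j, hi),
                                 nid(i + 1L, j + 1L, hi), nid(i, j + 1L, hi))
          meta_i[row + 1L] <- i; meta_j[row + 1L] <- j
          meta_l[row + 1L] <- l
          row <- row + 1L
        }
      }
    }
    list(elems = elems, meta = data.frame(i = meta_i, j = meta_j,
                                          layer = meta_l))
  }
  be <- build_elements(FALSE)
  sj <- scaled_jacobians(hex_mesh(nodes, be$elems, validate = FALSE))
  if (mean(sj) < 0) be <- build_elements(TRUE)

  meta <- be$meta
  meta$u <- (levels[meta$j] + levels[meta$j + 1L]) / 2

  node_sets <- list(
    equator_ring = as.integer(sapply(seq_len(nl), function(l) nid(1:n, 1L, l))),
    onh_ring = as.integer(sapply(seq_len(nl), function(l) nid(1:n, m, l))),
    inner_surface = nid(rep(1:n, m), rep(1:m, each = n), 1L),
    outer_surface = nid(rep(1:n, m), rep(1:m, each = n), nl))

  # inner-surface pressure faces: the face of each innermost-layer element
  # whose four corners are all inner-surface nodes
  inner_elems <- which(meta$layer == 1L)
  faces <- hex_faces()
  inset <- node_sets$inner_surface
  fs <- matrix(NA_integer_, length(inner_elems), 2L)
  for (k in seq_along(inner_elems)) {
    e <- inner_elems[k]
    for (fi in seq_along(faces)) {
      if (all(be$elems[e, faces[[fi]]] %in% inset)) {
        fs[k, ] <- c(e, fi)
        break
      }
    }
  }
  if (anyNA(fs)) stop("failed to identify inner-surface faces")
  mesh <- hex_mesh(nodes, be$elems, node_sets = node_sets,
                   face_sets = list(inner_surface = fs), meta = meta,
                   validate = TRUE)
  mesh
}

#' Convert an 8-node hex mesh to 20-node serendipity elements
#'
#' Every unique corner edge gains one shared mid-node.  Mid-nodes of edges
#' whose two endpoints both lie on the outer (resp. inner) surface node set
#' are projected to the closest point on that surface, so the quadratic
#' element boundary follows the curved input geometry; all other mid-nodes
#' are exact segment midpoints.
#'
#' @param mesh an 8-node [hex_mesh()].
#' @param outer,inner optional [tri_surface()]s to project boundary
#'   mid-nodes onto; alternatively `project_outer` / `project_inner`
#'   may supply arbitrary projection functions `(k x 3 matrix) -> k x 3`.
#' @param project_outer,project_inner optional projection functions that
#'   override the surface-based projection.
#' @return a 20-node [hex_mesh()] with node and face sets carried over and
#'   mid-nodes appended to the affected sets.
#' @export
convert_to_20node <- function(mesh, outer = NULL, inner = NULL,
                              project_outer = NULL, project_inner = NULL) {
  if (ncol(mesh$elements) != 8L) stop("mesh must be 8-node")
  ue <- mesh_unique_edges(mesh$elements)
  pairs <- ue$pairs
  mid <- (mesh$nodes[pairs[, 1], , drop = FALSE] +
          mesh$nodes[pairs[, 2], , drop = FALSE]) / 2
  edge_len <- sqrt(rowSums((mesh$nodes[pairs[, 1], , drop = FALSE] -
                            mesh$nodes[pairs[, 2], , drop = FALSE])^2))

  if (is.null(project_outer) && !is.null(outer)) {
    project_outer <- function(P) closest_point_on_surface(P, outer)$point
  }
  if (is.null(project_inner) && !is.null(inner)) {
    project_inner <- function(P) closest_point_on_surface(P, inner)$point
  }
  proj_set <- function(mid, set_name, project) {
    set <- mesh$node_sets[[set_name]]
    if (is.null(set) || is.null(project)) return(mid)
    on_set <- pairs[, 1] %in% set & pairs[, 2] %in% set
    if (any(on_set)) {
      newp <- project(mid[on_set, , drop = FALSE])
      moved <- sqrt(rowSums((newp - mid[on_set, , drop = FALSE])^2))
      if (any(moved > 0.5 * edge_len[on_set])) {
        stop("mid-node projection moved a node by more than half its edge ",
             "length (pathological geometry)")
      }
      mid[on_set, ] <- newp
    }
    mid
  }
  mid <- proj_set(mid, "outer_surface", project_outer)
  mid <- proj_set(mid, "inner_surface", project_inner)

  n0 <- nrow(mesh$nodes)
  nodes <- rbind(mesh$nodes, mid)
  elements <- cbind(mesh$elements, matrix(ue$slot + n0, nrow(mesh$elements), 12L))

  node_sets <- mesh$node_sets
  for (nm in names(node_sets)) {
    set <- node_sets[[nm]]
    inside <- which(pairs[, 1] %in% set & pairs[, 2] %in% set)
    node_sets[[nm]] <- c(set, inside + n0)
  }
  hex_mesh(nodes, elements, region = mesh$region, frames = mesh$frames,
           node_sets = node_sets, face_sets = mesh$face_sets,
           meta = mesh$meta, validate = FALSE)
}

# (edge slot, face, rotated corner cycle) table used by dihedral_quality:
# each of the 12 corner edges belongs to exactly two outward faces; the
# cycle is rotated so the shared edge runs corner 1 -> corner 2
dihedral_combos <- function() {
  E <- hex_edges()
  faces <- hex_faces()
  combos <- list()
  for (k in seq_len(12L)) {
    a <- E[k, 1]; b <- E[k, 2]
    hit <- list()
    for (f in faces) {
      cyc <- rep(f, 2L)
      for (s in 1:4) {
        if (cyc[s] == a && cyc[s + 1] == b) {
          hit[[length(hit) + 1L]] <- f[((s - 1L + 0:3) %% 4L) + 1L]
        } else if (cyc[s] == b && cyc[s + 1] == a) {
          hit[[length(hit) + 1L]] <- f[((s - 1L + 0:3) %% 4L) + 1L]
        }
      }
    }
    stopifnot(length(hit) == 2L)
    combos[[k]] <- hit
  }
  combos
}

#' Dihedral-angle distortion statistics of a hexahedral mesh
#'
#' For every element and each of its 12 corner edges, the dihedral angle is
#' the angle between the two adjacent bilinear faces, measured from their
#' outward normals evaluated at the shared edge midpoint; the distortion is
#' `|angle - 90 degrees|`.  A perfect cube scores zero on all edges.
#' Distortions are aggregated into the bins `[0,10) ... [40,50) [50,Inf)`
#' plus the mean and maximum.
#'
#' @param mesh a [hex_mesh()] (corner nodes are used even for 20-node
#'   meshes: quality is that of the trilinear corner shape).
#' @return a `quality_report`: tibble `histogram` (bin, count, fraction),
#'   `mean`, `max`, `n_elements`, `n_nodes`, `distortions` (all values,
#'   degrees).
#' @export
dihedral_quality <- function(mesh) {
  V <- mesh$nodes
  E8 <- mesh$elements[, 1:8, drop = FALSE]
  combos <- dihedral_combos()
  ne <- nrow(E8)
  dist <- matrix(NA_real_, ne, 12L)
  cross3 <- function(u, v) {
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  }
  face_normal_at_edge <- function(cyc) {
    q1 <- V[E8[, cyc[1]], , drop = FALSE]
    q2 <- V[E8[, cyc[2]], , drop = FALSE]
    q3 <- V[E8[, cyc[3]], , drop = FALSE]
    q4 <- V[E8[, cyc[4]], , drop = FALSE]
    du <- (q2 - q1) / 2                    # d/dxi at the edge midpoint
    dv <- (q4 + q3 - q1 - q2) / 4          # d/deta at the edge midpoint
    nrm <- cross3(du, dv)
    len <- sqrt(rowSums(nrm^2))
    if (any(len < 1e-300)) stop("degenerate face (zero normal)")
    nrm / len
  }
  for (k in seq_len(12L)) {
    n1 <- face_normal_at_edge(combos[[k]][[1]])
    n2 <- face_normal_at_edge(combos[[k]][[2]])
    dotv <- pmin(pmax(rowSums(n1 * n2), -1), 1)
    ang <- acos(dotv) * 180 / pi           # angle between outward normals
    dist[, k] <- abs(ang - 90)
  }
  d <- as.vector(dist)
  breaks <- c(0, 10, 20, 30, 40, 50, Inf)
  bins <- cut(d, breaks, right = FALSE,
              labels = c("[0,10)", "[10,20)", "[20,30)", "[30,40)",
                         "[40,50)", ">=50"))
  tab <- table(bins)
  hist <- tibble::tibble(bin = names(tab), count = as.integer(tab),
                         fraction = as.integer(tab) / length(d))
  structure(list(histogram = hist, mean = mean(d), max = max(d),
                 n_elements = ne, n_nodes = nrow(V), distortions = d),
            class = "quality_report")
}

#' @exportS3Method base::print
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %d elements, %d nodes\n",
              x$n_elements, x$n_nodes))
  cat(sprintf("  dihedral distortion: mean %.2f deg, max %.2f deg\n",
              x$mean, x$max))
  print(x$histogram)
  invisible(x)
}
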