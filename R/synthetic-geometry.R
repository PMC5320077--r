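#' Specification of the synthetic sclera shell fixture
#'
#' Parameters of the two-surface posterior-sclera stand-in used throughout
#' the test-suite and the worked examples.  The outer surface is the
#' posterior hemisphere of radius `R_out` with a circular optic-nerve-head
#' (ONH) canal hole of geodesic radius `r_canal`, whose centre sits
#' `canal_offset_deg` away from the posterior pole (the ONH of a real eye is
#' not at the pole).  The inner surface is an inward normal offset by a
#' smooth thickness profile: `t_pole` (1.1 mm) at the pole blending to
#' `t_equator` (0.38 mm) at the equator via a squared-cosine in polar angle.
#'
#' @param R_out outer radius, mm (default 12; adult eye diameter ~24 mm).
#' @param r_canal geodesic canal radius, mm (default 1.75).
#' @param canal_offset_deg canal-centre polar offset from the pole, degrees
#'   (default 15).
#' @param t_pole thickness at the posterior pole, mm (default 1.1).
#' @param t_equator thickness at the equator, mm (default 0.38).
#' @param n_circumferential,n_meridional vertex counts of the structured
#'   generator grid (defaults 96 and 48; minimum 8).
#' @param jitter tangential vertex jitter amplitude, mm (default 0).
#' @param seed RNG seed used when `jitter > 0` (default 0).
#' @return a `sclera_fixture_spec` list.
#' @export
sclera_fixture_spec <- function(R_out = 12, r_canal = 1.75,
                                canal_offset_deg = 15,
                                t_pole = 1.1, t_equator = 0.38,
                                n_circumferential = 96L, n_meridional = 48L,
                                jitter = 0, seed = 0L) {
  if (!(0 < t_equator && t_equator <= t_pole && t_pole < R_out)) {
    stop("thickness must satisfy 0 < t_equator <= t_pole < R_out")
  }
  psi_c <- r_canal / R_out
  off <- canal_offset_deg * pi / 180
  if (off + psi_c >= pi / 2) stop("canal must lie strictly inside the hemisphere")
  if (n_circumferential < 8L || n_meridional < 8L) stop("resolutions must be >= 8")
  structure(list(R_out = R_out, r_canal = r_canal,
                 canal_offset_deg = canal_offset_deg,
                 t_pole = t_pole, t_equator = t_equator,
                 n_circumferential = as.integer(n_circumferential),
                 n_meridional = as.integer(n_meridional),
                 jitter = jitter, seed = as.integer(seed)),
            class = "sclera_fixture_spec")
}

# thickness profile: squared-cosine blend in polar angle theta (0 = pole)
sclera_thickness <- function(theta, t_pole, t_equator) {
  t_equator + (t_pole - t_equator) * cos(theta)^2
}

#' Generate the synthetic sclera shell fixture
#'
#' Builds the outer and inner triangulated surfaces described by a
#' [sclera_fixture_spec()].  Construction uses a canal-centred spherical
#' coordinate system: rings of constant geodesic distance from the canal
#' centre are swept from the canal rim out to the (pole-centred) equator
#' circle, so both boundary loops are exact circles and every vertex lies
#' exactly on the sphere.  The inner surface offsets each outer vertex
#' inward along the radial normal by the local thickness.
#'
#' @param spec a [sclera_fixture_spec()].
#' @return list with elements `outer` and `inner` ([tri_surface()]s),
#'   `thickness` (analytic per-outer-vertex thickness, mm) and `spec`.
#' @export
make_sclera_fixture <- function(spec = sclera_fixture_spec()) {
  R <- spec$R_out
  alpha <- spec$canal_offset_deg * pi / 180
  psi_c <- spec$r_canal / R
  nc <- spec$n_circumferential
  nm <- spec$n_meridional

  # canal-centred frame: c at polar angle alpha from +z in the x-z plane
  cv <- c(sin(alpha), 0, cos(alpha))
  e1 <- c(cos(alpha), 0, -sin(alpha))
  e2 <- c(0, 1, 0)

  lam <- seq(0, 2 * pi, length.out = nc + 1L)[-(nc + 1L)]
  # geodesic angle from the canal centre at which the equator (z = 0) lies
  psi_eq <- atan2(cos(alpha), sin(alpha) * cos(lam))
  srow <- seq(0, 1, length.out = nm)

  V <- matrix(0, nc * nm, 3L)
  for (j in seq_len(nm)) {
    psi <- psi_c + srow[j] * (psi_eq - psi_c)
    dir <- outer(cos(psi), cv) +
      sin(psi) * (outer(cos(lam), e1) + outer(sin(lam), e2))
    V[(j - 1L) * nc + seq_len(nc), ] <- R * dir
  }
  # snap the equator row exactly onto z = 0 (guard rounding)
  eqr <- (nm - 1L) * nc + seq_len(nc)
  V[eqr, 3] <- 0
  V[eqr, 1:2] <- V[eqr, 1:2] * (R / sqrt(rowSums(V[eqr, 1:2, drop = FALSE]^2)))

  if (spec$jitter > 0) {
    set.seed(spec$seed)
    interior <- setdiff(seq_len(nc * nm), c(seq_len(nc), eqr))
    d1 <- stats::rnorm(length(interior), 0, spec$jitter)
    d2 <- stats::rnorm(length(interior), 0, spec$jitter)
    p <- V[interior, , drop = FALSE]
    r <- sqrt(rowSums(p^2))
    n <- p / r
    # tangential directions
    t1 <- cbind(-n[, 2], n[, 1], 0)
    t1 <- t1 / pmax(sqrt(rowSums(t1^2)), 1e-12)
    t2 <- cbind(n[, 2] * t1[, 3] - n[, 3] * t1[, 2],
                n[, 3] * t1[, 1] - n[, 1] * t1[, 3],
                n[, 1] * t1[, 2] - n[, 2] * t1[, 1])
    p <- p + d1 * t1 + d2 * t2
    V[interior, ] <- p * (R / sqrt(rowSums(p^2)))  # keep on sphere
  }

  F <- quad_grid_triangles(nc, nm, periodic = TRUE)

  theta <- acos(pmin(pmax(V[, 3] / R, -1), 1))
  thick <- sclera_thickness(theta, spec$t_pole, spec$t_equator)
  Vin <- V * (1 - thick / R)

  outer_s <- tri_surface(V, F)
  inner_s <- tri_surface(Vin, F)
  list(outer = outer_s, inner = inner_s, thickness = thick, spec = spec)
}

# triangulate an nc x nm structured grid (row-major rows of nc vertices),
# optionally periodic in the first (circumferential) index
quad_grid_triangles <- function(nc, nm, periodic = TRUE) {
  ni <- if (periodic) nc else nc - 1L
  F <- matrix(NA_integer_, 2L * ni * (nm - 1L), 3L)
  row <- 0L
  for (j in seq_len(nm - 1L)) {
    for (i in seq_len(ni)) {
      ip <- if (periodic && i == nc) 1L else i + 1L
      a <- (j - 1L) * nc + i
      b <- (j - 1L) * nc + ip
      c <- j * nc + ip
      d <- j * nc + i
      # winding chosen so fixture normals point away from the sphere centre
      F[row + 1L, ] <- c(a, c, b)
      F[row + 2L, ] <- c(a, d, c)
      row <- row + 2L
    }
  }
  F
}

#' Per-vertex thickness between two roughly parallel surfaces
#'
#' Distance from every outer vertex to the closest point anywhere on the
#' inner surface (point-to-triangle, not point-to-vertex).
#'
#' @param outer,inner [tri_surface()]s forming a shell.
#' @return numeric vector of thicknesses (mm), one per outer vertex.
#' @export
compute_thickness_map <- function(outer, inner) {
  cp <- closest_point_on_surface(outer$vertices, inner)
  R_ref <- max(sqrt(rowSums(outer$vertices^2)))
  if (any(cp$distance > 0.5 * R_ref)) {
    stop("surfaces do not form a shell (closest-point distance too large)")
  }
  cp$distance
}

#' Closest points on a triangle surface
#'
#' Exact point-to-triangle-mesh projection (brute force over triangles,
#' evaluated in compiled code).
#'
#' @param points n x 3 query points.
#' @param surface a [tri_surface()].
#' @return list with `point` (n x 3 projections), `distance`, `triangle`
#'   (1-based triangle index) and `bary` (n x 3 barycentric coordinates).
#' @export
closest_point_on_surface <- function(points, surface) {
  points <- matrix(as.double(points), ncol = 3L)
  res <- cpp_closest_point_trimesh(points, surface$vertices,
                                   surface$triangles)
  list(point = res$point, distance = as.numeric(res$distance),
       triangle = as.integer(res$triangle), bary = res$bary)
}

#' Flat annulus test surface
#'
#' A planar annulus in the `z = 0` plane: the simplest two-loop geometry,
#' whose harmonic field has the closed form `log(r / r_in) / log(r_out /
#' r_in)`.
#'
#' @param r_in,r_out inner and outer radii, mm.
#' @param n_circumferential,n_radial grid resolution (defaults 64, 16).
#' @return a [tri_surface()] with two boundary loops.
#' @export
make_annulus_fixture <- function(r_in, r_out, n_circumferential = 64L,
                                 n_radial = 16L) {
  if (!(0 < r_in && r_in < r_out)) stop("radii must satisfy 0 < r_in < r_out")
  nc <- as.integer(n_circumferential); nr <- as.integer(n_radial)
  phi <- seq(0, 2 * pi, length.out = nc + 1L)[-(nc + 1L)]
  r <- seq(r_in, r_out, length.out = nr)   # row 1 = inner rim
  V <- matrix(0, nc * nr, 3L)
  for (j in seq_len(nr)) {
    V[(j - 1L) * nc + seq_len(nc), ] <- cbind(r[j] * cos(phi),
                                              r[j] * sin(phi), 0)
  }
  F <- quad_grid_triangles(nc, nr, periodic = TRUE)
  tri_surface(V, F)
}

#' Mapped hexahedral mesh of a spherical-shell octant
#'
#' Validation mesh for the thick-walled-sphere (Lame) pressure problem,
#' built independently of the harmonic mesher.  The octant's spherical
#' triangle is decomposed into three quadrilateral blocks (corner,
#' edge-midpoint, centroid), each mapped as an `n x n` grid of normalized
#' bilinear points, then extruded radially.  Face sets: `inner`, `outer`,
#' `sym_x`, `sym_y`, `sym_z` (the three symmetry planes).
#'
#' @param r_in,r_out shell radii, mm.
#' @param n_angular grid divisions per block edge (default 4).
#' @param n_radial radial divisions (default 2).
#' @return an 8-node [hex_mesh()].
#' @export
make_mapped_spherical_shell <- function(r_in, r_out, n_angular = 4L,
                                        n_radial = 2L) {
  if (!(0 < r_in && r_in < r_out)) stop("radii must satisfy 0 < r_in < r_out")
  n <- as.integer(n_angular); nr <- as.integer(n_radial)
  if (n < 1L || nr < 1L) stop("divisions must be >= 1")
  A <- c(1, 0, 0); B <- c(0, 1, 0); C <- c(0, 0, 1)
  mid <- function(p, q) (p + q) / sqrt(sum((p + q)^2))
  MAB <- mid(A, B); MBC <- mid(B, C); MCA <- mid(C, A)
  G <- (A + B + C) / sqrt(sum((A + B + C)^2))
  blocks <- list(rbind(A, MAB, G, MCA),
                 rbind(B, MBC, G, MAB),
                 rbind(C, MCA, G, MBC))

  key_of <- function(p) paste(sprintf("%.12f", round(p, 9)), collapse = ",")
  node_key <- character(0)
  nodes <- list()
  get_node <- function(p) {
    k <- key_of(p)
    hit <- match(k, node_key)
    if (!is.na(hit)) return(hit)
    node_key[[length(node_key) + 1L]] <<- k
    nodes[[length(nodes) + 1L]] <<- p
    length(nodes)
  }

  radii <- seq(r_in, r_out, length.out = nr + 1L)
  elems <- list()
  for (blk in blocks) {
    u <- seq(0, 1, length.out = n + 1L)
    dirs <- array(0, c(n + 1L, n + 1L, 3L))
    for (i in seq_len(n + 1L)) for (j in seq_len(n + 1L)) {
      p <- (1 - u[i]) * (1 - u[j]) * blk[1, ] + u[i] * (1 - u[j]) * blk[2, ] +
        u[i] * u[j] * blk[3, ] + (1 - u[i]) * u[j] * blk[4, ]
      dirs[i, j, ] <- p / sqrt(sum(p^2))
    }
    for (k in seq_len(nr)) for (i in seq_len(n)) for (j in seq_len(n)) {
      corner <- function(di, dj, dk) {
        get_node(radii[k + dk] * dirs[i + di, j + dj, ])
      }
      # bottom at inner radius; ordering chosen for positive Jacobian
      elems[[length(elems) + 1L]] <- c(
        corner(0, 0, 0), corner(1, 0, 0), corner(1, 1, 0), corner(0, 1, 0),
        corner(0, 0, 1), corner(1, 0, 1), corner(1, 1, 1), corner(0, 1, 1))
    }
  }
  N <- do.call(rbind, nodes)
  E <- do.call(rbind, elems)
  # fix handedness if the block parameterization produced negative volumes
  m0 <- hex_mesh(N, E, validate = FALSE)
  sj <- scaled_jacobians(m0)
  if (mean(sj) < 0) {
    E <- E[, c(1L, 4L, 3L, 2L, 5L, 8L, 7L, 6L), drop = FALSE]
  }

  faces <- hex_faces()
  face_sets <- list(inner = NULL, outer = NULL,
                    sym_x = NULL, sym_y = NULL, sym_z = NULL)
  tol <- 1e-9 * r_out
  for (e in seq_len(nrow(E))) {
    for (fi in seq_along(faces)) {
      fn <- E[e, faces[[fi]]]
      P <- N[fn, , drop = FALSE]
      rr <- sqrt(rowSums(P^2))
      if (all(abs(rr - r_in) < tol)) {
        face_sets$inner <- rbind(face_sets$inner, c(e, fi))
      } else if (all(abs(rr - r_out) < tol)) {
        face_sets$outer <- rbind(face_sets$outer, c(e, fi))
      }
      if (all(abs(P[, 1]) < tol)) face_sets$sym_x <- rbind(face_sets$sym_x, c(e, fi))
      if (all(abs(P[, 2]) < tol)) face_sets$sym_y <- rbind(face_sets$sym_y, c(e, fi))
      if (all(abs(P[, 3]) < tol)) face_sets$sym_z <- rbind(face_sets$sym_z, c(e, fi))
    }
  }
  hex_mesh(N, E, face_sets = face_sets)
}
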