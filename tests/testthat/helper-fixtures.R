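# Shared geometry builders and cached expensive artifacts for the suite.

# right circular cylinder side surface: two boundary loops at z = 0 and z = H
cylinder_surface <- function(R = 1, H = 2, nc = 48L, nz = 20L) {
  phi <- seq(0, 2 * pi, length.out = nc + 1L)[-(nc + 1L)]
  V <- NULL
  for (j in seq_len(nz)) {
    z <- H * (j - 1L) / (nz - 1L)
    V <- rbind(V, cbind(R * cos(phi), R * sin(phi), z))
  }
  F <- harmonichex:::quad_grid_triangles(nc, nz, periodic = TRUE)
  tri_surface(V, F)
}

# closed lat-long sphere triangulation (no boundary)
closed_sphere_surface <- function(R = 1, nc = 16L, nm = 9L) {
  th <- seq(0, pi, length.out = nm)[-c(1L, nm)]
  phi <- seq(0, 2 * pi, length.out = nc + 1L)[-(nc + 1L)]
  V <- rbind(c(0, 0, R))
  for (t in th) V <- rbind(V, cbind(R * sin(t) * cos(phi),
                                    R * sin(t) * sin(phi), R * cos(t)))
  V <- rbind(V, c(0, 0, -R))
  nring <- length(th)
  id <- function(i, j) 1L + (j - 1L) * nc + ((i - 1L) %% nc) + 1L
  F <- NULL
  for (i in seq_len(nc)) F <- rbind(F, c(1L, id(i, 1L), id(i + 1L, 1L)))
  for (j in seq_len(nring - 1L)) for (i in seq_len(nc)) {
    F <- rbind(F,
               c(id(i, j), id(i, j + 1L), id(i + 1L, j + 1L)),
               c(id(i, j), id(i + 1L, j + 1L), id(i + 1L, j)))
  }
  south <- nrow(V)
  for (i in seq_len(nc)) F <- rbind(F, c(south, id(i + 1L, nring), id(i, nring)))
  tri_surface(V, F)
}

# single unit-cube hex mesh (internal corner ordering)
unit_cube_mesh <- function() {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  hex_mesh(V, matrix(1:8, 1L, 8L))
}

# nx x ny x nz block of unit cubes on [0, nx] x [0, ny] x [0, nz]
block_mesh <- function(nx = 2L, ny = 2L, nz = 2L, distort = 0, seed = 1L) {
  xs <- 0:nx; ys <- 0:ny; zs <- 0:nz
  id <- function(i, j, k) {
    (k - 1L) * (nx + 1L) * (ny + 1L) + (j - 1L) * (nx + 1L) + i
  }
  V <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  if (distort > 0) {
    set.seed(seed)
    interior <- V[, 1] > 0 & V[, 1] < nx & V[, 2] > 0 & V[, 2] < ny &
      V[, 3] > 0 & V[, 3] < nz
    V[interior, ] <- V[interior, ] +
      matrix(stats::runif(3 * sum(interior), -distort, distort),
             ncol = 3L)
  }
  E <- NULL
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    E <- rbind(E, c(id(i, j, k), id(i + 1L, j, k), id(i + 1L, j + 1L, k),
                    id(i, j + 1L, k),
                    id(i, j, k + 1L), id(i + 1L, j, k + 1L),
                    id(i + 1L, j + 1L, k + 1L), id(i, j + 1L, k + 1L)))
  }
  hex_mesh(V, E)
}

# small sclera fixture + shell mesh, cached for reuse across test files
.test_cache <- new.env(parent = emptyenv())

coarse_spec <- function(...) {
  sclera_fixture_spec(n_circumferential = 48L, n_meridional = 24L, ...)
}

coarse_fixture <- function() {
  if (is.null(.test_cache$fix)) .test_cache$fix <- make_sclera_fixture(coarse_spec())
  .test_cache$fix
}

# n must stay >= ~20 here: 20-node boundary mid-nodes are projected onto the
# curved surface, and on this thin shell a coarser circumferential chord puts
# the projected sagitta past the element thickness (folded elements)
coarse_shell <- function() {
  if (is.null(.test_cache$shell)) {
    .test_cache$shell <- build_shell_mesh(coarse_fixture(), n = 28L, m = 14L)
  }
  .test_cache$shell
}

# symmetric (pole-centred canal, no jitter) variant for symmetry oracles
symmetric_fixture <- function() {
  if (is.null(.test_cache$symfix)) {
    .test_cache$symfix <- make_sclera_fixture(
      sclera_fixture_spec(canal_offset_deg = 0,
                          n_circumferential = 48L, n_meridional = 24L))
  }
  .test_cache$symfix
}

# full-resolution shell at the production defaults (n = 40, m = 34),
# shared by the acceptance checks
default_shell <- function() {
  if (is.null(.test_cache$default_shell)) {
    .test_cache$default_shell <-
      build_shell_mesh(make_sclera_fixture(), n = 40L, m = 34L)
  }
  .test_cache$default_shell
}

# brute-force 2D segment intersection (strict interior crossing)
segments_cross <- function(p1, p2, q1, q2, tol = 1e-12) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < tol) return(FALSE)
  t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  s <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
  t > tol && t < 1 - tol && s > tol && s < 1 - tol
}

lame_radial_displacement <- function(r, a, b, p, E, nu) {
  p * a^3 * r / (E * (b^3 - a^3)) * ((1 - 2 * nu) + (1 + nu) * b^3 / (2 * r^3))
}

# radial projection closures for spherical meshes
radial_projector <- function(R) function(P) P * (R / sqrt(rowSums(P^2)))
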