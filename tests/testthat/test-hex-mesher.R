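test_that("middle-layer interpolation is the exact midpoint", {
  shell <- coarse_shell()
  g <- shell$grid_outer
  # identical grids -> identical layers
  same <- interpolate_middle_layer(g, g, 2L)
  expect_equal(same[[2]]$points, g$points, tolerance = 1e-15)
  # concentric spherical grids: middle nodes at the mean radius
  gi <- g
  r <- sqrt(g$points[, , 1]^2 + g$points[, , 2]^2 + g$points[, , 3]^2)
  for (k in 1:3) gi$points[, , k] <- g$points[, , k] * (11 / r)
  go <- g
  for (k in 1:3) go$points[, , k] <- g$points[, , k] * (12 / r)
  mids <- interpolate_middle_layer(go, gi, 2L)[[2]]
  rm_ <- sqrt(mids$points[, , 1]^2 + mids$points[, , 2]^2 +
                mids$points[, , 3]^2)
  expect_lt(max(abs(rm_ - 11.5)), 1e-9)
  # fixture grids: middle node halfway along the outer-inner segment
  layers <- interpolate_middle_layer(shell$grid_outer, shell$grid_inner, 2L)
  d_full <- layers[[3]]$points - layers[[1]]$points
  d_mid <- layers[[2]]$points - layers[[1]]$points
  tpar <- apply(d_mid * d_full, c(1, 2), sum) / apply(d_full^2, c(1, 2), sum)
  expect_lt(max(abs(tpar - 0.5)), 1e-9)
  expect_error(interpolate_middle_layer(g, list(n = 3, m = 3)), "share")
})

test_that("hex assembly obeys the count formula and element validity", {
  cyl <- cylinder_surface(R = 1, H = 2, nc = 32L, nz = 12L)
  f <- solve_harmonic(cyl)
  g <- trace_surface_grid(cyl, f, n = 8L, m = 5L)
  gi <- g
  r2 <- sqrt(g$points[, , 1]^2 + g$points[, , 2]^2)
  for (k in 1:2) gi$points[, , k] <- g$points[, , k] * (0.9 / r2)
  mesh <- assemble_hex_mesh(interpolate_middle_layer(g, gi, 2L))
  expect_equal(nrow(mesh$elements), 8L * 4L * 2L)
  expect_equal(nrow(mesh$nodes), 3L * 8L * 5L)
  sj <- scaled_jacobians(mesh)
  expect_true(all(sj > 0.9))

  # every interior mesh edge is shared by at most 4 hexes (brute force)
  ue <- harmonichex:::mesh_unique_edges(mesh$elements)
  counts <- table(as.vector(ue$slot))
  expect_true(all(counts <= 4L))
})

test_that("fixture mesh element count follows n x (m-1) x layers", {
  shell <- coarse_shell()
  n <- shell$grid_outer$n; m <- shell$grid_outer$m
  expect_equal(nrow(shell$mesh$elements), n * (m - 1L) * 2L)
  expect_true(all(scaled_jacobians(shell$mesh) > 0))
  # named sets for pressure and boundary conditions are populated
  expect_gt(length(shell$mesh$node_sets$equator_ring), 0L)
  expect_equal(nrow(shell$mesh$face_sets$inner_surface), n * (m - 1L))
})

test_that("20-node conversion adds one shared mid-node per unique edge", {
  m8 <- block_mesh(2L, 2L, 2L)
  m20 <- convert_to_20node(m8)
  ue <- harmonichex:::mesh_unique_edges(m8$elements)
  expect_equal(nrow(m20$nodes), nrow(m8$nodes) + nrow(ue$pairs))
  expect_equal(ncol(m20$elements), 20L)
  # single cube: the 12 added nodes are exact edge midpoints
  c8 <- unit_cube_mesh()
  c20 <- convert_to_20node(c8)
  HE <- harmonichex:::hex_edges()
  for (k in 1:12) {
    mid <- c20$nodes[c20$elements[1, 8L + k], ]
    expect_equal(mid, (c8$nodes[HE[k, 1], ] + c8$nodes[HE[k, 2], ]) / 2,
                 tolerance = 1e-15, ignore_attr = TRUE)
  }
})

test_that("boundary mid-nodes project onto the curved surfaces", {
  sph <- make_mapped_spherical_shell(11, 12, 2L, 1L)
  r <- sqrt(rowSums(sph$nodes^2))
  sph$node_sets$outer_surface <- which(abs(r - 12) < 1e-9)
  sph$node_sets$inner_surface <- which(abs(r - 11) < 1e-9)
  s20 <- convert_to_20node(sph, project_outer = radial_projector(12),
                           project_inner = radial_projector(11))
  r20 <- sqrt(rowSums(s20$nodes[s20$node_sets$outer_surface, ]^2))
  expect_lt(max(abs(r20 - 12)), 1e-6)
  r20i <- sqrt(rowSums(s20$nodes[s20$node_sets$inner_surface, ]^2))
  expect_lt(max(abs(r20i - 11)), 1e-6)
})

test_that("dihedral distortion is zero for a cube and exact for a shear", {
  q <- dihedral_quality(unit_cube_mesh())
  expect_equal(q$mean, 0, tolerance = 1e-12)
  expect_equal(q$max, 0, tolerance = 1e-12)
  expect_equal(sum(q$histogram$fraction), 1, tolerance = 1e-12)

  # shear the cube so the x-faces tilt by exactly 20 degrees
  V <- unit_cube_mesh()$nodes
  V[, 1] <- V[, 1] + tan(20 * pi / 180) * V[, 3]
  qs <- dihedral_quality(hex_mesh(V, matrix(1:8, 1, 8)))
  expect_equal(qs$max, 20, tolerance = 1e-9)
  expect_equal(sort(unique(round(qs$distortions, 9))), c(0, 20))
})

test_that("quality histogram fractions always sum to one", {
  shell <- coarse_shell()
  q <- shell$quality
  expect_equal(sum(q$histogram$fraction), 1, tolerance = 1e-12)
  expect_true(all(q$distortions >= 0))
  expect_lte(q$mean, q$max)
  expect_equal(glance(q)$fraction_below_20, mean(q$distortions < 20))
})

test_that("element density is higher near the canal than near the equator", {
  shell <- coarse_shell()
  mesh <- shell$mesh
  meta <- mesh$meta
  m <- shell$grid_outer$m
  width <- function(rows) {
    sel <- which(meta$j %in% rows & meta$layer == 1L)
    w <- numeric(length(sel))
    for (k in seq_along(sel)) {
      e <- mesh$elements[sel[k], ]
      w[k] <- sqrt(sum((mesh$nodes[e[2], ] - mesh$nodes[e[1], ])^2))
    }
    mean(w)
  }
  expect_lt(width((m - 2L):(m - 1L)), width(1:2))
})

test_that("no element flips across an (n, m) resolution sweep", {
  fix <- coarse_fixture()
  for (n in c(12L, 16L, 20L)) {
    for (m in c(10L, 13L, 16L)) {
      shell <- build_shell_mesh(fix, n = n, m = m, order = 8L)
      expect_true(all(scaled_jacobians(shell$mesh) > 0),
                  label = sprintf("scaled Jacobians positive at n=%d m=%d", n, m))
    }
  }
})

test_that("fixture grid quads are simple (non-self-intersecting)", {
  shell <- coarse_shell()
  g <- shell$grid_outer
  bad <- 0L
  for (j in seq_len(g$m - 1L)) {
    for (i in seq_len(g$n)) {
      ip <- if (i == g$n) 1L else i + 1L
      q <- rbind(g$points[i, j, ], g$points[ip, j, ],
                 g$points[ip, j + 1L, ], g$points[i, j + 1L, ])
      # project the quad to its best-fit plane and test edge crossings
      ctr <- colMeans(q)
      sv <- svd(sweep(q, 2, ctr))
      uv <- sweep(q, 2, ctr) %*% sv$v[, 1:2]
      if (segments_cross(uv[1, ], uv[2, ], uv[3, ], uv[4, ]) ||
          segments_cross(uv[2, ], uv[3, ], uv[4, ], uv[1, ])) {
        bad <- bad + 1L
      }
    }
  }
  expect_equal(bad, 0L)
})
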