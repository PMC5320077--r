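test_that("seeds are evenly spaced and phase-shiftable", {
  ann <- make_annulus_fixture(1, 2, 64L, 6L)
  loops <- extract_boundary_loops(ann)
  eq <- loops[[1]]
  seeds <- sample_seeds(eq, ann, 4L)
  ang <- vapply(seeds, function(s) atan2(s$point[2], s$point[1]), numeric(1))
  gaps <- sort(diff(sort(ang %% (2 * pi))))
  expect_equal(unname(diff(vapply(seeds, `[[`, numeric(1), "s"))),
               rep(eq$total_length / 4, 3), tolerance = 1e-9)
  # consecutive arc-length gaps all equal
  s8 <- sample_seeds(eq, ann, 8L)
  ss <- vapply(s8, `[[`, numeric(1), "s")
  expect_lt(diff(range(diff(ss))) / mean(diff(ss)), 1e-9)
  # half-gap phase shift gives a disjoint set with the same gaps
  s8b <- sample_seeds(eq, ann, 8L, phase = eq$total_length / 16)
  sb <- vapply(s8b, `[[`, numeric(1), "s")
  expect_equal(diff(sb), diff(ss), tolerance = 1e-9)
  expect_gt(min(abs(outer(ss, sb, `-`))), eq$total_length / 32)
  expect_error(sample_seeds(eq, ann, 2L), "at least 3")
})

test_that("streamlines on a cylinder are straight and have the right length", {
  cyl <- cylinder_surface(R = 1, H = 2, nc = 32L, nz = 12L)
  loops <- extract_boundary_loops(cyl)
  zmean <- vapply(loops, function(l) mean(cyl$vertices[l$vertex_indices, 3]),
                  numeric(1))
  top <- loops[[which.max(zmean)]]
  bottom <- loops[[which.min(zmean)]]
  # top loop = 1, bottom = 0
  f <- solve_harmonic(cyl, harmonic_constraints(list(top, bottom), c(1, 0)))
  seed <- sample_seeds(top, cyl, 4L)[[1]]
  sl <- trace_streamline(cyl, f, seed, onh_loop = bottom)
  P <- as.matrix(sl[, c("x", "y", "z")])
  # straight vertical path: x, y fixed; length = H
  expect_lt(max(abs(P[, 1] - P[1, 1])), 1e-6)
  expect_lt(max(abs(P[, 2] - P[1, 2])), 1e-6)
  len <- sum(sqrt(rowSums(diff(P)^2)))
  expect_equal(len, 2, tolerance = 1e-6)
  expect_true(all(diff(sl$f) < 0))
})

test_that("streamlines on the annulus are radial rays ending at the rim", {
  ann <- make_annulus_fixture(1, 2, 48L, 10L)
  loops <- extract_boundary_loops(ann)
  f <- solve_harmonic(ann)
  tt <- harmonichex:::tracing_tables(ann, f)
  seeds <- sample_seeds(loops[[1]], ann, 6L)
  for (sd in seeds[1:3]) {
    sl <- trace_streamline(ann, f, sd, onh_loop = loops[[2]], tables = tt)
    P <- as.matrix(sl[, c("x", "y")])
    crossz <- abs(P[, 1] * P[1, 2] - P[, 2] * P[1, 1])
    expect_lt(max(crossz), 1e-6)
    expect_equal(sqrt(sum(P[nrow(P), ]^2)), 1, tolerance = 1e-6)
  }
})

test_that("streamlines from distinct seeds never cross (brute force)", {
  ann <- make_annulus_fixture(1, 2, 48L, 10L)
  loops <- extract_boundary_loops(ann)
  f <- solve_harmonic(ann)
  tt <- harmonichex:::tracing_tables(ann, f)
  seeds <- sample_seeds(loops[[1]], ann, 8L)
  lines <- lapply(seeds, function(sd) {
    as.matrix(trace_streamline(ann, f, sd, onh_loop = loops[[2]],
                               tables = tt)[, c("x", "y")])
  })
  for (a in 1:7) for (b in (a + 1):8) {
    Pa <- lines[[a]]; Pb <- lines[[b]]
    for (i in seq_len(nrow(Pa) - 1)) for (j in seq_len(nrow(Pb) - 1)) {
      expect_false(segments_cross(Pa[i, ], Pa[i + 1, ],
                                  Pb[j, ], Pb[j + 1, ]))
    }
  }
})

test_that("isocontours are closed circles at the right level", {
  cyl <- cylinder_surface(R = 1, H = 1, nc = 48L, nz = 11L)
  loops <- extract_boundary_loops(cyl)
  zmean <- vapply(loops, function(l) mean(cyl$vertices[l$vertex_indices, 3]),
                  numeric(1))
  f <- solve_harmonic(cyl, harmonic_constraints(loops, ifelse(zmean > 0.5, 1, 0)))
  ic <- extract_isocontours(cyl, f, 0.5)[[1]]
  expect_equal(ic$length, 2 * pi, tolerance = 0.01)
  expect_lt(max(abs(ic$points[, 3] - 0.5)), 1e-9)

  # a level equal to a vertex value still yields a closed contour (tie rule)
  lev <- f$values[which.min(abs(f$values - 0.45))]
  ic2 <- extract_isocontours(cyl, f, lev)[[1]]
  expect_gt(nrow(ic2$points), 8)
  expect_equal(ic2$length, 2 * pi, tolerance = 0.02)
})

test_that("multiple levels give pairwise disjoint contours (brute force)", {
  ann <- make_annulus_fixture(1, 2, 48L, 10L)
  f <- solve_harmonic(ann)
  ics <- extract_isocontours(ann, f, c(0.2, 0.4, 0.6, 0.8))
  expect_length(ics, 4L)
  for (a in 1:3) for (b in (a + 1):4) {
    Pa <- ics[[a]]$points; Pb <- ics[[b]]$points
    na <- nrow(Pa); nb <- nrow(Pb)
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      expect_false(segments_cross(Pa[i, 1:2], Pa[if (i == na) 1 else i + 1, 1:2],
                                  Pb[j, 1:2], Pb[if (j == nb) 1 else j + 1, 1:2]))
    }
  }
})

test_that("the structured grid reproduces the analytic cylinder grid", {
  cyl <- cylinder_surface(R = 1, H = 2, nc = 32L, nz = 12L)
  loops <- extract_boundary_loops(cyl)
  # default constraints: loops[[1]] (seed side) = 1, loops[[2]] = 0
  f <- solve_harmonic(cyl)
  g <- trace_surface_grid(cyl, f, n = 8L, m = 5L)
  expect_equal(g$n, 8L); expect_equal(g$m, 5L)
  z1 <- mean(cyl$vertices[loops[[1]]$vertex_indices, 3])
  z2 <- mean(cyl$vertices[loops[[2]]$vertex_indices, 3])
  for (j in 1:5) {
    z <- g$points[, j, 3]
    expect_lt(diff(range(z)), 1e-6)
    expect_equal(mean(z), z1 + (z2 - z1) * (j - 1) / 4, tolerance = 1e-6)
  }
  ang <- atan2(g$points[, 1, 2], g$points[, 1, 1])
  gaps <- diff(sort(ang))
  expect_equal(unname(gaps), rep(2 * pi / 8, 7), tolerance = 1e-6)
})

test_that("grid rows sit on their levels and nodes on the surface", {
  shell <- coarse_shell()
  g <- shell$grid_outer
  fix <- shell$fixture
  f <- shell$field_outer
  tt <- harmonichex:::tracing_tables(fix$outer, f)
  for (j in 2:(g$m - 1)) {
    pts <- g$points[, j, ]
    cp <- closest_point_on_surface(pts, fix$outer)
    expect_lt(max(cp$distance), 1e-9)
    fval <- vapply(seq_len(g$n), function(i) {
      tri <- cp$triangle[i]
      sum(cp$bary[i, ] * f$values[fix$outer$triangles[tri, ]])
    }, numeric(1))
    expect_lt(max(abs(fval - g$levels[j])), 1e-7)
  }
  # boundary rows lie exactly on the boundary loops
  cp1 <- closest_point_on_surface(g$points[, 1, ], fix$outer)
  expect_lt(max(cp1$distance), 1e-9)
})

test_that("streamlines meet isocontours nearly orthogonally on the fixture", {
  shell <- coarse_shell()
  fix <- shell$fixture
  f <- shell$field_outer
  g <- shell$grid_outer
  # streamline direction ~ row difference; contour tangent ~ column difference
  ang_dev <- c()
  for (j in c(3L, 6L, 9L)) {
    for (i in seq_len(g$n)) {
      ip <- if (i == g$n) 1L else i + 1L
      tgt <- g$points[ip, j, ] - g$points[i, j, ]
      mer <- g$points[i, j + 1L, ] - g$points[i, j - 1L, ]
      cosang <- sum(tgt * mer) / sqrt(sum(tgt^2) * sum(mer^2))
      ang_dev <- c(ang_dev, abs(90 - acos(cosang) * 180 / pi))
    }
  }
  expect_lt(max(ang_dev), 15)
})

test_that("tracing input errors are caught", {
  ann <- make_annulus_fixture(1, 2, 24L, 6L)
  f <- solve_harmonic(ann)
  lines <- lapply(sample_seeds(extract_boundary_loops(ann)[[1]], ann, 4L),
                  function(sd) trace_streamline(ann, f, sd))
  expect_error(build_surface_grid(lines, 2L), "at least 3")
})
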