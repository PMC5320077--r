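test_that("mmHg to MPa conversion", {
  expect_identical(pressure_to_mpa(0), 0)
  expect_equal(pressure_to_mpa(30), 0.00399967, tolerance = 1e-6)
  expect_equal(pressure_to_mpa(760), 0.101325, tolerance = 1e-4)
  expect_error(pressure_to_mpa(-1), "negative")
})

test_that("principal values: analytic cases and characteristic-polynomial oracle", {
  expect_equal(principal_values(diag(c(3, 1, 2))), c(3, 2, 1))
  expect_equal(principal_values(0.7 * diag(3)), rep(0.7, 3))
  expect_error(principal_values(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3)),
               "symmetric")
  set.seed(11)
  for (rep in 1:5) {
    A <- matrix(stats::rnorm(9), 3); A <- (A + t(A)) / 2
    # oracle: roots of det(A - lambda I) via polyroot
    cp <- c(-det(A),
            A[1, 1] * A[2, 2] + A[1, 1] * A[3, 3] + A[2, 2] * A[3, 3] -
              A[1, 2]^2 - A[1, 3]^2 - A[2, 3]^2,
            -sum(diag(A)), 1)
    roots <- sort(Re(polyroot(cp)), decreasing = TRUE)
    expect_equal(principal_values(A), roots, tolerance = 1e-10)
    # vectorized closed form agrees
    v <- c(A[1, 1], A[2, 2], A[3, 3], A[2, 3], A[1, 3], A[1, 2])
    expect_equal(as.numeric(harmonichex:::principal_values_batch(
      matrix(v, 6, 1))), roots, tolerance = 1e-9)
  }
})

test_that("equivalent strain: volumetric zero, uniaxial closed form, isotropy", {
  expect_equal(equivalent_strain(0.01 * diag(3)), 0, tolerance = 1e-15)
  eps <- 0.02
  expect_equal(equivalent_strain(diag(c(eps, 0, 0))), 2 * eps / 3,
               tolerance = 1e-12)
  set.seed(5)
  E <- matrix(stats::rnorm(9), 3); E <- (E + t(E)) / 2
  A <- matrix(stats::rnorm(9), 3)
  R <- qr.Q(qr(A)); if (det(R) < 0) R[, 1] <- -R[, 1]
  expect_equal(equivalent_strain(R %*% E %*% t(R)), equivalent_strain(E),
               tolerance = 1e-10)
})

test_that("a 20-node cube under face pressure reproduces uniaxial elasticity", {
  for (order in c(8L, 20L)) {
    m <- if (order == 20L) convert_to_20node(unit_cube_mesh()) else
      unit_cube_mesh()
    iso <- isotropic_material(E = 3.8, nu = 0.49)
    nd <- m$nodes
    fixed_dofs <- c(3L * (which(abs(nd[, 1]) < 1e-12) - 1L) + 1L,
                    3L * (which(abs(nd[, 2]) < 1e-12) - 1L) + 2L,
                    3L * (which(abs(nd[, 3]) < 1e-12) - 1L) + 3L)
    p <- pressure_to_mpa(30)
    prob <- fe_problem(m, iso, fixed_nodes = NULL, fixed_dofs = fixed_dofs,
                       pressure_mmhg = 30,
                       pressure_faces = matrix(c(1L, 4L), 1))
    res <- assemble_and_solve(prob)
    ux <- res$u[abs(nd[, 1] - 1) < 1e-12, 1]
    expect_equal(mean(ux), -p / 3.8, tolerance = 1e-8)
    uy <- res$u[abs(nd[, 2] - 1) < 1e-12, 2]
    expect_equal(mean(uy), 0.49 * p / 3.8, tolerance = 1e-8)
    expect_lt(max(abs(res$stress[1, ] + p)), 1e-12)
    expect_lt(res$equilibrium_residual, 1e-8)
  }
})

test_that("rigid-body translation produces zero strain", {
  iso <- isotropic_material()
  t0 <- c(0.3, -0.2, 0.5)
  # prescribe the translation on the two end faces of a 2-cube column and
  # let the interior follow
  m2 <- convert_to_20node(block_mesh(2L, 1L, 1L))
  nd <- m2$nodes
  bnodes <- which(nd[, 1] < 1e-12 | nd[, 1] > 2 - 1e-12)
  presc <- cbind(as.vector(outer(3L * (bnodes - 1L), 1:3, `+`)),
                 rep(t0, each = length(bnodes)))
  prob <- fe_problem(m2, iso, fixed_nodes = NULL, prescribed = presc)
  res <- assemble_and_solve(prob)
  expect_lt(max(abs(res$u - matrix(t0, nrow(nd), 3, byrow = TRUE))), 1e-10)
  expect_lt(max(abs(res$strain)), 1e-10)
})

test_that("patch test: distorted blocks reproduce affine fields exactly", {
  affine <- function(X) {
    A <- rbind(c(2e-3, 1e-3, 0), c(1e-3, -1e-3, 5e-4), c(0, 5e-4, 3e-3))
    X %*% A + matrix(c(1e-3, -2e-3, 0), nrow(X), 3, byrow = TRUE)
  }
  A <- rbind(c(2e-3, 1e-3, 0), c(1e-3, -1e-3, 5e-4), c(0, 5e-4, 3e-3))
  eps_exact <- (A + t(A)) / 2
  for (order in c(8L, 20L)) {
    m8 <- block_mesh(2L, 2L, 2L, distort = 0.25, seed = 3L)
    m <- if (order == 20L) convert_to_20node(m8) else m8
    nd <- m$nodes
    on_bnd <- nd[, 1] < 1e-9 | nd[, 1] > 2 - 1e-9 |
      nd[, 2] < 1e-9 | nd[, 2] > 2 - 1e-9 |
      nd[, 3] < 1e-9 | nd[, 3] > 2 - 1e-9
    bn <- which(on_bnd)
    ub <- affine(nd[bn, , drop = FALSE])
    presc <- cbind(as.vector(t(cbind(3 * (bn - 1) + 1, 3 * (bn - 1) + 2,
                                     3 * (bn - 1) + 3))),
                   as.vector(t(ub)))
    prob <- fe_problem(m, isotropic_material(E = 3.8, nu = 0.49),
                       fixed_nodes = NULL, prescribed = presc)
    res <- assemble_and_solve(prob)
    expect_lt(max(abs(res$u - affine(nd))), 1e-9)
    voigt_exact <- c(diag(eps_exact), 2 * eps_exact[2, 3],
                     2 * eps_exact[1, 3], 2 * eps_exact[1, 2])
    expect_lt(max(abs(res$strain - voigt_exact)), 1e-9)
  }
})

test_that("Lame thick-sphere pressure solution converges within 2%", {
  a <- 11; b <- 12; p <- pressure_to_mpa(30)
  E <- 3.8; nu <- 0.49
  errs <- c()
  for (cfg in list(c(2L, 1L), c(4L, 2L), c(8L, 4L))) {
    m8 <- make_mapped_spherical_shell(a, b, cfg[1], cfg[2])
    r <- sqrt(rowSums(m8$nodes^2))
    m8$node_sets$outer_surface <- which(abs(r - b) < 1e-9)
    m8$node_sets$inner_surface <- which(abs(r - a) < 1e-9)
    m <- convert_to_20node(m8, project_outer = radial_projector(b),
                           project_inner = radial_projector(a))
    nd <- m$nodes
    fixed_dofs <- c(3L * (which(abs(nd[, 1]) < 1e-7) - 1L) + 1L,
                    3L * (which(abs(nd[, 2]) < 1e-7) - 1L) + 2L,
                    3L * (which(abs(nd[, 3]) < 1e-7) - 1L) + 3L)
    prob <- fe_problem(m, isotropic_material(E, nu), fixed_nodes = NULL,
                       fixed_dofs = fixed_dofs, pressure_mmhg = 30,
                       pressure_faces = m$face_sets$inner)
    res <- assemble_and_solve(prob)
    expect_lt(res$equilibrium_residual, 1e-8)
    r20 <- sqrt(rowSums(nd^2))
    ur <- rowSums(res$u * nd) / r20
    e <- 0
    for (R in c(a, b)) {
      sel <- abs(r20 - R) < 1e-6
      ana <- lame_radial_displacement(R, a, b, p, E, nu)
      e <- max(e, abs(mean(ur[sel]) - ana) / ana)
    }
    errs <- c(errs, e)
  }
  expect_lt(errs[3], 0.02)
  expect_true(all(diff(errs) < 0))
})

test_that("isotropic solves are frame-independent", {
  # an orthotropic material with equal moduli is isotropic; assembling it
  # with random per-element frames must match the frame-free assembly
  shell <- coarse_shell()
  set.seed(9)
  ne <- nrow(shell$mesh$elements)
  rand_frames <- shell$frames
  for (e in seq_len(min(ne, ne))) {
    A <- matrix(stats::rnorm(9), 3)
    R <- qr.Q(qr(A)); if (det(R) < 0) R[, 1] <- -R[, 1]
    rand_frames$x[e, ] <- R[, 1]
    rand_frames$y[e, ] <- R[, 2]
    rand_frames$z[e, ] <- R[, 3]
  }
  iso_as_ortho <- orthotropic_material(E_x = 3.8, E_y = 3.8, E_z = 3.8,
                                       nu = 0.49)
  p1 <- fe_problem(shell$mesh, iso_as_ortho, frames = rand_frames,
                   pressure_mmhg = 30)
  p2 <- fe_problem(shell$mesh, isotropic_material(3.8, 0.49),
                   pressure_mmhg = 30)
  r1 <- assemble_and_solve(p1)
  r2 <- assemble_and_solve(p2)
  expect_lt(max(abs(r1$u - r2$u)), 1e-9)
})

test_that("region maxima equal brute-force maxima over the raw arrays", {
  shell <- coarse_shell()
  res <- solve_shell_model(shell, "r0", iop_mmhg = 30)
  tab <- region_maxima(res, shell$labels)
  umag <- sqrt(rowSums(res$u^2))
  ps <- harmonichex:::principal_values_batch(res$stress)[1, ]
  for (rg in levels(shell$labels)) {
    els <- which(shell$labels == rg)
    nds <- unique(as.vector(shell$mesh$elements[els, ]))
    gsel <- res$gp_element %in% els
    row <- tab[tab$region == rg, ]
    expect_equal(row$max_displacement, max(umag[nds]))
    expect_equal(row$max_principal_stress, max(ps[gsel]))
  }
  # a uniform field reports the same value in every region
  fake <- res
  fake$u <- matrix(1, nrow(res$u), 3)
  fake$strain <- matrix(rep(c(0.01, 0.01, 0.01, 0, 0, 0), ncol(res$strain)),
                        6)
  fake$stress <- fake$strain
  tab2 <- region_maxima(fake, shell$labels)
  expect_equal(unique(tab2$max_displacement), sqrt(3))
  expect_equal(length(unique(round(tab2$max_principal_stress, 12))), 1L)
})

test_that("tidiers summarize results consistently", {
  shell <- coarse_shell()
  res <- solve_shell_model(shell, "isotropic", iop_mmhg = 30)
  td <- tidy(res)
  expect_equal(nrow(td), nrow(res$u))
  gl <- glance(res)
  expect_equal(gl$max_displacement, max(td$magnitude))
  q <- glance(shell$quality)
  expect_s3_class(q, "tbl_df")
  p <- ggplot2::autoplot(shell$quality)
  expect_s3_class(p, "ggplot")
})
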