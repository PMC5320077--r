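test_that("frames are orthonormal, right-handed and thickness-aligned", {
  shell <- coarse_shell()
  fr <- shell$frames
  for (nm in c("x", "y", "z")) {
    expect_lt(max(abs(sqrt(rowSums(fr[[nm]]^2)) - 1)), 1e-9)
  }
  expect_lt(max(abs(rowSums(fr$x * fr$y))), 1e-9)
  expect_lt(max(abs(rowSums(fr$y * fr$z))), 1e-9)
  expect_lt(max(abs(rowSums(fr$x * fr$z))), 1e-9)
  cx <- cbind(fr$x[, 2] * fr$y[, 3] - fr$x[, 3] * fr$y[, 2],
              fr$x[, 3] * fr$y[, 1] - fr$x[, 1] * fr$y[, 3],
              fr$x[, 1] * fr$y[, 2] - fr$x[, 2] * fr$y[, 1])
  expect_lt(max(abs(cx - fr$z)), 1e-9)
  # z within 25 degrees of the through-thickness direction
  mesh <- shell$mesh
  E8 <- mesh$elements[, 1:8]
  thick_dir <- (mesh$nodes[E8[, 5], ] + mesh$nodes[E8[, 6], ] +
                  mesh$nodes[E8[, 7], ] + mesh$nodes[E8[, 8], ] -
                  mesh$nodes[E8[, 1], ] - mesh$nodes[E8[, 2], ] -
                  mesh$nodes[E8[, 3], ] - mesh$nodes[E8[, 4], ]) / 4
  thick_dir <- thick_dir / sqrt(rowSums(thick_dir^2))
  cosang <- abs(rowSums(thick_dir * fr$z))
  expect_gt(min(cosang), cos(25 * pi / 180))
})

test_that("frames on the symmetric fixture match the analytic directions", {
  # full surface resolution so faceting stays below the 1-degree tolerance
  fix <- make_sclera_fixture(sclera_fixture_spec(canal_offset_deg = 0))
  shell <- build_shell_mesh(fix, n = 16L, m = 12L, order = 8L)
  fr <- shell$frames
  mesh <- shell$mesh
  E8 <- mesh$elements[, 1:8]
  cent <- (mesh$nodes[E8[, 1], ] + mesh$nodes[E8[, 2], ] +
             mesh$nodes[E8[, 3], ] + mesh$nodes[E8[, 4], ] +
             mesh$nodes[E8[, 5], ] + mesh$nodes[E8[, 6], ] +
             mesh$nodes[E8[, 7], ] + mesh$nodes[E8[, 8], ]) / 8
  # analytic frame: y = meridian toward the pole-centred canal (+theta
  # decreasing), x = latitude tangent, z = radial
  rho <- sqrt(cent[, 1]^2 + cent[, 2]^2)
  r <- sqrt(rowSums(cent^2))
  e_phi <- cbind(-cent[, 2], cent[, 1], 0) / rho
  e_r <- cent / r
  e_theta <- cbind(cent[, 1] * cent[, 3], cent[, 2] * cent[, 3],
                   -rho^2) / (r * rho)  # toward increasing polar angle
  y_ana <- -e_theta                     # toward the canal at the pole
  deg <- function(u, v) acos(pmin(pmax(rowSums(u * v), -1), 1)) * 180 / pi
  expect_lt(max(deg(fr$y, y_ana)), 1)
  expect_lt(max(pmin(deg(fr$x, e_phi), deg(fr$x, -e_phi))), 1)
  expect_lt(max(deg(fr$z, e_r)), 1)
})

test_that("x-axis follows the local isocontour tangent", {
  shell <- coarse_shell()
  fix <- shell$fixture
  ics <- extract_isocontours(fix$outer, shell$field_outer, c(0.3, 0.6))
  for (ic in ics) {
    # elements whose mid-level is close to this contour level
    sel <- which(abs(shell$mesh$meta$u - ic$level) < 0.03 &
                   shell$mesh$meta$layer == 1L)
    P <- ic$points
    seg <- P[c(2:nrow(P), 1L), ] - P
    seg <- seg / sqrt(rowSums(seg^2))
    E8 <- shell$mesh$elements[, 1:8]
    for (e in sel) {
      cent <- colMeans(shell$mesh$nodes[E8[e, ], ])
      i <- which.min(rowSums(sweep(P, 2, cent)^2))
      expect_gt(sum(shell$frames$x[e, ] * seg[i, ]), 0.98)
    }
  }
})

test_that("region labels partition the elements into three bands", {
  shell <- coarse_shell()
  lab <- shell$labels
  expect_equal(length(lab), nrow(shell$mesh$elements))
  expect_true(all(table(lab) > 0))
  expect_equal(sum(table(lab)), length(lab))
  # limit: u1, u2 -> 0 sends everything to PERIPHERAL
  lab2 <- label_regions(shell$mesh, u1 = 1e-9, u2 = 2e-9)
  expect_true(all(lab2 == "PERIPHERAL"))
  expect_error(label_regions(shell$mesh, u1 = 0.5, u2 = 0.2), "u1 < u2")
  # bands are isocontour-aligned: label depends only on the grid row j
  by_j <- tapply(as.character(lab), shell$mesh$meta$j,
                 function(x) length(unique(x)))
  expect_true(all(by_j == 1L))
})

test_that("rotation schemes follow the r1..r10 angle pattern", {
  expect_equal(fiber_rotation_scheme(0)$angle_peripheral, 0)
  s1 <- fiber_rotation_scheme("r1")
  expect_equal(s1$angle_peripapillary, 0)
  expect_equal(s1$angle_peripheral, 10)
  s2 <- fiber_rotation_scheme(2)
  expect_equal(s2$angle_peripapillary, 10)
  expect_equal(s2$angle_peripheral, 20)
  s3 <- fiber_rotation_scheme(3)
  expect_equal(s3$angle_peripapillary, 20)
  expect_equal(s3$angle_peripheral, 30)
  s10 <- fiber_rotation_scheme("r10")
  expect_equal(s10$angle_peripapillary, 80)
  expect_equal(s10$angle_peripheral, 90)
  for (k in 1:10) {
    s <- fiber_rotation_scheme(k)
    expect_equal(s$angle_peripheral, s$angle_peripapillary + 10)
  }
  expect_error(fiber_rotation_scheme(11), "unknown")
})

test_that("applying rotation schemes preserves orthonormal right-handed frames", {
  shell <- coarse_shell()
  for (k in c(0L, 3L, 10L)) {
    fr <- apply_rotation_scheme(shell$frames, shell$labels, k)
    expect_lt(max(abs(rowSums(fr$x * fr$y))), 1e-9)
    expect_lt(max(abs(sqrt(rowSums(fr$x^2)) - 1)), 1e-9)
    cx <- cbind(fr$x[, 2] * fr$y[, 3] - fr$x[, 3] * fr$y[, 2],
                fr$x[, 3] * fr$y[, 1] - fr$x[, 1] * fr$y[, 3],
                fr$x[, 1] * fr$y[, 2] - fr$x[, 2] * fr$y[, 1])
    expect_lt(max(abs(cx - fr$z)), 1e-9)
    expect_identical(fr$z, shell$frames$z)
  }
  # k = 0 is the identity
  fr0 <- apply_rotation_scheme(shell$frames, shell$labels, 0L)
  expect_equal(fr0$x, shell$frames$x, tolerance = 1e-15)
  # k = 10: peripheral x ends on the original y
  fr10 <- apply_rotation_scheme(shell$frames, shell$labels, 10L)
  per <- shell$labels == "PERIPHERAL"
  dots <- rowSums(fr10$x[per, ] * shell$frames$y[per, ])
  expect_gt(min(dots), 1 - 1e-9)
})

test_that("orthotropic stiffness reduces to the isotropic closed form", {
  m <- orthotropic_material(E_x = 3.8, E_y = 3.8, E_z = 3.8, nu = 0.49)
  iso <- isotropic_material(E = 3.8, nu = 0.49)
  expect_lt(max(abs(m$C_local - iso$C_local)), 1e-9)
  # rotating the (isotropic) stiffness changes nothing
  th <- 0.8
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_lt(max(abs(build_stiffness(m, R) - m$C_local)), 1e-9)
})

test_that("scleral constants give an ordered, positive-definite stiffness", {
  m <- orthotropic_material()  # 8.6 / 6 / 2.5 MPa, nu = 0.49
  C <- m$C_local
  expect_gt(C[1, 1], C[2, 2])
  expect_gt(C[2, 2], C[3, 3])
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(orthotropic_material(E_x = -1), "positive")
})

# independent oracle: rotate the full 3x3x3x3 elasticity tensor index-wise
rotate_tensor4 <- function(C66, R) {
  idx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  C4 <- array(0, c(3, 3, 3, 3))
  for (a in 1:6) for (b in 1:6) {
    i <- idx[a, 1]; j <- idx[a, 2]; k <- idx[b, 1]; l <- idx[b, 2]
    C4[i, j, k, l] <- C4[j, i, k, l] <- C4[i, j, l, k] <- C4[j, i, l, k] <-
      C66[a, b]
  }
  out <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- 0
    for (p in 1:3) for (q in 1:3) for (r in 1:3) for (t in 1:3) {
      s <- s + R[i, p] * R[j, q] * R[k, r] * R[l, t] * C4[p, q, r, t]
    }
    out[i, j, k, l] <- s
  }
  M <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6) {
    M[a, b] <- out[idx[a, 1], idx[a, 2], idx[b, 1], idx[b, 2]]
  }
  M
}

test_that("frame rotation of the stiffness matches the tensor oracle and
           conserves strain energy", {
  set.seed(42)
  m <- orthotropic_material()
  for (rep in 1:3) {
    A <- matrix(stats::rnorm(9), 3)
    R <- qr.Q(qr(A))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    Cg <- build_stiffness(m, R)
    Cg_oracle <- rotate_tensor4(m$C_local, R)
    expect_lt(max(abs(Cg - Cg_oracle)), 1e-9)

    # energy invariance: rotate a random strain state with the frame
    eps_t <- matrix(stats::rnorm(9), 3); eps_t <- (eps_t + t(eps_t)) / 2
    to_voigt <- function(E) c(E[1, 1], E[2, 2], E[3, 3],
                              2 * E[2, 3], 2 * E[1, 3], 2 * E[1, 2])
    e_loc <- to_voigt(eps_t)
    e_glob <- to_voigt(R %*% eps_t %*% t(R))
    w_loc <- 0.5 * sum(e_loc * (m$C_local %*% e_loc))
    w_glob <- 0.5 * sum(e_glob * (Cg %*% e_glob))
    expect_equal(w_glob, w_loc, tolerance = 1e-9)
  }
})
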