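#' Convert pressure from mmHg to MPa
#'
#' Uses 1 mmHg = 133.3224 Pa.
#'
#' @param p pressure in mmHg (>= 0).
#' @return pressure in MPa.
#' @export
pressure_to_mpa <- function(p) {
  if (any(p < 0)) stop("negative pressure")
  p * 133.3224e-6
}

#' Define a linear finite-element problem on a hex mesh
#'
#' @param mesh an 8- or 20-node [hex_mesh()].
#' @param material an [orthotropic_material()] or [isotropic_material()].
#' @param frames per-element [assign_local_frames()] result (required for
#'   orthotropic materials; ignored as a stiffness rotation for isotropic).
#' @param fixed_nodes integer node indices fixed in all three components,
#'   or the name of a node set (default `"equator_ring"`).
#' @param fixed_dofs optional additional global dof indices (for
#'   symmetry-plane rollers etc.), as `3 * (node - 1) + component`.
#' @param prescribed optional 2-column matrix `(dof, value)` of non-zero
#'   prescribed displacements (mm); these dofs are constrained too.
#' @param pressure_mmhg inner-surface pressure magnitude (mmHg).
#' @param pressure_faces face-set name carrying the pressure (default
#'   `"inner_surface"`) or a 2-column `(element, face)` matrix.
#' @return an `fe_problem`.
#' @export
fe_problem <- function(mesh, material, frames = NULL,
                       fixed_nodes = "equator_ring", fixed_dofs = NULL,
                       prescribed = NULL,
                       pressure_mmhg = 0, pressure_faces = "inner_surface") {
  if (is.character(fixed_nodes)) {
    fixed_nodes <- mesh$node_sets[[fixed_nodes]]
  }
  dofs <- unique(c(
    if (length(fixed_nodes)) as.vector(outer(3L * (fixed_nodes - 1L), 1:3, `+`)),
    fixed_dofs,
    if (!is.null(prescribed)) as.integer(prescribed[, 1])))
  if (!length(dofs)) stop("fixed set is empty")
  faces <- NULL
  if (pressure_mmhg > 0) {
    faces <- if (is.character(pressure_faces)) {
      mesh$face_sets[[pressure_faces]]
    } else pressure_faces
    if (is.null(faces) || !nrow(faces)) stop("pressure face set is empty")
  }
  structure(list(mesh = mesh, material = material, frames = frames,
                 fixed_dofs = sort(dofs), prescribed = prescribed,
                 pressure_mmhg = pressure_mmhg, pressure_faces = faces),
            class = "fe_problem")
}

# 8-node serendipity quad shape functions and derivatives at (xi, eta)
quad_shape <- function(xi, eta, n_nodes) {
  if (n_nodes == 4L) {
    xa <- c(-1, 1, 1, -1); ya <- c(-1, -1, 1, 1)
    N <- (1 + xa * xi) * (1 + ya * eta) / 4
    dNx <- xa * (1 + ya * eta) / 4
    dNy <- (1 + xa * xi) * ya / 4
  } else {
    xa <- c(-1, 1, 1, -1, 0, 1, 0, -1)
    ya <- c(-1, -1, 1, 1, -1, 0, 1, 0)
    N <- dNx <- dNy <- numeric(8L)
    for (a in 1:8) {
      if (xa[a] != 0 && ya[a] != 0) {
        N[a] <- (1 + xa[a] * xi) * (1 + ya[a] * eta) *
          (xa[a] * xi + ya[a] * eta - 1) / 4
        dNx[a] <- xa[a] * (1 + ya[a] * eta) *
          (2 * xa[a] * xi + ya[a] * eta) / 4
        dNy[a] <- (1 + xa[a] * xi) * ya[a] *
          (xa[a] * xi + 2 * ya[a] * eta) / 4
      } else if (xa[a] == 0) {
        N[a] <- (1 - xi^2) * (1 + ya[a] * eta) / 2
        dNx[a] <- -xi * (1 + ya[a] * eta)
        dNy[a] <- (1 - xi^2) * ya[a] / 2
      } else {
        N[a] <- (1 + xa[a] * xi) * (1 - eta^2) / 2
        dNx[a] <- xa[a] * (1 - eta^2) / 2
        dNy[a] <- -(1 + xa[a] * xi) * eta
      }
    }
  }
  list(N = N, dNx = dNx, dNy = dNy)
}

# consistent nodal forces for pressure p on the given element faces;
# traction = -p * outward face normal, integrated with 3x3 Gauss
pressure_forces <- function(mesh, faces, p_mpa) {
  nen <- ncol(mesh$elements)
  f <- numeric(3L * nrow(mesh$nodes))
  g <- sqrt(3 / 5)
  gp <- c(-g, 0, g); gw <- c(5, 8, 5) / 9
  hf <- hex_faces()
  for (r in seq_len(nrow(faces))) {
    e <- faces[r, 1]; fi <- faces[r, 2]
    corners <- hf[[fi]]
    loc <- if (nen == 20L) c(corners, hex_face_mids(corners)) else corners
    nodes <- mesh$elements[e, loc]
    X <- mesh$nodes[nodes, , drop = FALSE]
    nfn <- length(loc)
    for (i in 1:3) for (j in 1:3) {
      sh <- quad_shape(gp[i], gp[j], nfn)
      tx <- drop(sh$dNx %*% X)
      ty <- drop(sh$dNy %*% X)
      nrm <- c(tx[2] * ty[3] - tx[3] * ty[2],
               tx[3] * ty[1] - tx[1] * ty[3],
               tx[1] * ty[2] - tx[2] * ty[1])   # outward normal * dA
      w <- gw[i] * gw[j]
      for (a in seq_len(nfn)) {
        d <- 3L * (nodes[a] - 1L)
        f[d + 1:3] <- f[d + 1:3] - p_mpa * sh$N[a] * nrm * w
      }
    }
  }
  f
}

#' Assemble and solve the linear elastic problem
#'
#' Stiffness is assembled with serendipity shape functions (3x3x3 Gauss for
#' 20-node elements; 2x2x2 with mean-dilatation B-bar for 8-node elements,
#' which suppresses volumetric locking at the near-incompressible Poisson
#' ratio used here).  Pressure becomes consistent nodal forces on the
#' undeformed faces.  The reduced symmetric positive-definite system is
#' solved by sparse Cholesky factorization.
#'
#' @param problem an [fe_problem()].
#' @return an `fe_result`: nodal displacements `u` (n x 3, mm), per-Gauss
#'   `strain` and `stress` (6 x n_gp_total, Voigt), `gp_element` mapping,
#'   `equilibrium_residual` (relative), plus the problem's mesh reference.
#' @export
assemble_and_solve <- function(problem) {
  mesh <- problem$mesh
  nen <- ncol(mesh$elements)
  ne <- nrow(mesh$elements)
  nd <- nrow(mesh$nodes)
  Dstack <- element_stiffness_stack(ne, problem$material, problem$frames)
  ke <- cpp_hex_stiffness(mesh$nodes, mesh$elements, Dstack, nen == 8L)
  ndof <- 3L * nen
  G <- apply(mesh$elements, 1L, function(c) as.vector(rbind(3L * c - 2L,
                                                            3L * c - 1L,
                                                            3L * c)))
  ii <- G[rep(seq_len(ndof), times = ndof), , drop = FALSE]
  jj <- G[rep(seq_len(ndof), each = ndof), , drop = FALSE]
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(ke), dims = c(3L * nd, 3L * nd))

  f <- numeric(3L * nd)
  if (problem$pressure_mmhg > 0) {
    f <- pressure_forces(mesh, problem$pressure_faces,
                         pressure_to_mpa(problem$pressure_mmhg))
  }

  fixed <- problem$fixed_dofs
  free <- setdiff(seq_len(3L * nd), fixed)
  Ks <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  u <- numeric(3L * nd)
  if (!is.null(problem$prescribed)) {
    u[as.integer(problem$prescribed[, 1])] <- problem$prescribed[, 2]
  }
  rhs <- f[free] - as.numeric(K[free, fixed, drop = FALSE] %*% u[fixed])
  ch <- tryCatch(Matrix::Cholesky(Ks, LDL = FALSE),
                 error = function(e) stop("singular or non-PD system: ",
                                          conditionMessage(e)))
  u[free] <- as.numeric(Matrix::solve(ch, rhs))

  # reactions r = K u - f at fixed dofs; global equilibrium requires the
  # per-component sum of reactions plus applied free-dof loads to vanish
  r <- as.numeric(K %*% u) - f
  rmat <- matrix(r, nrow = 3L)
  fmat <- matrix(f, nrow = 3L)
  fixed_mask <- matrix(FALSE, 3L, nd)
  fixed_mask[fixed] <- TRUE
  reactions <- rmat * fixed_mask
  eq_resid <- sqrt(sum((rowSums(reactions) + rowSums(fmat))^2)) /
    max(sum(abs(fmat)), 1e-300)

  rec <- cpp_hex_recover(mesh$nodes, mesh$elements, Dstack, u, nen == 8L)
  ngp <- rec$ngp
  structure(
    list(mesh = mesh, u = matrix(u, ncol = 3L, byrow = TRUE),
         strain = rec$strain, stress = rec$stress,
         gp_element = rep(seq_len(ne), each = ngp), ngp = ngp,
         reactions = t(reactions),
         equilibrium_residual = eq_resid,
         free_residual = max(abs(r[free])) / max(max(abs(f)), 1e-300)),
    class = "fe_result")
}

#' @exportS3Method base::print
print.fe_result <- function(x, ...) {
  cat(sprintf("<fe_result> %d nodes, max |u| = %.5g mm, equilibrium residual %.2g\n",
              nrow(x$u), max(sqrt(rowSums(x$u^2))), x$equilibrium_residual))
  invisible(x)
}

#' Principal values of a symmetric 3x3 tensor
#'
#' @param tensor symmetric 3x3 matrix.
#' @return eigenvalues sorted descending.
#' @export
principal_values <- function(tensor) {
  if (max(abs(tensor - t(tensor))) > 1e-9 * max(1, max(abs(tensor)))) {
    stop("tensor is not symmetric")
  }
  sort(eigen((tensor + t(tensor)) / 2, symmetric = TRUE,
             only.values = TRUE)$values, decreasing = TRUE)
}

# vectorized principal values for Voigt columns (xx,yy,zz,yz,xz,xy);
# `shear_engineering` halves the shear rows first (strain input)
principal_values_batch <- function(voigt, shear_engineering = FALSE) {
  a11 <- voigt[1, ]; a22 <- voigt[2, ]; a33 <- voigt[3, ]
  s <- if (shear_engineering) 0.5 else 1
  a23 <- s * voigt[4, ]; a13 <- s * voigt[5, ]; a12 <- s * voigt[6, ]
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  safe_p <- pmax(p, 1e-300)
  b11 <- (a11 - q) / safe_p; b22 <- (a22 - q) / safe_p
  b33 <- (a33 - q) / safe_p
  b12 <- a12 / safe_p; b13 <- a13 / safe_p; b23 <- a23 / safe_p
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  rbind(e1, e2, e3)
}

#' Von Mises equivalent strain
#'
#' `sqrt(2/3 e : e)` of the deviatoric strain tensor `e`; accepts a
#' symmetric 3x3 tensor (true shear components) or a Voigt 6-vector /
#' 6-row matrix with engineering shears.
#'
#' @param strain strain tensor, Voigt vector, or 6 x k matrix of columns.
#' @return scalar (or length-k vector) equivalent strain.
#' @export
equivalent_strain <- function(strain) {
  if (is.matrix(strain) && nrow(strain) == 3L && ncol(strain) == 3L) {
    v <- c(strain[1, 1], strain[2, 2], strain[3, 3],
           2 * strain[2, 3], 2 * strain[1, 3], 2 * strain[1, 2])
    strain <- matrix(v, 6L, 1L)
  } else if (!is.matrix(strain)) {
    strain <- matrix(strain, 6L, 1L)
  }
  tr <- colSums(strain[1:3, , drop = FALSE]) / 3
  d11 <- strain[1, ] - tr; d22 <- strain[2, ] - tr; d33 <- strain[3, ] - tr
  e23 <- strain[4, ] / 2; e13 <- strain[5, ] / 2; e12 <- strain[6, ] / 2
  ee <- d11^2 + d22^2 + d33^2 + 2 * (e23^2 + e13^2 + e12^2)
  out <- sqrt(2 / 3 * ee)
  if (length(out) == 1L) out[[1]] else out
}

#' Region-wise maxima of the finite-element result
#'
#' Displacement maxima are taken over element nodes, stress and strain
#' maxima over element quadrature points, within each region band.
#'
#' @param result an [assemble_and_solve()] result.
#' @param labels per-element region labels from [label_regions()].
#' @return tibble with one row per region: `max_displacement` (mm),
#'   `max_principal_stress` (MPa), `max_principal_strain`,
#'   `max_equivalent_strain`.
#' @export
region_maxima <- function(result, labels) {
  mesh <- result$mesh
  if (length(labels) != nrow(mesh$elements)) stop("labels must cover all elements")
  umag <- sqrt(rowSums(result$u^2))
  ps <- principal_values_batch(result$stress)[1, ]
  pe <- principal_values_batch(result$strain, shear_engineering = TRUE)[1, ]
  eq <- equivalent_strain(result$strain)
  gp_lab <- labels[result$gp_element]
  rows <- lapply(levels(labels), function(rg) {
    els <- which(labels == rg)
    if (!length(els)) stop("empty region: ", rg)
    nds <- unique(as.vector(mesh$elements[els, , drop = FALSE]))
    gsel <- gp_lab == rg
    tibble::tibble(region = rg,
                   max_displacement = max(umag[nds]),
                   max_principal_stress = max(ps[gsel]),
                   max_principal_strain = max(pe[gsel]),
                   max_equivalent_strain = max(eq[gsel]))
  })
  do.call(rbind, rows)
}
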