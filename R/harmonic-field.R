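#' Cotangent Laplacian of a triangle surface
#'
#' Builds the sparse discrete Laplace operator with the discrete harmonic
#' (cotangent) edge weights `w_ij = (cot a_ij + cot b_ij) / 2`, where `a_ij`
#' and `b_ij` are the angles opposite edge `(i,j)` in its one or two
#' incident triangles.  Boundary edges use the single available cotangent.
#' Diagonal entries are the negated row sums, so every row sums to zero.
#'
#' Obtuse triangles produce negative edge weights; these are kept by default
#' (the operator is the standard one) and their count is reported in the
#' `n_negative_weights` attribute.  `clamp = TRUE` clamps weights at zero.
#'
#' @param surface a [tri_surface()].
#' @param clamp clamp negative weights to zero (default `FALSE`).
#' @return a symmetric `dgCMatrix` with attributes `n_negative_weights` and
#'   `edge_weights` (data frame i, j, w for `i < j`).
#' @export
cotangent_laplacian <- function(surface, clamp = FALSE) {
  V <- surface$vertices
  F <- surface$triangles
  # half-weight contribution cot(angle at opposite corner) / 2 per triangle
  cot_at <- function(p, q, r) {
    # cotangent of angle at p in triangle (p, q, r)
    u <- V[q, , drop = FALSE] - V[p, , drop = FALSE]
    w <- V[r, , drop = FALSE] - V[p, , drop = FALSE]
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    area2 <- sqrt(rowSums(cr^2))
    if (any(area2 < 1e-300)) stop("degenerate triangle: undefined cotangent")
    rowSums(u * w) / area2
  }
  # edge (2,3) is opposite corner 1, etc.
  ii <- c(F[, 2], F[, 3], F[, 1])
  jj <- c(F[, 3], F[, 1], F[, 2])
  ww <- c(cot_at(F[, 1], F[, 2], F[, 3]),
          cot_at(F[, 2], F[, 3], F[, 1]),
          cot_at(F[, 3], F[, 1], F[, 2])) / 2
  lo <- pmin(ii, jj); hi <- pmax(ii, jj)
  key <- paste(lo, hi)
  agg <- rowsum(ww, key)
  uk <- !duplicated(key)
  ei <- lo[uk]; ej <- hi[uk]
  ew <- as.numeric(agg[match(key[uk], rownames(agg)), 1])
  n_neg <- sum(ew < 0)
  if (clamp) ew <- pmax(ew, 0)
  n <- nrow(V)
  L <- Matrix::sparseMatrix(
    i = c(ei, ej, ei, ej),
    j = c(ej, ei, ei, ej),
    x = c(-ew, -ew, ew, ew),
    dims = c(n, n))
  attr(L, "n_negative_weights") <- n_neg
  attr(L, "edge_weights") <- data.frame(i = ei, j = ej, w = ew)
  L
}

#' Dirichlet constraints for the harmonic solve
#'
#' Maps boundary loops to fixed scalar values.  The package convention is
#' optic-nerve-head canal ring (shortest loop) = 0 and equator ring (longest
#' loop) = 1, so the solved field increases from the canal to the equator.
#'
#' @param loops list of boundary loops from [extract_boundary_loops()]
#'   (sorted longest first).
#' @param values numeric vector, one value per loop; default `c(1, 0)` for
#'   the two-loop shell (equator = 1, canal = 0).
#' @return a `harmonic_constraints` object: integer vertex indices and values.
#' @export
harmonic_constraints <- function(loops, values = NULL) {
  if (is.null(values)) {
    if (length(loops) != 2L) {
      stop("default constraint values need exactly two boundary loops")
    }
    values <- c(1, 0)
  }
  if (length(values) != length(loops)) stop("one value per loop required")
  # equal values on all loops are admitted: the solution is the constant
  # field (useful as a degenerate check); meshing needs distinct values
  idx <- unlist(lapply(loops, `[[`, "vertex_indices"))
  val <- rep(values, vapply(loops, function(l) length(l$vertex_indices),
                            integer(1)))
  structure(list(vertices = idx, values = val, loop_values = values),
            class = "harmonic_constraints")
}

#' Solve the constrained harmonic problem
#'
#' Finds the per-vertex scalar field with zero discrete Laplacian at every
#' free vertex, subject to Dirichlet values on the constrained vertices.
#' The reduced symmetric positive-definite system is solved directly
#' (sparse Cholesky) below `direct_max` unknowns, and otherwise by
#' Jacobi-preconditioned conjugate gradients to relative residual `tol`.
#'
#' @param surface a [tri_surface()].
#' @param constraints a [harmonic_constraints()] object; if `NULL` the
#'   default canal = 0 / equator = 1 constraints are built from the
#'   surface's boundary loops.
#' @param tol relative residual tolerance for the iterative path (default
#'   `1e-10`).
#' @param direct_max maximum number of unknowns for the direct path
#'   (default `5e4`).
#' @param laplacian optionally a precomputed [cotangent_laplacian()].
#' @return a `harmonic_field` object: `values` (per-vertex), `constraints`,
#'   `n_negative_weights`, `residual` (max abs Laplacian at free vertices).
#' @export
solve_harmonic <- function(surface, constraints = NULL, tol = 1e-10,
                           direct_max = 5e4, laplacian = NULL) {
  if (is.null(constraints)) {
    constraints <- harmonic_constraints(extract_boundary_loops(surface))
  }
  L <- laplacian %||% cotangent_laplacian(surface)
  n <- nrow(surface$vertices)
  fixed <- constraints$vertices
  if (anyDuplicated(fixed)) stop("constrained vertex listed twice")
  free <- setdiff(seq_len(n), fixed)
  f <- numeric(n)
  f[fixed] <- constraints$values
  if (length(free)) {
    A <- L[free, free, drop = FALSE]
    b <- -L[free, fixed, drop = FALSE] %*% f[fixed]
    if (length(free) <= direct_max) {
      x <- tryCatch(
        as.numeric(Matrix::solve(A, b)),
        error = function(e) stop("singular reduced system: ", conditionMessage(e)))
    } else {
      x <- pcg_solve(A, as.numeric(b), tol = tol)
    }
    f[free] <- x
  }
  res <- as.numeric(L %*% f)
  structure(
    list(values = f,
         constraints = constraints,
         n_negative_weights = attr(L, "n_negative_weights"),
         residual = if (length(free)) max(abs(res[free])) else 0),
    class = "harmonic_field")
}

# Jacobi-preconditioned conjugate gradients for sparse SPD systems
pcg_solve <- function(A, b, tol = 1e-10, maxit = 10000L) {
  d <- Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * nb) return(x)
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("conjugate gradient did not converge within ", maxit, " iterations")
}

#' @exportS3Method base::print
print.harmonic_field <- function(x, ...) {
  cat(sprintf("<harmonic_field> %d vertices, range [%.4g, %.4g], residual %.3g\n",
              length(x$values), min(x$values), max(x$values), x$residual))
  if (x$n_negative_weights > 0) {
    cat(sprintf("  note: %d negative cotangent weights (obtuse triangles)\n",
                x$n_negative_weights))
  }
  invisible(x)
}

#' Per-triangle gradient of a piecewise-linear scalar field
#'
#' The gradient of the linear interpolant is constant on each triangle and
#' tangent to its plane: `g = (f_j - f_i) (n x e_ki) / (2A) + (f_k - f_i)
#' (n x e_ij) / (2A)` in the standard rotated-edge form.
#'
#' @param surface a [tri_surface()].
#' @param field a `harmonic_field` or a plain numeric vector of per-vertex
#'   values.
#' @return numeric m x 3 matrix of per-triangle gradients (1/mm).
#' @export
field_gradient <- function(surface, field) {
  f <- if (inherits(field, "harmonic_field")) field$values else field
  V <- surface$vertices; F <- surface$triangles
  p1 <- V[F[, 1], , drop = FALSE]
  p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  e1 <- p3 - p2   # edge opposite vertex 1
  e2 <- p1 - p3
  e3 <- p2 - p1
  nrm <- triangle_normals(V, F)
  n <- nrm$unit
  area2 <- sqrt(rowSums(nrm$raw^2))  # 2 * area
  rot <- function(e) cbind(n[, 2] * e[, 3] - n[, 3] * e[, 2],
                           n[, 3] * e[, 1] - n[, 1] * e[, 3],
                           n[, 1] * e[, 2] - n[, 2] * e[, 1])
  (f[F[, 1]] * rot(e1) + f[F[, 2]] * rot(e2) + f[F[, 3]] * rot(e3)) / area2
}
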