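#' Per-element material frames from the harmonic field
#'
#' At each element centroid's projection onto the source surface, the frame
#' is: `y` = meridional axis, the normalized field gradient oriented toward
#' the canal (descending field); `z` = through-thickness axis, the outward
#' surface normal re-orthogonalized against `y`; `x = y x z` = the
#' circumferential axis, tangent to the local isocontour and following the
#' equator-loop winding.  This encodes the predominantly circumferential
#' arrangement of scleral collagen fibres around the optic nerve head.
#'
#' @param mesh a [hex_mesh()] generated from `surface`/`field`.
#' @param surface the outer [tri_surface()].
#' @param field the `harmonic_field` solved on `surface`.
#' @return a `material_frames` object: matrices `x`, `y`, `z` (m x 3 unit
#'   vectors per element).
#' @export
assign_local_frames <- function(mesh, surface, field) {
  E8 <- mesh$elements[, 1:8, drop = FALSE]
  cent <- matrix(0, nrow(E8), 3L)
  for (k in 1:8) cent <- cent + mesh$nodes[E8[, k], , drop = FALSE]
  cent <- cent / 8
  cp <- closest_point_on_surface(cent, surface)
  # area-weighted per-vertex normals and gradients, interpolated at the
  # projection point: smoother than the raw per-triangle quantities, so the
  # frames vary continuously over the faceted surface
  F <- surface$triangles
  raw_n <- triangle_normals(surface$vertices, F)$raw   # area-scaled
  gtri <- field_gradient(surface, field)
  areas <- triangle_areas(surface)
  nv <- nrow(surface$vertices)
  add_group <- function(M, idx, vals) {
    s <- rowsum(vals, idx)
    rows <- as.integer(rownames(s))
    M[rows, ] <- M[rows, ] + s
    M
  }
  vn <- matrix(0, nv, 3L)
  vg <- matrix(0, nv, 3L)
  for (k in 1:3) {
    vn <- add_group(vn, F[, k], raw_n)
    vg <- add_group(vg, F[, k], gtri * areas)
  }
  interp <- function(M) {
    out <- cp$bary[, 1] * M[F[cp$triangle, 1], , drop = FALSE] +
      cp$bary[, 2] * M[F[cp$triangle, 2], , drop = FALSE] +
      cp$bary[, 3] * M[F[cp$triangle, 3], , drop = FALSE]
    out / sqrt(rowSums(out^2))
  }
  g <- interp(vg)
  gmag <- sqrt(rowSums(field_gradient(surface, field)[cp$triangle, ,
                                                      drop = FALSE]^2))
  if (any(gmag < 1e-14)) stop("zero field gradient at a projection point")
  y <- -g                                          # toward the canal
  n <- interp(vn)
  z <- n - rowSums(n * y) * y
  z <- z / sqrt(rowSums(z^2))
  x <- cbind(y[, 2] * z[, 3] - y[, 3] * z[, 2],
             y[, 3] * z[, 1] - y[, 1] * z[, 3],
             y[, 1] * z[, 2] - y[, 2] * z[, 1])
  structure(list(x = x, y = y, z = z), class = "material_frames")
}

#' @exportS3Method base::print
print.material_frames <- function(x, ...) {
  cat(sprintf("<material_frames> %d elements\n", nrow(x$x)))
  invisible(x)
}

#' Label elements into scleral regions by harmonic field value
#'
#' Elements are banded by the field value `u` at their mid-level:
#' `u < u1` is `ONH_ADJACENT` (sclera bordering the canal), `u1 <= u < u2`
#' is `PERIPAPILLARY`, the rest `PERIPHERAL`.  The band boundaries are
#' isocontour-aligned by construction.
#'
#' @param mesh a [hex_mesh()] with per-element `u` metadata (as produced by
#'   [assemble_hex_mesh()]); alternatively supply `u` directly.
#' @param u1,u2 thresholds, `0 < u1 < u2 < 1` (defaults 0.15 and 0.45).
#' @param u optional explicit per-element field values.
#' @return factor of region labels, one per element.
#' @export
label_regions <- function(mesh, u1 = 0.15, u2 = 0.45, u = NULL) {
  if (!(u1 > 0 && u1 < u2 && u2 < 1)) stop("need 0 < u1 < u2 < 1")
  if (is.null(u)) {
    if (is.null(mesh$meta) || is.null(mesh$meta$u)) {
      stop("mesh has no per-element field metadata; supply u")
    }
    u <- mesh$meta$u
  }
  factor(ifelse(u < u1, "ONH_ADJACENT",
                ifelse(u < u2, "PERIPAPILLARY", "PERIPHERAL")),
         levels = c("ONH_ADJACENT", "PERIPAPILLARY", "PERIPHERAL"))
}

#' Fibre-rotation scheme r0 ... r10
#'
#' Scheme `k = 0` is the perfect circumferential arrangement.  For
#' `k >= 1`, peripheral fibres are rotated by `min(k * 10, 90)` degrees
#' about the local thickness axis and peripapillary fibres by ten degrees
#' less, so the sequence runs r1 = (0, 10), r2 = (10, 20), r3 = (20, 30),
#' ... and ends at r10 = (80, 90), where the peripheral fibres are exactly
#' meridional.  Canal-adjacent elements rotate with the peripapillary
#' angle.
#'
#' @param k scheme id, 0..10 (`"r3"` style strings accepted).
#' @return a `fiber_rotation_scheme` with `k`, `angle_peripapillary`,
#'   `angle_peripheral` (degrees).
#' @export
fiber_rotation_scheme <- function(k) {
  if (is.character(k)) k <- as.integer(sub("^[rR]", "", k))
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k > 10L) stop("unknown scheme id (use 0..10)")
  peripheral <- if (k >= 1L) min(k * 10, 90) else 0
  structure(list(k = k,
                 angle_peripapillary = if (k >= 1L) peripheral - 10 else 0,
                 angle_peripheral = peripheral),
            class = "fiber_rotation_scheme")
}

#' Rotate material frames by a fibre-rotation scheme
#'
#' Rotates `x` and `y` about the local `z` axis by the region's angle
#' (a hard switch at the band boundary); `z` is unchanged and
#' orthonormality is preserved exactly.
#'
#' @param frames a [assign_local_frames()] result.
#' @param labels region labels from [label_regions()].
#' @param scheme a [fiber_rotation_scheme()] or scheme id.
#' @return rotated `material_frames`.
#' @export
apply_rotation_scheme <- function(frames, labels, scheme) {
  if (!inherits(scheme, "fiber_rotation_scheme")) {
    scheme <- fiber_rotation_scheme(scheme)
  }
  ang <- rep(0, length(labels))
  ang[labels %in% c("ONH_ADJACENT", "PERIPAPILLARY")] <-
    scheme$angle_peripapillary
  ang[labels == "PERIPHERAL"] <- scheme$angle_peripheral
  th <- ang * pi / 180
  ct <- cos(th); st <- sin(th)
  x_new <- ct * frames$x + st * frames$y
  y_new <- -st * frames$x + ct * frames$y
  structure(list(x = x_new, y = y_new, z = frames$z),
            class = "material_frames")
}

#' Orthotropic elastic material
#'
#' Three Young's moduli along the local circumferential (`x`), meridional
#' (`y`) and thickness (`z`) axes, a single Poisson ratio applied to the
#' three coupling pairs (with reciprocal counterparts derived from
#' symmetry), and shear moduli closed by `G_ij = sqrt(E_i E_j) / (2 (1 +
#' nu))` unless supplied — a rule that reduces exactly to the isotropic
#' shear modulus when the moduli coincide.  Positive definiteness of the
#' stiffness is verified at construction.
#'
#' @param E_x,E_y,E_z Young's moduli (MPa); defaults are the scleral
#'   constants 8.6, 6 and 2.5 MPa.
#' @param nu Poisson ratio (default 0.49, near-incompressible).
#' @param G_yz,G_xz,G_xy optional shear-modulus overrides (MPa).
#' @return an `orthotropic_material` with the local 6x6 stiffness `C_local`
#'   (Voigt order xx, yy, zz, yz, xz, xy; engineering shears).
#' @export
orthotropic_material <- function(E_x = 8.6, E_y = 6, E_z = 2.5, nu = 0.49,
                                 G_yz = NULL, G_xz = NULL, G_xy = NULL) {
  if (any(c(E_x, E_y, E_z) <= 0)) stop("moduli must be positive")
  G_yz <- G_yz %||% (sqrt(E_y * E_z) / (2 * (1 + nu)))
  G_xz <- G_xz %||% (sqrt(E_x * E_z) / (2 * (1 + nu)))
  G_xy <- G_xy %||% (sqrt(E_x * E_y) / (2 * (1 + nu)))
  S <- diag(c(1 / E_x, 1 / E_y, 1 / E_z, 1 / G_yz, 1 / G_xz, 1 / G_xy))
  S[1, 2] <- S[2, 1] <- -nu / E_x   # nu_xy / E_x = nu_yx / E_y
  S[1, 3] <- S[3, 1] <- -nu / E_x   # nu_xz / E_x
  S[2, 3] <- S[3, 2] <- -nu / E_y   # nu_yz / E_y
  C <- solve(S)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("non-positive-definite stiffness for E = (", E_x, ", ", E_y, ", ",
         E_z, "), nu = ", nu)
  }
  structure(list(E_x = E_x, E_y = E_y, E_z = E_z, nu = nu,
                 G_yz = G_yz, G_xz = G_xz, G_xy = G_xy,
                 C_local = (C + t(C)) / 2),
            class = "orthotropic_material")
}

#' Isotropic elastic material
#'
#' @param E Young's modulus (MPa); the default 3.8 MPa is the direction
#'   average used for the isotropic scleral comparison model.
#' @param nu Poisson ratio (default 0.49).
#' @return an `isotropic_material` with the 6x6 stiffness `C_local`.
#' @export
isotropic_material <- function(E = 3.8, nu = 0.49) {
  if (E <= 0) stop("modulus must be positive")
  if (!(nu > 0 && nu < 0.5)) stop("need 0 < nu < 0.5")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  C[1:3, 1:3] <- C[1:3, 1:3] + lam
  structure(list(E = E, nu = nu, C_local = C),
            class = "isotropic_material")
}

# Bond stress-transformation matrix for Voigt order (xx,yy,zz,yz,xz,xy):
# sigma_global(voigt) = M %*% sigma_local(voigt), R columns = local axes
bond_matrix <- function(R) {
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- R^2
  M[1, 4:6] <- 2 * c(R[1, 2] * R[1, 3], R[1, 1] * R[1, 3], R[1, 1] * R[1, 2])
  M[2, 4:6] <- 2 * c(R[2, 2] * R[2, 3], R[2, 1] * R[2, 3], R[2, 1] * R[2, 2])
  M[3, 4:6] <- 2 * c(R[3, 2] * R[3, 3], R[3, 1] * R[3, 3], R[3, 1] * R[3, 2])
  M[4, 1:3] <- c(R[2, 1] * R[3, 1], R[2, 2] * R[3, 2], R[2, 3] * R[3, 3])
  M[5, 1:3] <- c(R[1, 1] * R[3, 1], R[1, 2] * R[3, 2], R[1, 3] * R[3, 3])
  M[6, 1:3] <- c(R[1, 1] * R[2, 1], R[1, 2] * R[2, 2], R[1, 3] * R[2, 3])
  M[4, 4] <- R[2, 2] * R[3, 3] + R[2, 3] * R[3, 2]
  M[4, 5] <- R[2, 1] * R[3, 3] + R[2, 3] * R[3, 1]
  M[4, 6] <- R[2, 1] * R[3, 2] + R[2, 2] * R[3, 1]
  M[5, 4] <- R[1, 2] * R[3, 3] + R[1, 3] * R[3, 2]
  M[5, 5] <- R[1, 1] * R[3, 3] + R[1, 3] * R[3, 1]
  M[5, 6] <- R[1, 1] * R[3, 2] + R[1, 2] * R[3, 1]
  M[6, 4] <- R[1, 2] * R[2, 3] + R[1, 3] * R[2, 2]
  M[6, 5] <- R[1, 1] * R[2, 3] + R[1, 3] * R[2, 1]
  M[6, 6] <- R[1, 1] * R[2, 2] + R[1, 2] * R[2, 1]
  M
}

#' Global 6x6 stiffness for a material in a given frame
#'
#' Rotates the local-frame stiffness to global coordinates via the 6x6
#' stress-transformation (Bond) operator: `C_g = M C_l M^T`.
#'
#' @param material an [orthotropic_material()] or [isotropic_material()].
#' @param frame either `NULL` (identity frame), a 3x3 rotation matrix whose
#'   columns are the local axes in global coordinates, or a list with unit
#'   vectors `x`, `y`, `z`.
#' @return symmetric positive-definite 6x6 stiffness (MPa), Voigt order
#'   (xx, yy, zz, yz, xz, xy).
#' @export
build_stiffness <- function(material, frame = NULL) {
  C <- material$C_local
  if (is.null(frame)) return(C)
  R <- if (is.matrix(frame)) frame else cbind(frame$x, frame$y, frame$z)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) {
    stop("frame axes are not orthonormal")
  }
  M <- bond_matrix(R)
  Cg <- M %*% C %*% t(M)
  (Cg + t(Cg)) / 2
}

# stacked 36 x E global stiffness matrices for a mesh
element_stiffness_stack <- function(n_elements, material, frames = NULL) {
  if (is.null(frames) || inherits(material, "isotropic_material")) {
    # isotropic stiffness is frame-invariant; orthotropic requires frames
    if (is.null(frames) && inherits(material, "orthotropic_material")) {
      stop("orthotropic material requires per-element frames")
    }
    return(matrix(as.vector(material$C_local), 36L, n_elements))
  }
  out <- matrix(NA_real_, 36L, n_elements)
  for (e in seq_len(n_elements)) {
    R <- cbind(frames$x[e, ], frames$y[e, ], frames$z[e, ])
    out[, e] <- as.vector(build_stiffness(material, R))
  }
  out
}
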