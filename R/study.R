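#' Build the full hexahedral sclera mesh from a fixture or surface pair
#'
#' Runs the meshing pipeline: harmonic field on the outer and inner
#' surfaces, seed sampling and streamline tracing, structured grid
#' extraction, layer interpolation, hex assembly, optional 20-node
#' conversion, material frames and region labels.  Inner-surface seeds are
#' placed at the same normalized arc-length parameters as the outer seeds
#' with the phase that minimizes the summed distance between matched
#' equator points, so the three node layers share one topology.
#'
#' @param fixture result of [make_sclera_fixture()], or a list with
#'   elements `outer` and `inner` ([tri_surface()]s).
#' @param n circumferential resolution (streamlines; default 40).
#' @param m meridional resolution (field levels; default 34).
#' @param n_layers element layers through the thickness (default 2).
#' @param order 8 or 20 (default 20).
#' @param u1,u2 region thresholds passed to [label_regions()].
#' @return list with `mesh` ([hex_mesh()] with frames and labels attached),
#'   `fixture`, `field_outer`, `field_inner`, `grid_outer`, `grid_inner`,
#'   `frames`, `labels`, `quality` ([dihedral_quality()] report).
#' @export
build_shell_mesh <- function(fixture, n = 40L, m = 34L, n_layers = 2L,
                             order = 20L, u1 = 0.15, u2 = 0.45) {
  outer <- fixture$outer; inner <- fixture$inner
  field_out <- solve_harmonic(outer)
  field_in <- solve_harmonic(inner)
  grid_out <- trace_surface_grid(outer, field_out, n, m, phase = 0)

  # match inner seeds to outer seeds by minimizing summed equator distance
  loops_in <- extract_boundary_loops(inner)
  eq_in <- loops_in[[1]]
  outer_seeds <- t(vapply(seq_len(n), function(i) grid_out$points[i, 1, ],
                          numeric(3)))
  obj <- function(phase) {
    s <- phase + eq_in$total_length * (seq_len(n) - 1L) / n
    pts <- t(vapply(s, function(si) loop_point_at(eq_in, inner, si)$point,
                    numeric(3)))
    sum(rowSums((pts - outer_seeds)^2))
  }
  coarse <- seq(0, eq_in$total_length, length.out = 257L)[-257L]
  vals <- vapply(coarse, obj, numeric(1))
  k0 <- which.min(vals)
  win <- eq_in$total_length / 256
  phase <- stats::optimize(obj, interval = coarse[k0] + c(-win, win))$minimum
  grid_in <- trace_surface_grid(inner, field_in, n, m, phase = phase)

  layers <- interpolate_middle_layer(grid_out, grid_in, n_layers)
  mesh <- assemble_hex_mesh(layers)
  quality <- dihedral_quality(mesh)
  if (order == 20L) {
    mesh <- convert_to_20node(mesh, outer = outer, inner = inner)
  } else if (order != 8L) stop("order must be 8 or 20")
  frames <- assign_local_frames(mesh, outer, field_out)
  labels <- label_regions(mesh, u1 = u1, u2 = u2)
  mesh$frames <- frames
  mesh$region <- as.character(labels)
  list(mesh = mesh, fixture = fixture, field_outer = field_out,
       field_inner = field_in, grid_outer = grid_out, grid_inner = grid_in,
       frames = frames, labels = labels, quality = quality)
}

#' Solve one shell model (isotropic or a fibre-rotation scheme)
#'
#' @param shell a [build_shell_mesh()] result.
#' @param model `"isotropic"` or a scheme id 0..10 / `"r0"`..`"r10"`
#'   (`"r0"` is the perfect circumferential anisotropic model).
#' @param iop_mmhg intraocular pressure (default 30 mmHg).
#' @param material optional override of the orthotropic constants.
#' @param material_iso optional override of the isotropic material.
#' @return an `fe_result`.
#' @export
solve_shell_model <- function(shell, model, iop_mmhg = 30,
                              material = orthotropic_material(),
                              material_iso = isotropic_material()) {
  if (identical(model, "isotropic")) {
    prob <- fe_problem(shell$mesh, material_iso,
                       pressure_mmhg = iop_mmhg)
  } else {
    scheme <- fiber_rotation_scheme(model)
    frames <- apply_rotation_scheme(shell$frames, shell$labels, scheme)
    prob <- fe_problem(shell$mesh, material, frames = frames,
                       pressure_mmhg = iop_mmhg)
  }
  assemble_and_solve(prob)
}

#' Isotropic-versus-anisotropic comparison study
#'
#' Solves the same mesh once per model (isotropic average material, perfect
#' circumferential orthotropic, and the ten fibre-rotation schemes) under
#' identical pressure and boundary conditions, and tabulates region-wise
#' maxima of displacement, principal stress, principal strain and
#' equivalent strain.
#'
#' @param shell a [build_shell_mesh()] result (or a
#'   [sclera_fixture_spec()], in which case the mesh is built first at the
#'   given resolution).
#' @param models character vector of models (default isotropic + r0..r10).
#' @param iop_mmhg intraocular pressure (default 30).
#' @param n,m mesh resolution used when `shell` is a spec.
#' @param keep_results keep the full `fe_result` objects (default FALSE).
#' @return a `comparison_study`: tibble `table` (model x region metrics),
#'   `global` (per-model global maxima), optionally `results`.
#' @export
run_comparison_study <- function(shell, models = c("isotropic",
                                                   paste0("r", 0:10)),
                                 iop_mmhg = 30, n = 40L, m = 34L,
                                 keep_results = FALSE) {
  if (inherits(shell, "sclera_fixture_spec")) {
    shell <- build_shell_mesh(make_sclera_fixture(shell), n = n, m = m)
  }
  rows <- list(); glob <- list(); res_list <- list()
  for (mod in models) {
    res <- solve_shell_model(shell, mod, iop_mmhg = iop_mmhg)
    rm <- region_maxima(res, shell$labels)
    rm$model <- mod
    rows[[mod]] <- rm
    glob[[mod]] <- tibble::tibble(
      model = mod,
      max_displacement = max(sqrt(rowSums(res$u^2))),
      max_principal_stress = max(principal_values_batch(res$stress)[1, ]),
      max_principal_strain = max(principal_values_batch(
        res$strain, shear_engineering = TRUE)[1, ]),
      max_equivalent_strain = max(equivalent_strain(res$strain)))
    if (keep_results) res_list[[mod]] <- res
  }
  tab <- do.call(rbind, rows)
  tab <- tab[, c("model", setdiff(names(tab), "model"))]
  structure(list(table = tab, global = do.call(rbind, glob),
                 results = if (keep_results) res_list),
            class = "comparison_study")
}

#' @exportS3Method base::print
print.comparison_study <- function(x, ...) {
  cat("<comparison_study>\n")
  print(x$global)
  invisible(x)
}

#' Mesh sensitivity of the perfect anisotropic solve
#'
#' Builds and solves the perfect circumferential anisotropic model at two
#' surface resolutions and reports the relative changes of the maximal
#' displacement magnitude and the maximal principal stress, with the finer
#' mesh as reference.
#'
#' @param spec a [sclera_fixture_spec()].
#' @param res_a,res_b `(n, m)` resolutions; `res_b` must be strictly finer.
#' @param iop_mmhg pressure (default 30).
#' @param order element order (default 20).
#' @return tibble with `metric`, `coarse`, `fine`, `rel_change_percent`.
#' @export
mesh_sensitivity <- function(spec = sclera_fixture_spec(),
                             res_a = c(40L, 34L), res_b = c(60L, 51L),
                             iop_mmhg = 30, order = 20L) {
  if (!(res_b[1] >= res_a[1] && res_b[2] >= res_a[2])) {
    stop("res_b must be at least as fine as res_a")
  }
  fixture <- make_sclera_fixture(spec)
  metrics <- function(nm) {
    shell <- build_shell_mesh(fixture, n = nm[1], m = nm[2], order = order)
    res <- solve_shell_model(shell, "r0", iop_mmhg = iop_mmhg)
    c(max_displacement = max(sqrt(rowSums(res$u^2))),
      max_principal_stress = max(principal_values_batch(res$stress)[1, ]))
  }
  a <- metrics(res_a)
  b <- metrics(res_b)
  tibble::tibble(metric = names(a), coarse = unname(a), fine = unname(b),
                 rel_change_percent = unname(100 * abs(a - b) / b))
}
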