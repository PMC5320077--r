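#' Evenly spaced seed points on a boundary loop
#'
#' Places `n` points at equal arc-length spacing around a boundary loop,
#' starting at arc-length offset `phase`.
#'
#' @param loop a boundary loop from [extract_boundary_loops()].
#' @param surface the owning [tri_surface()].
#' @param n number of seeds (>= 3, <= 4096).
#' @param phase arc-length offset (mm, default 0).
#' @return list of seeds, each with `point`, `edge` (loop edge vertex ids),
#'   `t` (edge parameter) and `s` (arc length).
#' @export
sample_seeds <- function(loop, surface, n, phase = 0) {
  n <- as.integer(n)
  if (n < 3L) stop("need at least 3 seeds")
  if (n > 4096L) stop("seed count exceeds the supported cap (4096)")
  s <- phase + loop$total_length * (seq_len(n) - 1L) / n
  lapply(s, function(si) {
    lp <- loop_point_at(loop, surface, si)
    list(point = lp$point, edge = lp$edge, t = lp$t, s = si %% loop$total_length)
  })
}

# per-triangle tracing tables: hat-function gradients, field gradient,
# neighbors by edge slot (slot 1 = edge 1-2, 2 = 2-3, 3 = 3-1)
tracing_tables <- function(surface, field) {
  f <- if (inherits(field, "harmonic_field")) field$values else field
  V <- surface$vertices; F <- surface$triangles
  nrm <- triangle_normals(V, F)
  area2 <- sqrt(rowSums(nrm$raw^2))
  n <- nrm$unit
  rot <- function(e) cbind(n[, 2] * e[, 3] - n[, 3] * e[, 2],
                           n[, 3] * e[, 1] - n[, 1] * e[, 3],
                           n[, 1] * e[, 2] - n[, 2] * e[, 1])
  p1 <- V[F[, 1], , drop = FALSE]; p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  gphi1 <- rot(p3 - p2) / area2
  gphi2 <- rot(p1 - p3) / area2
  gphi3 <- rot(p2 - p1) / area2
  g <- f[F[, 1]] * gphi1 + f[F[, 2]] * gphi2 + f[F[, 3]] * gphi3
  list(f = f, V = V, F = F,
       gphi = list(gphi1, gphi2, gphi3), grad = g,
       neighbors = triangle_edge_neighbors(F),
       v2t = vertex_triangle_map(F))
}

# barycentric coordinates of 3D point p in triangle t (assumed on its plane)
bary_in_triangle <- function(tt, t, p) {
  vs <- tt$F[t, ]
  a <- tt$V[vs[1], ]; b <- tt$V[vs[2], ]; c <- tt$V[vs[3], ]
  v0 <- b - a; v1 <- c - a; v2 <- p - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  c(1 - v - w, v, w)
}

# slot of the edge opposite local vertex k: opp 1 -> edge (2,3) = slot 2, etc.
.opp_slot <- c(2L, 3L, 1L)

#' Trace a gradient streamline from an equator seed
#'
#' Follows the negative gradient of the harmonic field (descending from the
#' equator value 1 toward the canal value 0) with exact straight segments
#' inside each triangle and exact edge crossings; no step-size integration
#' is involved because the gradient is constant per triangle.  Vertex hits
#' are resolved by a deterministic `1e-12` perturbation toward the triangle
#' interior.  The trace terminates when the field drops to `f_stop` or the
#' canal boundary is reached, and the final point is snapped onto the canal
#' (ONH) loop.
#'
#' @param surface a [tri_surface()].
#' @param field a `harmonic_field`.
#' @param seed a seed from [sample_seeds()].
#' @param f_stop termination level (default 1e-3).
#' @param onh_loop the canal boundary loop (for the terminal snap); if
#'   `NULL` the shortest boundary loop is used.
#' @param tables precomputed [tracing_tables()] (optional, for reuse).
#' @param max_steps step cap (default 100000).
#' @return a `streamline`: data frame with columns `triangle`, `b1 b2 b3`
#'   (barycentric), `x y z`, `f`, plus attribute `seed_s`.
#' @export
trace_streamline <- function(surface, field, seed, f_stop = 1e-3,
                             onh_loop = NULL, tables = NULL,
                             max_steps = 100000L) {
  tt <- tables %||% tracing_tables(surface, field)
  if (is.null(onh_loop)) {
    loops <- extract_boundary_loops(surface)
    onh_loop <- loops[[length(loops)]]
  }
  # starting triangle: the (single) triangle containing the seed edge
  e <- seed$edge
  cand <- intersect(tt$v2t[[e[1]]], tt$v2t[[e[2]]])
  if (length(cand) != 1L) stop("seed is not on a boundary edge")
  tri <- cand
  lam <- bary_in_triangle(tt, tri, seed$point)
  lam <- pmax(lam, 0); lam <- lam / sum(lam)

  samp_tri <- integer(0); samp_lam <- list(); samp_f <- numeric(0)
  record <- function(tri, lam) {
    vs <- tt$F[tri, ]
    fv <- sum(lam * tt$f[vs])
    samp_tri[[length(samp_tri) + 1L]] <<- tri
    samp_lam[[length(samp_lam) + 1L]] <<- lam
    samp_f[[length(samp_f) + 1L]] <<- fv
  }
  record(tri, lam)

  prev_edge_key <- ""
  for (step in seq_len(max_steps)) {
    g <- tt$grad[tri, ]
    gmag <- sqrt(sum(g^2))
    if (gmag < 1e-12) stop("streamline stagnation: gradient magnitude < 1e-12")
    d <- -g
    delta <- c(sum(tt$gphi[[1]][tri, ] * d),
               sum(tt$gphi[[2]][tri, ] * d),
               sum(tt$gphi[[3]][tri, ] * d))
    neg <- which(delta < -1e-300)
    if (!length(neg)) stop("streamline stagnation: no descending direction")
    s_exit <- (-lam[neg] / delta[neg])
    k <- neg[which.min(s_exit)]
    s <- max(min(s_exit), 0)
    lam_new <- lam + s * delta
    lam_new[k] <- 0
    # vertex-hit tie: nudge 1e-12 toward the interior
    small <- which(lam_new < 1e-12)
    if (length(small) > 1L) {
      lam_new[small] <- 1e-12
      lam_new[which.max(lam_new)] <- lam_new[which.max(lam_new)] -
        sum(lam_new) + 1
      lam_new[k] <- 0
    }
    lam_new <- pmax(lam_new, 0); lam_new <- lam_new / sum(lam_new)
    record(tri, lam_new)
    fv <- samp_f[length(samp_f)]

    slot <- .opp_slot[k]
    nb <- tt$neighbors[tri, slot]
    if (is.na(nb)) {
      # boundary reached: done (canal side), snap handled below
      break
    }
    if (fv <= f_stop) break
    # map the crossing point into the neighbor triangle
    p <- drop(lam_new %*% tt$V[tt$F[tri, ], , drop = FALSE])
    ek <- paste(sort(tt$F[tri, setdiff(1:3, k)]), collapse = "_")
    if (identical(ek, prev_edge_key)) {
      # immediate re-crossing of the same edge: slide to the lower-f endpoint
      ev <- tt$F[tri, setdiff(1:3, k)]
      v_low <- ev[which.min(tt$f[ev])]
      esc <- escape_via_vertex(tt, v_low)
      tri <- esc$tri; lam <- esc$lam
      prev_edge_key <- ""
      record(tri, lam)
      next
    }
    prev_edge_key <- ek
    tri <- nb
    lam <- bary_in_triangle(tt, tri, p)
    lam <- pmax(lam, 0); lam <- lam / sum(lam)
    if (step == max_steps) stop("streamline step cap exceeded")
  }

  # snap terminal point to the ONH loop
  end_lam <- samp_lam[[length(samp_lam)]]
  p_end <- drop(end_lam %*% tt$V[tt$F[samp_tri[length(samp_tri)], ], ,
                                 drop = FALSE])
  snap <- snap_to_loop(onh_loop, surface, p_end)
  cand2 <- intersect(tt$v2t[[snap$edge[1]]], tt$v2t[[snap$edge[2]]])
  tri_s <- cand2[1]
  lam_s <- bary_in_triangle(tt, tri_s, snap$point)
  lam_s <- pmax(lam_s, 0); lam_s <- lam_s / sum(lam_s)
  samp_tri <- c(samp_tri, tri_s)
  samp_lam[[length(samp_lam) + 1L]] <- lam_s
  samp_f <- c(samp_f, 0)

  lamm <- do.call(rbind, samp_lam)
  P <- matrix(NA_real_, length(samp_tri), 3L)
  for (i in seq_along(samp_tri)) {
    P[i, ] <- drop(lamm[i, ] %*% tt$V[tt$F[samp_tri[i], ], , drop = FALSE])
  }
  out <- data.frame(triangle = samp_tri, b1 = lamm[, 1], b2 = lamm[, 2],
                    b3 = lamm[, 3], x = P[, 1], y = P[, 2], z = P[, 3],
                    f = samp_f)
  # enforce monotone non-increasing record (duplicate crossings collapse)
  keep <- c(TRUE, diff(out$f) < 0)
  out <- out[keep | seq_len(nrow(out)) == nrow(out), , drop = FALSE]
  attr(out, "seed_s") <- seed$s
  class(out) <- c("streamline", class(out))
  out
}

# restart a stuck trace from a vertex: pick the incident triangle whose
# negative gradient points most steeply into it, and nudge off the corner
escape_via_vertex <- function(tt, v) {
  best <- NULL; best_rate <- Inf
  for (tri in tt$v2t[[v]]) {
    k <- match(v, tt$F[tri, ])
    d <- -tt$grad[tri, ]
    delta_k <- sum(tt$gphi[[k]][tri, ] * d)
    if (delta_k < best_rate) {
      best_rate <- delta_k; best <- list(tri = tri, k = k)
    }
  }
  lam <- rep(1e-9, 3L)
  lam[best$k] <- 1 - 2e-9
  list(tri = best$tri, lam = lam)
}

# closest point on a boundary loop polyline
snap_to_loop <- function(loop, surface, p) {
  vs <- loop$vertex_indices
  A <- surface$vertices[vs, , drop = FALSE]
  B <- surface$vertices[vs[c(2:length(vs), 1L)], , drop = FALSE]
  AB <- B - A
  t <- rowSums(sweep(-A, 2, p, `+`) * AB) / pmax(rowSums(AB^2), 1e-300)
  t <- pmin(pmax(t, 0), 1)
  Q <- A + t * AB
  d2 <- rowSums(sweep(Q, 2, p, `-`)^2)
  i <- which.min(d2)
  list(point = Q[i, ], edge = c(vs[i], vs[if (i == length(vs)) 1L else i + 1L]),
       t = t[i])
}

#' Extract closed isocontours of the harmonic field
#'
#' Marching-triangles extraction by linear interpolation along edges.
#' Vertices whose value ties a requested level are handled by a
#' deterministic `1e-12` shift.  Each contour is oriented with the same
#' winding as the equator loop (tangent along `normal x gradient`).
#'
#' @param surface a [tri_surface()].
#' @param field a `harmonic_field`.
#' @param levels numeric vector of levels strictly inside the constraint
#'   range.
#' @param tables precomputed [tracing_tables()] (optional).
#' @return list of `iso_contour` objects: `level`, `points` (closed
#'   polyline, k x 3, first point not repeated), `length` (mm).
#' @export
extract_isocontours <- function(surface, field, levels, tables = NULL) {
  tt <- tables %||% tracing_tables(surface, field)
  f <- tt$f
  rng <- range(f)
  if (any(levels <= rng[1] | levels >= rng[2])) {
    stop("levels must lie strictly between the field extrema")
  }
  lapply(levels, function(L) {
    fL <- f - L
    fL[fL == 0] <- 1e-12  # tie rule
    F <- tt$F
    s1 <- fL[F[, 1]]; s2 <- fL[F[, 2]]; s3 <- fL[F[, 3]]
    cross12 <- s1 * s2 < 0
    cross23 <- s2 * s3 < 0
    cross31 <- s3 * s1 < 0
    ncross <- cross12 + cross23 + cross31
    tri_ids <- which(ncross == 2L)
    if (!length(tri_ids)) stop("level ", L, " yields no contour")
    edge_pt <- function(a, b) {
      t <- fL[a] / (fL[a] - fL[b])
      (1 - t) * tt$V[a, , drop = FALSE] + t * tt$V[b, , drop = FALSE]
    }
    segs <- vector("list", length(tri_ids))
    keys <- matrix("", length(tri_ids), 2L)
    for (ii in seq_along(tri_ids)) {
      t0 <- tri_ids[ii]
      vs <- F[t0, ]
      crossings <- list()
      ck <- character(0)
      if (cross12[t0]) { crossings <- c(crossings, list(edge_pt(vs[1], vs[2])))
        ck <- c(ck, paste(sort(vs[1:2]), collapse = "_")) }
      if (cross23[t0]) { crossings <- c(crossings, list(edge_pt(vs[2], vs[3])))
        ck <- c(ck, paste(sort(vs[2:3]), collapse = "_")) }
      if (cross31[t0]) { crossings <- c(crossings, list(edge_pt(vs[3], vs[1])))
        ck <- c(ck, paste(sort(vs[c(3, 1)]), collapse = "_")) }
      segs[[ii]] <- rbind(crossings[[1]], crossings[[2]])
      keys[ii, ] <- ck
    }
    # chain segments by shared edge keys
    used <- rep(FALSE, length(tri_ids))
    comp_pts <- list()
    while (any(!used)) {
      start <- which(!used)[1]
      used[start] <- TRUE
      pts <- list(segs[[start]][1, ], segs[[start]][2, ])
      tang <- tt$grad[tri_ids[start], ]
      first_key <- keys[start, 1]
      cur_key <- keys[start, 2]
      repeat {
        nxt <- which(!used & (keys[, 1] == cur_key | keys[, 2] == cur_key))
        if (!length(nxt)) break
        nxt <- nxt[1]
        used[nxt] <- TRUE
        if (keys[nxt, 1] == cur_key) {
          pts[[length(pts) + 1L]] <- segs[[nxt]][2, ]
          cur_key <- keys[nxt, 2]
        } else {
          pts[[length(pts) + 1L]] <- segs[[nxt]][1, ]
          cur_key <- keys[nxt, 1]
        }
      }
      closed <- identical(cur_key, first_key)
      if (!closed) stop("open isocontour at level ", L,
                        " (non-annular topology)")
      P <- do.call(rbind, pts)
      P <- P[-nrow(P), , drop = FALSE]  # drop duplicated closing point
      comp_pts[[length(comp_pts) + 1L]] <- P
    }
    if (length(comp_pts) != 1L) {
      stop("level ", L, " yields ", length(comp_pts),
           " components (non-annular topology)")
    }
    P <- comp_pts[[1]]
    # orient along normal x gradient (the equator-loop winding)
    ctr <- colMeans(P)
    nearest <- closest_point_on_surface(matrix(ctr, 1), surface)
    tri0 <- nearest$triangle[1]
    nrm <- triangle_normals(tt$V, tt$F)$unit[tri0, ]
    g <- tt$grad[tri0, ]
    ref <- c(nrm[2] * g[3] - nrm[3] * g[2],
             nrm[3] * g[1] - nrm[1] * g[3],
             nrm[1] * g[2] - nrm[2] * g[1])
    seg_dir <- P[c(2:nrow(P), 1L), , drop = FALSE] - P
    # use the segment nearest the reference triangle for the sign test
    dots <- sum(seg_dir[which.min(rowSums(sweep(P, 2, ctr)^2)), ] * ref)
    total <- 0
    for (i in seq_len(nrow(P))) {
      q <- closest_point_on_surface(P[i, , drop = FALSE], surface)
      gq <- tt$grad[q$triangle[1], ]
      nq <- triangle_normals(tt$V, tt$F)$unit[q$triangle[1], ]
      refq <- c(nq[2] * gq[3] - nq[3] * gq[2],
                nq[3] * gq[1] - nq[1] * gq[3],
                nq[1] * gq[2] - nq[2] * gq[1])
      total <- total + sum(seg_dir[i, ] * refq)
      if (i >= 8) break  # a few segments decide the winding
    }
    if (total < 0) P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
    seg <- sqrt(rowSums((P[c(2:nrow(P), 1L), , drop = FALSE] - P)^2))
    structure(list(level = L, points = P, length = sum(seg)),
              class = "iso_contour")
  })
}

#' @exportS3Method base::print
print.iso_contour <- function(x, ...) {
  cat(sprintf("<iso_contour> level %.4g, %d points, length %.4f mm\n",
              x$level, nrow(x$points), x$length))
  invisible(x)
}

#' Build the structured surface quad grid
#'
#' Combines `n` streamlines (columns) and `m` evenly spaced field levels
#' (rows) into an `n x m` structured grid of on-surface nodes.  Row 1 lies
#' exactly on the equator loop (the seed points), row `m` exactly on the
#' canal loop (the snapped streamline ends); interior row `j` holds the
#' unique point of each streamline at level `1 - (j-1)/(m-1)`, found by
#' monotone interpolation along the streamline's sample sequence.
#'
#' @param streamlines list of [trace_streamline()] results, one per seed.
#' @param m number of rows (levels), >= 3.
#' @return a `surface_grid`: `points` (array n x m x 3), `levels` (length
#'   m), `n`, `m`.
#' @export
build_surface_grid <- function(streamlines, m) {
  n <- length(streamlines)
  m <- as.integer(m)
  if (m < 3L) stop("need at least 3 rows")
  levels <- 1 - (seq_len(m) - 1L) / (m - 1L)
  P <- array(NA_real_, c(n, m, 3L))
  for (i in seq_len(n)) {
    sl <- streamlines[[i]]
    P[i, 1, ] <- as.numeric(sl[1, c("x", "y", "z")])
    P[i, m, ] <- as.numeric(sl[nrow(sl), c("x", "y", "z")])
    fs <- sl$f
    if (min(fs) > min(levels[-m])) {
      stop("streamline ", i, " terminated above the smallest interior level")
    }
    for (j in 2:(m - 1L)) {
      L <- levels[j]
      k <- which(fs[-length(fs)] >= L & fs[-1] < L)[1]
      if (is.na(k)) stop("level ", L, " not bracketed on streamline ", i)
      t <- (fs[k] - L) / (fs[k] - fs[k + 1])
      P[i, j, ] <- (1 - t) * as.numeric(sl[k, c("x", "y", "z")]) +
        t * as.numeric(sl[k + 1, c("x", "y", "z")])
    }
  }
  structure(list(points = P, levels = levels, n = n, m = m),
            class = "surface_grid")
}

#' @exportS3Method base::print
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %d x %d nodes (circumferential x meridional)\n",
              x$n, x$m))
  invisible(x)
}

#' Trace the full grid for one surface
#'
#' Convenience wrapper: solves nothing, just runs seeds, streamlines and
#' grid assembly for a surface whose harmonic field is already available.
#'
#' @param surface a [tri_surface()].
#' @param field a `harmonic_field`.
#' @param n circumferential resolution (streamlines).
#' @param m meridional resolution (levels).
#' @param phase seed phase (arc length, mm).
#' @return a `surface_grid`.
#' @export
trace_surface_grid <- function(surface, field, n, m, phase = 0) {
  loops <- extract_boundary_loops(surface)
  if (length(loops) != 2L) stop("surface must have exactly two boundary loops")
  tt <- tracing_tables(surface, field)
  seeds <- sample_seeds(loops[[1]], surface, n, phase)
  lines <- lapply(seeds, function(sd) {
    trace_streamline(surface, field, sd, onh_loop = loops[[2]], tables = tt)
  })
  build_surface_grid(lines, m)
}
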