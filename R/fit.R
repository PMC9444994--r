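# Template personalization: pose initialization, iterative projection
# fitting with Laplacian displacement smoothing, fit accuracy, and the
# contraction field between corresponded ED/ES meshes.

#' Fitting configuration
#'
#' @param max_iterations Maximum projection/smoothing iterations.
#' @param tolerance Convergence tolerance (mm) on mean node movement.
#' @param lambda Laplacian smoothing weight (>= 0) on the displacement field
#'   from the initialized template.
#' @param init_pose Run similarity initialization before fitting.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(max_iterations = 30, tolerance = 0.01, lambda = 0.5,
                       init_pose = TRUE) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (max_iterations < 1) stop("max_iterations must be at least 1")
  if (lambda < 0) stop("lambda must be non-negative")
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, lambda = lambda,
                 init_pose = isTRUE(init_pose)),
            class = "fit_config")
}

# Mean radius of a polygon about its centroid.
poly_radius <- function(poly) {
  ctr <- colMeans(poly)
  mean(sqrt((poly[, 1] - ctr[1])^2 + (poly[, 2] - ctr[2])^2))
}

#' Initialize the template pose from contours
#'
#' Estimates an in-plane rotation (anterior marker onto the template anterior
#' meridian), a translation (contour centroid), a longitudinal scale from the
#' apex-base slice extent (the template apex is placed half a slice gap below
#' the most apical ring-bearing slice), and an in-plane scale from the mean
#' mid-cavity endocardial radius.
#'
#' @param template An `lv_template` (canonical orientation).
#' @param contours An `lv_contours` object with at least 3 slices.
#' @return A pose: list with `rot` (3 x 3), `s_xy`, `s_z`, `translation`.
#' @export
initialize_pose <- function(template, contours) {
  sl <- contours$slices
  if (length(sl) < 3) stop("at least 3 contour-bearing slices required")
  zs <- vapply(sl, `[[`, numeric(1), "z")
  gap <- contours$slice_gap
  z_hi <- max(zs) + gap / 2
  # Sub-slice apex localization: near the apex the cavity cross-section area
  # shrinks linearly with height, so extrapolating the two most apical
  # endocardial areas to zero places the endo apex below the lowest slice
  # with sub-slice resolution.
  shoelace <- function(p) {
    abs(sum(p[, 1] * c(p[-1, 2], p[1, 2]) - c(p[-1, 1], p[1, 1]) * p[, 2])) / 2
  }
  ord_z <- order(zs)
  z_lo <- min(zs) - gap / 2
  # The apical cap below the last ring-bearing slice is anatomically at most
  # about a centimetre; estimates are clamped to that range.
  z_floor <- min(zs) - max(gap, 10)
  z_ceil <- min(zs) - gap / 8
  if (length(sl) >= 2) {
    a1 <- shoelace(sl[[ord_z[1]]]$endo)
    a2 <- shoelace(sl[[ord_z[2]]]$endo)
    if (a2 > a1 && a1 > 0) {
      apex <- zs[ord_z[1]] - a1 * (zs[ord_z[2]] - zs[ord_z[1]]) / (a2 - a1)
      z_lo <- min(max(apex, zs[ord_z[1]] - gap), z_ceil)
    }
    # For an ellipsoidal cavity the cross-section area is exactly quadratic
    # in z, so the root of the quadratic through the three most apical areas
    # localizes the endocardial apex; linear extrapolation systematically
    # overshoots. Kept only when the root is real and anatomically plausible.
    if (length(sl) >= 3) {
      z3 <- zs[ord_z[1:3]]
      a3 <- c(a1, a2, shoelace(sl[[ord_z[3]]]$endo))
      # solved in offsets from the lowest slice so the estimate is exactly
      # translation-invariant
      w3 <- z3 - z3[1]
      cf <- tryCatch(solve(cbind(1, w3, w3^2), a3), error = function(e) NULL)
      if (!is.null(cf) && abs(cf[3]) > 1e-12) {
        disc <- cf[2]^2 - 4 * cf[3] * cf[1]
        if (disc >= 0) {
          roots <- z3[1] + (-cf[2] + c(-1, 1) * sqrt(disc)) / (2 * cf[3])
          roots <- roots[roots < z3[1]]
          if (length(roots)) {
            apex_q <- max(roots)
            if (apex_q >= z_floor && apex_q <= z_ceil) z_lo <- apex_q
          }
        }
      }
    }
  }
  # Ring-bearing slices span the cavity: map the template's endocardial
  # extent (endo apex to basal rim) onto the slice extent.
  tz <- range(template$nodes[template$param$layer == "endo", 3])
  s_z <- (z_hi - z_lo) / (tz[2] - tz[1])

  ang <- contours$anterior_angle
  rot <- rbind(c(cos(ang), -sin(ang), 0),
               c(sin(ang), cos(ang), 0),
               c(0, 0, 1))

  # template endo ring radii against relative height
  endo <- mesh_layer_array(template, "endo")
  ring_r <- sqrt(endo[, , 1]^2 + endo[, , 2]^2)
  t_rad <- colMeans(ring_r)
  t_rel <- (colMeans(endo[, , 3]) - tz[1]) / (tz[2] - tz[1])
  t_rel[t_rel < 0] <- 0

  mid <- which(zs >= stats::quantile(zs, 1 / 3) & zs <= stats::quantile(zs, 2 / 3))
  if (!length(mid)) mid <- order(abs(zs - stats::median(zs)))[1]
  ratios <- vapply(mid, function(i) {
    rel <- (zs[i] - z_lo) / (z_hi - z_lo)
    tr <- stats::approx(t_rel, t_rad, xout = rel, rule = 2)$y
    poly_radius(sl[[i]]$endo) / tr
  }, numeric(1))
  s_xy <- mean(ratios)

  ctr_xy <- colMeans(do.call(rbind, lapply(sl, function(s) {
    rbind(colMeans(s$endo), colMeans(s$epi))
  })))
  t_ctr_xy <- colMeans(template$nodes[, 1:2])
  pose <- list(rot = rot, s_xy = s_xy, s_z = s_z,
               translation = c(ctr_xy - s_xy * (rot[1:2, 1:2] %*% t_ctr_xy),
                               z_lo - s_z * tz[1]))
  pose
}

#' Apply a pose to a mesh
#'
#' @param mesh An `lv_mesh`.
#' @param pose A pose from [initialize_pose()].
#' @return The transformed mesh.
#' @export
apply_pose <- function(mesh, pose) {
  mesh$nodes <- apply_rigid(mesh$nodes, rot = pose$rot,
                            translation = pose$translation,
                            s_xy = pose$s_xy, s_z = pose$s_z)
  mesh
}

# Sparse combinatorial Laplacian of one surface grid (u closed, v open).
surface_laplacian <- function(n_circ, n_long) {
  idx <- function(u, v) (v - 1L) * n_circ + u
  u <- rep(seq_len(n_circ), n_long)
  v <- rep(seq_len(n_long), each = n_circ)
  i <- c(idx(u, v), idx(u, v))
  un <- ifelse(u == n_circ, 1L, u + 1L)
  j <- c(idx(un, v), idx(u, ifelse(v == n_long, n_long, v + 1L)))
  keep <- i != j
  i <- i[keep]
  j <- j[keep]
  n <- n_circ * n_long
  a <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n))
  a@x[a@x > 0] <- 1   # deduplicate parallel edges
  Matrix::Diagonal(x = Matrix::rowSums(a)) - a
}

# Nearest point on a closed polygon (2D) for a set of query points.
# Fully vectorized over points x segments; returns projected points.
project_to_polygon <- function(points, poly) {
  a <- poly
  b <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  ab_x <- b[, 1] - a[, 1]
  ab_y <- b[, 2] - a[, 2]
  len2 <- pmax(ab_x^2 + ab_y^2, 1e-12)
  ap_x <- outer(points[, 1], a[, 1], `-`)      # points x segments
  ap_y <- outer(points[, 2], a[, 2], `-`)
  t <- sweep(sweep(ap_x, 2, ab_x, `*`) + sweep(ap_y, 2, ab_y, `*`),
             2, len2, `/`)
  t <- pmin(pmax(t, 0), 1)
  px <- sweep(t, 2, ab_x, `*`)
  py <- sweep(t, 2, ab_y, `*`)
  dx <- ap_x - px
  dy <- ap_y - py
  d2 <- dx * dx + dy * dy
  k <- max.col(-d2, ties.method = "first")
  sel <- cbind(seq_len(nrow(points)), k)
  # Near-ties are averaged rather than resolved by argmin: an interior query
  # point on a symmetry axis of the polygon is equidistant from mirror-image
  # segments and a hard argmin is discontinuous there (breaking rigid
  # equivariance of the fit).
  near <- d2 <= d2[sel] + 1e-9 * (1 + d2[sel])
  nn <- rowSums(near)
  qx <- sweep(px, 2, a[, 1], `+`)
  qy <- sweep(py, 2, a[, 2], `+`)
  cbind(rowSums(qx * near) / nn, rowSums(qy * near) / nn)
}

#' Fit the LV template to segmentation contours
#'
#' Iterates nearest-point projection of every surface node onto the matching
#' surface's contour on the slice nearest to the node (restricted to half a
#' slice gap), blended with Laplacian smoothing of the in-plane displacement
#' field from the initialized template. Longitudinal placement comes from the
#' pose initialization (contours carry no information between slice planes);
#' nodes outside the slice range (the apex region) are carried by the
#' smoothness term. Node (u, v, layer) identity is preserved exactly, giving
#' anatomical correspondence across subjects.
#'
#' @param template An `lv_template`.
#' @param contours An `lv_contours` object.
#' @param config A [fit_config()].
#' @param pose Optional precomputed pose (skips initialization and the
#'   canonical-frame factorization).
#' @return The fitted `lv_mesh` with attribute `fit_info` (iterations,
#'   convergence flag, objective trace, thickness flag).
#' @export
fit_mesh <- function(template, contours, config = fit_config(), pose = NULL) {
  # The fit runs in a canonical frame (anterior marker at angle zero, contour
  # centroid at the origin) and the rigid part is re-applied to the result
  # exactly: nearest-point targets for near-axis nodes are not stable under
  # rigid motion of the inputs, so fitting in place would not be equivariant.
  if (!is.null(pose) || !config$init_pose) {
    return(fit_mesh_core(template, contours, config, pose))
  }
  ang <- contours$anterior_angle
  ctr <- contour_center(contours)
  canon <- contours
  canon$anterior_angle <- 0
  r2 <- rbind(c(cos(-ang), -sin(-ang)), c(sin(-ang), cos(-ang)))
  canon$slices <- lapply(contours$slices, function(s) {
    s$endo <- sweep(s$endo, 2, ctr[1:2]) %*% t(r2)
    s$epi <- sweep(s$epi, 2, ctr[1:2]) %*% t(r2)
    s$z <- s$z - ctr[3]
    s
  })
  fit <- fit_mesh_core(template, canon, config, NULL)
  rot <- rbind(c(cos(ang), -sin(ang), 0),
               c(sin(ang), cos(ang), 0),
               c(0, 0, 1))
  fit$nodes <- sweep(fit$nodes %*% t(rot), 2, ctr, `+`)
  info <- attr(fit, "fit_info")
  pc <- info$pose
  info$pose <- list(rot = rot %*% pc$rot, s_xy = pc$s_xy, s_z = pc$s_z,
                    translation = as.numeric(rot %*% pc$translation) + ctr)
  attr(fit, "fit_info") <- info
  fit
}

# In-plane centroid (endo + epi vertex means over slices) and mean slice
# height; the origin of the canonical fitting frame.
contour_center <- function(contours) {
  xy <- colMeans(do.call(rbind, lapply(contours$slices, function(s) {
    rbind(colMeans(s$endo), colMeans(s$epi))
  })))
  z <- mean(vapply(contours$slices, `[[`, numeric(1), "z"))
  c(xy, z)
}

fit_mesh_core <- function(template, contours, config = fit_config(),
                          pose = NULL) {
  if (is.null(pose)) {
    pose <- if (config$init_pose) initialize_pose(template, contours) else
      list(rot = diag(3), s_xy = 1, s_z = 1, translation = c(0, 0, 0))
  }
  mesh <- apply_pose(template, pose)
  class(mesh) <- "lv_mesh"
  n_circ <- mesh$n_circ
  n_long <- mesh$n_long
  n_surf <- n_circ * n_long
  lap <- surface_laplacian(n_circ, n_long)
  zs <- vapply(contours$slices, `[[`, numeric(1), "z")
  gap <- contours$slice_gap

  # Per node: bracketing slices and interpolation weight. Nodes between two
  # slice planes take a z-interpolated projection target; nodes above the top
  # slice (basal rim region) use the top slice within half a gap; nodes below
  # the lowest slice (apex region) carry no data term and are held by the
  # smoothness prior and the pose initialization.
  ord <- order(zs)
  zs_s <- zs[ord]
  node_brackets <- function(z) {
    lo <- findInterval(z, zs_s)
    if (lo >= 1 && lo < length(zs_s)) {
      t <- (z - zs_s[lo]) / (zs_s[lo + 1] - zs_s[lo])
      c(ord[lo], ord[lo + 1], t)
    } else if (lo == length(zs_s) && z - zs_s[lo] <= gap / 2) {
      c(ord[lo], ord[lo], 0)
    } else if (lo == 0 && zs_s[1] - z <= gap / 4) {
      c(ord[1], ord[1], 0)
    } else {
      c(NA_real_, NA_real_, NA_real_)
    }
  }
  surf_state <- lapply(c("endo", "epi"), function(layer) {
    nodes <- mesh$nodes[mesh$param$layer == layer, , drop = FALSE]
    br <- t(vapply(nodes[, 3], node_brackets, numeric(3)))
    w <- as.numeric(!is.na(br[, 1]))
    # The apex pole is a degenerate ring sitting on the contour's medial
    # axis, where the nearest-point target is ill-posed (and discontinuous);
    # it carries no in-plane information and is held by the smoothness prior.
    w[seq_len(n_circ)] <- 0
    a <- Matrix::Diagonal(x = w) + config$lambda * lap +
      Matrix::Diagonal(n_surf, 1e-9)
    list(layer = layer, init = nodes, cur = nodes, br = br, w = w,
         chol = Matrix::Cholesky(methods::as(a, "symmetricMatrix")))
  })

  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    movement <- 0
    data_term <- 0
    rough_term <- 0
    for (k in 1:2) {
      st <- surf_state[[k]]
      targets <- st$cur[, 1:2, drop = FALSE]
      for (s in seq_along(contours$slices)) {
        poly <- contours$slices[[s]][[st$layer]]
        for (side in 1:2) {
          sel <- which(!is.na(st$br[, side]) & st$br[, side] == s &
                         (side == 1 | st$br[, 1] != st$br[, 2]))
          if (!length(sel)) next
          pr <- project_to_polygon(st$cur[sel, 1:2, drop = FALSE], poly)
          wgt <- if (side == 1) 1 - st$br[sel, 3] else st$br[sel, 3]
          base <- if (side == 1) 0 else targets[sel, , drop = FALSE]
          targets[sel, ] <- (if (side == 1) wgt * pr else base + wgt * pr)
        }
      }
      new_xy <- st$init[, 1:2, drop = FALSE]
      for (cc in 1:2) {
        b <- st$w * (targets[, cc] - st$init[, cc])
        d <- as.numeric(Matrix::solve(st$chol, b))
        new_xy[, cc] <- st$init[, cc] + d
        rough_term <- rough_term +
          config$lambda * sum(d * as.numeric(lap %*% d))
      }
      movement <- movement + sum(sqrt(rowSums((new_xy - st$cur[, 1:2])^2)))
      data_term <- data_term +
        sum(st$w * rowSums((new_xy - targets)^2))
      st$cur[, 1:2] <- new_xy
      surf_state[[k]] <- st
    }
    objective <- c(objective, data_term + rough_term)
    if (movement / (2 * n_surf) < config$tolerance) {
      converged <- TRUE
      break
    }
  }

  for (k in 1:2) {
    mesh <- mesh_set_layer(mesh, surf_state[[k]]$layer,
                           array(surf_state[[k]]$cur, c(n_circ, n_long, 3)))
  }
  thick_ok <- all(wall_thickness(mesh) > 0)
  if (!thick_ok) warning("fitted mesh has non-positive wall thickness")
  if (!converged) warning("fit did not converge; returning best iterate")
  attr(mesh, "fit_info") <- list(iterations = iter, converged = converged,
                                 objective = objective,
                                 thickness_ok = thick_ok, pose = pose)
  mesh
}

# Exact point-to-triangle distances: one point against many triangles
# (Eberly's region classification, vectorized over triangles).
point_triangle_dist <- function(p, v1, v2, v3) {
  e0 <- v2 - v1
  e1 <- v3 - v1
  dv <- sweep(v1, 2, p)
  a <- rowSums(e0 * e0)
  b <- rowSums(e0 * e1)
  c2 <- rowSums(e1 * e1)
  d <- rowSums(e0 * dv)
  e <- rowSums(e1 * dv)
  det <- pmax(a * c2 - b * b, 1e-300)
  s <- b * e - c2 * d
  t <- b * d - a * e
  inside <- s + t <= det & s >= 0 & t >= 0
  s_in <- s / det
  t_in <- t / det
  # outside: clamp against each edge and take the best
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  s0 <- clamp01(-d / pmax(a, 1e-300))              # edge v1-v2 (t = 0)
  t0 <- clamp01(-e / pmax(c2, 1e-300))             # edge v1-v3 (s = 0)
  s2 <- clamp01((c2 + e - b - d) / pmax(a - 2 * b + c2, 1e-300))  # edge v2-v3
  dist2_at <- function(ss, tt) {
    px <- v1 + ss * e0 + tt * e1
    (px[, 1] - p[1])^2 + (px[, 2] - p[2])^2 + (px[, 3] - p[3])^2
  }
  d_edges <- pmin(dist2_at(s0, 0), dist2_at(0, t0), dist2_at(s2, 1 - s2))
  d_in <- dist2_at(s_in, t_in)
  sqrt(pmin(ifelse(inside, d_in, Inf), d_edges))
}

# Triangle vertex index triples of one surface (2 per quad).
surface_triangles <- function(n_circ, n_long) {
  idx <- function(u, v) (v - 1L) * n_circ + u
  u1 <- rep(seq_len(n_circ), n_long - 1L)
  v1 <- rep(seq_len(n_long - 1L), each = n_circ)
  u2 <- ifelse(u1 == n_circ, 1L, u1 + 1L)
  rbind(cbind(idx(u1, v1), idx(u2, v1), idx(u2, v1 + 1L)),
        cbind(idx(u1, v1), idx(u2, v1 + 1L), idx(u1, v1 + 1L)))
}

#' Contour-to-surface fit accuracy
#'
#' For every contour vertex, the 3D distance to the nearest point on the
#' matching mesh surface (exact point-to-triangle distances, restricted to
#' triangles within two slice gaps of the vertex plane).
#'
#' @param mesh A fitted `lv_mesh`.
#' @param contours The `lv_contours` the mesh was fitted to.
#' @return List with `median`, `iqr` (2-vector), and the full `distances`.
#' @export
fit_accuracy <- function(mesh, contours) {
  tri <- surface_triangles(mesh$n_circ, mesh$n_long)
  gap <- contours$slice_gap
  dists <- numeric(0)
  for (layer in c("endo", "epi")) {
    pts <- matrix(mesh_layer_array(mesh, layer), ncol = 3)
    v1 <- pts[tri[, 1], , drop = FALSE]
    v2 <- pts[tri[, 2], , drop = FALSE]
    v3 <- pts[tri[, 3], , drop = FALSE]
    tz_lo <- pmin(v1[, 3], v2[, 3], v3[, 3])
    tz_hi <- pmax(v1[, 3], v2[, 3], v3[, 3])
    for (s in contours$slices) {
      poly <- s[[layer]]
      keep <- tz_lo <= s$z + 2 * gap & tz_hi >= s$z - 2 * gap
      if (!any(keep)) keep <- rep(TRUE, nrow(v1))
      for (q in seq_len(nrow(poly))) {
        p <- c(poly[q, 1], poly[q, 2], s$z)
        dists <- c(dists, min(point_triangle_dist(
          p, v1[keep, , drop = FALSE], v2[keep, , drop = FALSE],
          v3[keep, , drop = FALSE])))
      }
    }
  }
  list(median = stats::median(dists),
       iqr = unname(stats::quantile(dists, c(0.25, 0.75))),
       distances = dists)
}

#' Contraction field between corresponded ED and ES meshes
#'
#' Node-wise displacement `x(ES) - x(ED)` with the bulk (mean) translation
#' removed; breath-hold table offsets between phase reconstructions are
#' nuisance.
#'
#' @param ed_mesh,es_mesh Meshes of one subject sharing the template
#'   topology.
#' @return Object of class `contraction_field` with `displacements`
#'   (n x 3 matrix, mm).
#' @export
contraction_field <- function(ed_mesh, es_mesh) {
  if (!same_topology(ed_mesh, es_mesh)) stop("topology mismatch")
  d <- es_mesh$nodes - ed_mesh$nodes
  if (!all(is.finite(d))) stop("non-finite displacements")
  d <- sweep(d, 2, colMeans(d))
  structure(list(displacements = d, n_circ = ed_mesh$n_circ,
                 n_long = ed_mesh$n_long),
            class = "contraction_field")
}

#' @method print contraction_field
#' @export
print.contraction_field <- function(x, ...) {
  mag <- sqrt(rowSums(x$displacements^2))
  cat(sprintf("Contraction field: %d nodes, |d| median %.2f mm (max %.2f)\n",
              nrow(x$displacements), stats::median(mag), max(mag)))
  invisible(x)
}
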