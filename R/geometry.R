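# Geometric measurements on LV meshes: cavity volumes, ejection fraction,
# wall thickness, AHA 17-segment maps, canonical alignment.

# Signed volume contribution of a triangle fan between two rings plus caps,
# via the divergence theorem: V = (1/6) sum det[p1 p2 p3].
signed_volume_triangles <- function(p1, p2, p3) {
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

# Closed signed volume of one surface: quad strip triangulation from apex to
# base plus a flat fan cap at the basal rim (centroid at mean rim height).
surface_closed_volume <- function(arr) {
  n_circ <- dim(arr)[1]
  n_long <- dim(arr)[2]
  pts <- matrix(arr, ncol = 3L)
  idx <- function(u, v) (v - 1L) * n_circ + u   # 1-based ring coords
  u1 <- seq_len(n_circ)
  u2 <- c(2:n_circ, 1L)
  vol <- 0
  for (v in seq_len(n_long - 1L)) {
    a <- pts[idx(u1, v), , drop = FALSE]
    b <- pts[idx(u2, v), , drop = FALSE]
    cc <- pts[idx(u2, v + 1L), , drop = FALSE]
    d <- pts[idx(u1, v + 1L), , drop = FALSE]
    vol <- vol + signed_volume_triangles(a, b, cc) +
      signed_volume_triangles(a, cc, d)
  }
  rim <- pts[idx(u1, n_long), , drop = FALSE]
  centroid <- colMeans(rim)
  centroid[3] <- mean(rim[, 3])
  cap_c <- matrix(centroid, nrow = n_circ, ncol = 3L, byrow = TRUE)
  vol <- vol + signed_volume_triangles(rim[u1, , drop = FALSE],
                                       rim[u2, , drop = FALSE], cap_c)
  vol
}

# Cheap self-intersection screen: every ring must be star-shaped about its
# own centroid (polar angles strictly increasing once unwrapped).
rings_look_simple <- function(arr) {
  n_long <- dim(arr)[2]
  for (v in 2:n_long) {
    ring <- arr[, v, ]
    ctr <- colMeans(ring)
    ang <- atan2(ring[, 2] - ctr[2], ring[, 1] - ctr[1])
    d <- diff(c(ang, ang[1] + 2 * pi))
    d <- (d + 2 * pi) %% (2 * pi)
    if (abs(sum(d) - 2 * pi) > 1e-6) return(FALSE)
  }
  TRUE
}

#' Cavity volume of an LV mesh
#'
#' Integrates the volume enclosed by the endocardial surface, closed by a
#' flat planar cap at the mean basal-rim plane, via the divergence theorem.
#'
#' @param mesh An `lv_mesh`.
#' @param layer Surface to integrate over; the cavity is the default
#'   `"endo"`, `"epi"` gives the total (cavity + myocardium) volume.
#' @return Volume in mL (1 mL = 1000 mm^3), positive.
#' @export
mesh_cavity_volume <- function(mesh, layer = "endo") {
  arr <- mesh_layer_array(mesh, layer)
  if (!rings_look_simple(arr)) {
    warning("surface rings are not star-shaped; possible self-intersection, ",
            "volume may be unreliable")
  }
  abs(surface_closed_volume(arr)) / 1000
}

#' Myocardial (wall) volume of an LV mesh
#'
#' @param mesh An `lv_mesh`.
#' @return Epicardial enclosed volume minus cavity volume, in mL.
#' @export
mesh_myocardial_volume <- function(mesh) {
  mesh_cavity_volume(mesh, "epi") - mesh_cavity_volume(mesh, "endo")
}

#' Left-ventricular ejection fraction
#'
#' @param edv End-diastolic volume (mL), must be positive.
#' @param esv End-systolic volume (mL).
#' @return `100 * (edv - esv) / edv` (percent). Values <= 0 indicate a
#'   degenerate fit and trigger exclusion downstream.
#' @export
lvef <- function(edv, esv) {
  if (any(edv <= 0)) stop("edv must be positive")
  100 * (edv - esv) / edv
}

#' Volume metrics for an ED/ES mesh pair
#'
#' @param ed_mesh,es_mesh Fitted meshes of the same subject and topology.
#' @return A list with `edv`, `esv`, `lvef` and `myocardial_mass_volume`
#'   (epi minus endo volume at ED), all in mL except `lvef` (percent).
#' @export
mesh_volumes <- function(ed_mesh, es_mesh) {
  if (!same_topology(ed_mesh, es_mesh)) stop("topology mismatch")
  edv <- mesh_cavity_volume(ed_mesh)
  esv <- mesh_cavity_volume(es_mesh)
  list(edv = edv, esv = esv, lvef = lvef(edv, esv),
       myocardial_mass_volume = mesh_myocardial_volume(ed_mesh))
}

#' Wall thickness map
#'
#' Euclidean distance between corresponding endocardial and epicardial nodes
#' at every (u, v) grid position.
#'
#' @param mesh An `lv_mesh`.
#' @return An `n_circ` x `n_long` matrix of thicknesses (mm).
#' @export
wall_thickness <- function(mesh) {
  endo <- mesh_layer_array(mesh, "endo")
  epi <- mesh_layer_array(mesh, "epi")
  sqrt((epi[, , 1] - endo[, , 1])^2 + (epi[, , 2] - endo[, , 2])^2 +
         (epi[, , 3] - endo[, , 3])^2)
}

#' AHA 17-segment map of the (u, v) grid
#'
#' Partitions the longitudinal range into an apical cap plus apical, mid and
#' basal thirds, and the circumference into 6 (basal, mid) or 4 (apical)
#' sectors centered on the anterior direction. Standard numbering: 1-6 basal,
#' 7-12 mid, 13-16 apical, 17 apex, with segment 1/7/13 anterior.
#'
#' @param mesh An `lv_mesh` in canonical orientation (`anterior_u` defined).
#' @return An `n_circ` x `n_long` integer matrix of segment labels in 1..17.
#' @export
aha17_map <- function(mesh) {
  if (is.null(mesh$anterior_u) || is.na(mesh$anterior_u)) {
    stop("mesh is not oriented: anterior_u undefined")
  }
  n_circ <- mesh$n_circ
  n_long <- mesh$n_long
  u <- 0:(n_circ - 1)
  v <- 0:(n_long - 1)
  # circumferential angle relative to the anterior direction, in [-pi, pi)
  delta <- 2 * pi * ((u - mesh$anterior_u) %% n_circ) / n_circ
  delta <- ifelse(delta >= pi, delta - 2 * pi, delta)
  sector6 <- (floor((delta + pi / 6) / (pi / 3)) %% 6) + 1
  sector4 <- (floor((delta + pi / 4) / (pi / 2)) %% 4) + 1
  t_long <- v / (n_long - 1)
  zone <- cut(t_long, breaks = c(-Inf, 1 / 8, 1 / 8 + 7 / 24, 1 / 8 + 14 / 24, Inf),
              labels = FALSE)  # 1 apex cap, 2 apical, 3 mid, 4 basal
  lab <- matrix(0L, n_circ, n_long)
  for (j in seq_len(n_long)) {
    lab[, j] <- switch(zone[j],
                       rep(17L, n_circ),
                       as.integer(12L + sector4),
                       as.integer(6L + sector6),
                       as.integer(sector6))
  }
  lab
}

#' Aggregate a per-(u,v) field over AHA-17 segments
#'
#' @param map Segment label matrix from [aha17_map()].
#' @param values Numeric matrix (or vector) of the same size as `map`.
#' @return Named numeric vector of 17 segment means (NA for segments with no
#'   nodes at coarse resolutions).
#' @export
segment_aggregate <- function(map, values) {
  if (length(map) != length(values)) stop("map and values sizes differ")
  out <- rep(NA_real_, 17)
  agg <- tapply(as.numeric(values), factor(as.integer(map), levels = 1:17),
                mean)
  out[as.integer(names(agg))] <- agg
  names(out) <- paste0("segment_", 1:17)
  out
}

#' Rigidly align a mesh to the canonical short-axis position
#'
#' Rotates and translates the mesh so that the long axis (apex to base) is
#' +z, the anterior direction is +x (the `anterior_u = 0` meridian), and the
#' node centroid is at the origin. No scaling is applied: size is signal for
#' the shape atlases.
#'
#' @param mesh An `lv_mesh`.
#' @param orientation List with `long_axis` (3-vector, apex-to-base) and
#'   `anterior` (3-vector); from stack metadata, or stored explicitly for
#'   synthetic stacks.
#' @return The aligned `lv_mesh`.
#' @export
canonical_align <- function(mesh, orientation) {
  zax <- orientation$long_axis
  ant <- orientation$anterior
  if (length(zax) != 3 || length(ant) != 3) stop("orientation vectors must be 3D")
  nz <- sqrt(sum(zax^2))
  if (nz < 1e-12) stop("degenerate long-axis vector")
  zax <- zax / nz
  ant_perp <- ant - sum(ant * zax) * zax
  na <- sqrt(sum(ant_perp^2))
  if (na < 1e-12) stop("anterior direction is degenerate or parallel to the long axis")
  xax <- ant_perp / na
  yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
           zax[3] * xax[1] - zax[1] * xax[3],
           zax[1] * xax[2] - zax[2] * xax[1])
  rot <- rbind(xax, yax, zax)
  centroid <- colMeans(mesh$nodes)
  mesh$nodes <- sweep(mesh$nodes, 2, centroid) %*% t(rot)
  colnames(mesh$nodes) <- c("x", "y", "z")
  mesh$anterior_u <- 0L
  mesh
}

# Apply rotation/translation (and optional in-plane / longitudinal scale)
# to a node matrix. Used by pose initialization and the generators.
apply_rigid <- function(nodes, rot = diag(3), translation = c(0, 0, 0),
                        s_xy = 1, s_z = 1) {
  scaled <- nodes %*% diag(c(s_xy, s_xy, s_z))
  sweep(scaled %*% t(rot), 2, translation, `+`)
}
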