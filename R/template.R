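# Parametric two-surface LV template mesh.
#
# The template is a truncated prolate-ellipsoidal shell sampled on a regular
# (circumferential u, longitudinal v) grid, one grid per surface (endo, epi).
# Node coordinates are in mm, right-handed axes, apex-to-base along +z.
# v = 0 is the apex pole (the u ring degenerates to a point there),
# v = n_long - 1 is the open basal rim.

#' Default LV template geometry
#'
#' Semi-axes and wall parameters of the idealized truncated prolate
#' ellipsoidal shell, chosen so that the end-diastolic cavity volume is close
#' to 144 mL, a typical post-infarction cohort median, with an equatorial
#' wall of 9 mm.
#'
#' @param a_endo Endocardial equatorial semi-axis (mm).
#' @param c_endo Endocardial long semi-axis (mm).
#' @param wall Equatorial wall thickness (mm); epicardial semi-axis is
#'   `a_endo + wall`.
#' @param apex_thickness Wall thickness at the apex (mm); epicardial long
#'   semi-axis is `c_endo + apex_thickness`.
#' @param z_base Height of the basal truncation plane above the ellipsoid
#'   center (mm). Both surfaces are truncated at the same plane.
#' @return A list of geometry parameters accepted by [build_template()].
#' @export
lv_geometry_params <- function(a_endo = 26, c_endo = 65, wall = 9,
                               apex_thickness = 6, z_base = 26) {
  if (a_endo <= 0 || c_endo <= 0) stop("semi-axes must be positive")
  if (wall <= 0 || apex_thickness <= 0) {
    stop("epicardial semi-axes must exceed endocardial semi-axes")
  }
  if (z_base <= 0 || z_base >= c_endo) {
    stop("z_base must lie strictly between 0 and c_endo")
  }
  list(a_endo = a_endo, c_endo = c_endo, wall = wall,
       apex_thickness = apex_thickness, z_base = z_base)
}

# Node index for (u, v, layer); u, v are 0-based, layer "endo" or "epi".
# Node storage order: endo surface first, u fastest within each v ring.
mesh_node_index <- function(u, v, layer, n_circ, n_long) {
  offset <- ifelse(layer == "epi", n_circ * n_long, 0L)
  offset + v * n_circ + u + 1L
}

# Sample one truncated-ellipsoid surface on the (u, v) grid.
ellipsoid_surface <- function(a, c_ax, z_base, n_circ, n_long) {
  theta_max <- acos(-z_base / c_ax)
  theta <- theta_max * (seq_len(n_long) - 1) / (n_long - 1)
  phi <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  st <- rep(sin(theta), each = n_circ)
  x <- a * st * cos(phi)
  y <- a * st * sin(phi)
  z <- rep(-c_ax * cos(theta), each = n_circ)
  cbind(x = x, y = y, z = z)
}

#' Build the parametric LV template mesh
#'
#' Samples endocardial and epicardial truncated prolate-ellipsoid surfaces on
#' a regular (circumferential, longitudinal) grid. The default 49 x 25 grid
#' per surface gives 2,450 nodes in total.
#'
#' @param n_circ Number of circumferential samples per ring (>= 8).
#' @param n_long Number of longitudinal rings from apex to base (>= 4).
#' @param geometry Geometry parameters, see [lv_geometry_params()].
#' @return An object of class `c("lv_template", "lv_mesh")`: a list with
#'   `nodes` (n x 3 matrix, mm), `param` (per-node `u`, `v`, `layer`),
#'   `n_circ`, `n_long`, `anterior_u` (circumferential index of the anterior
#'   direction, 0 = +x), and the `geometry` used.
#' @export
build_template <- function(n_circ = 49, n_long = 25,
                           geometry = lv_geometry_params()) {
  if (n_circ < 8) stop("n_circ must be at least 8")
  if (n_long < 4) stop("n_long must be at least 4")
  geometry <- do.call(lv_geometry_params, geometry)
  a_epi <- geometry$a_endo + geometry$wall
  c_epi <- geometry$c_endo + geometry$apex_thickness
  endo <- ellipsoid_surface(geometry$a_endo, geometry$c_endo,
                            geometry$z_base, n_circ, n_long)
  epi <- ellipsoid_surface(a_epi, c_epi, geometry$z_base, n_circ, n_long)
  grid <- expand.grid(u = 0:(n_circ - 1), v = 0:(n_long - 1))
  param <- data.frame(
    u = rep(grid$u, 2L), v = rep(grid$v, 2L),
    layer = rep(c("endo", "epi"), each = n_circ * n_long),
    stringsAsFactors = FALSE
  )
  mesh <- structure(
    list(nodes = rbind(endo, epi), param = param,
         n_circ = as.integer(n_circ), n_long = as.integer(n_long),
         anterior_u = 0L, phase = NA_character_, frame_index = NA_integer_,
         geometry = geometry),
    class = c("lv_template", "lv_mesh")
  )
  mesh
}

#' @method print lv_mesh
#' @export
print.lv_mesh <- function(x, ...) {
  kind <- if (inherits(x, "lv_template")) "LV template mesh" else "LV mesh"
  cat(sprintf("%s: %d nodes (%d circ x %d long x 2 surfaces)\n",
              kind, nrow(x$nodes), x$n_circ, x$n_long))
  if (!is.na(x$phase)) cat(sprintf("  phase: %s\n", x$phase))
  rng <- apply(x$nodes, 2, range)
  cat(sprintf("  extent (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' @export
plot.lv_mesh <- function(x, ...) {
  endo <- mesh_layer_array(x, "endo")
  epi <- mesh_layer_array(x, "epi")
  graphics::plot(epi[, , 1], epi[, , 3], pch = ".", col = "grey40", asp = 1,
                 xlab = "x (mm)", ylab = "z (mm)",
                 main = "LV mesh, long-axis projection", ...)
  graphics::points(endo[, , 1], endo[, , 3], pch = ".", col = "firebrick")
  invisible(x)
}

# Nodes of one surface as an [n_circ, n_long, 3] array (u fastest).
mesh_layer_array <- function(mesh, layer = c("endo", "epi")) {
  layer <- match.arg(layer)
  sel <- mesh$param$layer == layer
  array(mesh$nodes[sel, , drop = FALSE],
        dim = c(mesh$n_circ, mesh$n_long, 3L))
}

# Replace one surface of a mesh from an [n_circ, n_long, 3] array.
mesh_set_layer <- function(mesh, layer, arr) {
  sel <- mesh$param$layer == layer
  mesh$nodes[sel, ] <- matrix(arr, ncol = 3L)
  mesh
}

# Shared-topology check used by node-wise operations.
same_topology <- function(a, b) {
  a$n_circ == b$n_circ && a$n_long == b$n_long &&
    identical(a$param$layer, b$param$layer)
}

#' Flatten a mesh (or displacement set) to a shape vector
#'
#' Concatenates node coordinates in storage order (x, y, z per node) into the
#' flat vector used by the PCA atlases: length 3 x node count (7,350 for the
#' default template).
#'
#' @param mesh An `lv_mesh`, or an n x 3 matrix of displacements.
#' @return A numeric vector.
#' @export
as_shape_vector <- function(mesh) {
  m <- if (inherits(mesh, "lv_mesh")) mesh$nodes else mesh
  as.numeric(t(m))
}

# Inverse of as_shape_vector for node matrices.
shape_vector_to_nodes <- function(vec) {
  matrix(vec, ncol = 3L, byrow = TRUE)
}
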