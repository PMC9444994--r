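# Text-based I/O: meshes to ASCII PLY / legacy VTK polydata with (u, v,
# layer) point data, atlas archives as plain-text directories, AHA-17 CSV
# export and polar plots.

# Quad faces of both surfaces (0-based indices, PLY/VTK convention).
mesh_quads <- function(mesh) {
  n_circ <- mesh$n_circ
  n_long <- mesh$n_long
  quads <- list()
  for (layer_off in c(0L, n_circ * n_long)) {
    u1 <- rep(0:(n_circ - 1), n_long - 1L)
    v1 <- rep(0:(n_long - 2), each = n_circ)
    u2 <- (u1 + 1L) %% n_circ
    quads[[length(quads) + 1L]] <- cbind(
      layer_off + v1 * n_circ + u1,
      layer_off + v1 * n_circ + u2,
      layer_off + (v1 + 1L) * n_circ + u2,
      layer_off + (v1 + 1L) * n_circ + u1)
  }
  do.call(rbind, quads)
}

#' Write a mesh as ASCII PLY
#'
#' Vertex properties include the parameterization (`u`, `v`, `layer`; layer
#' 0 = endo, 1 = epi), so anatomical correspondence survives the export.
#'
#' @param mesh An `lv_mesh`.
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  quads <- mesh_quads(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(mesh$nodes)),
    "property float x", "property float y", "property float z",
    "property int u", "property int v", "property uchar layer",
    sprintf("element face %d", nrow(quads)),
    "property list uchar int vertex_indices", "end_header"), con)
  vert <- cbind(format(mesh$nodes, trim = TRUE, digits = 8),
                mesh$param$u, mesh$param$v,
                as.integer(mesh$param$layer == "epi"))
  writeLines(apply(vert, 1, paste, collapse = " "), con)
  writeLines(paste(4, quads[, 1], quads[, 2], quads[, 3], quads[, 4]), con)
  invisible(path)
}

#' Write a mesh as legacy ASCII VTK polydata
#'
#' @param mesh An `lv_mesh`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path) {
  quads <- mesh_quads(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "LV mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(mesh$nodes))), con)
  writeLines(apply(format(mesh$nodes, trim = TRUE, digits = 8), 1,
                   paste, collapse = " "), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(quads), 5 * nrow(quads)), con)
  writeLines(paste(4, quads[, 1], quads[, 2], quads[, 3], quads[, 4]), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(mesh$nodes)),
               "SCALARS layer int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$param$layer == "epi")), con)
  invisible(path)
}

#' Save a shape atlas as a plain-text archive
#'
#' Writes the mean, modes, eigenvalues and metadata (subject count, kind,
#' a hash of the mean for integrity) into a directory of CSV/JSON files.
#'
#' @param atlas A `shape_atlas`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
save_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(mean = atlas$mean),
                   file.path(dir, "mean.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(atlas$modes),
                   file.path(dir, "modes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(eigenvalue = atlas$eigenvalues),
                   file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(kind = atlas$kind, n_subjects = atlas$n_subjects,
         n_modes = ncol(atlas$modes),
         mean_checksum = sum(atlas$mean^2)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a shape atlas saved by [save_atlas()]
#'
#' @param dir Archive directory.
#' @return A `shape_atlas`.
#' @export
load_atlas <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  atlas <- structure(
    list(mean = utils::read.csv(file.path(dir, "mean.csv"))$mean,
         modes = as.matrix(utils::read.csv(file.path(dir, "modes.csv"))),
         eigenvalues = utils::read.csv(
           file.path(dir, "eigenvalues.csv"))$eigenvalue,
         n_subjects = meta$n_subjects, kind = meta$kind),
    class = "shape_atlas")
  dimnames(atlas$modes) <- NULL
  if (abs(sum(atlas$mean^2) - meta$mean_checksum) >
      1e-6 * (1 + meta$mean_checksum)) {
    warning("atlas checksum mismatch")
  }
  atlas
}

#' Export AHA-17 segment values as CSV
#'
#' @param values Named 17-vector from [segment_aggregate()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_aha17_csv <- function(values, path) {
  utils::write.csv(data.frame(segment = 1:17, value = as.numeric(values)),
                   path, row.names = FALSE)
  invisible(path)
}

#' AHA-17 polar plot
#'
#' Bull's-eye plot of 17 segment values on the current graphics device:
#' basal ring outside, apex at the center, anterior up.
#'
#' @param values Named 17-vector from [segment_aggregate()].
#' @param main Plot title.
#' @param palette Color ramp function (low to high).
#' @return Invisibly, the value range used for the color scale.
#' @export
aha17_polar_plot <- function(values, main = "AHA-17 polar map",
                             palette = grDevices::colorRampPalette(
                               c("steelblue", "white", "firebrick"))) {
  rng <- range(values, na.rm = TRUE)
  if (diff(rng) < 1e-12) rng <- rng + c(-0.5, 0.5)
  cols <- palette(64)
  col_of <- function(v) cols[pmax(1, pmin(64, 1 + floor(63 * (v - rng[1]) /
                                                          diff(rng))))]
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  draw_sector <- function(r0, r1, a0, a1, col) {
    th <- seq(a0, a1, length.out = 30)
    graphics::polygon(c(r1 * cos(th), r0 * cos(rev(th))),
                      c(r1 * sin(th), r0 * sin(rev(th))),
                      col = col, border = "grey30")
  }
  ring <- list(basal = c(0.75, 1), mid = c(0.5, 0.75), apical = c(0.25, 0.5))
  seg <- 0
  for (zone in c("basal", "mid")) {
    for (s in 1:6) {
      seg <- seg + 1
      a0 <- pi / 2 + (s - 1) * pi / 3 - pi / 6
      draw_sector(ring[[zone]][1], ring[[zone]][2], a0, a0 + pi / 3,
                  col_of(values[seg]))
    }
  }
  for (s in 1:4) {
    seg <- seg + 1
    a0 <- pi / 2 + (s - 1) * pi / 2 - pi / 4
    draw_sector(ring$apical[1], ring$apical[2], a0, a0 + pi / 2,
                col_of(values[seg]))
  }
  th <- seq(0, 2 * pi, length.out = 60)
  graphics::polygon(0.25 * cos(th), 0.25 * sin(th), col = col_of(values[17]),
                    border = "grey30")
  invisible(rng)
}
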