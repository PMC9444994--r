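# Cine short-axis mask stacks: rasterization of mesh pairs into multi-slice,
# multi-frame myocardium label volumes, and NIfTI import/export.

#' Cine mask stack constructor
#'
#' @param voxels Integer array `[nx, ny, n_slices, n_frames]` with labels
#'   0 = background, 1 = myocardium.
#' @param spacing In-plane pixel spacing `c(dx, dy)` (mm).
#' @param origin Patient-space coordinates (mm) of the center of voxel
#'   `[1, 1]`.
#' @param slice_positions Strictly monotone slice positions along the stack
#'   normal (mm).
#' @param slice_thickness Slice thickness (mm).
#' @param anterior_angle In-plane angle (radians) of the anterior reference
#'   direction; the synthetic orientation marker.
#' @return An object of class `cine_stack`.
#' @export
cine_stack <- function(voxels, spacing, origin, slice_positions,
                       slice_thickness, anterior_angle = 0) {
  if (any(spacing <= 0) || slice_thickness <= 0) stop("spacing must be positive")
  if (is.unsorted(slice_positions, strictly = TRUE) &&
      is.unsorted(rev(slice_positions), strictly = TRUE)) {
    stop("slice_positions must be strictly monotone")
  }
  if (!all(voxels %in% c(0L, 1L))) stop("labels must be 0/1")
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         slice_positions = slice_positions,
         slice_thickness = slice_thickness,
         anterior_angle = anterior_angle,
         n_frames = dim(voxels)[4]),
    class = "cine_stack"
  )
}

#' @method print cine_stack
#' @export
print.cine_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "Cine mask stack: %d x %d pixels, %d slices, %d frames (%.2g x %.2g mm, slices %.3g mm)\n",
    d[1], d[2], d[3], d[4], x$spacing[1], x$spacing[2], x$slice_thickness))
  invisible(x)
}

# In-plane x/y coordinates (mm) of voxel centers.
stack_axis <- function(stack, axis) {
  n <- dim(stack$voxels)[axis]
  stack$origin[axis] + (seq_len(n) - 1) * stack$spacing[axis]
}

# Cross-section polygon of one surface array at height z, or NULL when the
# plane misses the surface. Rings are ordered apex to base with monotone z
# per meridian, so one linear interpolation per u suffices.
surface_cross_section <- function(arr, z) {
  zcols <- arr[, , 3]
  k <- rowSums(zcols < z)
  if (any(k == 0L) || any(k == ncol(zcols))) return(NULL)
  n_circ <- nrow(zcols)
  i1 <- cbind(seq_len(n_circ), k)
  i2 <- cbind(seq_len(n_circ), k + 1L)
  z1 <- zcols[i1]
  z2 <- zcols[i2]
  t <- (z - z1) / (z2 - z1)
  cbind(arr[, , 1][i1] + t * (arr[, , 1][i2] - arr[, , 1][i1]),
        arr[, , 2][i1] + t * (arr[, , 2][i2] - arr[, , 2][i1]))
}

# Rasterize the region between an outer and an (optional) inner polygon onto
# the pixel grid; operates on the polygon bounding box only.
rasterize_ring <- function(mask, xs, ys, outer, inner = NULL) {
  pad <- 1.5 * max(diff(xs[1:2]), diff(ys[1:2]))
  ix <- which(xs >= min(outer[, 1]) - pad & xs <= max(outer[, 1]) + pad)
  iy <- which(ys >= min(outer[, 2]) - pad & ys <= max(outer[, 2]) + pad)
  if (!length(ix) || !length(iy)) return(mask)
  grid <- cbind(rep(xs[ix], length(iy)), rep(ys[iy], each = length(ix)))
  closed <- rbind(outer, outer[1, ])
  inside <- mgcv::in.out(closed, grid)
  if (!is.null(inner)) {
    inside <- inside & !mgcv::in.out(rbind(inner, inner[1, ]), grid)
  }
  mask[ix, iy] <- mask[ix, iy] | matrix(inside, length(ix), length(iy))
  mask
}

# Raised-cosine temporal contraction profile: 0 at frame 1 (ED), 1 at the ES
# frame, back to 0 at the last frame.
contraction_profile <- function(n_frames, es_frame) {
  f <- seq_len(n_frames)
  alpha <- numeric(n_frames)
  up <- f <= es_frame
  alpha[up] <- 0.5 * (1 - cos(pi * (f[up] - 1) / (es_frame - 1)))
  alpha[!up] <- 0.5 * (1 + cos(pi * (f[!up] - es_frame) / (n_frames - es_frame)))
  alpha
}

#' Rasterize an ED/ES mesh pair into a cine mask stack
#'
#' Interpolates the mesh linearly between ED (frame 1) and ES along a raised
#' cosine contraction curve, slices it at regular short-axis planes, and
#' rasterizes the myocardium (between epicardial and endocardial
#' cross-sections) at the configured pixel spacing. Optional per-slice
#' in-plane misalignment (constant across frames, as breath-hold offsets are)
#' is drawn from the current RNG stream.
#'
#' @param ed_mesh,es_mesh Canonical meshes of one subject, same topology.
#' @param config A [cohort_config()] (rasterization fields are used).
#' @param margin In-plane margin (mm) beyond the ED epicardial extent.
#' @return A [cine_stack()] whose metadata records spacing, slice positions
#'   and the anterior orientation marker.
#' @export
rasterize_stack <- function(ed_mesh, es_mesh, config, margin = 10) {
  if (!same_topology(ed_mesh, es_mesh)) stop("topology mismatch")
  ed <- list(endo = mesh_layer_array(ed_mesh, "endo"),
             epi = mesh_layer_array(ed_mesh, "epi"))
  es <- list(endo = mesh_layer_array(es_mesh, "endo"),
             epi = mesh_layer_array(es_mesh, "epi"))
  sp <- config$spacing
  extent <- max(abs(ed$epi[, , 1:2])) + margin
  half_n <- ceiling(extent / sp)
  xs <- sp * (-half_n:half_n)
  ys <- xs
  z_lo <- min(ed$epi[, , 3], es$epi[, , 3])
  z_hi <- max(ed$epi[, , 3], es$epi[, , 3])
  zs <- seq(z_lo + config$slice_thickness / 2, z_hi,
            by = config$slice_thickness)
  if (extent > abs(xs[1]) + sp / 2) stop("mesh exceeds field of view")
  n_sl <- length(zs)
  shifts <- matrix(stats::rnorm(2 * n_sl, sd = config$misalign_sd), n_sl, 2)
  alpha <- contraction_profile(config$n_frames, config$es_frame)
  vox <- array(0L, dim = c(length(xs), length(ys), n_sl, config$n_frames))
  for (f in seq_len(config$n_frames)) {
    a <- alpha[f]
    endo <- ed$endo + a * (es$endo - ed$endo)
    epi <- ed$epi + a * (es$epi - ed$epi)
    for (s in seq_len(n_sl)) {
      outer_poly <- surface_cross_section(epi, zs[s])
      if (is.null(outer_poly)) next
      inner_poly <- surface_cross_section(endo, zs[s])
      outer_poly <- sweep(outer_poly, 2, shifts[s, ], `+`)
      if (!is.null(inner_poly)) {
        inner_poly <- sweep(inner_poly, 2, shifts[s, ], `+`)
      }
      m <- rasterize_ring(matrix(FALSE, length(xs), length(ys)),
                          xs, ys, outer_poly, inner_poly)
      vox[, , s, f] <- m * 1L
    }
  }
  cine_stack(vox, spacing = c(sp, sp), origin = c(xs[1], ys[1]),
             slice_positions = zs, slice_thickness = config$slice_thickness,
             anterior_angle = 0)
}

#' Drop frames from a cine stack
#'
#' Utility for reproducibility experiments: removes the given frames (e.g.
#' the detected ED/ES frames) so that phase detection and mesh fitting can be
#' repeated on the perturbed stack.
#'
#' @param stack A [cine_stack()].
#' @param frames Integer frame indices to remove.
#' @return The reduced `cine_stack`.
#' @export
drop_frames <- function(stack, frames) {
  keep <- setdiff(seq_len(stack$n_frames), frames)
  if (length(keep) < 2) stop("at least two frames must remain")
  cine_stack(stack$voxels[, , , keep, drop = FALSE], stack$spacing,
             stack$origin, stack$slice_positions, stack$slice_thickness,
             stack$anterior_angle)
}

#' Write a cine stack as a 4D NIfTI label volume
#'
#' The voxel array is written with in-plane spacing and slice thickness in
#' `pixdim`; stack origin, slice positions and the anterior orientation
#' marker go to a JSON sidecar next to the volume.
#'
#' @param stack A [cine_stack()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_stack_nifti <- function(stack, path) {
  img <- RNifti::asNifti(stack$voxels)
  RNifti::pixdim(img) <- c(stack$spacing, stack$slice_thickness, 1)
  RNifti::writeNifti(img, path)
  meta <- list(origin = stack$origin,
               slice_positions = stack$slice_positions,
               slice_thickness = stack$slice_thickness,
               anterior_angle = stack$anterior_angle)
  jsonlite::write_json(meta, paste0(sub("\\.nii(\\.gz)?$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cine stack written by [write_stack_nifti()]
#'
#' @param path Path to the NIfTI volume.
#' @return A [cine_stack()].
#' @export
read_stack_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(sub("\\.nii(\\.gz)?$", "", path), ".json"),
                              simplifyVector = TRUE)
  pd <- RNifti::pixdim(img)
  cine_stack(array(as.integer(img > 0.5), dim = dim(img)),
             spacing = pd[1:2], origin = meta$origin,
             slice_positions = meta$slice_positions,
             slice_thickness = meta$slice_thickness,
             anterior_angle = meta$anterior_angle)
}
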