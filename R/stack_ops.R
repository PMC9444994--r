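# Stack-level computations on segmentation masks: blood-pool area, ED/ES
# phase detection, Dice overlap, sub-pixel contour extraction, and the
# degenerate-subject exclusion filter.

# Cavity pixels enclosed by the myocardium ring of one slice image, by
# morphological hole filling. When the ring is broken, a best-effort fill
# after morphological closing is attempted and flagged.
fill_cavity <- function(ring) {
  ring <- ring != 0
  if (!any(ring)) return(list(cavity = ring & FALSE, flagged = FALSE))
  filled <- EBImage::fillHull(ring * 1) > 0.5
  cavity <- filled & !ring
  flagged <- FALSE
  if (!any(cavity)) {
    closed <- EBImage::closing(ring * 1, EBImage::makeBrush(3, "box")) > 0.5
    filled <- EBImage::fillHull(closed * 1) > 0.5
    cavity <- filled & !closed
    if (any(cavity)) flagged <- TRUE
  }
  list(cavity = cavity, flagged = flagged)
}

#' LV blood-pool area of one slice/frame
#'
#' The cavity is the hole enclosed by the myocardium ring (morphological fill
#' of the ring minus the ring), converted to mm^2 with the pixel area.
#'
#' @param stack A [cine_stack()].
#' @param slice,frame 1-based indices.
#' @return Area in mm^2; 0 with a warning when the slice carries no closed
#'   myocardium ring (a broken ring is filled best-effort and flagged).
#' @export
blood_pool_area <- function(stack, slice, frame) {
  d <- dim(stack$voxels)
  if (slice < 1 || slice > d[3] || frame < 1 || frame > d[4]) {
    stop("slice/frame index out of range")
  }
  fc <- fill_cavity(stack$voxels[, , slice, frame])
  if (fc$flagged) {
    warning("broken myocardium ring; cavity filled best-effort")
  } else if (!any(fc$cavity)) {
    warning("no closed myocardium ring on this slice")
  }
  sum(fc$cavity) * prod(stack$spacing)
}

# Quiet per-frame cavity areas at one slice.
cavity_areas <- function(stack, slice) {
  vapply(seq_len(stack$n_frames), function(f) {
    sum(fill_cavity(stack$voxels[, , slice, f])$cavity)
  }, numeric(1)) * prod(stack$spacing)
}

#' Detect ED and ES phases from the mid-ventricular blood-pool area
#'
#' ED and ES are the frames of maximal and minimal LV blood-pool area at the
#' mid-ventricular slice, defined as the middle (lower median) of the
#' ring-bearing slices at the first frame. Ties are broken to the earliest
#' frame.
#'
#' @param stack A [cine_stack()] with at least 2 frames.
#' @return List with `ed_frame`, `es_frame`, `mid_slice` (1-based).
#' @export
detect_phases <- function(stack) {
  if (stack$n_frames < 2) stop("at least two frames required")
  n_sl <- dim(stack$voxels)[3]
  ring <- which(vapply(seq_len(n_sl), function(s) {
    any(fill_cavity(stack$voxels[, , s, 1])$cavity)
  }, logical(1)))
  if (!length(ring)) stop("no ring-bearing slice in the stack")
  mid <- ring[floor(length(ring) / 2) + 1L]
  areas <- cavity_areas(stack, mid)
  if (all(areas == 0)) stop("all blood-pool areas are zero")
  ed <- which.max(areas)
  es <- which.min(areas)
  if (ed == es) stop("indistinct phases: blood-pool area is constant")
  list(ed_frame = ed, es_frame = es, mid_slice = mid)
}

#' Dice overlap of two masks
#'
#' @param mask_a,mask_b Logical/0-1 arrays of identical shape.
#' @return `2|A n B| / (|A| + |B|)` in `[0, 1]`; 1 when both masks are empty.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)) ||
      length(mask_a) != length(mask_b)) {
    stop("mask shapes differ")
  }
  a <- mask_a != 0
  b <- mask_b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Close a contourLines loop and orient it counter-clockwise.
orient_ccw <- function(poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  x <- poly[, 1]
  y <- poly[, 2]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (area2 < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  poly
}

#' Extract sub-pixel endo/epi contours from a mask stack
#'
#' For every slice of one frame, fills the myocardium ring, and traces the
#' 0.5 iso-contours of the filled region (epicardium) and of the cavity
#' (endocardium) with marching squares, in mm coordinates. Slices without a
#' closed ring are omitted and recorded.
#'
#' @param stack A [cine_stack()].
#' @param frame 1-based frame index.
#' @return An object of class `lv_contours`: list of per-slice contours
#'   (`z`, `endo`, `epi` polygon matrices, `flagged`), the slice gap, the
#'   anterior orientation marker, and the omitted slice indices.
#' @export
extract_contours <- function(stack, frame) {
  d <- dim(stack$voxels)
  if (frame < 1 || frame > d[4]) stop("frame index out of range")
  xs <- stack_axis(stack, 1)
  ys <- stack_axis(stack, 2)
  slices <- list()
  omitted <- integer(0)
  for (s in seq_len(d[3])) {
    ring <- stack$voxels[, , s, frame] != 0
    fc <- fill_cavity(ring)
    if (!any(fc$cavity)) {
      omitted <- c(omitted, s)
      next
    }
    filled <- (ring | fc$cavity) * 1
    epi_cl <- grDevices::contourLines(xs, ys, filled, levels = 0.5)
    endo_cl <- grDevices::contourLines(xs, ys, fc$cavity * 1, levels = 0.5)
    if (!length(epi_cl) || !length(endo_cl)) {
      omitted <- c(omitted, s)
      next
    }
    pick <- function(cl) {
      lens <- vapply(cl, function(p) length(p$x), numeric(1))
      p <- cl[[which.max(lens)]]
      orient_ccw(cbind(p$x, p$y))
    }
    slices[[length(slices) + 1L]] <- list(
      z = stack$slice_positions[s], slice = s,
      endo = pick(endo_cl), epi = pick(epi_cl), flagged = fc$flagged
    )
  }
  structure(
    list(slices = slices, slice_gap = stack$slice_thickness,
         anterior_angle = stack$anterior_angle, omitted = omitted),
    class = "lv_contours"
  )
}

#' @method print lv_contours
#' @export
print.lv_contours <- function(x, ...) {
  cat(sprintf("LV contours: %d ring-bearing slices (%d omitted), gap %.3g mm\n",
              length(x$slices), length(x$omitted), x$slice_gap))
  invisible(x)
}

#' Exact contours from a mesh
#'
#' Slices a mesh with short-axis planes, returning an `lv_contours` object
#' with one `n_circ`-vertex polygon per surface and slice. Used to generate
#' noise-free fixtures and for mask round-trip checks.
#'
#' @param mesh An `lv_mesh`.
#' @param slice_positions Plane heights (mm).
#' @param slice_gap Slice gap recorded in the result (defaults to the
#'   position step).
#' @return An `lv_contours` object.
#' @export
slice_mesh_contours <- function(mesh, slice_positions,
                                slice_gap = NULL) {
  if (is.null(slice_gap)) {
    slice_gap <- if (length(slice_positions) > 1) {
      abs(diff(slice_positions[1:2]))
    } else 8
  }
  endo <- mesh_layer_array(mesh, "endo")
  epi <- mesh_layer_array(mesh, "epi")
  slices <- list()
  omitted <- integer(0)
  for (s in seq_along(slice_positions)) {
    z <- slice_positions[s]
    en <- surface_cross_section(endo, z)
    ep <- surface_cross_section(epi, z)
    if (is.null(en) || is.null(ep)) {
      omitted <- c(omitted, s)
      next
    }
    slices[[length(slices) + 1L]] <-
      list(z = z, slice = s, endo = en, epi = ep, flagged = FALSE)
  }
  structure(
    list(slices = slices, slice_gap = slice_gap, anterior_angle = 0,
         omitted = omitted),
    class = "lv_contours"
  )
}

#' Exclude subjects with degenerate mesh-derived LVEF
#'
#' Subjects whose mesh LVEF is non-positive (a degenerate fit, usually from
#' incorrect phase selection) are removed from downstream statistics.
#'
#' @param cohort_volumes Data frame with at least `id` and `lvef` columns.
#' @return List with `kept` (ids), `excluded` (ids) and `log` (data frame of
#'   exclusions with reasons).
#' @export
exclusion_filter <- function(cohort_volumes) {
  if (nrow(cohort_volumes) == 0) {
    return(list(kept = integer(0), excluded = integer(0),
                log = data.frame(id = integer(0), reason = character(0))))
  }
  bad <- cohort_volumes$lvef <= 0
  list(
    kept = cohort_volumes$id[!bad],
    excluded = cohort_volumes$id[bad],
    log = data.frame(
      id = cohort_volumes$id[bad],
      reason = sprintf("non-positive mesh LVEF (%.1f%%)",
                       cohort_volumes$lvef[bad])
    )
  )
}
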