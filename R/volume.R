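#' 3D image volume with physical grid metadata
#'
#' The unit of all image I/O and preprocessing: a 3D intensity array together
#' with per-axis voxel spacing (mm), the physical coordinate of the first
#' voxel centre (origin, mm along each axis' anatomical direction), and the
#' anatomical axis carried by each array dimension. The anatomical axes are
#' labelled `"LR"` (left-right), `"AP"` (anterior-posterior) and `"SI"`
#' (superior-inferior); world space is RAS with all stored axes pointing in
#' the positive world direction. Voxel indices are interpreted cell-centred:
#' voxel `i` (1-based in R) sits at physical coordinate
#' `origin + (i - 1) * spacing` along its axis.
#'
#' @param data numeric 3D array of intensities (finite).
#' @param spacing numeric length-3, voxel spacing in mm per array dimension.
#' @param origin numeric length-3, physical coordinate (mm) of the first
#'   voxel centre along each array dimension.
#' @param axis_labels character length-3, a permutation of
#'   `c("LR", "AP", "SI")` naming the anatomical axis of each array
#'   dimension.
#' @return An object of class `volume_image`.
#' @examples
#' v <- volume_image(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 3))
#' v
#' @export
volume_image <- function(data, spacing, origin = c(0, 0, 0),
                         axis_labels = c("LR", "AP", "SI")) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("'data' must be a 3D array")
  }
  if (any(!is.finite(data))) stopf("'data' contains non-finite intensities")
  check_positive(spacing, "spacing")
  if (length(spacing) != 3L || length(origin) != 3L) {
    stopf("'spacing' and 'origin' must have length 3")
  }
  if (!setequal(axis_labels, c("LR", "AP", "SI")) ||
      length(axis_labels) != 3L) {
    stopf("'axis_labels' must be a permutation of LR, AP, SI")
  }
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin = as.numeric(origin), axis_labels = as.character(axis_labels)),
    class = "volume_image"
  )
}

#' Binary segmentation mask on an image grid
#'
#' Same grid metadata as [volume_image()], values restricted to 0/1.
#'
#' @inheritParams volume_image
#' @return An object of class `c("seg_mask", "volume_image")`.
#' @export
seg_mask <- function(data, spacing, origin = c(0, 0, 0),
                     axis_labels = c("LR", "AP", "SI")) {
  if (!all(data %in% c(0, 1))) stopf("mask values must be 0 or 1")
  v <- volume_image(data, spacing, origin, axis_labels)
  class(v) <- c("seg_mask", "volume_image")
  v
}

is_seg_mask <- function(x) inherits(x, "seg_mask")

#' @export
print.volume_image <- function(x, ...) {
  kind <- if (is_seg_mask(x)) "seg_mask" else "volume_image"
  cat(sprintf("<%s> %s voxels, spacing %s mm, axes %s\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              paste(x$axis_labels, collapse = "-")))
  if (is_seg_mask(x)) {
    cat(sprintf("  foreground voxels: %d (%.2f ml)\n", sum(x$data),
                mask_volume(x)))
  } else {
    cat(sprintf("  intensity range: [%.3g, %.3g]\n", min(x$data), max(x$data)))
  }
  invisible(x)
}

# canonical array axis order (first-to-last) per view, slicing axis last
view_axis_order <- function(view) {
  switch(view,
    axial    = c("LR", "AP", "SI"),
    sagittal = c("AP", "SI", "LR"),
    coronal  = c("LR", "SI", "AP"),
    stopf("unknown view '%s' (use axial, sagittal or coronal)", view)
  )
}

#' Permute a volume so a given acquisition plane is the slicing plane
#'
#' Reorders the array axes (pure permutation, no interpolation) so that the
#' slicing axis of the requested view comes last: axial slices stack along
#' SI, sagittal along LR, coronal along AP. Spacing, origin and axis labels
#' are permuted consistently, so the physical position of every voxel is
#' unchanged.
#'
#' @param v a [volume_image()] or [seg_mask()].
#' @param view one of `"axial"`, `"sagittal"`, `"coronal"`.
#' @return The permuted object, same class as `v`.
#' @export
reslice_view <- function(v, view) {
  stopifnot(inherits(v, "volume_image"))
  target <- view_axis_order(view)
  perm <- match(target, v$axis_labels)
  out <- v
  out$data <- aperm(v$data, perm)
  out$spacing <- v$spacing[perm]
  out$origin <- v$origin[perm]
  out$axis_labels <- v$axis_labels[perm]
  out
}

# physical voxel-centre coordinates along one axis
axis_coords <- function(v, d) {
  v$origin[d] + (seq_len(dim(v$data)[d]) - 1) * v$spacing[d]
}
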