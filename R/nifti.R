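# NIfTI input/output. World space is RAS; only (near) axis-aligned xforms
# are supported, which covers the orthogonally acquired stacks this package
# works with. Axis flips in the header are resolved on read by reordering
# the data so every stored axis points in the positive world direction.

world_rows <- c(LR = 1L, AP = 2L, SI = 3L)

#' Read a NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file and returns a [volume_image()] whose axis
#' labels, spacing and origin are derived from the header xform. Axes stored
#' in a negative world direction are flipped to the package's positive RAS
#' convention.
#'
#' @param path path to a NIfTI-1 file.
#' @param mask logical; if `TRUE` the volume is binarized (> 0.5) and
#'   returned as a [seg_mask()].
#' @return A [volume_image()] (or [seg_mask()]).
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("failed to read NIfTI '%s': %s",
                                            path, conditionMessage(e)))
  data <- as.array(img)
  dm <- dim(data)
  if (length(dm) > 3L) {
    if (prod(dm[-(1:3)]) != 1L) stopf("'%s' is not a 3D volume", path)
    dm <- dm[1:3]
  }
  if (length(dm) != 3L) stopf("'%s' is not a 3D volume", path)
  data <- array(as.numeric(data), dm)   # strip NIfTI attributes
  aff <- RNifti::xform(img)

  labels <- character(3)
  spacing <- numeric(3)
  origin <- numeric(3)
  for (j in 1:3) {
    col <- aff[1:3, j]
    spacing[j] <- sqrt(sum(col^2))
    if (spacing[j] <= 0) stopf("degenerate xform in '%s' (axis %d)", path, j)
    r <- which.max(abs(col))
    off_axis <- sqrt(sum(col[-r]^2)) / spacing[j]
    if (off_axis > 1e-3) {
      warning(sprintf("oblique xform in '%s'; using dominant-axis approximation",
                      path))
    }
    labels[j] <- names(world_rows)[r]
    if (col[r] < 0) {
      # flip this array axis to point positively along the world axis
      idx <- rev(seq_len(dim(data)[j]))
      data <- switch(j, data[idx, , , drop = FALSE],
                     data[, idx, , drop = FALSE],
                     data[, , idx, drop = FALSE])
      origin[j] <- aff[r, 4] + (dim(data)[j] - 1) * col[r]
    } else {
      origin[j] <- aff[r, 4]
    }
  }
  if (anyDuplicated(labels)) {
    stopf("xform of '%s' does not map array axes to three distinct anatomical axes",
          path)
  }
  if (mask) {
    seg_mask((data > 0.5) * 1, spacing, origin, labels)
  } else {
    volume_image(data, spacing, origin, labels)
  }
}

#' Write a volume to NIfTI
#'
#' Encodes spacing, origin and anatomical axis order in the qform/sform
#' affine (RAS, axis-aligned).
#'
#' @param v a [volume_image()] or [seg_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_image"))
  aff <- diag(4)
  aff[1:3, 1:3] <- 0
  for (j in 1:3) {
    r <- world_rows[[v$axis_labels[j]]]
    aff[r, j] <- v$spacing[j]
    aff[r, 4] <- v$origin[j]
  }
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
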