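# Segmentation and volumetry metrics: mask volume, PI-RADS ellipsoid-formula
# volume, Dice, average surface distance and relative volume difference.

#' Volume enclosed by a binary mask
#'
#' Foreground voxel count times voxel volume, in ml.
#'
#' @param mask a [seg_mask()].
#' @return Volume in ml.
#' @examples
#' m <- seg_mask(array(rep(1, 1000), c(10, 10, 10)), spacing = c(0.5, 0.5, 3))
#' mask_volume(m)  # 0.75 ml
#' @export
mask_volume <- function(mask) {
  if (!inherits(mask, "volume_image") || is.null(mask$spacing)) {
    stopf("'mask' must carry grid spacing metadata")
  }
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' Ellipsoid-formula prostate volume (PI-RADS 2.1)
#'
#' `pi/6 * W * H * L / 1000` ml from the three orthogonal maximal diameters
#' in mm (width, height, length), the manual volumetry standard this package
#' uses as the reference (PVref role).
#'
#' @param W_mm,H_mm,L_mm orthogonal diameters in mm (positive).
#' @return Volume in ml.
#' @export
ellipsoid_formula_volume <- function(W_mm, H_mm, L_mm) {
  check_positive(c(W_mm, H_mm, L_mm), "diameters")
  pi / 6 * W_mm * H_mm * L_mm / 1000
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    stopf("masks are on different grids (%s vs %s)",
          paste(dim(a$data), collapse = "x"), paste(dim(b$data), collapse = "x"))
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-9) {
    stopf("masks have different spacings")
  }
  invisible(TRUE)
}

#' Dice score coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks score 1 by convention
#' (logged as a message); empty versus non-empty scores 0.
#'
#' @param pred,ref [seg_mask()] objects on the same grid.
#' @return Dice overlap in `[0, 1]`.
#' @export
dsc <- function(pred, ref) {
  check_same_grid(pred, ref)
  sa <- sum(pred$data); sb <- sum(ref$data)
  if (sa + sb == 0) {
    message("dsc: both masks empty; returning 1 by convention")
    return(1)
  }
  2 * sum(pred$data * ref$data) / (sa + sb)
}

# 6-connectivity boundary voxels of a binary array (outside counts as
# background, so foreground voxels on the array edge are surface voxels)
boundary_voxels <- function(m) {
  d <- dim(m)
  pad <- array(0, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- function(di, dj, dk) {
    pad[(2:(d[1] + 1)) + di, (2:(d[2] + 1)) + dj, (2:(d[3] + 1)) + dk]
  }
  nb_min <- core(1, 0, 0) * core(-1, 0, 0) * core(0, 1, 0) *
    core(0, -1, 0) * core(0, 0, 1) * core(0, 0, -1)
  which(m == 1 & nb_min == 0, arr.ind = TRUE)
}

#' Average surface distance
#'
#' Symmetric mean of nearest-surface distances between the boundaries of two
#' binary masks, in physical mm: the mean over boundary voxels of `pred` of
#' the distance to the nearest boundary voxel of `ref`, averaged with the
#' opposite direction. Boundaries use 6-connectivity; distances account for
#' anisotropic spacing.
#'
#' @param pred,ref non-empty [seg_mask()] objects on the same grid.
#' @return Average surface distance in mm.
#' @export
asd <- function(pred, ref) {
  check_same_grid(pred, ref)
  if (sum(pred$data) == 0) stopf("asd undefined: 'pred' mask is empty")
  if (sum(ref$data) == 0) stopf("asd undefined: 'ref' mask is empty")
  sp <- pred$spacing
  pa <- boundary_voxels(pred$data)
  pb <- boundary_voxels(ref$data)
  A <- sweep(pa, 2, sp, `*`)
  B <- sweep(pb, 2, sp, `*`)
  (mean_nn_dist_cpp(A, B) + mean_nn_dist_cpp(B, A)) / 2
}

#' Relative volume difference
#'
#' `100 * (pv_pred - pv_ref) / pv_ref` percent; negative values reflect
#' underestimation and positive values overestimation relative to the
#' reference.
#'
#' @param pv_pred,pv_ref volumes in ml; `pv_ref` must be positive.
#' @return Signed percent difference.
#' @export
rvd <- function(pv_pred, pv_ref) {
  if (any(pv_ref <= 0)) stopf("'pv_ref' must be positive")
  100 * (pv_pred - pv_ref) / pv_ref
}
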