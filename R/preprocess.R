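# Preprocessing: percentile-clipped z-score intensity normalization and
# resampling of images/masks to a common reference space.

#' Normalize volume intensities
#'
#' Clips intensities to a percentile window (default 0.5th to 99.5th) and
#' then z-scores the clipped volume, the de facto standard preparation for
#' T2-weighted stacks from heterogeneous scanners. The mapping is monotone
#' non-decreasing and invariant to positive affine rescaling of the input.
#'
#' @param v a [volume_image()].
#' @param clip length-2 numeric, lower/upper clip quantiles in `[0, 1]`.
#' @return A [volume_image()] with mean 0 and SD 1.
#' @export
normalize_intensity <- function(v, clip = c(0.005, 0.995)) {
  stopifnot(inherits(v, "volume_image"))
  if (length(clip) != 2L || clip[1] < 0 || clip[2] > 1 || clip[1] >= clip[2]) {
    stopf("'clip' must be increasing quantiles in [0, 1]")
  }
  x <- v$data
  if (length(unique(as.vector(x))) < 2L) {
    stopf("cannot normalize a constant volume (SD undefined)")
  }
  q <- quantile(x, probs = clip, names = FALSE)
  x <- pmin(pmax(x, q[1]), q[2])
  s <- sd(x)
  if (s == 0) stopf("volume is constant after clipping (SD undefined)")
  out <- v
  out$data <- array((x - mean(x)) / s, dim(v$data))
  out
}

#' Resample a volume or mask to a target spacing
#'
#' Resamples onto a grid with the requested spacing covering the same
#' physical extent (cell-centred convention). Images are interpolated with a
#' third-order (cubic Catmull-Rom) spline; masks with linear interpolation
#' followed by a 0.5 threshold, which keeps the output binary. A single-slice
#' axis cannot support the cubic kernel and falls back to linear with a
#' warning.
#'
#' @param v a [volume_image()] or [seg_mask()].
#' @param target_spacing numeric length-3, target spacing in mm per array
#'   axis (default the 0.5 x 0.5 x 3.0 mm reference space).
#' @return The resampled object, same class as `v`.
#' @export
resample_to_reference <- function(v, target_spacing = c(0.5, 0.5, 3.0)) {
  stopifnot(inherits(v, "volume_image"))
  check_positive(target_spacing, "target_spacing")
  if (length(target_spacing) != 3L) stopf("'target_spacing' must have length 3")
  n_in <- dim(v$data)
  s <- v$spacing
  t <- as.numeric(target_spacing)
  n_out <- pmax(1L, as.integer(round(n_in * s / t)))
  coords <- lapply(1:3, function(d) {
    ((seq_len(n_out[d]) - 0.5) * t[d]) / s[d] - 0.5
  })
  is_mask <- is_seg_mask(v)
  method <- if (is_mask) 0L else 1L
  if (!is_mask && any(n_in == 1L)) {
    warning("single-slice axis: falling back to linear interpolation")
    method <- 0L
  }
  y <- resample_grid_cpp(v$data, coords[[1]], coords[[2]], coords[[3]], method)
  origin <- v$origin + (t - s) / 2
  if (is_mask) {
    seg_mask((y >= 0.5) * 1, t, origin, v$axis_labels)
  } else {
    volume_image(y, t, origin, v$axis_labels)
  }
}
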