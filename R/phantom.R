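# Synthetic multi-planar phantom exams: a deformed-ellipsoid gland in a
# noisy, bias-modulated background, rendered on a fine isotropic grid and
# resliced/resampled to per-view anisotropic grids with known ground truth.

#' Parametric description of a synthetic gland phantom
#'
#' Describes one phantom: an ellipsoid gland (semi-axes along LR, AP, SI)
#' with a smooth low-order spherical-harmonic radial perturbation, a
#' two-class intensity model with multiplicative low-frequency bias and
#' additive Gaussian noise, and per-view acquisition grids. The analytic
#' volume is known (exactly `4/3*pi*a*b*c/1000` ml at zero deformation,
#' by spherical quadrature otherwise).
#'
#' @param semi_axes numeric length-3 `(a, b, c)`, gland semi-axes in mm
#'   along LR, AP, SI.
#' @param center_offset numeric length-3, gland centre offset from the grid
#'   centre in mm.
#' @param deform_amplitude radial perturbation amplitude as a fraction of
#'   the local radius, in `[0, 0.3]`.
#' @param noise_sd additive Gaussian noise SD (intensity units) per view.
#' @param bias_amplitude multiplicative low-frequency bias field strength.
#' @param fg_intensity,bg_intensity gland and background intensities.
#' @param view_spacings named list with entries `axial`, `sagittal`,
#'   `coronal`, each `c(in_plane_mm, slice_mm)`.
#' @param views_present character subset of
#'   `c("axial", "sagittal", "coronal")`; must contain `"axial"`, the
#'   canonical plane.
#' @param fine_spacing isotropic rendering spacing in mm.
#' @param extent_mm optional fixed cubic field of view in mm; if `NULL` the
#'   extent adapts to the gland size.
#' @param seed integer; identical seed and spec give a bit-identical phantom.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(semi_axes = c(20, 20, 20), deform_amplitude = 0,
#'                      noise_sd = 0)
#' ellipsoid_true_volume(20, 20, 20)  # 33.51 ml
#' @export
phantom_spec <- function(semi_axes = c(23, 19, 27),
                         center_offset = c(0, 0, 0),
                         deform_amplitude = 0.08,
                         noise_sd = 0.08,
                         bias_amplitude = 0.15,
                         fg_intensity = 1.0,
                         bg_intensity = 0.2,
                         view_spacings = list(axial = c(0.5, 3.0),
                                              sagittal = c(0.5, 3.0),
                                              coronal = c(0.5, 3.0)),
                         views_present = c("axial", "sagittal", "coronal"),
                         fine_spacing = 0.5,
                         extent_mm = NULL,
                         seed = 1L) {
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0)) {
    stopf("invalid 'semi_axes': must be three positive values")
  }
  if (length(center_offset) != 3L || any(!is.finite(center_offset))) {
    stopf("invalid 'center_offset'")
  }
  if (!is.finite(deform_amplitude) || deform_amplitude < 0 ||
      deform_amplitude > 0.3) {
    stopf("invalid 'deform_amplitude': must be in [0, 0.3]")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stopf("invalid 'noise_sd': must be >= 0")
  if (!is.finite(bias_amplitude) || bias_amplitude < 0) {
    stopf("invalid 'bias_amplitude'")
  }
  views_present <- unique(as.character(views_present))
  if (!all(views_present %in% c("axial", "sagittal", "coronal"))) {
    stopf("invalid 'views_present': unknown view label")
  }
  if (!"axial" %in% views_present) {
    stopf("invalid 'views_present': axial (the canonical plane) is required")
  }
  for (vw in c("axial", "sagittal", "coronal")) {
    sp <- view_spacings[[vw]]
    if (is.null(sp) || length(sp) != 2L || any(sp <= 0)) {
      stopf("invalid 'view_spacings': entry '%s' must be c(in_plane, slice) > 0", vw)
    }
  }
  check_positive(fine_spacing, "fine_spacing")
  if (!is.null(extent_mm)) check_positive(extent_mm, "extent_mm")
  structure(
    list(semi_axes = as.numeric(semi_axes),
         center_offset = as.numeric(center_offset),
         deform_amplitude = deform_amplitude, noise_sd = noise_sd,
         bias_amplitude = bias_amplitude, fg_intensity = fg_intensity,
         bg_intensity = bg_intensity, view_spacings = view_spacings,
         views_present = views_present, fine_spacing = fine_spacing,
         extent_mm = extent_mm, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Analytic ellipsoid volume
#'
#' `4/3 * pi * a * b * c / 1000` ml from semi-axes in mm. Together with
#' [ellipsoid_formula_volume()] this links the phantom ground truth to the
#' PI-RADS ellipsoid formula: for diameters `W = 2a`, `H = 2b`, `L = 2c`,
#' `pi/6 * W * H * L` equals `4/3 * pi * a * b * c` exactly.
#'
#' @param a_mm,b_mm,c_mm semi-axes in mm (positive).
#' @return Volume in ml.
#' @export
ellipsoid_true_volume <- function(a_mm, b_mm, c_mm) {
  check_positive(c(a_mm, b_mm, c_mm), "semi-axes")
  4 / 3 * pi * a_mm * b_mm * c_mm / 1000
}

# Low-order real spherical-harmonic basis (l = 2 and part of l = 3),
# unnormalized; the combination is rescaled to unit max amplitude.
sh_eval <- function(theta, phi, coef) {
  ct <- cos(theta); st <- sin(theta)
  B <- cbind(3 * ct^2 - 1,
             st * ct * cos(phi),
             st * ct * sin(phi),
             st^2 * cos(2 * phi),
             st^2 * sin(2 * phi),
             (5 * ct^3 - 3 * ct),
             st^3 * cos(3 * phi))
  as.vector(B %*% coef)
}

# deformation field closure for a spec: f(theta, phi) with max |f| = 1
deform_field <- function(spec) {
  if (spec$deform_amplitude == 0) {
    return(function(theta, phi) rep(0, length(theta)))
  }
  coef <- with_seed(sub_seed(spec$seed, "deform"), rnorm(7))
  th <- seq(0, pi, length.out = 91)
  ph <- seq(0, 2 * pi, length.out = 181)[-181]
  g <- expand.grid(th = th, ph = ph)
  scale <- max(abs(sh_eval(g$th, g$ph, coef)))
  if (scale == 0) scale <- 1
  coef <- coef / scale
  function(theta, phi) sh_eval(theta, phi, coef)
}

# analytic volume (ml) by spherical quadrature: V = (abc/3) * Int m^3 dOmega
phantom_volume_ml <- function(spec, f) {
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; c3 <- spec$semi_axes[3]
  if (spec$deform_amplitude == 0) {
    return(ellipsoid_true_volume(a, b, c3))
  }
  gl <- gauss_legendre(96)        # nodes in cos(theta)
  nphi <- 192
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  theta <- acos(gl$nodes)
  G <- expand.grid(theta = theta, phi = phi)
  m <- 1 + spec$deform_amplitude * f(G$theta, G$phi)
  w <- rep(gl$weights, times = nphi) * (2 * pi / nphi)
  integral <- sum(w * m^3)
  (a * b * c3 / 3) * integral / 1000
}

# maximal extents (mm) along LR/AP/SI of the deformed surface
phantom_diameters <- function(spec, f) {
  a <- spec$semi_axes
  if (spec$deform_amplitude == 0) return(2 * a)
  th <- seq(0, pi, length.out = 181)
  ph <- seq(0, 2 * pi, length.out = 361)[-361]
  G <- expand.grid(theta = th, phi = ph)
  m <- 1 + spec$deform_amplitude * f(G$theta, G$phi)
  x <- a[1] * m * sin(G$theta) * cos(G$phi)
  y <- a[2] * m * sin(G$theta) * sin(G$phi)
  z <- a[3] * m * cos(G$theta)
  c(max(x) - min(x), max(y) - min(y), max(z) - min(z))
}

#' Generate a multi-planar phantom exam with ground truth
#'
#' Renders the gland on a fine isotropic grid, then reslices and resamples
#' it to each requested view's anisotropic grid (cubic spline for the
#' intensities) and adds per-view Gaussian noise. The axial-grid training
#' mask, per-view masks (for fully supervised baselines) and the analytic
#' ground truth are returned alongside.
#'
#' @param spec a [phantom_spec()].
#' @param id exam identifier string.
#' @return A list with elements `exam` (class `mp_exam`: `id`, `views` as a
#'   named list of [volume_image()], `mask` on the axial grid, `view_masks`
#'   for sagittal/coronal) and `truth` (class `mp_truth`: fine-grid `mask3d`,
#'   `true_volume` in ml, `ellipsoid_diameters` `(W, H, L)` in mm).
#' @export
generate_phantom <- function(spec, id = sprintf("phantom_%04d", spec$seed)) {
  stopifnot(inherits(spec, "phantom_spec"))
  f <- deform_field(spec)
  a <- spec$semi_axes; d <- spec$deform_amplitude
  h <- spec$fine_spacing
  extent <- spec$extent_mm
  if (is.null(extent)) {
    extent <- 2 * (max(a) * (1 + d) + max(abs(spec$center_offset))) + 8
  }
  n <- as.integer(ceiling(extent / h))
  coords <- (seq_len(n) - 0.5 - n / 2) * h    # centred physical coords

  ux <- (coords - spec$center_offset[1]) / a[1]
  uy <- (coords - spec$center_offset[2]) / a[2]
  uz <- (coords - spec$center_offset[3]) / a[3]
  UX <- array(ux, c(n, n, n))
  UY <- array(rep(uy, each = n), c(n, n, n))
  UZ <- array(rep(uz, each = n * n), c(n, n, n))
  rho <- sqrt(UX^2 + UY^2 + UZ^2)

  inside <- rho <= (1 - d)
  if (d > 0) {
    shell <- which(rho > (1 - d) & rho < (1 + d))
    if (length(shell)) {
      r <- rho[shell]
      theta <- acos(pmin(pmax(UZ[shell] / r, -1), 1))
      phi <- atan2(UY[shell], UX[shell])
      inside[shell] <- r <= 1 + d * f(theta, phi)
    }
  }
  mask_fine <- array(as.numeric(inside), c(n, n, n))

  intens <- spec$bg_intensity + (spec$fg_intensity - spec$bg_intensity) * mask_fine
  if (spec$bias_amplitude > 0) {
    ph <- with_seed(sub_seed(spec$seed, "bias"), runif(3, 0, 2 * pi))
    w <- pi / extent
    bias <- 1 + spec$bias_amplitude *
      outer(outer(sin(w * coords + ph[1]), sin(w * coords + ph[2])),
            sin(w * coords + ph[3]))
    intens <- intens * array(bias, c(n, n, n))
  }

  origin <- rep(coords[1], 3)
  fine_img <- volume_image(intens, rep(h, 3), origin)
  fine_mask <- seg_mask(mask_fine, rep(h, 3), origin)

  views <- list()
  for (vw in spec$views_present) {
    sp <- spec$view_spacings[[vw]]
    vimg <- resample_to_reference(reslice_view(fine_img, vw),
                                  c(sp[1], sp[1], sp[2]))
    if (spec$noise_sd > 0) {
      noise <- with_seed(sub_seed(spec$seed, paste0("noise_", vw)),
                         rnorm(length(vimg$data), 0, spec$noise_sd))
      vimg$data <- vimg$data + array(noise, dim(vimg$data))
    }
    views[[vw]] <- vimg
  }

  view_mask <- function(vw) {
    sp <- spec$view_spacings[[vw]]
    resample_to_reference(reslice_view(fine_mask, vw), c(sp[1], sp[1], sp[2]))
  }
  mask_ax <- view_mask("axial")
  view_masks <- list()
  for (vw in setdiff(spec$views_present, "axial")) {
    view_masks[[vw]] <- view_mask(vw)
  }

  truth <- structure(
    list(mask3d = fine_mask,
         true_volume = phantom_volume_ml(spec, f),
         ellipsoid_diameters = phantom_diameters(spec, f)),
    class = "mp_truth"
  )
  if (sum(truth$mask3d$data) == 0) stopf("phantom mask is empty; enlarge extent")
  exam <- structure(
    list(id = id, views = views, mask = mask_ax, view_masks = view_masks,
         pv_ref = ellipsoid_formula_volume(truth$ellipsoid_diameters[1],
                                           truth$ellipsoid_diameters[2],
                                           truth$ellipsoid_diameters[3]),
         spec = spec),
    class = "mp_exam"
  )
  list(exam = exam, truth = truth)
}

#' @export
print.mp_exam <- function(x, ...) {
  cat(sprintf("<mp_exam> %s: views {%s}, axial grid %s, EF reference %.2f ml\n",
              x$id, paste(names(x$views), collapse = ", "),
              paste(dim(x$mask$data), collapse = "x"), x$pv_ref))
  invisible(x)
}

#' Generate a cohort of phantom exams
#'
#' Draws per-exam gland geometry, deformation, noise and bias from uniform
#' ranges and renders every phantom on a fixed field of view, so that all
#' exams in the cohort share per-view grid sizes. The default conditions are
#' the package's desk-scale study cohort: 48 mm field of view at a 0.5 mm
#' fine grid, per-view spacing 0.75 mm in-plane / 3.0 mm slice (axial slices
#' 64 x 64 x 16), gland semi-axes uniform in 13-20 mm.
#'
#' @param n number of exams (>= 1).
#' @param base_spec a [phantom_spec()] providing all non-varied parameters.
#' @param variability named list of uniform ranges `c(lo, hi)`:
#'   `semi_axes` (mm, drawn independently per axis), `deform_amplitude`,
#'   `noise_sd`, `bias_amplitude`, `center_offset` (mm, per axis).
#' @param scenario `"full"` (all three views), `"axial_only"`, or `"mixed"`
#'   (each exam keeps axial and independently keeps each orthogonal view
#'   with probability 1/2).
#' @param seed integer cohort seed; the cohort is reproducible from it.
#' @return List of `n` elements, each `list(exam, truth)` as in
#'   [generate_phantom()].
#' @export
make_cohort <- function(n,
                        base_spec = phantom_spec(
                          view_spacings = list(axial = c(0.75, 3.0),
                                               sagittal = c(0.75, 3.0),
                                               coronal = c(0.75, 3.0)),
                          extent_mm = 48),
                        variability = list(semi_axes = c(13, 20),
                                           deform_amplitude = c(0, 0.12),
                                           noise_sd = c(0.03, 0.10),
                                           bias_amplitude = c(0, 0.20),
                                           center_offset = c(-3, 3)),
                        scenario = c("full", "axial_only", "mixed"),
                        seed = 1L) {
  if (!is.numeric(n) || n < 1) stopf("'n' must be >= 1")
  scenario <- match.arg(scenario)
  for (nm in names(variability)) {
    rg <- variability[[nm]]
    if (length(rg) != 2L || any(!is.finite(rg)) || rg[2] < rg[1]) {
      stopf("invalid variability range for '%s'", nm)
    }
  }
  draws <- with_seed(sub_seed(seed, "cohort"), {
    lapply(seq_len(n), function(i) {
      list(semi = runif(3, variability$semi_axes[1], variability$semi_axes[2]),
           deform = runif(1, variability$deform_amplitude[1],
                          variability$deform_amplitude[2]),
           noise = runif(1, variability$noise_sd[1], variability$noise_sd[2]),
           bias = runif(1, variability$bias_amplitude[1],
                        variability$bias_amplitude[2]),
           offset = runif(3, variability$center_offset[1],
                          variability$center_offset[2]),
           keep = runif(2) < 0.5)
    })
  })
  lapply(seq_len(n), function(i) {
    dr <- draws[[i]]
    views <- switch(scenario,
      full = c("axial", "sagittal", "coronal"),
      axial_only = "axial",
      mixed = c("axial", c("sagittal", "coronal")[dr$keep])
    )
    spec <- phantom_spec(
      semi_axes = dr$semi, center_offset = dr$offset,
      deform_amplitude = dr$deform, noise_sd = dr$noise,
      bias_amplitude = dr$bias,
      fg_intensity = base_spec$fg_intensity,
      bg_intensity = base_spec$bg_intensity,
      view_spacings = base_spec$view_spacings,
      views_present = views,
      fine_spacing = base_spec$fine_spacing,
      extent_mm = base_spec$extent_mm,
      seed = sub_seed(seed, paste0("exam", i))
    )
    generate_phantom(spec, id = sprintf("exam_%03d", i))
  })
}

#' Write a cohort to disk as NIfTI volumes plus a CSV manifest
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(ct) {
    ex <- ct$exam
    for (vw in names(ex$views)) {
      write_volume(ex$views[[vw]], file.path(dir, sprintf("%s_%s.nii.gz",
                                                          ex$id, vw)))
    }
    write_volume(ex$mask, file.path(dir, sprintf("%s_axial_mask.nii.gz", ex$id)))
    data.frame(id = ex$id, views = paste(names(ex$views), collapse = "+"),
               true_volume_ml = ct$truth$true_volume,
               W_mm = ct$truth$ellipsoid_diameters[1],
               H_mm = ct$truth$ellipsoid_diameters[2],
               L_mm = ct$truth$ellipsoid_diameters[3],
               seed = ex$spec$seed)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "cohort_manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
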