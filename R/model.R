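# Multi-planar network construction and the public forward surface.
#
# The architecture follows the training diagram of the framework: three
# plane roles (axial, sagittal, coronal) share one 2D U-Net encoder
# parameter set; per-slice latents are produced by global average pooling
# of the deepest encoder features followed by a linear projection; the
# latents of the available views are fused by their arithmetic mean; the
# fused latent is broadcast and concatenated onto the deepest axial feature
# map before decoding; the decoder receives skip connections only from the
# axial encoder pass.

#' Model and training configuration
#'
#' @param encoder_depth number of encoder resolution levels (>= 2) above the
#'   bottleneck.
#' @param base_channels channels at the first level; doubled per level.
#' @param latent_dim dimensionality of the shared latent space.
#' @param in_plane_size slice side in pixels; must be divisible by
#'   `2^encoder_depth`.
#' @param lambda_contrastive weight of the cosine alignment terms (>= 0;
#'   0 disables them, recovering the plain Dice + cross-entropy loss).
#'   Default 0.25.
#' @param learning_rate initial SGD learning rate.
#' @param momentum SGD momentum (default 0.99).
#' @param epochs training epochs per fold.
#' @param folds cross-validation folds (>= 2).
#' @param slices_per_exam axial slices sampled per exam per epoch.
#' @param dice_eps Dice smoothing constant.
#' @param contrastive_mode `"align"` (positive-pair cosine alignment,
#'   default) or `"infonce"` (temperature-scaled, other exams in the batch
#'   act as negatives).
#' @param infonce_temperature temperature for `"infonce"` mode.
#' @param grad_clip global gradient-norm clip applied per step.
#' @param lr_power exponent of the polynomial learning-rate decay.
#' @param seed integer seed governing initialization and batching.
#' @param preset `"desk"` (default desk-scale settings) or `"paper"`
#'   (300 epochs, five folds, the full-scale protocol).
#' @return Object of class `mpkb_config`.
#' @export
mpkb_config <- function(encoder_depth = 2L, base_channels = 8L,
                        latent_dim = 16L, in_plane_size = 64L,
                        lambda_contrastive = 0.25, learning_rate = 0.01,
                        momentum = 0.99, epochs = 20L, folds = 5L,
                        slices_per_exam = 3L, dice_eps = 1e-5,
                        contrastive_mode = c("align", "infonce"),
                        infonce_temperature = 0.1, grad_clip = 2.0,
                        lr_power = 0.9, seed = 1L,
                        preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  contrastive_mode <- match.arg(contrastive_mode)
  if (preset == "paper") {
    epochs <- 300L
    folds <- 5L
  }
  if (encoder_depth < 2) stopf("'encoder_depth' must be >= 2")
  if (folds < 2) stopf("'folds' must be >= 2")
  if (lambda_contrastive < 0) stopf("'lambda_contrastive' must be >= 0")
  if (in_plane_size %% (2^encoder_depth) != 0) {
    stopf("'in_plane_size' (%d) must be divisible by 2^encoder_depth (%d)",
          in_plane_size, 2^encoder_depth)
  }
  structure(
    list(encoder_depth = as.integer(encoder_depth),
         base_channels = as.integer(base_channels),
         latent_dim = as.integer(latent_dim),
         in_plane_size = as.integer(in_plane_size),
         lambda_contrastive = lambda_contrastive,
         learning_rate = learning_rate, momentum = momentum,
         epochs = as.integer(epochs), folds = as.integer(folds),
         slices_per_exam = as.integer(slices_per_exam),
         dice_eps = dice_eps, contrastive_mode = contrastive_mode,
         infonce_temperature = infonce_temperature, grad_clip = grad_clip,
         lr_power = lr_power, seed = as.integer(seed), preset = preset),
    class = "mpkb_config"
  )
}

conv_init <- function(k, cin, cout) {
  list(w = array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

enc_channels <- function(cfg) {
  c(cfg$base_channels * 2^(seq_len(cfg$encoder_depth) - 1),
    cfg$base_channels * 2^cfg$encoder_depth)
}

init_params <- function(cfg) {
  ch <- enc_channels(cfg)
  D <- cfg$encoder_depth
  cb <- ch[D + 1]
  with_seed(sub_seed(cfg$seed, "init"), {
    p <- list()
    cin <- 1L
    for (l in seq_len(D)) {
      p[[sprintf("enc%d_c1", l)]] <- conv_init(3, cin, ch[l])
      p[[sprintf("enc%d_c2", l)]] <- conv_init(3, ch[l], ch[l])
      cin <- ch[l]
    }
    p$bot_c1 <- conv_init(3, ch[D], cb)
    p$bot_c2 <- conv_init(3, cb, cb)
    p$latent <- list(w = matrix(rnorm(cb * cfg$latent_dim, 0, sqrt(1 / cb)),
                                cb, cfg$latent_dim),
                     b = numeric(cfg$latent_dim))
    p$fuse <- conv_init(3, cb + cfg$latent_dim, cb)
    for (l in rev(seq_len(D))) {
      cup <- if (l == D) cb else ch[l + 1]
      p[[sprintf("dec%d_c1", l)]] <- conv_init(3, ch[l] + cup, ch[l])
      p[[sprintf("dec%d_c2", l)]] <- conv_init(3, ch[l], ch[l])
    }
    p$final <- conv_init(1, ch[1], 1)
    p
  })
}

n_params <- function(p) {
  sum(vapply(p, function(q) length(q$w) + length(q$b), numeric(1)))
}

#' Build a multi-planar knowledge-based segmentation model
#'
#' Instantiates the network with seeded He-normal initialization. One
#' parameter set serves all three encoder roles (weight sharing is
#' structural: there is a single encoder in memory), and the decoder
#' receives skip tensors only from the axial pass.
#'
#' @param cfg an [mpkb_config()].
#' @return Object of class `mpkb_model` with elements `cfg`, `params`,
#'   `n_params`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "mpkb_config"))
  params <- init_params(cfg)
  structure(list(cfg = cfg, params = params, n_params = n_params(params)),
            class = "mpkb_model")
}

#' @export
print.mpkb_model <- function(x, ...) {
  cfg <- x$cfg
  ch <- enc_channels(cfg)
  cat("<mpkb_model> weight-shared multi-planar 2D U-Net\n")
  cat(sprintf("  encoder: depth %d, channels %s (shared across axial/sagittal/coronal)\n",
              cfg$encoder_depth,
              paste(ch[seq_len(cfg$encoder_depth)], collapse = "-")))
  cat(sprintf("  bottleneck: %d channels -> latent dim %d, mean fusion over views\n",
              ch[cfg$encoder_depth + 1], cfg$latent_dim))
  cat(sprintf("  decoder: axial skip connections only; in-plane %dx%d\n",
              cfg$in_plane_size, cfg$in_plane_size))
  cat(sprintf("  parameters: %d\n", x$n_params))
  invisible(x)
}

#' Batch of 2D slices from one view
#'
#' @param images array `H x W x B` (or `H x W x 1 x B`) of normalized slice
#'   intensities.
#' @param view source view label.
#' @param exam_ids per-slice exam provenance (length B).
#' @return Object of class `slice_batch`.
#' @export
slice_batch <- function(images, view = "axial", exam_ids = NULL) {
  d <- dim(images)
  if (length(d) == 3L) dim(images) <- c(d[1], d[2], 1L, d[3])
  else if (length(d) != 4L || d[3] != 1L) stopf("'images' must be H x W x B")
  if (dim(images)[1] != dim(images)[2]) {
    stopf("slices must be square (got %d x %d)", dim(images)[1], dim(images)[2])
  }
  view <- match.arg(view, c("axial", "sagittal", "coronal"))
  B <- dim(images)[4]
  if (is.null(exam_ids)) exam_ids <- rep(NA_character_, B)
  if (length(exam_ids) != B) stopf("'exam_ids' must have one entry per slice")
  structure(list(images = images, view = view, exam_ids = as.character(exam_ids)),
            class = "slice_batch")
}

#' Per-slice latent features from one view encoder
#'
#' @param vectors matrix, one `latent_dim` row per slice.
#' @param view source view label.
#' @return Object of class `latent_features`.
#' @export
latent_features <- function(vectors, view) {
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = 1)
  if (any(!is.finite(vectors))) stopf("latent vectors must be finite")
  structure(list(vectors = vectors, view = view), class = "latent_features")
}

#' Encode a slice batch into the shared latent space
#'
#' Runs the (shared) encoder on the batch and returns one fixed-dimension
#' latent vector per slice: global average pooling of the deepest feature
#' map followed by a linear projection. The latent dimensionality does not
#' depend on the view.
#'
#' @param model an [build_model()] result (or a fitted `mpkb` member).
#' @param batch a [slice_batch()].
#' @return [latent_features()] with one row per slice.
#' @export
encode_view <- function(model, batch) {
  stopifnot(inherits(model, "mpkb_model"), inherits(batch, "slice_batch"))
  check_in_plane(model$cfg, batch)
  enc <- enc_forward(model$params, model$cfg, batch$images)
  latent_features(enc$z, batch$view)
}

check_in_plane <- function(cfg, batch) {
  if (dim(batch$images)[1] != cfg$in_plane_size) {
    stopf("slice size %d does not match configured in-plane size %d",
          dim(batch$images)[1], cfg$in_plane_size)
  }
  invisible(TRUE)
}

#' Fuse per-view latents by their arithmetic mean
#'
#' The bottleneck fusion rule: the mean over the available views' projected
#' latents. The output dimension equals `latent_dim` regardless of how many
#' views are present, which is what lets inference activate only the
#' encoders whose planes were acquired; a single (axial) view fuses to
#' itself. The axial (canonical-plane) latent is required.
#'
#' @param latents list of [latent_features()]; context entries may have a
#'   single row (exam-level context), which is broadcast across the axial
#'   rows.
#' @return Fused latent matrix, one row per axial slice.
#' @export
fuse_latents <- function(latents) {
  if (inherits(latents, "latent_features")) latents <- list(latents)
  views <- vapply(latents, function(z) z$view, character(1))
  if (!"axial" %in% views) {
    stopf("axial latent missing: the canonical plane is required for fusion")
  }
  zax <- latents[[which(views == "axial")[1]]]$vectors
  B <- nrow(zax)
  acc <- zax
  cnt <- 1
  for (z in latents[views != "axial"]) {
    v <- z$vectors
    if (nrow(v) == 1L && B > 1L) v <- v[rep(1, B), , drop = FALSE]
    if (!identical(dim(v), dim(zax))) {
      stopf("latent dimensions disagree across views")
    }
    acc <- acc + v
    cnt <- cnt + 1
  }
  acc / cnt
}

#' Forward segmentation pass
#'
#' Predicts per-pixel foreground probabilities for a batch of axial slices,
#' optionally conditioned on sagittal/coronal context batches through the
#' fused bottleneck latent. With no context the fusion degrades to the mean
#' of one, so the call is identical to an axial-only deployment. Context
#' enters only through the bottleneck: skip connections come exclusively
#' from the axial pass.
#'
#' @param model an `mpkb_model`.
#' @param axial_batch a [slice_batch()] with `view = "axial"`.
#' @param context optional list of [slice_batch()]es (sagittal/coronal) from
#'   the same exams; either one slice per axial slice or a single exam-level
#'   slice.
#' @return Array `H x W x B` of probabilities in `[0, 1]`.
#' @export
forward_segment <- function(model, axial_batch, context = NULL) {
  stopifnot(inherits(model, "mpkb_model"))
  if (axial_batch$view != "axial") stopf("'axial_batch' must have view 'axial'")
  check_in_plane(model$cfg, axial_batch)
  lat <- list(encode_view(model, axial_batch))
  if (!is.null(context)) {
    for (cb in context) {
      if (cb$view == "axial") stopf("context batches must be sagittal/coronal")
      check_pairing(axial_batch, cb)
      lat <- c(lat, list(encode_view(model, cb)))
    }
  }
  zf <- fuse_latents(lat)
  enc <- enc_forward(model$params, model$cfg, axial_batch$images)
  out <- dec_forward(model$params, model$cfg, enc, zf)
  probs <- out$probs
  dim(probs) <- dim(probs)[c(1, 2, 4)]
  probs
}

check_pairing <- function(axial_batch, ctx_batch) {
  aid <- axial_batch$exam_ids
  cid <- ctx_batch$exam_ids
  if (all(is.na(aid)) || all(is.na(cid))) return(invisible(TRUE))
  ok <- if (length(cid) == length(aid)) {
    all(cid == aid, na.rm = TRUE)
  } else if (length(cid) == 1L) {
    all(aid == cid[1], na.rm = TRUE)
  } else FALSE
  if (!ok) {
    stopf("context exam ids disagree with axial exam ids (pairing error)")
  }
  invisible(TRUE)
}
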