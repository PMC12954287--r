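# Cross-validated training with axial-only supervision and ensemble
# inference. The KB model's data path reads only the axial mask; the fully
# supervised reference model ("baseline") additionally decodes sagittal and
# coronal passes through the weight-tied decoder, supervised with per-view
# masks, and is identical to the KB model at inference.

# Precompute per-exam normalized view arrays and mask slices once per fold.
prepare_exam <- function(exam, model_type) {
  if (is.null(exam$views$axial)) stopf("exam '%s' lacks an axial view", exam$id)
  if (is.null(exam$mask)) stopf("exam '%s' lacks an axial mask", exam$id)
  out <- list(id = exam$id,
              ax = normalize_intensity(exam$views$axial)$data,
              mask = exam$mask$data)
  for (vw in c("sagittal", "coronal")) {
    if (!is.null(exam$views[[vw]])) {
      out[[vw]] <- normalize_intensity(exam$views[[vw]])$data
      if (model_type == "baseline") {
        vm <- exam$view_masks[[vw]]
        if (is.null(vm)) {
          stopf("fully supervised model requires a %s mask for exam '%s'",
                vw, exam$id)
        }
        out[[paste0(vw, "_mask")]] <- vm$data
      }
    }
  }
  out
}

central_range <- function(nz, frac) {
  lo <- max(1L, floor(nz * (1 - frac) / 2) + 1L)
  hi <- min(nz, ceiling(nz * (1 + frac) / 2))
  lo:hi
}

slice_tensor <- function(vol3d, idx) {
  H <- dim(vol3d)[1]; W <- dim(vol3d)[2]
  array(vol3d[, , idx], c(H, W, 1L, length(idx)))
}

contrastive_grad <- function(cfg, za, zo) {
  if (cfg$contrastive_mode == "infonce") {
    infonce_loss_grad(za, zo, cfg$infonce_temperature)
  } else {
    cosine_loss_grad(za, zo)
  }
}

# one optimization step on one exam; returns the loss bundle
train_step <- function(params, cfg, ex, model_type, vel, lr) {
  nz <- dim(ex$ax)[3]
  ns <- min(cfg$slices_per_exam, nz)
  cand <- central_range(nz, 0.75)
  idx <- if (length(cand) >= ns) sample(cand, ns) else
    sample(nz, ns, replace = TRUE)
  xax <- slice_tensor(ex$ax, idx)
  targ <- ex$mask[, , idx, drop = FALSE]

  G <- grad_env()
  encA <- enc_forward(params, cfg, xax)
  lat <- list(encA$z)
  ctx <- list()
  for (vw in c("sagittal", "coronal")) {
    if (!is.null(ex[[vw]])) {
      nzv <- dim(ex[[vw]])[3]
      vidx <- sample(central_range(nzv, 0.5), ns, replace = TRUE)
      xv <- slice_tensor(ex[[vw]], vidx)
      encV <- enc_forward(params, cfg, xv)
      ctx[[vw]] <- list(enc = encV, x = xv, idx = vidx)
      lat <- c(lat, list(encV$z))
    }
  }
  nviews <- length(lat)
  zf <- Reduce(`+`, lat) / nviews
  dec <- dec_forward(params, cfg, encA, zf)
  seg <- seg_loss_grad(dec$probs, targ, cfg$dice_eps)

  con <- list(sagittal = NULL, coronal = NULL)
  lam <- cfg$lambda_contrastive
  if (lam > 0) {
    for (vw in names(ctx)) con[[vw]] <- contrastive_grad(cfg, encA$z, ctx[[vw]]$enc$z)
  }

  db <- dec_backward(params, cfg, encA, dec, seg$glogits, G)
  gz_share <- db$g_zf / nviews
  gz_ax <- gz_share
  for (vw in names(ctx)) {
    gz_v <- gz_share
    if (!is.null(con[[vw]])) {
      gz_ax <- gz_ax + lam * con[[vw]]$ga
      gz_v <- gz_v + lam * con[[vw]]$go
    }
    enc_backward(params, cfg, ctx[[vw]]$enc, G, gz = gz_v)
  }
  enc_backward(params, cfg, encA, G, g_b2 = db$g_b2, gz = gz_ax,
               g_skips = db$g_skips)

  if (model_type == "baseline") {
    # auxiliary weight-tied decoding of each context view, supervised with
    # that view's mask; dropped at inference
    for (vw in names(ctx)) {
      encV <- ctx[[vw]]$enc
      vtarg <- ex[[paste0(vw, "_mask")]][, , ctx[[vw]]$idx, drop = FALSE]
      decV <- dec_forward(params, cfg, encV, encV$z)
      segV <- seg_loss_grad(decV$probs, vtarg, cfg$dice_eps)
      dbV <- dec_backward(params, cfg, encV, decV, segV$glogits, G)
      enc_backward(params, cfg, encV, G, g_b2 = dbV$g_b2, gz = dbV$g_zf,
                   g_skips = dbV$g_skips)
    }
  }

  # global gradient-norm clipping guards the high-momentum optimizer
  # against occasional exploding steps at small batch sizes
  gsq <- 0
  for (nm in names(params)) {
    g <- G[[nm]]
    if (!is.null(g)) gsq <- gsq + sum(g$w^2) + sum(g$b^2)
  }
  if (!is.finite(gsq)) {
    stopf("non-finite gradient encountered (exam '%s'); try a lower learning rate",
          ex$id)
  }
  gscale <- if (gsq > cfg$grad_clip^2) cfg$grad_clip / sqrt(gsq) else 1

  # SGD with momentum, in place across the shared parameter list
  for (nm in names(params)) {
    g <- G[[nm]]
    if (is.null(g)) next
    g$w <- g$w * gscale
    g$b <- g$b * gscale
    vel[[nm]]$w <- cfg$momentum * vel[[nm]]$w - lr * g$w
    vel[[nm]]$b <- cfg$momentum * vel[[nm]]$b - lr * g$b
    params[[nm]]$w <- params[[nm]]$w + vel[[nm]]$w
    params[[nm]]$b <- params[[nm]]$b + vel[[nm]]$b
  }
  bundle <- kb_total_loss(seg,
                          if (is.null(con$sagittal)) NULL else con$sagittal$value,
                          if (is.null(con$coronal)) NULL else con$coronal$value,
                          lam)
  list(params = params, vel = vel, bundle = bundle)
}

#' Train one model on a set of exams
#'
#' Minimizes the knowledge-based loss with SGD (momentum, polynomial
#' learning-rate decay) for `cfg$epochs` epochs. Training supervision uses
#' only the axial masks for the KB model; the `"baseline"` (fully
#' supervised multi-planar reference) additionally supervises weight-tied
#' auxiliary decodings of the sagittal/coronal passes with per-view masks
#' and uses `lambda = 0`.
#'
#' @param exams list of `mp_exam` objects (each with an axial mask).
#' @param cfg an [mpkb_config()].
#' @param fold_idx fold index (seeds the initialization/batching substream).
#' @param seed run seed.
#' @param model_type `"kb"` or `"baseline"`.
#' @param verbose print per-epoch losses.
#' @return An `mpkb_model` with a `history` data frame of per-epoch mean
#'   loss terms attached.
#' @export
train_fold <- function(exams, cfg, fold_idx = 1L, seed = cfg$seed,
                       model_type = c("kb", "baseline"), verbose = FALSE) {
  model_type <- match.arg(model_type)
  cfg_fold <- cfg
  if (model_type == "baseline") cfg_fold$lambda_contrastive <- 0
  cfg_fold$seed <- sub_seed(seed, sprintf("fold%d_init", fold_idx))
  model <- build_model(cfg_fold)
  params <- model$params
  vel <- lapply(params, function(p) list(w = p$w * 0, b = p$b * 0))
  data <- lapply(exams, prepare_exam, model_type = model_type)
  hist <- list()
  if (cfg$epochs > 0) {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate * (1 - (epoch - 1) / cfg$epochs)^cfg$lr_power
      terms <- with_seed(sub_seed(seed, sprintf("fold%d_epoch%d", fold_idx, epoch)), {
        ord <- sample(length(data))
        acc <- c(dice = 0, ce = 0, sag = 0, cor = 0, total = 0,
                 nsag = 0, ncor = 0)
        for (i in ord) {
          st <- train_step(params, cfg_fold, data[[i]], model_type, vel, lr)
          params <- st$params
          vel <- st$vel
          b <- st$bundle
          acc["dice"] <- acc["dice"] + b$dice_term
          acc["ce"] <- acc["ce"] + b$ce_term
          acc["total"] <- acc["total"] + b$total
          if (!is.na(b$contrastive_ax_sag)) {
            acc["sag"] <- acc["sag"] + b$contrastive_ax_sag
            acc["nsag"] <- acc["nsag"] + 1
          }
          if (!is.na(b$contrastive_ax_cor)) {
            acc["cor"] <- acc["cor"] + b$contrastive_ax_cor
            acc["ncor"] <- acc["ncor"] + 1
          }
        }
        acc
      })
      ne <- length(data)
      hist[[epoch]] <- data.frame(
        epoch = epoch, lr = lr,
        dice_term = terms["dice"] / ne, ce_term = terms["ce"] / ne,
        contrastive_ax_sag = if (terms["nsag"] > 0) terms["sag"] / terms["nsag"] else NA,
        contrastive_ax_cor = if (terms["ncor"] > 0) terms["cor"] / terms["ncor"] else NA,
        total = terms["total"] / ne, row.names = NULL)
      if (verbose) {
        message(sprintf("fold %d epoch %3d: total %.4f dice %.4f ce %.4f",
                        fold_idx, epoch, hist[[epoch]]$total,
                        hist[[epoch]]$dice_term, hist[[epoch]]$ce_term))
      }
    }
  }
  model$params <- params
  model$history <- if (length(hist)) do.call(rbind, hist) else NULL
  model$model_type <- model_type
  model
}

#' Fit a cross-validated multi-planar KB segmentation ensemble
#'
#' Assigns exams to folds reproducibly (exam-level partition, no slice
#' leakage), trains one model per fold on the complementary exams, and
#' returns the fold ensemble whose averaged probabilities drive prediction.
#'
#' @param exams list of `mp_exam` training exams (each with an axial mask).
#' @param cfg an [mpkb_config()].
#' @param seed run seed; all randomness (folds, initialization, batching)
#'   derives from it through named substreams.
#' @param model_type `"kb"` (axial-only supervision + contrastive
#'   alignment) or `"baseline"` (fully supervised multi-planar reference,
#'   `lambda = 0`).
#' @param verbose print per-epoch losses.
#' @return Object of class `mpkb` with members, fold assignments and
#'   training histories.
#' @export
mpkb_fit <- function(exams, cfg = mpkb_config(), seed = cfg$seed,
                     model_type = c("kb", "baseline"), verbose = FALSE) {
  stopifnot(inherits(cfg, "mpkb_config"))
  model_type <- match.arg(model_type)
  n <- length(exams)
  if (n < cfg$folds) {
    stopf("need at least %d exams for %d folds (got %d)", cfg$folds,
          cfg$folds, n)
  }
  ids <- vapply(exams, function(e) e$id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate exam ids")
  folds <- fold_assignments(ids, cfg$folds, seed)
  members <- vector("list", cfg$folds)
  history <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    train_set <- exams[folds[ids] != f]
    m <- train_fold(train_set, cfg, fold_idx = f, seed = seed,
                    model_type = model_type, verbose = verbose)
    members[[f]] <- m
    history[[f]] <- m$history
  }
  structure(list(members = members, cfg = cfg, fold_assignments = folds,
                 model_type = model_type, history = history, seed = seed),
            class = "mpkb")
}

# deterministic exam-level fold partition: permutation by seeded substream,
# then round-robin; depends only on the sorted id set, not input order
fold_assignments <- function(ids, folds, seed) {
  ids_sorted <- sort(ids)
  perm <- with_seed(sub_seed(seed, "folds"), sample(length(ids_sorted)))
  assign <- (seq_along(ids_sorted) %% folds) + 1L
  out <- integer(length(ids_sorted))
  out[perm] <- assign
  names(out) <- ids_sorted
  out
}

#' @export
print.mpkb <- function(x, ...) {
  cat(sprintf("<mpkb> %s model: %d-fold ensemble, %d params/member\n",
              x$model_type, x$cfg$folds, x$members[[1]]$n_params))
  cat(sprintf("  trained %d epochs, lambda = %.2f, latent dim %d\n",
              x$cfg$epochs,
              if (x$model_type == "kb") x$cfg$lambda_contrastive else 0,
              x$cfg$latent_dim))
  invisible(x)
}

#' @export
summary.mpkb <- function(object, ...) {
  print(object)
  h <- object$history[[1]]
  if (!is.null(h)) {
    cat("fold 1 loss history (first/last epoch):\n")
    print(h[c(1, nrow(h)), c("epoch", "dice_term", "ce_term", "total")],
          row.names = FALSE)
  }
  invisible(object)
}

# exam-level context latent: mean latent over the central 50% slices
context_latent <- function(member, vol3d, view) {
  nz <- dim(vol3d)[3]
  idx <- central_range(nz, 0.5)
  x <- slice_tensor(vol3d, idx)
  enc <- enc_forward(member$params, member$cfg, x)
  latent_features(matrix(colMeans(enc$z), 1), view)
}

#' Predict a segmentation mask for one exam
#'
#' Runs every fold member on all axial slices, conditioning the bottleneck
#' on the exam-level context latents of the views named in `scenario`,
#' averages the per-pixel probabilities over members, and thresholds at 0.5
#' to assemble a 3D mask on the exam's axial grid. Views present in the
#' exam but outside `scenario` are ignored.
#'
#' @param object a fitted [mpkb_fit()] ensemble.
#' @param exam an `mp_exam`.
#' @param scenario character vector of views to use (must contain
#'   `"axial"`), or `"full"` / `"axial_only"` shorthands.
#' @param ... unused.
#' @return A [seg_mask()] on the exam's axial grid.
#' @export
predict.mpkb <- function(object, exam, scenario = "full", ...) {
  views <- scenario_views(scenario)
  missing_views <- setdiff(views, names(exam$views))
  if (length(missing_views)) {
    stopf("scenario requests views the exam lacks: %s",
          paste(missing_views, collapse = ", "))
  }
  ax_vol <- normalize_intensity(exam$views$axial)
  nz <- dim(ax_vol$data)[3]
  xax <- slice_tensor(ax_vol$data, seq_len(nz))
  ctx_data <- lapply(setdiff(views, "axial"), function(vw) {
    list(view = vw, data = normalize_intensity(exam$views[[vw]])$data)
  })
  prob_sum <- 0
  for (member in object$members) {
    enc <- enc_forward(member$params, member$cfg, xax)
    lat <- list(latent_features(enc$z, "axial"))
    for (cd in ctx_data) {
      lat <- c(lat, list(context_latent(member, cd$data, cd$view)))
    }
    zf <- fuse_latents(lat)
    dec <- dec_forward(member$params, member$cfg, enc, zf)
    prob_sum <- prob_sum + dec$probs
  }
  probs <- prob_sum / length(object$members)
  dim(probs) <- dim(probs)[c(1, 2, 4)]
  grid <- exam$views$axial
  seg_mask((probs >= 0.5) * 1, grid$spacing, grid$origin, grid$axis_labels)
}

scenario_views <- function(scenario) {
  if (identical(scenario, "full")) return(c("axial", "sagittal", "coronal"))
  if (identical(scenario, "axial_only")) return("axial")
  views <- unique(as.character(scenario))
  bad <- setdiff(views, c("axial", "sagittal", "coronal"))
  if (length(bad)) stopf("unknown view in scenario: %s", paste(bad, collapse = ", "))
  if (!"axial" %in% views) stopf("scenario must contain the axial view")
  views
}

#' Ensemble prediction (module surface)
#'
#' Thin wrapper over [predict.mpkb()].
#'
#' @param ens a fitted [mpkb_fit()] ensemble.
#' @param exam an `mp_exam`.
#' @param scenario views available at inference (see [predict.mpkb()]).
#' @return A [seg_mask()] on the exam's axial grid.
#' @export
predict_ensemble <- function(ens, exam, scenario = "full") {
  predict(ens, exam, scenario = scenario)
}
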