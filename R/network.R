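# Internal forward/backward engine. Tensors are (H, W, C, B) arrays; the
# backward passes are hand-derived and accumulate parameter gradients into
# an environment keyed by parameter name, so the three weight-shared
# encoder passes of one step sum their gradients naturally.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# broadcast a B x C matrix over the spatial dims of a (H, W, C, B) tensor
broadcast_spatial <- function(m, H, W) {
  array(rep(as.vector(t(m)), each = H * W), c(H, W, ncol(m), nrow(m)))
}

grad_env <- function() new.env(parent = emptyenv())

acc_grad <- function(G, name, gw, gb) {
  if (is.null(G[[name]])) {
    G[[name]] <- list(w = gw, b = gb)
  } else {
    G[[name]]$w <- G[[name]]$w + gw
    G[[name]]$b <- G[[name]]$b + gb
  }
  invisible(NULL)
}

# ---- encoder ---------------------------------------------------------------

enc_forward <- function(params, cfg, x) {
  D <- cfg$encoder_depth
  levels <- vector("list", D)
  cur <- x
  for (l in seq_len(D)) {
    a1 <- relu(conv2d_fw_cpp(cur, params[[sprintf("enc%d_c1", l)]]$w,
                             params[[sprintf("enc%d_c1", l)]]$b))
    a2 <- relu(conv2d_fw_cpp(a1, params[[sprintf("enc%d_c2", l)]]$w,
                             params[[sprintf("enc%d_c2", l)]]$b))
    mp <- maxpool2_fw_cpp(a2)
    levels[[l]] <- list(input = cur, a1 = a1, a2 = a2, am = mp$argmax)
    cur <- mp$y
  }
  b1 <- relu(conv2d_fw_cpp(cur, params$bot_c1$w, params$bot_c1$b))
  b2 <- relu(conv2d_fw_cpp(b1, params$bot_c2$w, params$bot_c2$b))
  db <- dim(b2)
  g <- t(matrix(colMeans(matrix(b2, db[1] * db[2], db[3] * db[4])),
                db[3], db[4]))          # B x Cb
  z <- g %*% params$latent$w +
    matrix(params$latent$b, nrow(g), cfg$latent_dim, byrow = TRUE)
  list(levels = levels, pool_out = cur, b1 = b1, b2 = b2, g = g, z = z)
}

# g_b2: gradient on the deepest feature map (or NULL); gz: gradient on the
# projected latent (or NULL); g_skips: per-level extra gradients on the
# skip tensors a2 (or NULL), as produced by the decoder backward.
enc_backward <- function(params, cfg, cache, G, g_b2 = NULL, gz = NULL,
                         g_skips = NULL) {
  D <- cfg$encoder_depth
  b2 <- cache$b2
  db <- dim(b2)
  if (is.null(g_b2)) g_b2 <- array(0, db)
  if (!is.null(gz)) {
    acc_grad(G, "latent", t(cache$g) %*% gz, colSums(gz))
    gg <- gz %*% t(params$latent$w) / (db[1] * db[2])   # B x Cb
    g_b2 <- g_b2 + broadcast_spatial(gg, db[1], db[2])
  }
  g_pre <- g_b2 * (b2 > 0)
  bw <- conv2d_bw_cpp(cache$b1, params$bot_c2$w, g_pre)
  acc_grad(G, "bot_c2", bw$gw, bw$gb)
  g_pre <- bw$gx * (cache$b1 > 0)
  bw <- conv2d_bw_cpp(cache$pool_out, params$bot_c1$w, g_pre)
  acc_grad(G, "bot_c1", bw$gw, bw$gb)
  g_cur <- bw$gx
  for (l in rev(seq_len(D))) {
    lv <- cache$levels[[l]]
    da <- dim(lv$a2)
    g_a2 <- maxpool2_bw_cpp(g_cur, lv$am, da[1], da[2])
    if (!is.null(g_skips) && !is.null(g_skips[[l]])) {
      g_a2 <- g_a2 + g_skips[[l]]
    }
    g_pre <- g_a2 * (lv$a2 > 0)
    bw <- conv2d_bw_cpp(lv$a1, params[[sprintf("enc%d_c2", l)]]$w, g_pre)
    acc_grad(G, sprintf("enc%d_c2", l), bw$gw, bw$gb)
    g_pre <- bw$gx * (lv$a1 > 0)
    bw <- conv2d_bw_cpp(lv$input, params[[sprintf("enc%d_c1", l)]]$w, g_pre)
    acc_grad(G, sprintf("enc%d_c1", l), bw$gw, bw$gb)
    g_cur <- bw$gx
  }
  invisible(NULL)
}

# ---- fusion + decoder ------------------------------------------------------

dec_forward <- function(params, cfg, enc, zf) {
  D <- cfg$encoder_depth
  db <- dim(enc$b2)
  zmap <- broadcast_spatial(zf, db[1], db[2])
  fin <- concat_ch(enc$b2, zmap)
  f <- relu(conv2d_fw_cpp(fin, params$fuse$w, params$fuse$b))
  cur <- f
  steps <- vector("list", D)
  for (l in rev(seq_len(D))) {
    up <- upsample2_fw_cpp(cur)
    cat_in <- concat_ch(enc$levels[[l]]$a2, up)
    d1 <- relu(conv2d_fw_cpp(cat_in, params[[sprintf("dec%d_c1", l)]]$w,
                             params[[sprintf("dec%d_c1", l)]]$b))
    d2 <- relu(conv2d_fw_cpp(d1, params[[sprintf("dec%d_c2", l)]]$w,
                             params[[sprintf("dec%d_c2", l)]]$b))
    steps[[l]] <- list(pre_up_dim = dim(cur), cat_in = cat_in, d1 = d1, d2 = d2)
    cur <- d2
  }
  logits <- conv2d_fw_cpp(cur, params$final$w, params$final$b)
  probs <- 1 / (1 + exp(-logits))
  list(probs = probs, logits = logits, fin = fin, f = f, steps = steps)
}

# returns gradients wrt the deepest axial feature map, the fused latent and
# the per-level skip tensors; parameter gradients accumulate into G.
dec_backward <- function(params, cfg, enc, dec, glogits, G) {
  D <- cfg$encoder_depth
  top <- dec$steps[[1]]$d2
  bw <- conv2d_bw_cpp(top, params$final$w, glogits)
  acc_grad(G, "final", bw$gw, bw$gb)
  g_cur <- bw$gx
  g_skips <- vector("list", D)
  for (l in seq_len(D)) {
    st <- dec$steps[[l]]
    g_pre <- g_cur * (st$d2 > 0)
    bw <- conv2d_bw_cpp(st$d1, params[[sprintf("dec%d_c2", l)]]$w, g_pre)
    acc_grad(G, sprintf("dec%d_c2", l), bw$gw, bw$gb)
    g_pre <- bw$gx * (st$d1 > 0)
    bw <- conv2d_bw_cpp(st$cat_in, params[[sprintf("dec%d_c1", l)]]$w, g_pre)
    acc_grad(G, sprintf("dec%d_c1", l), bw$gw, bw$gb)
    g_cat <- bw$gx
    c_skip <- dim(enc$levels[[l]]$a2)[3]
    g_skips[[l]] <- g_cat[, , seq_len(c_skip), , drop = FALSE]
    g_up <- g_cat[, , c_skip + seq_len(dim(g_cat)[3] - c_skip), , drop = FALSE]
    g_cur <- upsample2_bw_cpp(g_up, st$pre_up_dim[1], st$pre_up_dim[2])
  }
  g_pre <- g_cur * (dec$f > 0)
  bw <- conv2d_bw_cpp(dec$fin, params$fuse$w, g_pre)
  acc_grad(G, "fuse", bw$gw, bw$gb)
  g_fin <- bw$gx
  cb <- dim(enc$b2)[3]
  g_b2 <- g_fin[, , seq_len(cb), , drop = FALSE]
  g_zmap <- g_fin[, , cb + seq_len(cfg$latent_dim), , drop = FALSE]
  dzm <- dim(g_zmap)
  g_zf <- t(matrix(colSums(matrix(g_zmap, dzm[1] * dzm[2], dzm[3] * dzm[4])),
                   dzm[3], dzm[4]))

  list(g_b2 = g_b2, g_zf = g_zf, g_skips = g_skips)
}

# ---- loss gradients --------------------------------------------------------

# gradient of dice + CE wrt logits, plus the loss terms
seg_loss_grad <- function(probs, target, eps) {
  p <- probs
  t <- target
  if (length(dim(p)) == 4L) dim(t) <- dim(p)
  sp <- sum(p); st <- sum(t); ip <- sum(p * t)
  denom <- sp + st + eps
  dice <- 1 - (2 * ip + eps) / denom
  dd_dp <- -(2 * t * denom - (2 * ip + eps)) / denom^2
  n <- length(p)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  ce <- -sum(t * log(pc) + (1 - t) * log(1 - pc)) / n
  glogits <- dd_dp * p * (1 - p) + (p - t) / n
  list(dice_term = dice, ce_term = ce, glogits = glogits)
}

# cosine alignment loss and gradients wrt both latent matrices (mean over rows)
cosine_loss_grad <- function(za, zo) {
  na <- sqrt(rowSums(za^2)); no <- sqrt(rowSums(zo^2))
  if (any(na == 0 | no == 0)) stopf("zero-norm latent in contrastive loss")
  B <- nrow(za)
  cosv <- rowSums(za * zo) / (na * no)
  ga <- -(zo / (na * no) - (cosv / na^2) * za) / B
  go <- -(za / (na * no) - (cosv / no^2) * zo) / B
  list(value = mean(1 - cosv), ga = ga, go = go)
}

# InfoNCE variant: latents of other exams in the batch act as negatives.
# Loss = -mean_i log( exp(c_ii/T) / sum_j exp(c_ij/T) ), c = cosine matrix.
infonce_loss_grad <- function(za, zo, temp) {
  B <- nrow(za)
  na <- sqrt(rowSums(za^2)); no <- sqrt(rowSums(zo^2))
  if (any(na == 0 | no == 0)) stopf("zero-norm latent in contrastive loss")
  ua <- za / na; uo <- zo / no
  C <- ua %*% t(uo)
  S <- exp(C / temp)
  P <- S / rowSums(S)
  value <- -mean(log(pmax(diag(P), 1e-12)))
  gC <- (P - diag(B)) / (temp * B)
  gua <- gC %*% uo
  guo <- t(gC) %*% ua
  ga <- (gua - ua * rowSums(gua * ua)) / na
  go <- (guo - uo * rowSums(guo * uo)) / no
  list(value = value, ga = ga, go = go)
}
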