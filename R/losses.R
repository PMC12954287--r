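# The knowledge-based training objective: Dice + binary cross-entropy
# segmentation loss plus weighted cosine-distance alignment terms between
# the axial latent and each orthogonal-view latent.

#' Dice and cross-entropy segmentation loss terms
#'
#' Soft foreground Dice loss `1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps)`
#' and mean binary cross-entropy over all pixels.
#'
#' @param probs predicted foreground probabilities in `[0, 1]`.
#' @param target binary reference of the same shape.
#' @param eps Dice smoothing constant.
#' @return List with `dice_term` and `ce_term` (both >= 0).
#' @export
dice_ce_loss <- function(probs, target, eps = 1e-5) {
  if (!identical(dim(probs), dim(target)) &&
      length(probs) != length(target)) {
    stopf("'probs' and 'target' shapes differ")
  }
  if (any(probs < 0 | probs > 1)) stopf("'probs' must lie in [0, 1]")
  p <- as.vector(probs); t <- as.vector(target)
  dice <- 1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  ce <- -mean(t * log(pc) + (1 - t) * log(1 - pc))
  list(dice_term = dice, ce_term = ce)
}

#' Cosine alignment (contrastive) loss between paired latents
#'
#' Mean over paired samples of `1 - cos(z_axial_i, z_other_i)`; range
#' `[0, 2]`, zero when the orthogonal-view representation already matches
#' the axial one, symmetric in its arguments and invariant to positive
#' rescaling of either latent.
#'
#' @param z_axial,z_other [latent_features()] objects or plain matrices with
#'   one latent vector per row; rows are paired by position (same exam).
#' @return Mean cosine distance in `[0, 2]`.
#' @export
cosine_alignment_loss <- function(z_axial, z_other) {
  A <- latent_matrix(z_axial)
  B <- latent_matrix(z_other)
  if (!identical(dim(A), dim(B))) stopf("latent matrices differ in shape")
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  bad <- which(na == 0 | nb == 0)
  if (length(bad)) {
    stopf("undefined cosine for zero-norm latent (pair %s)",
          paste(bad, collapse = ", "))
  }
  mean(1 - rowSums(A * B) / (na * nb))
}

latent_matrix <- function(z) {
  if (inherits(z, "latent_features")) return(z$vectors)
  if (is.matrix(z)) return(z)
  matrix(z, nrow = 1)
}

#' Assemble the knowledge-based total loss
#'
#' `total = dice + ce + lambda * (contrastive_ax_sag + contrastive_ax_cor)`,
#' with absent views contributing nothing (and not rescaling `lambda`).
#' `lambda = 0` recovers the plain segmentation loss. The default weight is
#' 0.25.
#'
#' @param seg_terms list with `dice_term` and `ce_term` (from
#'   [dice_ce_loss()]).
#' @param con_ax_sag,con_ax_cor cosine alignment terms, or `NULL` when the
#'   view is absent.
#' @param lambda contrastive weight (>= 0).
#' @return Object of class `kb_loss_bundle`: `dice_term`, `ce_term`,
#'   `contrastive_ax_sag`, `contrastive_ax_cor` (`NA` when absent), `total`.
#' @export
kb_total_loss <- function(seg_terms, con_ax_sag = NULL, con_ax_cor = NULL,
                          lambda = 0.25) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0) {
    stopf("'lambda' must be a non-negative scalar")
  }
  con_sum <- 0
  if (!is.null(con_ax_sag)) con_sum <- con_sum + con_ax_sag
  if (!is.null(con_ax_cor)) con_sum <- con_sum + con_ax_cor
  structure(
    list(dice_term = seg_terms$dice_term, ce_term = seg_terms$ce_term,
         contrastive_ax_sag = if (is.null(con_ax_sag)) NA_real_ else con_ax_sag,
         contrastive_ax_cor = if (is.null(con_ax_cor)) NA_real_ else con_ax_cor,
         lambda = lambda,
         total = seg_terms$dice_term + seg_terms$ce_term + lambda * con_sum),
    class = "kb_loss_bundle"
  )
}

#' @export
print.kb_loss_bundle <- function(x, ...) {
  cat(sprintf(
    "<kb_loss_bundle> total %.4f = dice %.4f + ce %.4f + %.2f * (ax-sag %s + ax-cor %s)\n",
    x$total, x$dice_term, x$ce_term, x$lambda,
    format(x$contrastive_ax_sag, digits = 4),
    format(x$contrastive_ax_cor, digits = 4)))
  invisible(x)
}
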