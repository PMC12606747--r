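# Training objectives: penalty-reduced focal losses for the center and
# keypoint heatmaps, an L1 loss on the summed two-hop offsets, and their
# weighted total. The printed forms of the focal terms omit the
# conventional leading minus (which would make the loss negative); the
# standard negated loss is implemented. Natural log throughout;
# predictions are clamped to [1e-6, 1 - 1e-6] before logs.

#' Loss hyperparameters
#'
#' @param alpha,beta focal-loss exponents (defaults 2 and 4).
#' @param lambda_hm,lambda_hp,lambda_hm_hp branch weights (defaults all 1).
#' @return List of class `loss_config`.
#' @export
loss_config <- function(alpha = 2, beta = 4, lambda_hm = 1, lambda_hp = 1,
                        lambda_hm_hp = 1) {
  stopifnot(alpha > 0, beta > 0, lambda_hm >= 0, lambda_hp >= 0,
            lambda_hm_hp >= 0)
  structure(list(alpha = alpha, beta = beta, lambda_hm = lambda_hm,
                 lambda_hp = lambda_hp, lambda_hm_hp = lambda_hm_hp),
            class = "loss_config")
}

#' Penalty-reduced focal loss for the center heatmap
#'
#' `L = -(1/N) [ sum_{target=1} (1-p)^alpha log p
#'             + sum_{target<1} (1-target)^beta p^alpha log(1-p) ]`,
#' where `p` is the prediction and the `(1-target)^beta` factor
#' down-weights negatives inside the Gaussian neighborhood of a peak.
#'
#' @param pred predicted heatmap, values in `(0, 1)` (clamped internally).
#' @param target ground-truth heatmap (1 at peaks, Gaussian tails below 1).
#' @param n_pos number of positive cells `N`; 0 falls back to 1 with a
#'   warning.
#' @param cfg a [loss_config()].
#' @return Scalar loss, non-negative up to clamp epsilon.
#' @export
center_focal_loss <- function(pred, target, n_pos, cfg = loss_config()) {
  if (n_pos < 1) {
    warning("focal loss with n_pos = 0; dividing by 1")
    n_pos <- 1
  }
  focal_core(pred, target, n_pos, cfg$alpha, cfg$beta)$loss
}

#' Penalty-reduced focal loss for the keypoint heatmaps
#'
#' Identical functional form to [center_focal_loss()] applied over the K
#' keypoint channels, with `n_pos` the number of positive keypoint
#' samples.
#'
#' @inheritParams center_focal_loss
#' @export
keypoint_focal_loss <- function(pred, target, n_pos, cfg = loss_config()) {
  center_focal_loss(pred, target, n_pos, cfg)
}

#' L1 loss on the summed two-hop offsets
#'
#' Penalizes `|pred - target|` at masked entries only. `pred_off` is the
#' composed center-to-keypoint displacement (`off1` of the owning part
#' plus `off2` of the keypoint, gathered at ground-truth center cells), so
#' the loss depends only on the sum of the two hops. Normalized by the
#' number of masked keypoints by default; `normalize = FALSE` gives the
#' bare sum.
#'
#' @param pred_off,target_off M x 2K matrices (x, y interleaved per
#'   keypoint; rows are instances).
#' @param mask M x K matrix marking visible keypoints.
#' @param normalize divide by `sum(mask)` (default TRUE).
#' @return Scalar loss; 0 with a warning when the mask is empty.
#' @export
offset_l1_loss <- function(pred_off, target_off, mask, normalize = TRUE) {
  pred_off <- as.matrix(pred_off); target_off <- as.matrix(target_off)
  mask <- as.matrix(mask)
  stopifnot(ncol(pred_off) == 2L * ncol(mask),
            all(dim(pred_off) == dim(target_off)))
  n_vis <- sum(mask)
  if (n_vis == 0) {
    warning("offset loss with empty mask; returning 0")
    return(0)
  }
  mask2 <- mask[, rep(seq_len(ncol(mask)), each = 2L), drop = FALSE]
  tot <- sum(abs(pred_off - target_off) * mask2)
  if (normalize) tot / n_vis else tot
}

#' Weighted total training loss
#'
#' @param l_hm,l_hp,l_hm_hp the center-heatmap, offset-regression and
#'   keypoint-heatmap losses.
#' @param cfg a [loss_config()] carrying the branch weights.
#' @return `lambda_hm*l_hm + lambda_hp*l_hp + lambda_hm_hp*l_hm_hp`.
#' @export
total_loss <- function(l_hm, l_hp, l_hm_hp, cfg = loss_config()) {
  comps <- c(hm = l_hm, hp = l_hp, hm_hp = l_hm_hp)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad)) {
    stop("training abort: non-finite loss in branch ", paste(bad, collapse = ", "))
  }
  cfg$lambda_hm * l_hm + cfg$lambda_hp * l_hp + cfg$lambda_hm_hp * l_hm_hp
}
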