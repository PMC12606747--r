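# OKS computation and COCO-style AP/AP50/AP75/AR over detection sets.

#' Object keypoint similarity between a predicted and a ground-truth pose
#'
#' Mean over the ground truth's `v > 0` keypoints of
#' `exp(-d_i^2 / (2 s^2 k_i^2))`, with `d_i` the Euclidean error in input
#' pixels, `s` the ground-truth object scale and `k_i` the per-keypoint
#' constant from the schema.
#'
#' @param pred a `decoded_pose` or K x 2 keypoint matrix.
#' @param gt a [pose_instance()].
#' @param schema a [skeleton_schema()].
#' @return OKS in `[0, 1]`.
#' @export
oks <- function(pred, gt, schema) {
  kp_pred <- if (inherits(pred, "decoded_pose")) pred$keypoints else as.matrix(pred)
  kp_gt <- gt$keypoints
  vis <- kp_gt[, 3] > 0
  if (!any(vis)) stop("undefined OKS: ground truth has no v>0 keypoint")
  d2 <- (kp_pred[vis, 1] - kp_gt[vis, 1])^2 + (kp_pred[vis, 2] - kp_gt[vis, 2])^2
  k <- schema$keypoints$oks_k[vis]
  s <- gt$scale_s
  mean(exp(-d2 / (2 * s^2 * k^2)))
}

#' Greedy one-to-one matching of predictions to ground truth
#'
#' Predictions are visited in decreasing score order; each takes the
#' highest-OKS still-unmatched ground truth with OKS at least `threshold`.
#' Remaining predictions are false positives, remaining ground truths
#' false negatives.
#'
#' @param preds list of `decoded_pose` (any order; sorted internally).
#' @param gts list of [pose_instance()]; entries without visible keypoints
#'   are excluded.
#' @param schema a [skeleton_schema()].
#' @param threshold OKS threshold.
#' @return List: `order` (indices of preds by decreasing score), `tp`
#'   (logical per ordered pred), `matched_gt` (gt index or NA), `n_fn`.
#' @export
match_and_score <- function(preds, gts, schema, threshold) {
  gts <- Filter(function(g) any(g$keypoints[, 3] > 0), gts)
  scores <- vapply(preds, function(p) p$score, 0)
  ord <- order(-scores)
  matched <- logical(length(gts))
  tp <- logical(length(preds))
  mg <- rep(NA_integer_, length(preds))
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    best <- NA_integer_; best_oks <- threshold
    for (j in seq_along(gts)) {
      if (matched[j]) next
      o <- oks(preds[[i]], gts[[j]], schema)
      if (o >= best_oks) { best <- j; best_oks <- o }
    }
    if (!is.na(best)) { matched[best] <- TRUE; tp[ii] <- TRUE; mg[ii] <- best }
  }
  list(order = ord, tp = tp, matched_gt = mg, n_fn = sum(!matched))
}

#' COCO-style AP/AR evaluation over a detection set
#'
#' AP per OKS threshold uses score-ranked precision-recall with 101-point
#' interpolation; `ap` averages thresholds 0.50 to 0.95 (step 0.05), and
#' `ar` is the mean over the same thresholds of the recall at `max_det`
#' detections per image.
#'
#' @param all_preds list (per image) of lists of `decoded_pose`.
#' @param all_gts list (per image) of lists of [pose_instance()].
#' @param schema a [skeleton_schema()].
#' @param thresholds OKS thresholds (default `seq(0.5, 0.95, 0.05)`).
#' @param max_det detections kept per image (default 30).
#' @return List of class `eval_result`: `ap`, `ap50`, `ap75`, `ar`,
#'   `per_threshold` data.frame.
#' @export
evaluate_poses <- function(all_preds, all_gts, schema,
                           thresholds = seq(0.5, 0.95, by = 0.05),
                           max_det = 30L) {
  stopifnot(length(all_preds) == length(all_gts))
  n_gt <- sum(vapply(all_gts, function(g) {
    sum(vapply(g, function(x) any(x$keypoints[, 3] > 0), TRUE))
  }, 0))
  if (n_gt == 0L) stop("evaluation error: no ground-truth instances")
  all_preds <- lapply(all_preds, function(ps) {
    if (length(ps) <= max_det) return(ps)
    ps[order(-vapply(ps, function(p) p$score, 0))[seq_len(max_det)]]
  })
  per <- lapply(thresholds, function(thr) {
    scores <- numeric(0); tps <- logical(0)
    for (i in seq_along(all_preds)) {
      m <- match_and_score(all_preds[[i]], all_gts[[i]], schema, thr)
      s <- vapply(all_preds[[i]], function(p) p$score, 0)
      scores <- c(scores, s[m$order])
      tps <- c(tps, m$tp)
    }
    if (length(scores) == 0L) {
      return(data.frame(threshold = thr, ap = 0, recall = 0))
    }
    ord <- order(-scores)
    tp_cum <- cumsum(tps[ord]); fp_cum <- cumsum(!tps[ord])
    recall <- tp_cum / n_gt
    precision <- tp_cum / (tp_cum + fp_cum)
    rg <- seq(0, 1, by = 0.01)
    ap <- mean(vapply(rg, function(r) {
      sel <- recall >= r
      if (any(sel)) max(precision[sel]) else 0
    }, 0))
    data.frame(threshold = thr, ap = ap, recall = max(recall))
  })
  per <- do.call(rbind, per)
  at <- function(t) { i <- which(abs(per$threshold - t) < 1e-9)
                      if (length(i)) per$ap[i] else NA_real_ }
  structure(list(ap = mean(per$ap), ap50 = at(0.5), ap75 = at(0.75),
                 ar = mean(per$recall), per_threshold = per),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("AP %.3f  AP50 %.3f  AP75 %.3f  AR %.3f\n",
              x$ap, x$ap50, x$ap75, x$ar))
  invisible(x)
}
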