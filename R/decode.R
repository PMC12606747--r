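# Decoding network outputs into scored multi-instance poses: 3x3 local-max
# peak extraction on the center heatmap, two-hop offset composition at the
# center cell, and optional flip-test fusion at the pose level.

#' Find instance centers on a center heatmap
#'
#' Cells that are 3x3 local maxima (ties resolved toward the
#' smaller 0-based `(row, col)`), score at least `score_thresh`, top
#' `max_det` by score.
#'
#' @param center_heatmap h x w matrix in `[0, 1]`.
#' @param max_det maximum detections (default 30, above the densest
#'   supported scene).
#' @param score_thresh minimum peak value (default 0.05).
#' @return data.frame with 0-based `row`, `col` and `score`, ordered by
#'   decreasing score then `(row, col)`.
#' @export
find_centers <- function(center_heatmap, max_det = 30L, score_thresh = 0.05) {
  hm <- as.matrix(center_heatmap)
  h <- nrow(hm); w <- ncol(hm)
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- hm
  ismax <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ismax <- ismax & (hm >= pad[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx])
  }
  keep <- which(ismax & hm >= score_thresh, arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    return(data.frame(row = integer(), col = integer(), score = numeric()))
  }
  df <- data.frame(row = keep[, 1] - 1L, col = keep[, 2] - 1L,
                   score = hm[keep])
  df <- df[order(-df$score, df$row, df$col), , drop = FALSE]
  head(df, max_det)
}

#' Compose a pose from two-hop offsets at a center cell
#'
#' Keypoint `n`, owned by part `p`, lands at
#' `stride * (center + off1[p] + off2[n])` — the summed two-hop
#' displacement read at the center cell (the part-point shift is already
#' baked into the part features through the warped sampling; setting
#' `off2_at_part = TRUE` instead reads the second hop at the rounded
#' part-point cell).
#'
#' @param center_cell 0-based `(row, col)` of the center.
#' @param off1_field h x w x 2P array (x, y interleaved per part),
#'   output-stride units.
#' @param off2_field h x w x 2K array (x, y interleaved per keypoint).
#' @param schema a [skeleton_schema()].
#' @param stride output stride.
#' @param score detection score to attach.
#' @param off2_at_part read `off2` at the part-point cell instead of the
#'   center cell.
#' @return A `decoded_pose`: `keypoints` (K x 2, input px), `score`,
#'   `center` (input px).
#' @export
compose_pose <- function(center_cell, off1_field, off2_field, schema,
                         stride = 4L, score = 1, off2_at_part = FALSE) {
  cy <- center_cell[1]; cx <- center_cell[2]
  ri <- cy + 1L; ci <- cx + 1L
  K <- schema$n_keypoints
  kp <- matrix(0, K, 2L)
  h <- dim(off2_field)[1]; w <- dim(off2_field)[2]
  for (n in seq_len(K)) {
    p <- schema$part_of[n]
    o1x <- off1_field[ri, ci, 2L * p - 1L]; o1y <- off1_field[ri, ci, 2L * p]
    if (off2_at_part) {
      pr <- max(1L, min(h, round(cy + o1y) + 1L))
      pc <- max(1L, min(w, round(cx + o1x) + 1L))
      o2x <- off2_field[pr, pc, 2L * n - 1L]; o2y <- off2_field[pr, pc, 2L * n]
    } else {
      o2x <- off2_field[ri, ci, 2L * n - 1L]; o2y <- off2_field[ri, ci, 2L * n]
    }
    kp[n, ] <- stride * c(cx + o1x + o2x, cy + o1y + o2y)
  }
  structure(list(keypoints = kp, score = score,
                 center = stride * c(cx, cy)),
            class = "decoded_pose")
}

#' Decode network outputs into scored poses
#'
#' @param outputs list with `center_heatmap`, `off1_field`, `off2_field`
#'   (as produced by [model_forward()] or built from encoded targets).
#' @param schema a [skeleton_schema()].
#' @param stride output stride.
#' @param max_det,score_thresh peak selection, see [find_centers()].
#' @param off2_at_part see [compose_pose()].
#' @return List of `decoded_pose`.
#' @export
decode_poses <- function(outputs, schema, stride = 4L, max_det = 30L,
                         score_thresh = 0.05, off2_at_part = FALSE) {
  ctrs <- find_centers(outputs$center_heatmap, max_det, score_thresh)
  lapply(seq_len(nrow(ctrs)), function(i) {
    compose_pose(c(ctrs$row[i], ctrs$col[i]), outputs$off1_field,
                 outputs$off2_field, schema, stride, score = ctrs$score[i],
                 off2_at_part = off2_at_part)
  })
}

#' Fuse poses decoded from an image and its horizontal mirror
#'
#' Flipped poses are un-mirrored (`x -> image_w - 1 - x`), their keypoints
#' re-ordered by the bilateral permutation, then greedily matched to the
#' direct-pass poses by center distance (closest pairs first, up to
#' `max_dist`). Matched pairs average coordinates and scores; unmatched
#' poses from either pass survive unchanged.
#'
#' @param poses,poses_flipped lists of `decoded_pose` from the image and
#'   its mirror.
#' @param flip_perm permutation from [flip_permutation()].
#' @param image_w image width in pixels.
#' @param max_dist maximum center distance for a match (default 16 px).
#' @return List of `decoded_pose`.
#' @export
flip_fuse <- function(poses, poses_flipped, flip_perm, image_w,
                      max_dist = 16) {
  unflip <- lapply(poses_flipped, function(p) {
    kp <- p$keypoints
    kp[, 1] <- image_w - 1 - kp[, 1]
    p$keypoints <- kp[flip_perm, , drop = FALSE]
    p$center[1] <- image_w - 1 - p$center[1]
    p
  })
  if (length(unflip) == 0L) return(poses)
  if (length(poses) == 0L) return(unflip)
  na <- length(poses); nb <- length(unflip)
  d <- matrix(Inf, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    d[i, j] <- sqrt(sum((poses[[i]]$center - unflip[[j]]$center)^2))
  }
  used_a <- logical(na); used_b <- logical(nb)
  fused <- list()
  ord <- order(d)
  for (k in ord) {
    if (!is.finite(d[k]) || d[k] > max_dist) break
    i <- (k - 1L) %% na + 1L; j <- (k - 1L) %/% na + 1L
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    p <- poses[[i]]
    p$keypoints <- (poses[[i]]$keypoints + unflip[[j]]$keypoints) / 2
    p$score <- (poses[[i]]$score + unflip[[j]]$score) / 2
    p$center <- (poses[[i]]$center + unflip[[j]]$center) / 2
    fused[[length(fused) + 1L]] <- p
  }
  c(fused, poses[!used_a], unflip[!used_b])
}

# ideal network outputs reconstructed from encoded targets: the exact
# displacement goes into off2, off1 is zero (only the sum matters)
targets_to_outputs <- function(targets, schema) {
  h <- nrow(targets$center_heatmap); w <- ncol(targets$center_heatmap)
  P <- schema$n_parts; K <- schema$n_keypoints
  list(center_heatmap = targets$center_heatmap,
       off1_field = array(0, dim = c(h, w, 2L * P)),
       off2_field = targets$offset_targets)
}
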