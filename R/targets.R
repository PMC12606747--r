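# Training-target encoding: center heatmap, per-keypoint heatmaps, and
# center-to-keypoint offset fields with validity masks, all on the
# output-stride grid. Heatmap arrays are indexed [row, col, channel] with
# 0-based cell (row, col) = matrix index - 1.

#' Gaussian peak radius for a bounding box
#'
#' Radius (in output-grid pixels) such that a box shifted by it still
#' overlaps the original at least `iou_floor`; the penalty-reduced focal
#' loss assumes this Gaussian neighborhood around every positive. Uses the
#' standard corner/center-heatmap quadratic-root construction (three shift
#' cases, smallest root), clamped to at least 1 cell.
#'
#' @param bbox_h,bbox_w box height/width in output-grid pixels.
#' @param iou_floor minimum IoU preserved under the shift (default 0.3).
#' @return Radius, a positive scalar, monotone in box size.
#' @export
gaussian_radius <- function(bbox_h, bbox_w, iou_floor = 0.3) {
  stopifnot(bbox_h > 0, bbox_w > 0, iou_floor > 0, iou_floor < 1)
  h <- bbox_h; w <- bbox_w; o <- iou_floor
  b1 <- h + w; c1 <- w * h * (1 - o) / (1 + o)
  r1 <- (b1 + sqrt(b1^2 - 4 * c1)) / 2
  b2 <- 2 * (h + w); c2 <- (1 - o) * w * h
  r2 <- (b2 + sqrt(b2^2 - 4 * 4 * c2)) / (2 * 4)
  a3 <- 4 * o; b3 <- -2 * o * (h + w); c3 <- (o - 1) * w * h
  r3 <- (b3 + sqrt(b3^2 - 4 * a3 * c3)) / (2 * a3)
  max(min(r1, r2, r3), 1)
}

splat_gaussian <- function(hm, cx, cy, sigma) {
  h <- nrow(hm); w <- ncol(hm)
  r <- ceiling(3 * sigma)
  c0 <- max(1L, cx - r + 1L); c1 <- min(w, cx + r + 1L)
  r0 <- max(1L, cy - r + 1L); r1 <- min(h, cy + r + 1L)
  dy2 <- (((r0:r1) - 1L) - cy)^2
  dx2 <- (((c0:c1) - 1L) - cx)^2
  g <- exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
  hm[r0:r1, c0:c1] <- pmax(hm[r0:r1, c0:c1], g)
  hm
}

#' Encode instances into training targets
#'
#' Each instance with at least one visible keypoint writes an unnormalized
#' Gaussian peak (max-combined on overlap, exactly 1 at its quantized
#' center cell) on the center heatmap; every `v > 0` keypoint writes a
#' Gaussian on its own keypoint-heatmap channel; the offset channels at
#' the instance's center cell hold the center-to-keypoint displacement in
#' output-stride pixel units, with the mask marking exactly those entries.
#' When two instances share a quantized center cell the later one wins the
#' offset slot (collisions are counted in the result).
#'
#' @param instances list of [pose_instance()].
#' @param schema a [skeleton_schema()].
#' @param image_size `(H, W)` input pixels; `stride` must divide both.
#' @param stride output stride (default 4).
#' @param iou_floor Gaussian radius IoU floor (default 0.3); the Gaussian
#'   sigma is `radius / 3`.
#' @return List of class `training_targets`: `center_heatmap` (h x w),
#'   `keypoint_heatmaps` (h x w x K), `offset_targets` (h x w x 2K),
#'   `offset_mask` (h x w x K), `n_pos_centers`, `n_pos_keypoints`,
#'   `center_cells` (N x 2, 0-based row/col), `n_collisions`.
#' @export
encode_targets <- function(instances, schema, image_size, stride = 4L,
                           iou_floor = 0.3) {
  H <- image_size[1]; W <- image_size[2]
  if (H %% stride != 0 || W %% stride != 0) {
    stop("stride ", stride, " must divide the image size ", H, "x", W)
  }
  h <- H %/% stride; w <- W %/% stride
  K <- schema$n_keypoints
  center_hm <- matrix(0, h, w)
  kp_hm <- array(0, dim = c(h, w, K))
  off <- array(0, dim = c(h, w, 2L * K))
  mask <- array(0, dim = c(h, w, K))
  n_pos_centers <- 0L; n_pos_kp <- 0L; n_coll <- 0L
  cells <- matrix(NA_integer_, 0L, 2L)
  occupied <- matrix(FALSE, h, w)
  for (inst in instances) {
    kp <- inst$keypoints
    vis <- kp[, 3] > 0
    if (!any(vis)) {
      warning("skipping instance ", inst$instance_id, ": no visible keypoint")
      next
    }
    n_pos_centers <- n_pos_centers + 1L
    ctr <- inst$center / stride
    cx <- floor(ctr[1]); cy <- floor(ctr[2])
    cx <- max(0L, min(w - 1L, cx)); cy <- max(0L, min(h - 1L, cy))
    bw <- (max(kp[vis, 1]) - min(kp[vis, 1])) / stride
    bh <- (max(kp[vis, 2]) - min(kp[vis, 2])) / stride
    radius <- gaussian_radius(max(bh, 1e-3), max(bw, 1e-3), iou_floor)
    sigma <- radius / 3
    center_hm <- splat_gaussian(center_hm, cx, cy, sigma)
    center_hm[cy + 1L, cx + 1L] <- 1
    if (occupied[cy + 1L, cx + 1L]) {
      n_coll <- n_coll + 1L
      off[cy + 1L, cx + 1L, ] <- 0   # later instance wins the whole slot
      mask[cy + 1L, cx + 1L, ] <- 0
    }
    occupied[cy + 1L, cx + 1L] <- TRUE
    cells <- rbind(cells, c(cy, cx))
    for (n in which(vis)) {
      kx <- kp[n, 1] / stride; ky <- kp[n, 2] / stride
      off[cy + 1L, cx + 1L, 2L * n - 1L] <- kx - cx
      off[cy + 1L, cx + 1L, 2L * n] <- ky - cy
      mask[cy + 1L, cx + 1L, n] <- 1
      kcx <- max(0L, min(w - 1L, floor(kx)))
      kcy <- max(0L, min(h - 1L, floor(ky)))
      kp_hm[, , n] <- splat_gaussian(kp_hm[, , n], kcx, kcy, sigma)
      kp_hm[kcy + 1L, kcx + 1L, n] <- 1
      n_pos_kp <- n_pos_kp + 1L
    }
  }
  structure(list(center_heatmap = center_hm, keypoint_heatmaps = kp_hm,
                 offset_targets = off, offset_mask = mask,
                 n_pos_centers = n_pos_centers, n_pos_keypoints = n_pos_kp,
                 center_cells = cells, n_collisions = n_coll,
                 stride = stride, image_size = c(H, W)),
            class = "training_targets")
}
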