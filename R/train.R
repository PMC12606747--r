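# Training: augmentation, learning-rate schedules, the Adam loop over
# synthetic scenes, checkpointing, and inference with optional flip-test
# fusion.

#' Training configuration
#'
#' Defaults follow the benchmark protocol: Adam with initial learning rate
#' 1.25e-4 annealed cosine-wise to 1e-5, weight decay 1e-4, random
#' rotation in [-30, 30] degrees, scaling in [0.75, 1.5], translation in
#' [-40, 40] input pixels and horizontal flipping with probability 0.5.
#' Both the cosine schedule and the step schedule (decay x10 at epochs 90
#' and 120) are available.
#'
#' @param eta0,eta_min initial / minimum learning rate.
#' @param t_max total epochs.
#' @param batch_size gradient-accumulation batch.
#' @param input_size `(H, W)` training resolution.
#' @param seed master RNG seed for the run.
#' @param schedule `"cosine"` or `"step"`.
#' @param step_milestones epochs at which the step schedule divides the
#'   rate by 10.
#' @param augment list: `enabled`, `rot_deg`, `scale`, `translate_px`,
#'   `hflip_p`.
#' @param weight_decay L2 coefficient.
#' @param loss a [loss_config()].
#' @param eval_every evaluate AP on the training scenes every this many
#'   epochs (0 = off).
#' @param normalize_offsets divide the offset loss by the visible-keypoint
#'   count (FALSE restores the bare sum).
#' @return List of class `train_config`.
#' @export
train_config <- function(eta0 = 1.25e-4, eta_min = 1e-5, t_max = 140L,
                         batch_size = 16L, input_size = c(512L, 512L),
                         seed = 1L, schedule = c("cosine", "step"),
                         step_milestones = c(90L, 120L),
                         augment = list(enabled = TRUE,
                                        rot_deg = c(-30, 30),
                                        scale = c(0.75, 1.5),
                                        translate_px = c(-40, 40),
                                        hflip_p = 0.5),
                         weight_decay = 1e-4, loss = loss_config(),
                         eval_every = 0L, normalize_offsets = TRUE) {
  schedule <- match.arg(schedule)
  stopifnot(eta_min > 0, eta_min < eta0, t_max >= 1L)
  structure(list(eta0 = eta0, eta_min = eta_min, t_max = as.integer(t_max),
                 batch_size = as.integer(batch_size),
                 input_size = as.integer(input_size), seed = as.integer(seed),
                 schedule = schedule, step_milestones = step_milestones,
                 augment = augment, weight_decay = weight_decay,
                 loss = loss, eval_every = as.integer(eval_every),
                 normalize_offsets = normalize_offsets),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `eta_t = eta_min + (eta0 - eta_min)/2 * (1 + cos(pi * t_cur / t_max))`.
#'
#' @param t_cur current epoch, `0 <= t_cur <= t_max` (values beyond
#'   `t_max` clamp to `eta_min` with a warning).
#' @param cfg a [train_config()].
#' @return Learning rate.
#' @export
cosine_lr <- function(t_cur, cfg = train_config()) {
  if (t_cur > cfg$t_max) {
    warning("t_cur beyond t_max; clamping to eta_min")
    return(cfg$eta_min)
  }
  cfg$eta_min + 0.5 * (cfg$eta0 - cfg$eta_min) * (1 + cos(t_cur / cfg$t_max * pi))
}

#' Step-decay learning rate
#'
#' Divides `eta0` by 10 at each milestone epoch.
#'
#' @inheritParams cosine_lr
#' @export
step_lr <- function(t_cur, cfg = train_config()) {
  cfg$eta0 * 0.1^sum(t_cur >= cfg$step_milestones)
}

#' Random affine + flip augmentation of one annotated image
#'
#' Draws rotation, isotropic scale, translation and an optional horizontal
#' flip from the configured ranges (using the current RNG state), applies
#' the same transform to the image (bilinear, out-of-frame filled with
#' the image mean) and to every keypoint. The flip also re-orders
#' keypoints by the bilateral permutation. Keypoints pushed out of frame
#' get `v = 0`.
#'
#' @param image H x W x 3 array.
#' @param instances list of [pose_instance()].
#' @param schema a [skeleton_schema()].
#' @param augment ranges, see [train_config()].
#' @param draw optional fixed draw
#'   `list(rot_deg=, scale=, translate=, flip=)` overriding randomness.
#' @return List `(image, instances)`.
#' @export
augment_sample <- function(image, instances, schema,
                           augment = train_config()$augment, draw = NULL) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (is.null(draw)) {
    draw <- list(rot_deg = runif(1, augment$rot_deg[1], augment$rot_deg[2]),
                 scale = runif(1, augment$scale[1], augment$scale[2]),
                 translate = c(runif(1, augment$translate_px[1], augment$translate_px[2]),
                               runif(1, augment$translate_px[1], augment$translate_px[2])),
                 flip = runif(1) < (augment$hflip_p %||% 0))
  }
  ang <- draw$rot_deg * pi / 180
  s <- draw$scale; tr <- draw$translate
  cc <- c((W - 1) / 2, (H - 1) / 2)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  fwd <- function(p) {
    p <- matrix(p, ncol = 2L)
    if (draw$flip) p[, 1] <- W - 1 - p[, 1]
    sweep(s * t(R %*% t(sweep(p, 2L, cc))), 2L, cc + tr, "+")
  }
  # inverse map for image warping
  gx <- rep(0:(W - 1L), each = H); gy <- rep(0:(H - 1L), times = W)
  q <- cbind(gx, gy)
  qc <- sweep(q, 2L, cc + tr)
  src <- sweep(t(t(R) %*% t(qc)) / s, 2L, cc, "+")
  if (draw$flip) src[, 1] <- W - 1 - src[, 1]
  outside <- src[, 1] < 0 | src[, 1] > W - 1 | src[, 2] < 0 | src[, 2] > H - 1
  fill <- mean(image)
  img2 <- array(0, dim = dim(image))
  for (ch in seq_len(dim(image)[3])) {
    v <- cpp_grid_sample_fw(array(image[, , ch], dim = c(H, W, 1L)),
                            src[, 1], src[, 2])
    v[outside] <- fill
    img2[, , ch] <- matrix(v, H, W)
  }
  perm <- flip_permutation(schema)
  inst2 <- lapply(instances, function(inst) {
    kp <- inst$keypoints
    if (draw$flip) kp <- kp[perm, , drop = FALSE]
    xy <- fwd(kp[, 1:2])
    v <- kp[, 3]
    oob <- xy[, 1] < 0 | xy[, 1] > W - 1 | xy[, 2] < 0 | xy[, 2] > H - 1
    v[oob] <- 0
    if (!any(v > 0)) return(NULL)
    pose_instance(cbind(xy, v), schema, inst$instance_id)
  })
  list(image = img2, instances = Filter(Negate(is.null), inst2))
}

# --- optimizer --------------------------------------------------------------

adam_step <- function(model, lr, weight_decay = 1e-4, gscale = 1,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- model$opt
  if (is.null(st$t)) { st$t <- 0L; st$m <- list(); st$v <- list() }
  st$t <- st$t + 1L
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad * gscale + weight_decay * p$val
    m <- (st$m[[nm]] %||% 0) * beta1 + (1 - beta1) * g
    v <- (st$v[[nm]] %||% 0) * beta2 + (1 - beta2) * g^2
    st$m[[nm]] <- m; st$v[[nm]] <- v
    p$val <- p$val - lr * (m / (1 - beta1^st$t)) /
      (sqrt(v / (1 - beta2^st$t)) + eps)
  }
  invisible(NULL)
}

# build the three branch losses for one sample on the current tape
sample_losses_ad <- function(model, fw, targets, cfg) {
  schema <- model$schema
  h <- fw$h; w <- fw$w; N <- h * w
  K <- schema$n_keypoints; P <- schema$n_parts
  l_hm <- ad_focal(fw$center,
                   array(targets$center_heatmap, dim = c(h, w, 1L)),
                   max(targets$n_pos_centers, 1L),
                   cfg$loss$alpha, cfg$loss$beta)
  l_kp <- ad_focal(fw$kp_hm, targets$keypoint_heatmaps,
                   max(targets$n_pos_keypoints, 1L),
                   cfg$loss$alpha, cfg$loss$beta)
  cells <- targets$center_cells
  M <- nrow(cells)
  if (M > 0L) {
    idx <- cells[, 1] + h * cells[, 2] + 1L     # column-major cell index
    targ <- matrix(0, M, 2L * K); msk <- matrix(0, M, K)
    for (m in seq_len(M)) {
      targ[m, ] <- targets$offset_targets[cells[m, 1] + 1L, cells[m, 2] + 1L, ]
      msk[m, ] <- targets$offset_mask[cells[m, 1] + 1L, cells[m, 2] + 1L, ]
    }
    colmap <- as.vector(vapply(seq_len(K), function(n) {
      p <- schema$part_of[n]; c(2L * p - 1L, 2L * p)
    }, integer(2L)))
    off1_rows <- ad_cols(ad_rows(ad_reshape(fw$off1, c(N, 2L * P)), idx), colmap)
    off2_rows <- ad_rows(fw$off2_mat, idx)
    pred <- ad_add(off1_rows, off2_rows)
    msk2 <- msk[, rep(seq_len(K), each = 2L), drop = FALSE]
    denom <- if (cfg$normalize_offsets) max(sum(msk), 1) else 1
    l_off <- ad_l1_masked(pred, targ, msk2, denom)
  } else {
    l_off <- ad_tensor(0)
  }
  list(hm = l_hm, hp = l_off, hm_hp = l_kp)
}

#' Train a pose model on annotated scenes
#'
#' Runs the full objective — penalty-reduced focal losses on the center
#' and keypoint heatmaps plus the L1 loss on the summed two-hop offsets —
#' with Adam, the configured learning-rate schedule, and optional
#' augmentation. All randomness derives from `cfg$seed`, so a `(scene
#' seed, train seed)` pair fully determines the run.
#'
#' @param cfg a [train_config()].
#' @param scenes list of `scene_sample` (e.g. [generate_scenes()]).
#' @param model optional warm-start [pose_model()].
#' @param model_cfg a [pose_model_config()] when building a fresh model.
#' @param verbose print per-epoch losses.
#' @return List of class `train_result`: `model`, `log` (per-epoch
#'   data.frame), `eval` (AP snapshots if `eval_every > 0`).
#' @export
train_pose_model <- function(cfg, scenes, model = NULL,
                             model_cfg = pose_model_config(),
                             verbose = FALSE) {
  schema <- load_schema(scenes[[1]]$metadata$config$species)
  if (is.null(model)) model <- pose_model(schema, model_cfg, seed = cfg$seed)
  stride <- model$config$stride
  set.seed(cfg$seed * 10007L %% 2147483L + 1L)
  dims <- dim(scenes[[1]]$image)
  aug_on <- isTRUE(cfg$augment$enabled)
  static_targets <- if (!aug_on) {
    lapply(scenes, function(s) {
      encode_targets(s$instances, schema, dim(s$image)[1:2], stride)
    })
  } else NULL
  log <- vector("list", cfg$t_max)
  evals <- list()
  nb <- 0L
  ad_zero_grads(model$params)
  for (epoch in seq_len(cfg$t_max)) {
    lr <- if (cfg$schedule == "cosine") cosine_lr(epoch - 1L, cfg) else
      step_lr(epoch - 1L, cfg)
    acc <- c(hm = 0, hp = 0, hm_hp = 0)
    for (si in seq_along(scenes)) {
      if (aug_on) {
        aug <- augment_sample(scenes[[si]]$image, scenes[[si]]$instances,
                              schema, cfg$augment)
        if (length(aug$instances) == 0L) next
        img <- aug$image
        targets <- encode_targets(aug$instances, schema, dims[1:2], stride)
      } else {
        img <- scenes[[si]]$image
        targets <- static_targets[[si]]
      }
      if (targets$n_pos_centers == 0L) next
      ad_begin()
      fw <- model_forward_ad(model, img, mode = "train")
      ls <- sample_losses_ad(model, fw, targets, cfg)
      vals <- c(hm = ad_val(ls$hm), hp = ad_val(ls$hp), hm_hp = ad_val(ls$hm_hp))
      total_loss(vals["hm"], vals["hp"], vals["hm_hp"], cfg$loss) # NaN guard
      tot <- ad_wsum(list(ls$hm, ls$hp, ls$hm_hp),
                     c(cfg$loss$lambda_hm, cfg$loss$lambda_hp,
                       cfg$loss$lambda_hm_hp))
      ad_backward(tot)
      acc <- acc + vals
      nb <- nb + 1L
      if (nb >= cfg$batch_size) {
        adam_step(model, lr, cfg$weight_decay, gscale = 1 / nb)
        ad_zero_grads(model$params)
        nb <- 0L
      }
    }
    if (nb > 0L) {
      adam_step(model, lr, cfg$weight_decay, gscale = 1 / nb)
      ad_zero_grads(model$params)
      nb <- 0L
    }
    log[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                               l_hm = acc["hm"] / length(scenes),
                               l_hp = acc["hp"] / length(scenes),
                               l_hm_hp = acc["hm_hp"] / length(scenes))
    if (verbose && (epoch %% 10L == 0L || epoch == 1L)) {
      message(sprintf("epoch %3d  lr %.2e  hm %.4f  hp %.4f  hm_hp %.4f",
                      epoch, lr, acc["hm"] / length(scenes),
                      acc["hp"] / length(scenes), acc["hm_hp"] / length(scenes)))
    }
    if (cfg$eval_every > 0L && epoch %% cfg$eval_every == 0L) {
      ev <- evaluate_on_scenes(model, scenes)
      evals[[length(evals) + 1L]] <- data.frame(epoch = epoch, ap = ev$ap,
                                                ap50 = ev$ap50, ar = ev$ar)
      if (verbose) message(sprintf("  eval: AP %.3f AP50 %.3f", ev$ap, ev$ap50))
    }
  }
  structure(list(model = model, log = do.call(rbind, log),
                 eval = if (length(evals)) do.call(rbind, evals) else NULL),
            class = "train_result")
}

#' Decode and evaluate a model on scenes
#'
#' @param model a [pose_model()].
#' @param scenes list of `scene_sample`.
#' @param ... passed to [decode_poses()].
#' @return An `eval_result`.
#' @export
evaluate_on_scenes <- function(model, scenes, ...) {
  preds <- lapply(scenes, function(s) {
    out <- model_forward(model, s$image, mode = "infer")
    decode_poses(out, model$schema, stride = model$config$stride, ...)
  })
  gts <- lapply(scenes, `[[`, "instances")
  evaluate_poses(preds, gts, model$schema)
}

# --- checkpointing ----------------------------------------------------------

#' Save / load a model checkpoint (weights + config echo)
#'
#' @param model a [pose_model()].
#' @param path file path.
#' @return `save_checkpoint` the path; `load_checkpoint` a [pose_model()].
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(schema_species = model$schema$species,
              schema = model$schema, config = model$config,
              weights = lapply(model$params, ad_val))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- pose_model(obj$schema, obj$config, seed = 0L)
  for (nm in names(obj$weights)) model$params[[nm]]$val <- obj$weights[[nm]]
  model
}

# --- inference --------------------------------------------------------------

resize_bilinear <- function(image, H2, W2) {
  H <- dim(image)[1]; W <- dim(image)[2]
  gx <- rep(0:(W2 - 1L), each = H2); gy <- rep(0:(H2 - 1L), times = W2)
  sx <- (gx + 0.5) * W / W2 - 0.5; sy <- (gy + 0.5) * H / H2 - 0.5
  out <- array(0, dim = c(H2, W2, dim(image)[3]))
  for (ch in seq_len(dim(image)[3])) {
    out[, , ch] <- matrix(cpp_grid_sample_fw(array(image[, , ch],
                                                   dim = c(H, W, 1L)),
                                             sx, sy), H2, W2)
  }
  out
}

pad_to_mult <- function(image, mult = 32L) {
  H <- dim(image)[1]; W <- dim(image)[2]
  H2 <- ceiling(H / mult) * mult; W2 <- ceiling(W / mult) * mult
  if (H2 == H && W2 == W) return(image)
  out <- array(mean(image), dim = c(H2, W2, dim(image)[3]))
  out[seq_len(H), seq_len(W), ] <- image
  out
}

#' Run inference on images
#'
#' Optionally resizes the short side (preserving aspect), pads to a
#' multiple of 32, forwards in inference mode (no keypoint-heatmap
#' branch), optionally fuses with the horizontally flipped pass, and
#' rescales poses to original image coordinates.
#'
#' @param model a [pose_model()].
#' @param images list of H x W x 3 arrays (or a single array).
#' @param flip enable flip-test fusion.
#' @param short_side resize target for the short side (NULL = keep size).
#' @param max_det,score_thresh decoding parameters.
#' @return List (per image) of lists of `decoded_pose`.
#' @export
infer_poses <- function(model, images, flip = FALSE, short_side = NULL,
                        max_det = 30L, score_thresh = 0.05) {
  if (!is.list(images)) images <- list(images)
  lapply(images, function(img) {
    H <- dim(img)[1]; W <- dim(img)[2]
    scale <- 1
    if (!is.null(short_side)) {
      scale <- short_side / min(H, W)
      img <- resize_bilinear(img, round(H * scale), round(W * scale))
    }
    img <- pad_to_mult(img)
    out <- model_forward(model, img, mode = "infer")
    poses <- decode_poses(out, model$schema, stride = model$config$stride,
                          max_det = max_det, score_thresh = score_thresh)
    if (flip) {
      mimg <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
      mout <- model_forward(model, mimg, mode = "infer")
      mposes <- decode_poses(mout, model$schema, stride = model$config$stride,
                             max_det = max_det, score_thresh = score_thresh)
      poses <- flip_fuse(poses, mposes, flip_permutation(model$schema),
                         dim(img)[2])
    }
    lapply(poses, function(p) {
      p$keypoints <- p$keypoints / scale
      p$center <- p$center / scale
      p
    })
  })
}

#' Overlay decoded poses on an image
#'
#' Draws keypoint dots and skeleton connections; optionally writes a PNG.
#'
#' @param image H x W x 3 array.
#' @param poses list of `decoded_pose`.
#' @param schema a [skeleton_schema()].
#' @param path optional output PNG path.
#' @return The annotated image array, invisibly if written.
#' @export
render_poses <- function(image, poses, schema, path = NULL) {
  img <- image
  H <- dim(img)[1]; W <- dim(img)[2]
  put_disc <- function(img, x, y, r, col) {
    m <- stamp_mask(matrix(FALSE, H, W), x, y, r)
    for (ch in 1:3) { v <- img[, , ch]; v[m] <- col[ch]; img[, , ch] <- v }
    img
  }
  for (p in poses) {
    if (!is.null(schema$skeleton_edges)) {
      for (e in seq_len(nrow(schema$skeleton_edges))) {
        a <- p$keypoints[schema$skeleton_edges[e, 1], ]
        b <- p$keypoints[schema$skeleton_edges[e, 2], ]
        n <- max(2L, ceiling(sqrt(sum((a - b)^2))))
        xs <- seq(a[1], b[1], length.out = n); ys <- seq(a[2], b[2], length.out = n)
        m <- stamp_mask(matrix(FALSE, H, W), xs, ys, rep(0.8, n))
        for (ch in 1:3) { v <- img[, , ch]; v[m] <- c(1, 1, 1)[ch]; img[, , ch] <- v }
      }
    }
    for (n in seq_len(nrow(p$keypoints))) {
      img <- put_disc(img, p$keypoints[n, 1], p$keypoints[n, 2], 1.6,
                      c(0.9, 0.15, 0.15))
    }
  }
  img <- pmin(pmax(img, 0), 1)
  if (!is.null(path)) { png::writePNG(img, path); return(invisible(img)) }
  img
}
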