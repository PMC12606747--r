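# Independent reference implementations used only to cross-check the
# package: central-difference gradients, a nested-loop bilinear sampler /
# multi-scale fusion, and a from-scratch OKS-matching AP evaluator.

num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# scalar bilinear lookup with border clamping, written longhand
bilinear_ref <- function(f, x, y, ch) {
  H <- dim(f)[1]; W <- dim(f)[2]
  x <- min(max(x, 0), W - 1); y <- min(max(y, 0), H - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- min(x0 + 1, W - 1); y1 <- min(y0 + 1, H - 1)
  wx <- x - x0; wy <- y - y0
  (1 - wy) * ((1 - wx) * f[y0 + 1, x0 + 1, ch] + wx * f[y0 + 1, x1 + 1, ch]) +
    wy * ((1 - wx) * f[y1 + 1, x0 + 1, ch] + wx * f[y1 + 1, x1 + 1, ch])
}

# nested-loop reference for multi-scale sampling + softmax-weighted fusion
mfs_ref <- function(features, off1_field, levels, weights, base = 4) {
  d <- dim(off1_field); h <- d[1]; w <- d[2]; P <- d[3] / 2
  C <- dim(features[[as.character(base)]])[3]
  out <- array(0, dim = c(h, w, P, C))
  for (p in seq_len(P)) {
    a <- exp(weights[p, ] - max(weights[p, ])); a <- a / sum(a)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      x <- (j - 1) + off1_field[i, j, 2 * p - 1]
      y <- (i - 1) + off1_field[i, j, 2 * p]
      for (ch in seq_len(C)) {
        acc <- 0
        for (li in seq_along(levels)) {
          s <- levels[li]
          if (s == base) { xs <- x; ys <- y } else {
            xs <- (x + 0.5) * base / s - 0.5; ys <- (y + 0.5) * base / s - 0.5
          }
          acc <- acc + a[li] * bilinear_ref(features[[as.character(s)]], xs, ys, ch)
        }
        out[i, j, p, ch] <- acc
      }
    }
  }
  out
}

oks_ref <- function(kp_pred, gt_kp, s, k) {
  vis <- gt_kp[, 3] > 0
  d2 <- (kp_pred[vis, 1] - gt_kp[vis, 1])^2 + (kp_pred[vis, 2] - gt_kp[vis, 2])^2
  mean(exp(-d2 / (2 * s^2 * k[vis]^2)))
}

# from-scratch AP/AR over detection fixtures (lists of plain matrices),
# COCO protocol: per-image greedy matching, global score ranking,
# 101-point interpolated AP
eval_ref <- function(pred_sets, gt_sets, k, thresholds = seq(0.5, 0.95, 0.05),
                     max_det = 30) {
  n_gt <- sum(vapply(gt_sets, length, 1L))
  aps <- numeric(0); recalls <- numeric(0)
  for (thr in thresholds) {
    recs <- list()
    for (ii in seq_along(pred_sets)) {
      preds <- pred_sets[[ii]]; gts <- gt_sets[[ii]]
      if (length(preds) > max_det) {
        preds <- preds[order(-vapply(preds, `[[`, 0, "score"))[1:max_det]]
      }
      taken <- logical(length(gts))
      for (p in preds[order(-vapply(preds, `[[`, 0, "score"))]) {
        o_best <- -1; j_best <- 0
        for (j in seq_along(gts)) {
          if (taken[j]) next
          o <- oks_ref(p$kp, gts[[j]]$kp, gts[[j]]$s, k)
          if (o >= thr && o > o_best) { o_best <- o; j_best <- j }
        }
        hit <- j_best > 0
        if (hit) taken[j_best] <- TRUE
        recs[[length(recs) + 1]] <- c(score = p$score, tp = as.numeric(hit))
      }
    }
    if (length(recs) == 0) { aps <- c(aps, 0); recalls <- c(recalls, 0); next }
    m <- do.call(rbind, recs)
    m <- m[order(-m[, "score"]), , drop = FALSE]
    tp <- cumsum(m[, "tp"]); fp <- cumsum(1 - m[, "tp"])
    rec <- tp / n_gt; prec <- tp / (tp + fp)
    ap <- mean(sapply(seq(0, 1, 0.01), function(r) {
      sel <- rec >= r
      if (any(sel)) max(prec[sel]) else 0
    }))
    aps <- c(aps, ap); recalls <- c(recalls, max(rec))
  }
  list(ap = mean(aps), per = aps, ar = mean(recalls))
}

# random detection fixture on one "image": jittered copies of random GT
# poses plus spurious extras
random_fixture <- function(schema, n_img = 3, seed = 1) {
  set.seed(seed)
  K <- schema$n_keypoints
  pred_sets <- list(); gt_sets <- list()
  gt_poses <- list(); pred_poses <- list()
  for (i in seq_len(n_img)) {
    n <- sample(1:4, 1)
    gts_pkg <- list(); gts_ref <- list()
    preds_pkg <- list(); preds_ref <- list()
    for (j in seq_len(n)) {
      base <- matrix(runif(2 * K, 20, 200), K, 2)
      v <- sample(c(1, 2), K, replace = TRUE)
      gts_pkg[[j]] <- pose_instance(cbind(base, v), schema, j)
      gts_ref[[j]] <- list(kp = cbind(base, v), s = gts_pkg[[j]]$scale_s)
      if (runif(1) < 0.85) {  # jittered detection
        kp <- base + matrix(rnorm(2 * K, 0, runif(1, 0.5, 6)), K, 2)
        sc <- runif(1)
        preds_pkg[[length(preds_pkg) + 1]] <-
          structure(list(keypoints = kp, score = sc, center = colMeans(kp)),
                    class = "decoded_pose")
        preds_ref[[length(preds_ref) + 1]] <- list(kp = kp, score = sc)
      }
    }
    if (runif(1) < 0.5) {    # spurious detection
      kp <- matrix(runif(2 * K, 0, 220), K, 2)
      sc <- runif(1)
      preds_pkg[[length(preds_pkg) + 1]] <-
        structure(list(keypoints = kp, score = sc, center = colMeans(kp)),
                  class = "decoded_pose")
      preds_ref[[length(preds_ref) + 1]] <- list(kp = kp, score = sc)
    }
    gt_poses[[i]] <- gts_pkg; gt_sets[[i]] <- gts_ref
    pred_poses[[i]] <- preds_pkg; pred_sets[[i]] <- preds_ref
  }
  list(pred_pkg = pred_poses, gt_pkg = gt_poses,
       pred_ref = pred_sets, gt_ref = gt_sets)
}

tiny_model_config <- function(...) {
  pose_model_config(backbone_channels = 8L, stem_channels = 6L,
                    head_hidden = 8L, channels = 8L, sgl_ffn = 16L,
                    sgl_heads = 2L, ...)
}
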