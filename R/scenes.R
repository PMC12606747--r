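# Seeded synthetic multi-animal scenes with exact keypoint annotations.
# The generator emulates the imaging regime of dense behavioral recordings
# of small organisms: several visually similar, non-rigid individuals per
# frame, frequent body overlap and occlusion, and optional blur / glare /
# low-light degradations. Worm bodies are smooth random curves (including
# self-coiling), fish are a tapered body with an articulated tail, flies
# are body blobs with six legs and two wings.

#' Configuration for the synthetic scene generator
#'
#' Defaults define the study conditions the generator emulates: images the
#' size of the benchmark input resolution, species-typical instance counts
#' (1-4 worms or fish, 5-10 flies per frame), and a 50% chance per
#' instance that it may be placed overlapping earlier ones.
#'
#' @param species `"celegans"`, `"zebrafish"` or `"drosophila"`.
#' @param image_size `(H, W)` in pixels, at least 64 x 64.
#' @param n_instances integer range `c(lo, hi)`; drawn uniformly per scene.
#'   Defaults per species to the densities above.
#' @param occlusion_prob probability that an instance may overlap earlier
#'   instances; at 0 placement is strictly non-overlapping and every
#'   keypoint is fully visible.
#' @param blur_sigma Gaussian blur in pixels applied to the final image
#'   (0 = off).
#' @param glare_prob probability of adding a bright glare blob.
#' @param low_light intensity multiplier in (0, 1]; 1 = off.
#' @param background `"plain"` or `"textured"`.
#' @param seed integer; a scene index is combined with it so every scene
#'   has its own reproducible stream.
#' @param keep_masks keep per-instance foreground masks in the metadata
#'   (used by consistency checks; off by default to save memory).
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(species = "celegans", image_size = c(512L, 512L),
                         n_instances = NULL, occlusion_prob = 0.5,
                         blur_sigma = 0, glare_prob = 0, low_light = 1,
                         background = c("plain", "textured"), seed = 1L,
                         keep_masks = FALSE) {
  background <- match.arg(background)
  if (is.null(n_instances)) {
    n_instances <- switch(species,
      celegans = c(1L, 4L), zebrafish = c(1L, 4L), drosophila = c(5L, 10L),
      c(1L, 4L))
  }
  if (length(n_instances) == 1L) n_instances <- rep(n_instances, 2L)
  stopifnot(n_instances[1] >= 1L, all(image_size >= 64L),
            occlusion_prob >= 0, occlusion_prob <= 1, blur_sigma >= 0)
  structure(list(species = species, image_size = as.integer(image_size),
                 n_instances = as.integer(n_instances),
                 occlusion_prob = occlusion_prob, blur_sigma = blur_sigma,
                 glare_prob = glare_prob, low_light = low_light,
                 background = background, seed = as.integer(seed),
                 keep_masks = keep_masks),
            class = "scene_config")
}

# --- low-level raster helpers (0-based pixel-centered coordinates) ----------

stamp_mask <- function(mask, xs, ys, rs) {
  H <- nrow(mask); W <- ncol(mask)
  if (length(rs) == 1L) rs <- rep(rs, length(xs))
  for (k in seq_along(xs)) {
    r <- rs[k]; x <- xs[k]; y <- ys[k]
    c0 <- max(1L, floor(x - r) + 1L); c1 <- min(W, ceiling(x + r) + 1L)
    r0 <- max(1L, floor(y - r) + 1L); r1 <- min(H, ceiling(y + r) + 1L)
    if (c0 > c1 || r0 > r1) next
    dy2 <- (((r0:r1) - 1) - y)^2
    dx2 <- (((c0:c1) - 1) - x)^2
    mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | (outer(dy2, dx2, "+") <= r^2)
  }
  mask
}

# resample a polyline to n points equally spaced in arclength
resample_polyline <- function(pts, n) {
  d <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(d))
  tt <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, pts[, 1], xout = tt)$y,
        stats::approx(s, pts[, 2], xout = tt)$y)
}

polyline_at_frac <- function(pts, fracs) {
  d <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(d)); tot <- s[length(s)]
  cbind(stats::approx(s, pts[, 1], xout = fracs * tot)$y,
        stats::approx(s, pts[, 2], xout = fracs * tot)$y)
}

polyline_normals <- function(pts) {
  n <- nrow(pts)
  tang <- rbind(pts[2, ] - pts[1, ],
                pts[3:n, ] - pts[1:(n - 2), ],
                pts[n, ] - pts[n - 1, ])
  len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
  tang <- tang / len
  cbind(-tang[, 2], tang[, 1])
}

rot2 <- function(ang) matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)

gaussian_blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  kn <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-kn):kn)^2 / (2 * sigma^2)); k <- k / sum(k)
  blur1 <- function(x) { # along rows, replicate padding
    n <- nrow(x)
    pad <- x[c(rep(1L, kn), seq_len(n), rep(n, kn)), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + n - 1L), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(m))))
}

# --- species shape models ---------------------------------------------------
# each returns list(strokes = list of list(pts, radii, value),
#                   keypoints = K x 2 matrix) centered near the origin

worm_shape <- function(scale = 1) {
  len <- runif(1, 45, 75) * scale
  n <- 48L
  turn <- rnorm(1, 0, 2.2) / n            # net body turn; large -> coiling
  kcur <- turn + stats::filter(rnorm(n, 0, 0.10), 0.85, method = "recursive")
  th <- cumsum(as.numeric(kcur)) + runif(1, 0, 2 * pi)
  step <- len / n
  pts <- cbind(cumsum(cos(th)) * step, cumsum(sin(th)) * step)
  pts <- sweep(pts, 2L, colMeans(pts))
  dense <- resample_polyline(pts, max(40L, ceiling(len / 0.7)))
  tt <- seq(0, 1, length.out = nrow(dense))
  wmax <- runif(1, 2.6, 3.4) * scale
  radii <- pmax(wmax * (0.35 + 0.65 * sqrt(pmax(1 - (2 * tt - 1)^2, 0))), 1.2)
  kp <- polyline_at_frac(dense, c(0, 0.25, 0.5, 0.75, 1))
  list(strokes = list(list(pts = dense, radii = radii, value = runif(1, 0.22, 0.32))),
       keypoints = kp)
}

fish_shape <- function(scale = 1) {
  len <- runif(1, 90, 150) * scale
  n <- 60L
  th0 <- runif(1, 0, 2 * pi)
  bend <- runif(1, -1.1, 1.1)
  tt <- seq(0, 1, length.out = n)
  th <- th0 + bend * (tt - 0.5)
  step <- len / n
  pts <- cbind(cumsum(cos(th)) * step, cumsum(sin(th)) * step)
  pts <- sweep(pts, 2L, colMeans(pts))
  spine <- resample_polyline(pts, max(60L, ceiling(len / 0.7)))
  ts <- seq(0, 1, length.out = nrow(spine))
  body_w <- len * 0.15 * sin(pi * pmin(ts / 0.85, 1))^0.9
  fin_w <- ifelse(ts > 0.86, len * 0.08 * (ts - 0.86) / 0.14, 0)
  radii <- pmax(body_w, fin_w, 1.3)
  nrm <- polyline_normals(spine)
  at <- function(f) polyline_at_frac(spine, f)
  nrm_at <- function(f) nrm[pmax(1L, round(f * (nrow(spine) - 1)) + 1L), , drop = FALSE]
  wid_at <- function(f) radii[pmax(1L, round(f * (nrow(spine) - 1)) + 1L)]
  kp <- rbind(
    at(0),                                               # snout
    at(0.10) + nrm_at(0.10) * wid_at(0.10) * 0.6,        # head_left
    at(0.10) - nrm_at(0.10) * wid_at(0.10) * 0.6,        # head_right
    at(0.35) + nrm_at(0.35) * wid_at(0.35) * 0.7,        # dorsal_front
    at(0.58) + nrm_at(0.58) * wid_at(0.58) * 0.7,        # dorsal_rear
    at(0.35) - nrm_at(0.35) * wid_at(0.35) * 0.7,        # ventral_front
    at(0.58) - nrm_at(0.58) * wid_at(0.58) * 0.7,        # ventral_rear
    at(0.45),                                            # mid_body
    at(0.80),                                            # caudal_peduncle
    at(1))                                               # tail_tip
  list(strokes = list(list(pts = spine, radii = radii, value = runif(1, 0.26, 0.36))),
       keypoints = kp)
}

fly_shape <- function(scale = 1) {
  B <- runif(1, 36, 50) * scale
  th <- runif(1, 0, 2 * pi)
  ax <- c(cos(th), sin(th)); perp <- c(-ax[2], ax[1])
  ctr <- c(0, 0)
  p <- function(a, b) ctr + ax * a * B + perp * b * B
  seg <- function(from, to, n = 20L) cbind(seq(from[1], to[1], length.out = n),
                                           seq(from[2], to[2], length.out = n))
  body_v <- runif(1, 0.20, 0.30)
  strokes <- list()
  # wings first (drawn under the body), angled backward
  wings <- list()
  for (s in c(1, -1)) {
    wdir <- rot2(s * (pi - runif(1, 0.35, 0.55))) %*% ax  # back-out direction
    base <- p(-0.02, s * 0.07)
    tip <- base + as.numeric(wdir) * 0.55 * B
    pts <- seg(base, tip, 24L)
    tt <- seq(0, 1, length.out = nrow(pts))
    strokes[[length(strokes) + 1L]] <-
      list(pts = pts, radii = pmax(0.10 * B * sin(pi * tt)^0.7, 1.2),
           value = 0.62)
    wings[[if (s > 0) "left" else "right"]] <- list(base = base, tip = tip)
  }
  # legs: three per side with a bend at mid-length
  legs <- list()
  ang_front <- c(55, 95, 135) * pi / 180
  for (s in c(1, -1)) {
    for (li in 1:3) {
      root <- p(0.16 - 0.13 * (li - 1), s * 0.10)
      d1 <- as.numeric(rot2(s * ang_front[li]) %*% ax)
      joint <- root + d1 * 0.20 * B
      d2 <- as.numeric(rot2(s * 0.45) %*% d1)
      tip <- joint + d2 * 0.20 * B
      strokes[[length(strokes) + 1L]] <-
        list(pts = rbind(root, joint, tip), radii = 1.3, value = 0.35)
      legs[[paste0(c("front", "mid", "hind")[li], if (s > 0) "_l" else "_r")]] <-
        list(joint = joint, tip = tip)
    }
  }
  # head, thorax, abdomen blobs
  strokes[[length(strokes) + 1L]] <-
    list(pts = seg(p(0.34, 0), p(0.42, 0), 6L), radii = 0.11 * B, value = body_v)
  strokes[[length(strokes) + 1L]] <-
    list(pts = seg(p(0.00, 0), p(0.16, 0), 8L), radii = 0.14 * B, value = body_v)
  nab <- 16L
  abr <- seq(0.13, 0.05, length.out = nab) * B
  strokes[[length(strokes) + 1L]] <-
    list(pts = seg(p(-0.06, 0), p(-0.45, 0), nab), radii = abr, value = body_v)
  head_c <- p(0.38, 0); thx_c <- p(0.08, 0)
  kp <- rbind(
    head_c + ax * 0.09 * B,                       # proboscis
    head_c + as.numeric(rot2(0.7) %*% ax) * 0.09 * B,    # antenna_left
    head_c + as.numeric(rot2(-0.7) %*% ax) * 0.09 * B,   # antenna_right
    head_c + perp * 0.08 * B,                     # eye_left
    head_c - perp * 0.08 * B,                     # eye_right
    thx_c + ax * 0.05 * B,                        # notum
    thx_c - ax * 0.09 * B,                        # scutellum
    p(-0.10, 0), p(-0.27, 0), p(-0.44, 0),        # abdomen base/mid/tip
    wings$left$base, wings$left$tip,
    wings$right$base, wings$right$tip,
    legs$front_l$joint, legs$front_l$tip, legs$front_r$joint, legs$front_r$tip,
    legs$mid_l$joint, legs$mid_l$tip, legs$mid_r$joint, legs$mid_r$tip,
    legs$hind_l$joint, legs$hind_l$tip, legs$hind_r$joint, legs$hind_r$tip)
  list(strokes = strokes, keypoints = kp)
}

draw_instance <- function(shape, H, W) {
  mask <- matrix(FALSE, H, W)
  vals <- matrix(NA_real_, H, W)
  for (st in shape$strokes) {
    m <- matrix(FALSE, H, W)
    m <- stamp_mask(m, st$pts[, 1], st$pts[, 2],
                    if (length(st$radii) == 1L) rep(st$radii, nrow(st$pts)) else st$radii)
    vals[m] <- st$value
    mask <- mask | m
  }
  list(mask = mask, vals = vals)
}

# --- scene generation -------------------------------------------------------

#' Generate one synthetic multi-animal scene
#'
#' Renders `n` instances of the configured species onto a grayscale canvas
#' (replicated to 3 channels), records exact keypoint coordinates, and
#' derives COCO-style visibility: a keypoint of an earlier-drawn instance
#' whose 3-px neighborhood is covered at least 60% by later-drawn bodies is
#' marked occluded (`v = 1`); everything else on canvas is visible
#' (`v = 2`). Later instances occlude earlier ones. Each instance draws
#' from its own RNG substream, so adding instances never perturbs earlier
#' ones; the whole scene is a deterministic function of
#' `(cfg$seed, scene_index)`.
#'
#' @param cfg a [scene_config()].
#' @param scene_index integer; combined with `cfg$seed` for per-scene
#'   streams when generating a dataset.
#' @return A list of class `scene_sample`: `image` (H x W x 3 in `[0,1]`),
#'   `instances` (list of [pose_instance()]), `metadata` (config echo,
#'   per-instance overlap fraction, optionally masks).
#' @export
generate_scene <- function(cfg, scene_index = 0L) {
  schema <- load_schema(cfg$species)
  shape_fun <- switch(cfg$species,
    celegans = worm_shape, zebrafish = fish_shape, drosophila = fly_shape,
    stop("unknown species: ", cfg$species))
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  # animals are modeled at benchmark scale (512-px frames); shrink with the canvas
  sscale <- max(0.5, min(1, min(H, W) / 512))
  scene_seed <- (cfg$seed %% 1000003L) * 2011L + scene_index
  set.seed(scene_seed)
  n <- if (cfg$n_instances[1] == cfg$n_instances[2]) cfg$n_instances[1] else
    sample(cfg$n_instances[1]:cfg$n_instances[2], 1L)
  bg_level <- runif(1, 0.86, 0.94)
  img <- matrix(bg_level, H, W)
  if (cfg$background == "textured") {
    tex <- matrix(rnorm(ceiling(H / 16) * ceiling(W / 16), 0, 1),
                  ceiling(H / 16), ceiling(W / 16))
    tex <- gaussian_blur_mat(tex[rep(seq_len(nrow(tex)), each = 16)[1:H],
                                 rep(seq_len(ncol(tex)), each = 16)[1:W]], 8)
    img <- pmin(pmax(img + 0.05 * tex, 0), 1)
  }
  masks <- vector("list", n)
  kps <- vector("list", n)
  union_mask <- matrix(FALSE, H, W)
  margin <- 4
  for (i in seq_len(n)) {
    set.seed(scene_seed + 7919L * i)
    allow_overlap <- runif(1) < cfg$occlusion_prob
    placed <- FALSE
    for (try in 1:60) {
      shape <- shape_fun(sscale)
      ext <- apply(abs(shape$keypoints), 2L, max) + 8
      ext <- pmin(ext, c((W - 1) / 2 - margin, (H - 1) / 2 - margin))
      ctr <- c(runif(1, margin + ext[1], W - 1 - margin - ext[1]),
               runif(1, margin + ext[2], H - 1 - margin - ext[2]))
      shift <- function(m) sweep(m, 2L, ctr, "+")
      sh <- shape
      sh$keypoints <- shift(shape$keypoints)
      sh$strokes <- lapply(shape$strokes, function(st) { st$pts <- shift(st$pts); st })
      if (any(sh$keypoints[, 1] < 1 | sh$keypoints[, 1] > W - 2 |
              sh$keypoints[, 2] < 1 | sh$keypoints[, 2] > H - 2)) next
      dr <- draw_instance(sh, H, W)
      if (!allow_overlap && any(dr$mask & union_mask)) next
      masks[[i]] <- dr$mask
      kps[[i]] <- sh$keypoints
      img[dr$mask] <- dr$vals[dr$mask]
      union_mask <- union_mask | dr$mask
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("placement error: could not place instance ", i, " of ", n,
           " without overlap; reduce n_instances or raise occlusion_prob")
    }
  }
  # visibility: later-drawn bodies occlude earlier keypoints
  above <- matrix(FALSE, H, W)
  vflags <- vector("list", n)
  for (i in rev(seq_len(n))) {
    k <- kps[[i]]
    v <- rep(2L, nrow(k))
    if (i < n) {
      for (j in seq_len(nrow(k))) {
        if (disc_coverage(above, k[j, 1], k[j, 2], 3) >= 0.6) v[j] <- 1L
      }
    }
    vflags[[i]] <- v
    above <- above | masks[[i]]
  }
  overlap_frac <- vapply(seq_len(n), function(i) {
    later <- matrix(FALSE, H, W)
    if (i < n) for (j in (i + 1):n) later <- later | masks[[j]]
    m <- sum(masks[[i]])
    if (m == 0) 0 else sum(masks[[i]] & later) / m
  }, 0)
  # speckle + optional degradations
  set.seed(scene_seed + 999983L)
  img <- pmin(pmax(img + matrix(rnorm(H * W, 0, 0.012), H, W), 0), 1)
  if (cfg$blur_sigma > 0) img <- gaussian_blur_mat(img, cfg$blur_sigma)
  if (cfg$glare_prob > 0 && runif(1) < cfg$glare_prob) {
    gx <- runif(1, 0, W - 1); gy <- runif(1, 0, H - 1)
    gs <- runif(1, 0.08, 0.2) * min(H, W)
    d2 <- outer((seq_len(H) - 1 - gy)^2, (seq_len(W) - 1 - gx)^2, "+")
    img <- pmin(img + 0.5 * exp(-d2 / (2 * gs^2)), 1)
  }
  if (cfg$low_light < 1) img <- img * cfg$low_light
  instances <- lapply(seq_len(n), function(i) {
    pose_instance(cbind(kps[[i]], vflags[[i]]), schema, instance_id = i)
  })
  meta <- list(config = cfg, scene_index = scene_index, seed = scene_seed,
               overlap_fraction = overlap_frac)
  if (cfg$keep_masks) meta$masks <- masks
  structure(list(image = array(img, dim = c(H, W, 3L)),
                 instances = instances, metadata = meta),
            class = "scene_sample")
}

disc_coverage <- function(mask, x, y, r) {
  H <- nrow(mask); W <- ncol(mask)
  c0 <- max(1L, floor(x - r) + 1L); c1 <- min(W, ceiling(x + r) + 1L)
  r0 <- max(1L, floor(y - r) + 1L); r1 <- min(H, ceiling(y + r) + 1L)
  if (c0 > c1 || r0 > r1) return(0)
  dy2 <- (((r0:r1) - 1) - y)^2; dx2 <- (((c0:c1) - 1) - x)^2
  disc <- outer(dy2, dx2, "+") <= r^2
  if (!any(disc)) return(0)
  sum(mask[r0:r1, c0:c1] & disc) / sum(disc)
}

#' Generate a dataset of synthetic scenes
#'
#' @param cfg a [scene_config()].
#' @param n_images number of scenes; scene `i` uses stream
#'   `(cfg$seed, i)`.
#' @return List of `scene_sample`.
#' @export
generate_scenes <- function(cfg, n_images) {
  lapply(seq_len(n_images), function(i) generate_scene(cfg, scene_index = i))
}
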