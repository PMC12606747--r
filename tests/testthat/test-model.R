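sp <- asNamespace("structpose")

worm_model <- function(seed = 2) {
  pose_model(load_schema("celegans"), tiny_model_config(), seed = seed)
}

test_that("backbone produces a consistent, deterministic pyramid", {
  m <- worm_model()
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  f1 <- backbone_forward(m, img)
  f2 <- backbone_forward(m, img)
  expect_equal(dim(f1[["4"]]), c(32L, 32L, 8L))
  expect_equal(dim(f1[["8"]]), c(16L, 16L, 8L))
  expect_identical(f1, f2)
  expect_error(backbone_forward(m, array(0, c(100, 100, 3))), "shape error")
  m2 <- pose_model(load_schema("celegans"), tiny_model_config(), seed = 2)
  z <- array(0, c(64, 64, 3))
  expect_identical(backbone_forward(m, z), backbone_forward(m2, z))
})

test_that("part perception emits 2P offset channels per species", {
  m <- worm_model()
  f4 <- backbone_forward(m, array(0.5, c(64, 64, 3)))[["4"]]
  expect_equal(dim(part_perception(m, f4))[3], 10L)
  fly <- pose_model(load_schema("drosophila"), tiny_model_config(), seed = 1)
  f4f <- backbone_forward(fly, array(0.5, c(64, 64, 3)))[["4"]]
  expect_equal(dim(part_perception(fly, f4f))[3], 18L)
  # zeroed head weights collapse part points onto the centers
  m$params$pp2_w$val[] <- 0; m$params$pp2_b$val[] <- 0
  expect_true(all(part_perception(m, f4) == 0))
})

test_that("MFS equals direct lookup at zero offset and exact bilinear values", {
  set.seed(6)
  f4 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  off0 <- array(0, c(8, 8, 2 * 2))   # 2 parts
  out <- mfs_sample_fuse(list("4" = f4), off0,
                         list(levels = 4L, weights = matrix(0, 2, 1)))
  for (p in 1:2) expect_equal(out[, , p, ], f4, tolerance = 0)
  # linear ramp g(x, y) = x sampled at fractional offsets
  ramp <- array(rep(0:7, each = 8), c(8, 8, 1))
  off <- array(0, c(8, 8, 2)); off[, , 1] <- 0.5
  o <- mfs_sample_fuse(list("4" = ramp), off,
                       list(levels = 4L, weights = matrix(0, 1, 1)))
  expect_equal(o[3, 3, 1, 1], 2.5)
  expect_equal(o[5, 8, 1, 1], 7)      # border-clamped, never an error
})

test_that("MFS matches a nested-loop reference on 8x8 grids", {
  set.seed(7)
  feats <- list("4" = array(rnorm(8 * 8 * 3), c(8, 8, 3)),
                "8" = array(rnorm(4 * 4 * 3), c(4, 4, 3)))
  off1 <- array(rnorm(8 * 8 * 6, 0, 1.5), c(8, 8, 6))   # 3 parts
  wts <- matrix(rnorm(3 * 2), 3, 2)
  got <- mfs_sample_fuse(feats, off1, list(levels = c(4L, 8L), weights = wts))
  want <- mfs_ref(feats, off1, c(4, 8), wts)
  expect_lt(max(abs(got - want)), 1e-5)
})

test_that("the model's internal MFS agrees with the standalone module", {
  m <- worm_model()
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- model_forward(m, img, mode = "train")
  wts <- do.call(rbind, lapply(1:5, function(p) {
    sp$ad_val(m$params[[paste0("fuse_theta", p)]])
  }))
  standalone <- mfs_sample_fuse(out$transformed_levels, out$off1_field,
                                list(levels = c(4L, 8L), weights = wts))
  expect_lt(max(abs(standalone - out$part_features)), 1e-10)
})

test_that("SGL attention rows sum to one and cells are independent", {
  set.seed(8)
  cfg <- tiny_model_config()
  w <- sgl_init(5, 8, cfg, seed = 3)
  pf <- array(rnorm(4 * 4 * 5 * 8), c(4, 4, 5, 8))
  pf[2, 2, , ] <- pf[1, 1, , ]        # two cells share identical token sets
  out <- sgl_refine(pf, w, cfg)
  A <- attr(out, "attention")
  expect_equal(apply(A, c(1, 2), sum), matrix(1, 16, 5), tolerance = 1e-12)
  expect_equal(out[2, 2, , ], out[1, 1, , ], tolerance = 1e-12)
})

test_that("SGL with zeroed output projections is the identity", {
  cfg <- tiny_model_config()
  w <- sgl_init(5, 8, cfg, seed = 4)
  w$sgl1_wo$val[] <- 0; w$sgl1_bo$val[] <- 0
  w$sgl1_w2$val[] <- 0; w$sgl1_b2$val[] <- 0
  pf <- array(rnorm(3 * 3 * 5 * 8), c(3, 3, 5, 8))
  out <- sgl_refine(pf, w, cfg)
  expect_identical(as.vector(out), as.vector(pf))
})

test_that("SGL is part-permutation equivariant with permuted type embeddings", {
  set.seed(9)
  cfg <- tiny_model_config()
  w <- sgl_init(4, 8, cfg, seed = 5)
  pf <- array(rnorm(3 * 3 * 4 * 8), c(3, 3, 4, 8))
  out <- sgl_refine(pf, w, cfg)
  perm <- c(3, 1, 4, 2)
  w2 <- w
  w2$type_embed <- sp$ad_tensor(sp$ad_val(w$type_embed)[perm, ])
  out_p <- sgl_refine(pf[, , perm, , drop = FALSE], w2, cfg)
  expect_equal(out_p, out[, , perm, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("off2 channel count is 2K and ownership routing is structural", {
  m <- worm_model()
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- model_forward(m, img)
  expect_equal(dim(out$off2_field)[3], 10L)
  fly <- pose_model(load_schema("drosophila"), tiny_model_config(), seed = 1)
  expect_equal(dim(model_forward(fly, img)$off2_field)[3], 52L)
  # zeroing part p's refined features perturbs only p's keypoint channels
  set.seed(10)
  N <- 16L; P <- 5L
  tok <- matrix(rnorm(N * P * 8), N * P, 8)
  sp$ad_begin()
  base <- sp$ad_val(sp$off2_head_ad(m, sp$ad_tensor(tok, track = FALSE), N))
  for (p in 1:P) {
    tok2 <- tok
    tok2[seq(p, N * P, by = P), ] <- 0
    sp$ad_begin()
    alt <- sp$ad_val(sp$off2_head_ad(m, sp$ad_tensor(tok2, track = FALSE), N))
    changed <- which(colSums(abs(alt - base)) > 1e-12)
    kp_p <- m$schema$parts[[p]]$keypoint_indices
    own <- sort(as.vector(rbind(2L * kp_p - 1L, 2L * kp_p)))
    expect_true(all(changed %in% own))
    expect_true(length(changed) > 0)
  }
})

test_that("train and infer modes agree bit-for-bit on shared outputs", {
  m <- worm_model()
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  a <- model_forward(m, img, mode = "train")
  b <- model_forward(m, img, mode = "infer")
  expect_identical(a$center_heatmap, b$center_heatmap)
  expect_identical(a$off1_field, b$off1_field)
  expect_identical(a$off2_field, b$off2_field)
  expect_null(b$keypoint_heatmaps)
  expect_false(is.null(a$keypoint_heatmaps))
})

test_that("each loss branch back-propagates into the backbone", {
  sch <- load_schema("celegans")
  m <- worm_model()
  cfg <- scene_config("celegans", image_size = c(64, 64),
                      n_instances = c(2, 2), seed = 11)
  s <- generate_scene(cfg)
  tg <- encode_targets(s$instances, sch, c(64, 64), 4)
  tc <- train_config(t_max = 1L, augment = list(enabled = FALSE))
  for (branch in c("hm", "hp", "hm_hp")) {
    sp$ad_zero_grads(m$params)
    sp$ad_begin()
    fw <- sp$model_forward_ad(m, s$image, "train")
    ls <- sp$sample_losses_ad(m, fw, tg, tc)
    sp$ad_backward(ls[[branch]])
    gnorm <- sqrt(sum(m$params$stem1_w$grad^2))
    expect_gt(gnorm, 0)
  }
})

test_that("invalid head/schema combinations fail at construction", {
  expect_error(pose_model_config(channels = 10L, sgl_heads = 4L), "divisible")
  expect_error(pose_model_config(fuse_levels = c(8L, 16L)), "stride 4")
})
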