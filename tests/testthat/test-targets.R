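test_that("gaussian radius grows with box size and clamps at one cell", {
  expect_gte(gaussian_radius(20, 20), gaussian_radius(10, 10))
  expect_gte(gaussian_radius(10, 10), 1)
  expect_equal(gaussian_radius(1e-3, 1e-3), 1)
  # independent evaluation of the three quadratic roots at both sizes
  radius_ref <- function(h, w, o) {
    r1 <- ((h + w) + sqrt((h + w)^2 - 4 * (w * h * (1 - o) / (1 + o)))) / 2
    r2 <- (2 * (h + w) + sqrt(4 * (h + w)^2 - 16 * (1 - o) * w * h)) / 8
    r3 <- ((-2 * o * (h + w)) +
             sqrt(4 * o^2 * (h + w)^2 - 16 * o * (o - 1) * w * h)) / (8 * o)
    max(min(r1, r2, r3), 1)
  }
  expect_equal(gaussian_radius(10, 10, 0.7), radius_ref(10, 10, 0.7))
  expect_equal(gaussian_radius(100, 100, 0.7), radius_ref(100, 100, 0.7))
  expect_lt(gaussian_radius(10, 10, 0.7), gaussian_radius(100, 100, 0.7))
})

make_worm_inst <- function(kp_xy, v = 2, schema = load_schema("celegans"), id = 1L) {
  pose_instance(cbind(kp_xy, v), schema, id)
}

test_that("targets put a unit peak at the quantized center and exact offsets", {
  sch <- load_schema("celegans")
  kp <- matrix(c(32, 40, 36, 40, 40, 40, 44, 40, 48, 40), 5, 2, byrow = TRUE)
  inst <- make_worm_inst(kp)                      # centroid at (40, 40)
  tg <- encode_targets(list(inst), sch, c(80, 80), 4)
  expect_equal(tg$center_heatmap[11, 11], 1)      # cell (10, 10), 0-based
  expect_equal(tg$n_pos_centers, 1L)
  expect_equal(tg$n_pos_keypoints, 5L)
  # keypoint 5 at (48, 40): offset (48 - 40)/4 = +2, dy 0
  expect_equal(tg$offset_targets[11, 11, 9], 2)
  expect_equal(tg$offset_targets[11, 11, 10], 0)
  expect_true(all(tg$offset_mask[11, 11, ] == 1))
  expect_true(all(tg$center_heatmap >= 0 & tg$center_heatmap <= 1))
  expect_true(all(tg$keypoint_heatmaps >= 0 & tg$keypoint_heatmaps <= 1))
  expect_equal(sum(tg$center_heatmap == 1), 1L)
})

test_that("offset targets are zero wherever the mask is zero", {
  sch <- load_schema("zebrafish")
  cfg <- scene_config("zebrafish", image_size = c(160, 160),
                      n_instances = c(3, 3), occlusion_prob = 0.6, seed = 23)
  s <- generate_scene(cfg)
  tg <- encode_targets(s$instances, sch, c(160, 160), 4)
  mask2 <- tg$offset_mask[, , rep(seq_len(sch$n_keypoints), each = 2)]
  dim(mask2) <- dim(tg$offset_targets)
  expect_true(all(tg$offset_targets[mask2 == 0] == 0))
  expect_equal(sum(tg$center_heatmap == 1), tg$n_pos_centers - tg$n_collisions)
})

test_that("coincident centers keep the later instance at the shared cell", {
  sch <- load_schema("celegans")
  kp1 <- matrix(c(30, 40, 35, 40, 40, 40, 45, 40, 50, 40), 5, 2, byrow = TRUE)
  kp2 <- kp1; kp2[, 2] <- kp2[, 2] + 1            # same quantized center cell
  i1 <- make_worm_inst(kp1, id = 1L); i2 <- make_worm_inst(kp2, id = 2L)
  expect_equal(floor(i1$center / 4), floor(i2$center / 4))
  tg <- encode_targets(list(i1, i2), sch, c(80, 80), 4)
  expect_equal(tg$n_collisions, 1L)
  cy <- floor(i2$center[2] / 4); cx <- floor(i2$center[1] / 4)
  # the stored offset reproduces instance 2's keypoints, not instance 1's
  kx <- (cx + tg$offset_targets[cy + 1, cx + 1, 5]) * 4
  ky <- (cy + tg$offset_targets[cy + 1, cx + 1, 6]) * 4
  expect_equal(c(kx, ky), kp2[3, ], tolerance = 1e-9)
})

test_that("an instance with no visible keypoints is skipped with a warning", {
  sch <- load_schema("celegans")
  kp <- matrix(c(30, 40, 35, 40, 40, 40, 45, 40, 50, 40), 5, 2, byrow = TRUE)
  good <- make_worm_inst(kp, id = 1L)
  bad <- pose_instance(cbind(kp, 0), sch, 2L)
  expect_warning(tg <- encode_targets(list(good, bad), sch, c(80, 80), 4),
                 "no visible keypoint")
  expect_equal(tg$n_pos_centers, 1L)
  expect_error(encode_targets(list(good), sch, c(81, 81), 4), "divide")
})

test_that("ideal outputs decoded from targets recover the annotation", {
  sch <- load_schema("celegans")
  cfg <- scene_config("celegans", image_size = c(128, 128),
                      n_instances = c(2, 3), occlusion_prob = 0.4, seed = 31)
  for (i in 1:5) {
    s <- generate_scene(cfg, i)
    tg <- encode_targets(s$instances, sch, c(128, 128), 4)
    out <- structpose:::targets_to_outputs(tg, sch)
    poses <- decode_poses(out, sch, stride = 4)
    expect_equal(length(poses), tg$n_pos_centers - tg$n_collisions)
    for (inst in s$instances) {
      ctr_d <- vapply(poses, function(p) sum((p$center - (inst$center %/% 4) * 4)^2), 0)
      p <- poses[[which.min(ctr_d)]]
      vis <- inst$keypoints[, 3] > 0
      err <- sqrt(rowSums((p$keypoints[vis, , drop = FALSE] -
                           inst$keypoints[vis, 1:2, drop = FALSE])^2))
      expect_lt(max(err), 2 + 1e-9)               # stride/2 quantization bound
    }
  }
})
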