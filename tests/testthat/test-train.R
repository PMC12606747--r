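test_that("cosine schedule hits its endpoints and midpoint exactly", {
  cfg <- train_config(t_max = 140L)
  expect_identical(cosine_lr(0, cfg), 1.25e-4)
  expect_identical(cosine_lr(140, cfg), 1e-5)
  expect_equal(cosine_lr(70, cfg), 6.75e-5, tolerance = 1e-18)
  expect_warning(lr <- cosine_lr(141, cfg), "clamp")
  expect_equal(lr, 1e-5)
})

test_that("step schedule decays by 10 exactly at the milestone epochs", {
  cfg <- train_config(schedule = "step", step_milestones = c(90L, 120L))
  expect_equal(step_lr(89, cfg), 1.25e-4)
  expect_equal(step_lr(90, cfg), 1.25e-5)
  expect_equal(step_lr(119, cfg), 1.25e-5)
  expect_equal(step_lr(120, cfg), 1.25e-6)
})

test_that("identity augmentation draw leaves image and keypoints unchanged", {
  cfg <- scene_config("celegans", image_size = c(96, 96),
                      n_instances = c(2, 2), seed = 43)
  s <- generate_scene(cfg)
  sch <- load_schema("celegans")
  out <- augment_sample(s$image, s$instances, sch,
                        draw = list(rot_deg = 0, scale = 1,
                                    translate = c(0, 0), flip = FALSE))
  expect_equal(out$image, s$image, tolerance = 1e-12)
  expect_equal(out$instances[[1]]$keypoints, s$instances[[1]]$keypoints,
               tolerance = 1e-12)
})

test_that("a pure flip mirrors coordinates and swaps bilateral keypoints", {
  sch <- load_schema("zebrafish")
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))   # width 96
  kp <- cbind(matrix(runif(20, 10, 80), 10, 2), 2)
  kp[2, 1:2] <- c(10, 50)                          # head_left at x = 10
  inst <- pose_instance(kp, sch, 1L)
  out <- augment_sample(img, list(inst), sch,
                        draw = list(rot_deg = 0, scale = 1,
                                    translate = c(0, 0), flip = TRUE))
  kp2 <- out$instances[[1]]$keypoints
  # head_right (index 3) now carries the mirrored head_left coordinate
  expect_equal(kp2[3, 1], 96 - 1 - 10, tolerance = 1e-9)
  expect_equal(kp2[3, 2], 50, tolerance = 1e-9)
  expect_equal(out$image[, 1, 1], img[, 96, 1], tolerance = 1e-9)
  # width-100 mirror formula: x = 10 -> 89
  expect_equal((100 - 1) - 10, 89)
})

test_that("rotation moves keypoints by the exact rotation matrix", {
  sch <- load_schema("celegans")
  H <- 64; W <- 64
  img <- array(0.5, c(H, W, 3))
  cc <- c((W - 1) / 2, (H - 1) / 2)
  kp <- matrix(0, 5, 3); kp[, 3] <- 2
  kp[, 1] <- cc[1] + c(1, 5, -3, 0, 2); kp[, 2] <- cc[2] + c(0, 1, 2, -4, 2)
  inst <- pose_instance(kp, sch, 1L)
  out <- augment_sample(img, list(inst), sch,
                        draw = list(rot_deg = 90, scale = 1,
                                    translate = c(0, 0), flip = FALSE))
  got <- out$instances[[1]]$keypoints[, 1:2]
  rel <- sweep(kp[, 1:2], 2, cc)
  want <- sweep(cbind(-rel[, 2], rel[, 1]), 2, cc, "+")
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("augmentation keeps visible keypoints on the warped body", {
  sch <- load_schema("celegans")
  cfg <- scene_config("celegans", image_size = c(96, 96),
                      n_instances = c(1, 1), occlusion_prob = 0, seed = 47)
  s <- generate_scene(cfg)
  set.seed(3)
  for (rep in 1:5) {
    out <- augment_sample(s$image, s$instances, sch,
                          augment = list(rot_deg = c(-30, 30),
                                         scale = c(0.9, 1.3),
                                         translate_px = c(-10, 10),
                                         hflip_p = 0.5))
    fg <- out$image[, , 1] < 0.6     # worm body is dark on a light field
    for (inst in out$instances) {
      kp <- inst$keypoints
      for (n in which(kp[, 3] > 0)) {
        expect_gt(structpose:::disc_coverage(fg, kp[n, 1], kp[n, 2], 2), 0)
      }
    }
  }
})

test_that("short training runs are reproducible and logged", {
  scenes <- generate_scenes(scene_config("celegans", image_size = c(64, 64),
                                         n_instances = c(1, 2), seed = 51), 2)
  tc <- train_config(eta0 = 1e-3, t_max = 2L, batch_size = 2L, seed = 9L,
                     augment = list(enabled = FALSE))
  r1 <- train_pose_model(tc, scenes, model_cfg = tiny_model_config())
  r2 <- train_pose_model(tc, scenes, model_cfg = tiny_model_config())
  expect_identical(r1$log, r2$log)
  expect_equal(nrow(r1$log), 2L)
  expect_true(all(is.finite(as.matrix(r1$log))))
  expect_identical(lapply(r1$model$params, function(p) p$val),
                   lapply(r2$model$params, function(p) p$val))
})

test_that("checkpoints restore a model that predicts identically", {
  scenes <- generate_scenes(scene_config("celegans", image_size = c(64, 64),
                                         n_instances = c(1, 1), seed = 53), 1)
  tc <- train_config(eta0 = 1e-3, t_max = 1L, batch_size = 1L, seed = 4L,
                     augment = list(enabled = FALSE))
  r <- train_pose_model(tc, scenes, model_cfg = tiny_model_config())
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(r$model, path)
  m2 <- load_checkpoint(path)
  img <- scenes[[1]]$image
  expect_identical(model_forward(r$model, img)$off2_field,
                   model_forward(m2, img)$off2_field)
})

test_that("inference returns one pose group per image, deterministically", {
  sch <- load_schema("celegans")
  m <- pose_model(sch, tiny_model_config(), seed = 6)
  imgs <- lapply(1:3, function(i) {
    generate_scene(scene_config("celegans", image_size = c(64, 64),
                                n_instances = c(1, 1), seed = 60 + i))$image
  })
  out1 <- infer_poses(m, imgs, score_thresh = 0)
  out2 <- infer_poses(m, imgs, score_thresh = 0)
  expect_length(out1, 3L)
  expect_identical(out1, out2)
  # resizing path: short side 96 pads to a /32 grid and rescales back
  out3 <- infer_poses(m, imgs[1], short_side = 96, score_thresh = 0)
  expect_length(out3, 1L)
})
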