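test_that("scene generation is bit-deterministic given the seed", {
  cfg <- scene_config("celegans", image_size = c(128, 128),
                      n_instances = c(3, 3), seed = 7)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$image, s2$image)
  expect_identical(lapply(s1$instances, `[[`, "keypoints"),
                   lapply(s2$instances, `[[`, "keypoints"))
})

test_that("zero occlusion probability yields fully visible annotations", {
  cfg <- scene_config("celegans", image_size = c(160, 160),
                      n_instances = c(3, 3), occlusion_prob = 0, seed = 11)
  s <- generate_scene(cfg)
  for (inst in s$instances) expect_true(all(inst$keypoints[, 3] == 2))
  expect_true(all(s$metadata$overlap_fraction == 0))
})

test_that("dense fly scenes carry the full 26-triplet annotation per instance", {
  cfg <- scene_config("drosophila", image_size = c(256, 256),
                      n_instances = c(10, 10), occlusion_prob = 1, seed = 3)
  s <- generate_scene(cfg)
  expect_length(s$instances, 10L)
  for (inst in s$instances) {
    expect_equal(dim(inst$keypoints), c(26L, 3L))
    kp <- inst$keypoints
    vis <- kp[, 3] > 0
    expect_true(all(kp[vis, 1] >= 0 & kp[vis, 1] <= 255 &
                    kp[vis, 2] >= 0 & kp[vis, 2] <= 255))
  }
})

test_that("annotated keypoints land on rendered foreground", {
  for (sp in c("celegans", "zebrafish", "drosophila")) {
    cfg <- scene_config(sp, image_size = c(192, 192), occlusion_prob = 0.5,
                        seed = 29, keep_masks = TRUE)
    for (i in 1:5) {
      s <- generate_scene(cfg, scene_index = i)
      for (j in seq_along(s$instances)) {
        kp <- s$instances[[j]]$keypoints
        m <- s$metadata$masks[[j]]
        for (n in which(kp[, 3] == 2)) {
          expect_gt(structpose:::disc_coverage(m, kp[n, 1], kp[n, 2], 2), 0)
        }
      }
    }
  }
})

test_that("instance counts track the configured density", {
  cfg <- scene_config("celegans", image_size = c(128, 128),
                      n_instances = c(1, 4), occlusion_prob = 1, seed = 5)
  counts <- vapply(1:200, function(i) length(generate_scene(cfg, i)$instances), 1L)
  expect_lt(abs(mean(counts) - 2.5), 0.25)
})

test_that("impossible non-overlapping placement raises a placement error", {
  cfg <- scene_config("zebrafish", image_size = c(96, 96),
                      n_instances = c(12, 12), occlusion_prob = 0, seed = 2)
  expect_error(generate_scene(cfg), "placement error")
})

test_that("COCO write/read round-trips annotations", {
  dir <- withr::local_tempdir()
  cfg <- scene_config("celegans", image_size = c(128, 128),
                      n_instances = c(2, 2), occlusion_prob = 0.8, seed = 13)
  samples <- generate_scenes(cfg, 3)
  write_coco(samples, dir)
  back <- read_coco(file.path(dir, "annotations.json"))
  expect_length(back, 3L)
  expect_equal(sum(vapply(back, function(b) length(b$instances), 1L)), 6L)
  ids <- unlist(lapply(back, function(b) vapply(b$instances, `[[`, 1L, "instance_id")))
  expect_equal(anyDuplicated(ids), 0L)
  for (i in 1:3) {
    for (j in seq_along(samples[[i]]$instances)) {
      a <- samples[[i]]$instances[[j]]$keypoints
      b <- back[[i]]$instances[[j]]$keypoints
      expect_lt(max(abs(a[a[, 3] > 0, 1:2] - b[b[, 3] > 0, 1:2])), 0.011)
      expect_identical(a[, 3], b[, 3])
    }
  }
  img <- back[[1]]$load_image()
  expect_equal(dim(img), c(128L, 128L, 3L))
  expect_lt(max(abs(img - samples[[1]]$image)), 1 / 255)
})

test_that("a scene without instances still writes an image entry", {
  dir <- withr::local_tempdir()
  cfg <- scene_config("celegans", image_size = c(128, 128),
                      n_instances = c(1, 1), seed = 17)
  s <- generate_scene(cfg)
  s$instances <- list()
  write_coco(list(s), dir)
  back <- read_coco(file.path(dir, "annotations.json"))
  expect_length(back, 1L)
  expect_length(back[[1]]$instances, 0L)
})

test_that("malformed annotations are rejected with the offending id", {
  dir <- withr::local_tempdir()
  cfg <- scene_config("celegans", image_size = c(128, 128),
                      n_instances = c(1, 1), seed = 19)
  write_coco(generate_scenes(cfg, 1), dir)
  path <- file.path(dir, "annotations.json")
  raw <- jsonlite::read_json(path)
  raw$annotations[[1]]$keypoints <- raw$annotations[[1]]$keypoints[1:7]
  jsonlite::write_json(raw, path, auto_unbox = TRUE)
  expect_error(read_coco(path), "parse error.*annotation 1")
  raw$categories[[1]]$name <- "unknownbeast"
  jsonlite::write_json(raw, path, auto_unbox = TRUE)
  expect_error(read_coco(path), "schema-resolution")
})
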