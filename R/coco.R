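# COCO-keypoints JSON dialect: images / annotations (flat x,y,v triplets) /
# categories carrying the schema name. Coordinates are written with 2
# decimals, 0-based pixel-centered; visibility follows the COCO convention
# {0 absent, 1 labeled-occluded, 2 visible}.

#' Write scenes as a COCO-keypoints dataset
#'
#' Writes `annotations.json` plus one PNG per scene under `dir/images/`.
#' The result round-trips through [read_coco()] losslessly (coordinates to
#' 0.01 px, visibility exactly).
#'
#' @param samples list of `scene_sample` (from [generate_scene()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, the annotation file path.
#' @export
write_coco <- function(samples, dir) {
  stopifnot(length(samples) >= 1L)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("I/O error: cannot create directory ", dir)
  species <- unique(vapply(samples, function(s) s$metadata$config$species, ""))
  cats <- lapply(seq_along(species), function(ci) {
    sch <- load_schema(species[ci])
    list(id = ci, name = species[ci],
         keypoints = as.list(sch$keypoints$name),
         skeleton = if (is.null(sch$skeleton_edges)) list() else
           lapply(seq_len(nrow(sch$skeleton_edges)),
                  function(r) as.list(sch$skeleton_edges[r, ])),
         oks_k = as.list(sch$keypoints$oks_k))
  })
  images <- list(); annotations <- list(); ann_id <- 0L
  for (im_id in seq_along(samples)) {
    s <- samples[[im_id]]
    H <- dim(s$image)[1]; W <- dim(s$image)[2]
    fn <- sprintf("scene_%05d.png", im_id)
    png::writePNG(s$image, file.path(dir, "images", fn))
    images[[im_id]] <- list(id = im_id, file_name = fn, width = W, height = H)
    ci <- match(s$metadata$config$species, species)
    for (inst in s$instances) {
      ann_id <- ann_id + 1L
      kp <- inst$keypoints
      vis <- kp[, 3] > 0
      flat <- as.vector(t(cbind(round(kp[, 1], 2), round(kp[, 2], 2), kp[, 3])))
      flat[rep(!vis, each = 3) & rep(c(TRUE, TRUE, FALSE), nrow(kp))] <- 0
      bbox <- if (any(vis)) {
        c(min(kp[vis, 1]), min(kp[vis, 2]),
          max(kp[vis, 1]) - min(kp[vis, 1]), max(kp[vis, 2]) - min(kp[vis, 2]))
      } else c(0, 0, 0, 0)
      annotations[[ann_id]] <- list(
        id = ann_id, image_id = im_id, category_id = ci,
        keypoints = as.list(flat), num_keypoints = sum(vis),
        bbox = as.list(round(bbox, 2)), area = round(bbox[3] * bbox[4], 2),
        iscrowd = 0L)
    }
  }
  path <- file.path(dir, "annotations.json")
  jsonlite::write_json(list(images = images, annotations = annotations,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO-keypoints dataset
#'
#' Schemas are resolved from the category name (built-ins by name, or a
#' schema supplied explicitly). Images load lazily through the returned
#' `load_image()` closures.
#'
#' @param path path to the annotation JSON (images are searched in
#'   `images/` next to it).
#' @param schema optional [skeleton_schema()] overriding category
#'   resolution.
#' @return List of `scene_sample`-like records: `instances`,
#'   `load_image()`, `image_info`, `schema`.
#' @export
read_coco <- function(path, schema = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  img_dir <- file.path(dirname(path), "images")
  schemas <- list()
  for (cat in raw$categories) {
    schemas[[as.character(cat$id)]] <- if (!is.null(schema)) schema else {
      if (!cat$name %in% c("celegans", "zebrafish", "drosophila")) {
        stop("schema-resolution error: unknown category '", cat$name,
             "'; pass schema= explicitly")
      }
      load_schema(cat$name)
    }
  }
  by_img <- split(raw$annotations,
                  vapply(raw$annotations, function(a) a$image_id, 1))
  lapply(raw$images, function(im) {
    anns <- by_img[[as.character(im$id)]] %||% list()
    instances <- lapply(anns, function(a) {
      sch <- schemas[[as.character(a$category_id)]]
      if (is.null(sch)) stop("schema-resolution error: annotation ", a$id,
                             " references unknown category ", a$category_id)
      flat <- as.numeric(unlist(a$keypoints))
      if (length(flat) != 3L * sch$n_keypoints) {
        stop("parse error: annotation ", a$id, " has ", length(flat),
             " keypoint values, expected ", 3L * sch$n_keypoints)
      }
      kp <- matrix(flat, ncol = 3L, byrow = TRUE)
      pose_instance(kp, sch, instance_id = a$id)
    })
    fp <- file.path(img_dir, im$file_name)
    structure(list(
      instances = instances,
      image_info = list(id = im$id, file_name = im$file_name,
                        width = im$width, height = im$height),
      schema = schemas[[1]],
      load_image = local({ fp0 <- fp; function() {
        arr <- png::readPNG(fp0)
        if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), c(dim(arr), 3L))
        arr[, , 1:3, drop = FALSE]
      }})), class = "coco_record")
  })
}

#' Write decoded poses as COCO keypoint-results JSON
#'
#' One record per pose: `image_id`, `category_id`, flat `keypoints`
#' triplets (v fixed at 2) and the detection `score`.
#'
#' @param detections list (per image) of lists of `decoded_pose`.
#' @param image_ids integer ids parallel to `detections`.
#' @param path output file.
#' @param category_id category of the poses.
#' @return Invisibly, `path`.
#' @export
write_results_json <- function(detections, image_ids, path, category_id = 1L) {
  out <- list(); k <- 0L
  for (i in seq_along(detections)) {
    for (p in detections[[i]]) {
      k <- k + 1L
      out[[k]] <- list(
        image_id = image_ids[i], category_id = category_id,
        keypoints = as.list(as.vector(t(cbind(round(p$keypoints, 2), 2)))),
        score = p$score)
    }
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
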