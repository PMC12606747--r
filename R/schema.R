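# Skeleton schemas: the instance -> parts -> keypoints hierarchy that the
# two-hop regression follows, plus per-keypoint OKS constants and the
# bilateral flip permutation.

#' Construct a skeleton schema
#'
#' A schema defines the ordered keypoints of a species, their grouping into
#' anatomical parts (every keypoint belongs to exactly one part), the
#' per-keypoint OKS constants used in evaluation, the bilateral flip
#' relation, and how an instance's center is derived from its keypoints.
#'
#' @param species species name (also the COCO category name).
#' @param keypoints data.frame with columns `name`, `oks_k` (positive),
#'   `flip_partner` (1-based keypoint index; a midline keypoint points to
#'   itself).
#' @param parts list of `list(name=, keypoint_indices=)` with 1-based
#'   keypoint indices; the parts must partition the keypoints and each part
#'   may hold 1 to 6 keypoints.
#' @param skeleton_edges optional 2-column matrix of 1-based keypoint index
#'   pairs used only for rendering.
#' @param center_rule `"keypoint_centroid"` (mean of visible keypoints) or
#'   `"bbox_center"` (center of their tight bounding box).
#' @return An object of class `skeleton_schema`.
#' @export
skeleton_schema <- function(species, keypoints, parts, skeleton_edges = NULL,
                            center_rule = c("keypoint_centroid", "bbox_center")) {
  center_rule <- match.arg(center_rule)
  sch <- structure(list(
    species = species,
    keypoints = keypoints,
    parts = parts,
    skeleton_edges = skeleton_edges,
    center_rule = center_rule
  ), class = "skeleton_schema")
  sch$n_keypoints <- nrow(keypoints)
  sch$n_parts <- length(parts)
  part_of <- integer(sch$n_keypoints)
  for (p in seq_along(parts)) part_of[parts[[p]]$keypoint_indices] <- p
  sch$part_of <- part_of
  errs <- validate_schema(sch)
  if (length(errs)) {
    stop("invalid skeleton schema:\n  - ", paste(errs, collapse = "\n  - "))
  }
  sch
}

# all violations collected, not just the first
validate_schema <- function(sch) {
  errs <- character()
  kp <- sch$keypoints
  K <- nrow(kp)
  if (K < 1L) errs <- c(errs, "schema has no keypoints")
  if (anyDuplicated(kp$name)) errs <- c(errs, "duplicated keypoint names")
  if (any(kp$oks_k <= 0)) errs <- c(errs, "oks_k must be positive for every keypoint")
  fp <- kp$flip_partner
  if (any(fp < 1L | fp > K)) {
    errs <- c(errs, "flip_partner index out of range")
  } else if (!identical(fp[fp], seq_len(K))) {
    errs <- c(errs, "flip relation is not an involution (partner of partner must be self)")
  }
  idx <- unlist(lapply(sch$parts, `[[`, "keypoint_indices"))
  sizes <- vapply(sch$parts, function(p) length(p$keypoint_indices), 1L)
  if (any(sizes < 1L | sizes > 6L)) {
    errs <- c(errs, "each part must contain 1 to 6 keypoints")
  }
  if (length(idx) != K || anyDuplicated(idx) || !setequal(idx, seq_len(K))) {
    errs <- c(errs, "parts must partition the keypoints (no gaps, no overlaps)")
  }
  if (!is.null(sch$skeleton_edges)) {
    se <- sch$skeleton_edges
    if (any(se < 1L | se > K)) errs <- c(errs, "skeleton edge index out of range")
  }
  errs
}

#' @export
print.skeleton_schema <- function(x, ...) {
  cat(sprintf("<skeleton_schema> %s: %d keypoints in %d parts (center: %s)\n",
              x$species, x$n_keypoints, x$n_parts, x$center_rule))
  for (p in x$parts) {
    cat(sprintf("  %-12s %s\n", p$name,
                paste(x$keypoints$name[p$keypoint_indices], collapse = ", ")))
  }
  invisible(x)
}

#' Load a skeleton schema from file or by built-in name
#'
#' Reads the documented YAML/JSON schema dialect (keys `species`,
#' `keypoints` with `name`/`oks_k`/`flip_partner`, `parts` with
#' `name`/`keypoints`, optional `skeleton`, `center_rule`). `flip_partner`
#' and part membership may name keypoints or give 0-based indices.
#' The names `"celegans"`, `"zebrafish"` and `"drosophila"` resolve to the
#' schemas shipped with the package.
#'
#' @param path file path, or one of the built-in schema names.
#' @return A [skeleton_schema()].
#' @examples
#' sch <- load_schema("celegans")
#' sch$n_parts   # 5 single-keypoint parts
#' @export
load_schema <- function(path) {
  if (path %in% c("celegans", "zebrafish", "drosophila")) {
    path <- system.file("schemas", paste0(path, ".yaml"), package = "structpose")
  }
  if (!file.exists(path)) stop("schema file not found: ", path)
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (key in c("species", "keypoints", "parts")) {
    if (is.null(raw[[key]])) stop("schema format error: missing field '", key, "'")
  }
  kp_names <- vapply(raw$keypoints, function(k) {
    if (is.null(k$name)) stop("schema format error: keypoint without 'name'")
    k$name
  }, "")
  resolve_kp <- function(ref, what) {
    if (is.character(ref)) {
      i <- match(ref, kp_names)
      if (is.na(i)) stop("schema format error: unknown keypoint '", ref, "' in ", what)
      i
    } else {
      as.integer(ref) + 1L  # file indices are 0-based
    }
  }
  kp <- data.frame(
    name = kp_names,
    oks_k = vapply(raw$keypoints, function(k) as.numeric(k$oks_k %||% 0.1), 0),
    flip_partner = vapply(seq_along(raw$keypoints), function(i) {
      ref <- raw$keypoints[[i]]$flip_partner
      if (is.null(ref)) i else resolve_kp(ref, kp_names[i])
    }, 1L),
    stringsAsFactors = FALSE
  )
  parts <- lapply(raw$parts, function(p) {
    if (is.null(p$name) || is.null(p$keypoints)) {
      stop("schema format error: part needs 'name' and 'keypoints'")
    }
    list(name = p$name,
         keypoint_indices = unname(vapply(p$keypoints, resolve_kp, 1L,
                                          what = p$name)))
  })
  edges <- NULL
  if (!is.null(raw$skeleton)) {
    edges <- do.call(rbind, lapply(raw$skeleton, function(e) {
      c(resolve_kp(e[[1]], "skeleton"), resolve_kp(e[[2]], "skeleton"))
    }))
  }
  skeleton_schema(raw$species, kp, parts, edges,
                  center_rule = raw$center_rule %||% "keypoint_centroid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bilateral flip permutation of a schema
#'
#' Returns the 1-based keypoint permutation to apply after mirroring an
#' image horizontally: left/right partner keypoints swap, midline keypoints
#' stay. Applying it twice is the identity.
#'
#' @param schema a [skeleton_schema()].
#' @return Integer vector of length `schema$n_keypoints`.
#' @export
flip_permutation <- function(schema) {
  schema$keypoints$flip_partner
}

#' Construct a pose instance
#'
#' One animal's annotated pose: a K x 3 matrix of `(x, y, v)` rows with
#' COCO-style visibility (`0` absent, `1` labeled-but-occluded, `2`
#' visible), plus the derived center and OKS object scale. Coordinates are
#' 0-based, pixel-centered, continuous.
#'
#' @param keypoints K x 3 numeric matrix `(x, y, v)`.
#' @param schema a [skeleton_schema()].
#' @param instance_id integer id.
#' @return An object of class `pose_instance` with fields `keypoints`,
#'   `center`, `scale_s`, `instance_id`.
#' @export
pose_instance <- function(keypoints, schema, instance_id = 0L) {
  keypoints <- unname(as.matrix(keypoints))
  if (nrow(keypoints) != schema$n_keypoints || ncol(keypoints) != 3L) {
    stop("keypoints must be a ", schema$n_keypoints, " x 3 matrix")
  }
  inst <- structure(list(keypoints = keypoints, instance_id = instance_id),
                    class = "pose_instance")
  vis <- keypoints[, 3] > 0
  inst$center <- if (any(vis)) instance_center(inst, schema) else c(NA_real_, NA_real_)
  inst$scale_s <- oks_scale(keypoints)
  inst
}

# OKS object scale: sqrt of the tight bbox area of v>0 keypoints, padded
# 10% per side; floored at 1 px so single-keypoint instances stay usable
oks_scale <- function(keypoints) {
  vis <- keypoints[, 3] > 0
  if (sum(vis) < 1L) return(NA_real_)
  xs <- keypoints[vis, 1]; ys <- keypoints[vis, 2]
  w <- (max(xs) - min(xs)) * 1.2
  h <- (max(ys) - min(ys)) * 1.2
  max(sqrt(w * h), 1)
}

#' Ground-truth center of an instance
#'
#' @param inst a [pose_instance()] (or a K x 3 keypoint matrix).
#' @param schema a [skeleton_schema()]; its `center_rule` selects the mean
#'   of visible keypoints or the center of their tight bounding box.
#' @return Numeric `(x, y)`.
#' @export
instance_center <- function(inst, schema) {
  kp <- if (inherits(inst, "pose_instance")) inst$keypoints else as.matrix(inst)
  vis <- kp[, 3] > 0
  if (!any(vis)) stop("undefined center: instance has no visible keypoint")
  xs <- kp[vis, 1]; ys <- kp[vis, 2]
  if (schema$center_rule == "keypoint_centroid") {
    c(mean(xs), mean(ys))
  } else {
    c((min(xs) + max(xs)) / 2, (min(ys) + max(ys)) / 2)
  }
}
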