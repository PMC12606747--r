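# The three-branch network: a lightweight multi-scale CNN backbone
# (pluggable contract: anything producing a stride-keyed feature pyramid
# qualifies), the Part Perception head regressing first-hop center->part
# offsets, multi-scale feature sampling (MFS) at the predicted part
# points, structure-guided refinement (SGL) of the part tokens, per-part
# second-hop heads, and the train-only keypoint-heatmap head.

#' Network configuration
#'
#' @param backbone_channels feature width of every pyramid level.
#' @param stem_channels width of the first stem convolution.
#' @param head_hidden hidden width of the prediction heads.
#' @param channels uniform channel dimension C after channel
#'   transformation (part token width).
#' @param fuse_levels strides participating in MFS (default `c(4, 8)`,
#'   the best-performing combination; stride 4 is mandatory).
#' @param ct_variant `"CT2"` (conv-ReLU-conv+norm-ReLU-conv; the final
#'   convolution stands in for a deformable convolution, see the package
#'   vignette) or `"CT1"` (conv-ReLU-conv).
#' @param fusion `"A_add"` (learnable softmax-weighted sum per part) or
#'   `"con_cat"` (channel concatenation + 1x1 mix).
#' @param sgl_layers,sgl_ffn,sgl_heads transformer depth, feed-forward
#'   width and head count (defaults 1 / 512 / 4).
#' @param sgl_type_embed add the learnable part-type embedding to the
#'   query/key path (default TRUE).
#' @param sgl_raw_qk use the summed tokens directly as Q and K instead of
#'   projecting them (the literal reading of the attention description).
#' @param stride output stride (default 4).
#' @return List of class `pose_model_config`.
#' @export
pose_model_config <- function(backbone_channels = 32L, stem_channels = 16L,
                              head_hidden = 32L, channels = 64L,
                              fuse_levels = c(4L, 8L),
                              ct_variant = c("CT2", "CT1"),
                              fusion = c("A_add", "con_cat"),
                              sgl_layers = 1L, sgl_ffn = 512L,
                              sgl_heads = 4L, sgl_type_embed = TRUE,
                              sgl_raw_qk = FALSE, stride = 4L) {
  ct_variant <- match.arg(ct_variant)
  fusion <- match.arg(fusion)
  if (!4L %in% fuse_levels) stop("fuse_levels must include stride 4")
  if (channels %% sgl_heads != 0L) {
    stop("config error: channels (", channels,
         ") must be divisible by sgl_heads (", sgl_heads, ")")
  }
  structure(list(backbone_channels = backbone_channels,
                 stem_channels = stem_channels, head_hidden = head_hidden,
                 channels = channels, fuse_levels = sort(fuse_levels),
                 ct_variant = ct_variant, fusion = fusion,
                 sgl_layers = sgl_layers, sgl_ffn = sgl_ffn,
                 sgl_heads = sgl_heads, sgl_type_embed = sgl_type_embed,
                 sgl_raw_qk = sgl_raw_qk, stride = stride),
            class = "pose_model_config")
}

conv_par <- function(kh, kw, cin, cout) {
  ad_tensor(array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
                  dim = c(kh, kw, cin, cout)))
}
lin_par <- function(cin, cout, gain = 2) {
  ad_tensor(matrix(rnorm(cin * cout, 0, sqrt(gain / cin)), cin, cout))
}
vec_par <- function(n, value = 0) ad_tensor(rep(value, n))

#' Build a pose model
#'
#' Initializes all parameters (He-style) from `seed`. The center-head bias
#' starts at `log(0.1/0.9)` so the initial center heatmap is near the
#' background rate.
#'
#' @param schema a [skeleton_schema()].
#' @param config a [pose_model_config()].
#' @param seed RNG seed for initialization.
#' @return List of class `pose_model` with `schema`, `config`, `params`.
#' @export
pose_model <- function(schema, config = pose_model_config(), seed = 0L) {
  set.seed(seed)
  P <- schema$n_parts; K <- schema$n_keypoints
  bc <- config$backbone_channels; sc <- config$stem_channels
  hh <- config$head_hidden; C <- config$channels
  pars <- list(
    stem1_w = conv_par(3, 3, 3, sc), stem1_b = vec_par(sc),
    stem2_w = conv_par(3, 3, sc, bc), stem2_b = vec_par(bc),
    res4a_w = conv_par(3, 3, bc, bc), res4a_b = vec_par(bc),
    res4b_w = conv_par(3, 3, bc, bc), res4b_b = vec_par(bc),
    ctr1_w = conv_par(3, 3, bc, hh), ctr1_b = vec_par(hh),
    ctr2_w = conv_par(1, 1, hh, 1), ctr2_b = vec_par(1, log(0.1 / 0.9)),
    kp1_w = conv_par(3, 3, bc, hh), kp1_b = vec_par(hh),
    kp2_w = conv_par(1, 1, hh, K), kp2_b = vec_par(K, log(0.1 / 0.9)),
    pp1_w = conv_par(3, 3, bc, hh), pp1_b = vec_par(hh),
    pp2_w = conv_par(1, 1, hh, 2L * P), pp2_b = vec_par(2L * P)
  )
  for (s in setdiff(config$fuse_levels, 4L)) {
    prev <- if (s == 8L) bc else bc
    pars[[paste0("down", s, "_w")]] <- conv_par(3, 3, prev, bc)
    pars[[paste0("down", s, "_b")]] <- vec_par(bc)
  }
  # make sure intermediate downsampling stages exist (e.g. 8 when only 16 fused)
  needed <- unique(unlist(lapply(setdiff(config$fuse_levels, 4L),
                                 function(s) 2^seq(3, log2(s)))))
  for (s in setdiff(needed, 4L)) {
    key <- paste0("down", s, "_w")
    if (is.null(pars[[key]])) {
      pars[[key]] <- conv_par(3, 3, bc, bc)
      pars[[paste0("down", s, "_b")]] <- vec_par(bc)
    }
  }
  for (s in config$fuse_levels) {
    pfx <- paste0("ct", s, "_")
    pars[[paste0(pfx, "1w")]] <- conv_par(3, 3, bc, C)
    pars[[paste0(pfx, "1b")]] <- vec_par(C)
    pars[[paste0(pfx, "2w")]] <- conv_par(3, 3, C, C)
    pars[[paste0(pfx, "2b")]] <- vec_par(C)
    if (config$ct_variant == "CT2") {
      pars[[paste0(pfx, "ng")]] <- vec_par(C, 1)
      pars[[paste0(pfx, "nb")]] <- vec_par(C)
      pars[[paste0(pfx, "3w")]] <- conv_par(3, 3, C, C)
      pars[[paste0(pfx, "3b")]] <- vec_par(C)
    }
  }
  L <- length(config$fuse_levels)
  if (config$fusion == "A_add") {
    for (p in seq_len(P)) pars[[paste0("fuse_theta", p)]] <- vec_par(L)
  } else {
    pars$mix_w <- lin_par(C * L, C)
    pars$mix_b <- vec_par(C)
  }
  pars$type_embed <- ad_tensor(matrix(rnorm(P * C, 0, 0.02), P, C))
  for (i in seq_len(config$sgl_layers)) {
    pfx <- paste0("sgl", i, "_")
    pars[[paste0(pfx, "ln1g")]] <- vec_par(C, 1)
    pars[[paste0(pfx, "ln1b")]] <- vec_par(C)
    if (!config$sgl_raw_qk) {
      pars[[paste0(pfx, "wq")]] <- lin_par(C, C, 1)
      pars[[paste0(pfx, "bq")]] <- vec_par(C)
      pars[[paste0(pfx, "wk")]] <- lin_par(C, C, 1)
      pars[[paste0(pfx, "bk")]] <- vec_par(C)
    }
    pars[[paste0(pfx, "wv")]] <- lin_par(C, C, 1)
    pars[[paste0(pfx, "bv")]] <- vec_par(C)
    pars[[paste0(pfx, "wo")]] <- lin_par(C, C, 1)
    pars[[paste0(pfx, "bo")]] <- vec_par(C)
    pars[[paste0(pfx, "ln2g")]] <- vec_par(C, 1)
    pars[[paste0(pfx, "ln2b")]] <- vec_par(C)
    pars[[paste0(pfx, "w1")]] <- lin_par(C, config$sgl_ffn)
    pars[[paste0(pfx, "b1")]] <- vec_par(config$sgl_ffn)
    pars[[paste0(pfx, "w2")]] <- lin_par(config$sgl_ffn, C)
    pars[[paste0(pfx, "b2")]] <- vec_par(C)
  }
  for (p in seq_len(P)) {
    kp_n <- length(schema$parts[[p]]$keypoint_indices)
    pars[[paste0("off2_", p, "_w")]] <- lin_par(C, 2L * kp_n, 1)
    pars[[paste0("off2_", p, "_b")]] <- vec_par(2L * kp_n)
  }
  structure(list(schema = schema, config = config, params = pars,
                 opt = new.env(parent = emptyenv())),
            class = "pose_model")
}

# --- forward pieces (autodiff tensors in, tensors out) ----------------------

conv_block <- function(x, pars, name, stride = 1L, pad = 1L, act = TRUE) {
  out <- ad_conv2d(x, pars[[paste0(name, "_w")]], pars[[paste0(name, "_b")]],
                   stride = stride, pad = pad)
  if (act) ad_relu(out) else out
}

backbone_ad <- function(model, x) {
  pars <- model$params
  f2 <- conv_block(x, pars, "stem1", stride = 2L)
  f4 <- conv_block(f2, pars, "stem2", stride = 2L)
  r <- conv_block(f4, pars, "res4a")
  r <- ad_conv2d(r, pars$res4b_w, pars$res4b_b, stride = 1L, pad = 1L)
  f4 <- ad_relu(ad_add(f4, r))
  feats <- list("4" = f4)
  cur <- f4
  for (s in c(8L, 16L, 32L)) {
    key <- paste0("down", s, "_w")
    if (is.null(pars[[key]])) break
    cur <- ad_relu(ad_conv2d(cur, pars[[key]], pars[[paste0("down", s, "_b")]],
                             stride = 2L, pad = 1L))
    feats[[as.character(s)]] <- cur
  }
  feats
}

#' Backbone forward pass
#'
#' Runs the lightweight multi-scale backbone on one image and returns the
#' feature pyramid as plain arrays keyed by stride. Any provider of such a
#' pyramid can substitute for this backbone in [model_forward()].
#'
#' @param model a [pose_model()].
#' @param image H x W x 3 array, H and W divisible by 32.
#' @return Named list of `(H/s) x (W/s) x C` arrays, strides as names.
#' @export
backbone_forward <- function(model, image) {
  d <- dim(image)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("shape error: image size ", d[1], "x", d[2],
         " not divisible by 32")
  }
  ad_begin()
  feats <- backbone_ad(model, ad_tensor(image, track = FALSE))
  lapply(feats, ad_val)
}

part_perception_ad <- function(model, f4) {
  h <- conv_block(f4, model$params, "pp1")
  ad_conv2d(h, model$params$pp2_w, model$params$pp2_b, stride = 1L, pad = 0L)
}

#' Part Perception head: first-hop offsets
#'
#' Per-cell convolutional regression of the center-to-part offsets
#' (2P channels: x, y interleaved per part, output-stride units).
#'
#' @param model a [pose_model()].
#' @param f4 stride-4 feature array from [backbone_forward()].
#' @return h x w x 2P array.
#' @export
part_perception <- function(model, f4) {
  ad_begin()
  ad_val(part_perception_ad(model, ad_tensor(f4, track = FALSE)))
}

ch_trans_ad <- function(model, feat, s) {
  pars <- model$params
  pfx <- paste0("ct", s, "_")
  h <- ad_relu(ad_conv2d(feat, pars[[paste0(pfx, "1w")]],
                         pars[[paste0(pfx, "1b")]], 1L, 1L))
  h <- ad_conv2d(h, pars[[paste0(pfx, "2w")]], pars[[paste0(pfx, "2b")]], 1L, 1L)
  if (model$config$ct_variant == "CT2") {
    h <- ad_relu(ad_bn2d(h, pars[[paste0(pfx, "ng")]], pars[[paste0(pfx, "nb")]]))
    h <- ad_conv2d(h, pars[[paste0(pfx, "3w")]], pars[[paste0(pfx, "3b")]], 1L, 1L)
  }
  h
}

# interleave per-part N x C matrices into a (N*P) x C token matrix with
# part index fastest
ad_interleave_rows <- function(xs) {
  P <- length(xs)
  vals <- lapply(xs, ad_val)
  N <- nrow(vals[[1]]); C <- ncol(vals[[1]])
  out_v <- matrix(0, N * P, C)
  for (p in seq_len(P)) out_v[seq(p, N * P, by = P), ] <- vals[[p]]
  out <- ad_tensor(out_v)
  ad_push(out, function(g) {
    for (p in seq_len(P)) {
      ad_accum(xs[[p]], g[seq(p, N * P, by = P), , drop = FALSE])
    }
  })
}

# MFS over autodiff tensors. ct_feats: named list (stride -> tensor);
# off1: h x w x 2P tensor. Returns token tensor (N*P) x C, part fastest,
# cells in column-major order of the h x w grid.
mfs_ad <- function(model, ct_feats, off1, h, w) {
  cfg <- model$config; pars <- model$params
  P <- model$schema$n_parts
  N <- h * w
  base_x <- rep(0:(w - 1L), each = h)   # column-major cell enumeration
  base_y <- rep(0:(h - 1L), times = w)
  off1_mat <- ad_reshape(off1, c(N, 2L * P))
  per_part <- vector("list", P)
  for (p in seq_len(P)) {
    ox <- ad_add(ad_cols(off1_mat, 2L * p - 1L), matrix(base_x, ncol = 1L))
    oy <- ad_add(ad_cols(off1_mat, 2L * p), matrix(base_y, ncol = 1L))
    samples <- vector("list", length(cfg$fuse_levels))
    for (li in seq_along(cfg$fuse_levels)) {
      s <- cfg$fuse_levels[li]
      if (s == 4L) {
        xs <- ox; ys <- oy
      } else {
        sc <- 4 / s
        xs <- ad_add(ad_scale(ad_add(ox, 0.5), sc), -0.5)
        ys <- ad_add(ad_scale(ad_add(oy, 0.5), sc), -0.5)
      }
      samples[[li]] <- ad_grid_sample(ct_feats[[as.character(s)]], xs, ys)
    }
    per_part[[p]] <- if (cfg$fusion == "A_add") {
      if (length(samples) == 1L) samples[[1]] else
        ad_fuse_add(samples, pars[[paste0("fuse_theta", p)]])
    } else {
      ad_add_rowvec(ad_matmul(ad_cbind(samples), pars$mix_w), pars$mix_b)
    }
  }
  ad_interleave_rows(per_part)
}

sgl_layer_ad <- function(tokens, pars, pfx, cfg, P) {
  C <- ncol(ad_val(tokens))
  dh <- C %/% cfg$sgl_heads
  h1 <- ad_layernorm(tokens, pars[[paste0(pfx, "ln1g")]],
                     pars[[paste0(pfx, "ln1b")]])
  qk_in <- if (cfg$sgl_type_embed) ad_add_tokenwise(h1, pars$type_embed) else h1
  if (cfg$sgl_raw_qk) {
    Q <- qk_in; K <- qk_in
  } else {
    Q <- ad_add_rowvec(ad_matmul(qk_in, pars[[paste0(pfx, "wq")]]),
                       pars[[paste0(pfx, "bq")]])
    K <- ad_add_rowvec(ad_matmul(qk_in, pars[[paste0(pfx, "wk")]]),
                       pars[[paste0(pfx, "bk")]])
  }
  V <- ad_add_rowvec(ad_matmul(h1, pars[[paste0(pfx, "wv")]]),
                     pars[[paste0(pfx, "bv")]])
  heads <- vector("list", cfg$sgl_heads)
  attn <- NULL
  for (hh in seq_len(cfg$sgl_heads)) {
    cols <- ((hh - 1L) * dh + 1L):(hh * dh)
    o <- ad_attention(ad_cols(Q, cols), ad_cols(K, cols), ad_cols(V, cols),
                      P, 1 / sqrt(dh))
    if (hh == 1L) attn <- attr(o, "attn")
    heads[[hh]] <- o
  }
  mh <- ad_add_rowvec(ad_matmul(ad_cbind(heads), pars[[paste0(pfx, "wo")]]),
                      pars[[paste0(pfx, "bo")]])
  tokens <- ad_add(tokens, mh)
  h2 <- ad_layernorm(tokens, pars[[paste0(pfx, "ln2g")]],
                     pars[[paste0(pfx, "ln2b")]])
  ff <- ad_relu(ad_add_rowvec(ad_matmul(h2, pars[[paste0(pfx, "w1")]]),
                              pars[[paste0(pfx, "b1")]]))
  ff <- ad_add_rowvec(ad_matmul(ff, pars[[paste0(pfx, "w2")]]),
                      pars[[paste0(pfx, "b2")]])
  out <- ad_add(tokens, ff)
  attr(out, "attn") <- attn
  out
}

sgl_ad <- function(model, tokens) {
  cfg <- model$config
  P <- model$schema$n_parts
  attn <- NULL
  for (i in seq_len(cfg$sgl_layers)) {
    tokens <- sgl_layer_ad(tokens, model$params, paste0("sgl", i, "_"), cfg, P)
    attn <- attr(tokens, "attn")
  }
  attr(tokens, "attn") <- attn
  tokens
}

off2_head_ad <- function(model, tokens, N) {
  schema <- model$schema
  P <- schema$n_parts; K <- schema$n_keypoints
  NP <- N * P
  blocks <- vector("list", P)
  for (p in seq_len(P)) {
    Tp <- ad_rows(tokens, seq(p, NP, by = P))
    blocks[[p]] <- ad_add_rowvec(ad_matmul(Tp, model$params[[paste0("off2_", p, "_w")]]),
                                 model$params[[paste0("off2_", p, "_b")]])
  }
  kseq <- unlist(lapply(schema$parts, `[[`, "keypoint_indices"))
  pos <- match(seq_len(K), kseq)
  perm <- as.vector(rbind(2L * pos - 1L, 2L * pos))
  ad_cols(ad_cbind(blocks), perm)
}

# full forward on the tape; returns autodiff tensors plus layout info
model_forward_ad <- function(model, image, mode = "train") {
  cfg <- model$config
  x <- ad_tensor(image, track = FALSE)
  feats <- backbone_ad(model, x)
  f4 <- feats[["4"]]
  d4 <- dim(ad_val(f4)); h <- d4[1]; w <- d4[2]; N <- h * w
  center <- ad_sigmoid(ad_conv2d(conv_block(f4, model$params, "ctr1"),
                                 model$params$ctr2_w, model$params$ctr2_b,
                                 1L, 0L))
  kp_hm <- if (mode == "train") {
    ad_sigmoid(ad_conv2d(conv_block(f4, model$params, "kp1"),
                         model$params$kp2_w, model$params$kp2_b, 1L, 0L))
  } else NULL
  off1 <- part_perception_ad(model, f4)
  ct_feats <- list()
  for (s in cfg$fuse_levels) {
    ct_feats[[as.character(s)]] <- ch_trans_ad(model, feats[[as.character(s)]], s)
  }
  tokens <- mfs_ad(model, ct_feats, off1, h, w)
  refined <- sgl_ad(model, tokens)
  off2 <- off2_head_ad(model, refined, N)
  list(center = center, off1 = off1, off2_mat = off2, kp_hm = kp_hm,
       tokens = tokens, refined = refined, ct_feats = ct_feats,
       h = h, w = w)
}

tokens_to_array <- function(tok, h, w, P) {
  C <- ncol(tok)
  arr <- array(0, dim = c(h, w, P, C))
  for (p in seq_len(P)) {
    arr[, , p, ] <- array(tok[seq(p, nrow(tok), by = P), ], dim = c(h, w, C))
  }
  arr
}

#' Full network forward pass
#'
#' Runs backbone, heads, MFS and SGL on one image. In `"infer"` mode the
#' keypoint-heatmap head is skipped entirely; the center heatmap and both
#' offset fields are identical between modes for equal weights.
#'
#' @param model a [pose_model()].
#' @param image H x W x 3 array in `[0, 1]`, sides divisible by 32.
#' @param mode `"infer"` or `"train"`.
#' @return List of class `network_outputs`: `center_heatmap` (h x w),
#'   `off1_field` (h x w x 2P), `off2_field` (h x w x 2K),
#'   `keypoint_heatmaps` (h x w x K, train mode only), `part_features`
#'   and `part_features_refined` (h x w x P x C), `attention`
#'   (first-layer, first-head attention weights).
#' @export
model_forward <- function(model, image, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  d <- dim(image)
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop("shape error: image size not divisible by 32")
  }
  ad_begin()
  fw <- model_forward_ad(model, image, mode)
  P <- model$schema$n_parts; K <- model$schema$n_keypoints
  h <- fw$h; w <- fw$w
  structure(list(
    center_heatmap = matrix(ad_val(fw$center), h, w),
    off1_field = ad_val(fw$off1),
    off2_field = array(ad_val(fw$off2_mat), dim = c(h, w, 2L * K)),
    keypoint_heatmaps = if (mode == "train") ad_val(fw$kp_hm) else NULL,
    part_features = tokens_to_array(ad_val(fw$tokens), h, w, P),
    part_features_refined = tokens_to_array(ad_val(fw$refined), h, w, P),
    transformed_levels = lapply(fw$ct_feats, ad_val),
    attention = attr(fw$refined, "attn"),
    stride = model$config$stride, mode = mode
  ), class = "network_outputs")
}

# --- standalone numeric module surfaces -------------------------------------

#' Multi-scale feature sampling and fusion
#'
#' For every output cell `(i, j)` and part `p`, samples each
#' channel-transformed pyramid level by bilinear interpolation at the
#' shifted location `(i, j) + off1[p]` (converted to the level's
#' coordinates), then fuses levels either by a learnable
#' softmax-normalized weight per part (`"A_add"`) or by concatenation plus
#' a 1x1 mix (`"con_cat"`). Sampling outside a grid is border-clamped.
#'
#' @param features named list (stride -> h_l x w_l x C array) of
#'   channel-uniform transformed levels; must contain the base stride.
#' @param off1_field h x w x 2P array of first-hop offsets in base-stride
#'   units.
#' @param fuse_cfg list: `levels` (strides, default names of `features`),
#'   `fusion` (`"A_add"`/`"con_cat"`), `weights` (P x L fusion logits,
#'   default all equal), `mix_w`/`mix_b` (for `"con_cat"`),
#'   `base_stride` (default 4).
#' @return h x w x P x C array of fused part features.
#' @export
mfs_sample_fuse <- function(features, off1_field, fuse_cfg = list()) {
  levels <- fuse_cfg$levels %||% as.integer(names(features))
  base <- fuse_cfg$base_stride %||% 4L
  fusion <- fuse_cfg$fusion %||% "A_add"
  d <- dim(off1_field); h <- d[1]; w <- d[2]; P <- d[3] %/% 2L
  C <- dim(features[[as.character(base)]])[3]
  N <- h * w
  base_x <- rep(0:(w - 1L), each = h)
  base_y <- rep(0:(h - 1L), times = w)
  wts <- fuse_cfg$weights %||% matrix(0, P, length(levels))
  out <- array(0, dim = c(h, w, P, C))
  for (p in seq_len(P)) {
    xs <- base_x + as.vector(off1_field[, , 2L * p - 1L])
    ys <- base_y + as.vector(off1_field[, , 2L * p])
    samples <- lapply(seq_along(levels), function(li) {
      s <- levels[li]
      if (s == base) {
        cpp_grid_sample_fw(features[[as.character(s)]], xs, ys)
      } else {
        sc <- base / s
        cpp_grid_sample_fw(features[[as.character(s)]],
                           (xs + 0.5) * sc - 0.5, (ys + 0.5) * sc - 0.5)
      }
    })
    fused <- if (fusion == "A_add") {
      a <- exp(wts[p, ] - max(wts[p, ])); a <- a / sum(a)
      Reduce(`+`, Map(function(m, ai) ai * m, samples, a))
    } else {
      sweep(do.call(cbind, samples) %*% fuse_cfg$mix_w, 2L, fuse_cfg$mix_b, "+")
    }
    out[, , p, ] <- array(fused, dim = c(h, w, C))
  }
  out
}

#' Initialize standalone SGL weights
#'
#' @param P number of parts; `C` token width.
#' @param cfg a [pose_model_config()] (SGL fields are used).
#' @param seed RNG seed.
#' @return List with per-layer weight lists and the `type_embed` matrix.
#' @export
sgl_init <- function(P, C, cfg = pose_model_config(channels = C), seed = 0L) {
  set.seed(seed)
  pars <- list(type_embed = ad_tensor(matrix(rnorm(P * C, 0, 0.02), P, C)))
  for (i in seq_len(cfg$sgl_layers)) {
    pfx <- paste0("sgl", i, "_")
    pars[[paste0(pfx, "ln1g")]] <- vec_par(C, 1)
    pars[[paste0(pfx, "ln1b")]] <- vec_par(C)
    if (!cfg$sgl_raw_qk) {
      pars[[paste0(pfx, "wq")]] <- lin_par(C, C, 1)
      pars[[paste0(pfx, "bq")]] <- vec_par(C)
      pars[[paste0(pfx, "wk")]] <- lin_par(C, C, 1)
      pars[[paste0(pfx, "bk")]] <- vec_par(C)
    }
    pars[[paste0(pfx, "wv")]] <- lin_par(C, C, 1)
    pars[[paste0(pfx, "bv")]] <- vec_par(C)
    pars[[paste0(pfx, "wo")]] <- lin_par(C, C, 1)
    pars[[paste0(pfx, "bo")]] <- vec_par(C)
    pars[[paste0(pfx, "ln2g")]] <- vec_par(C, 1)
    pars[[paste0(pfx, "ln2b")]] <- vec_par(C)
    pars[[paste0(pfx, "w1")]] <- lin_par(C, cfg$sgl_ffn)
    pars[[paste0(pfx, "b1")]] <- vec_par(cfg$sgl_ffn)
    pars[[paste0(pfx, "w2")]] <- lin_par(cfg$sgl_ffn, C)
    pars[[paste0(pfx, "b2")]] <- vec_par(C)
  }
  pars
}

#' Structure-guided refinement of part tokens
#'
#' At every spatial cell independently, the P part tokens pass through
#' LayerNorm -> multi-head self-attention -> LayerNorm -> feed-forward,
#' both with residual connections. Queries and keys derive from the
#' tokens plus the learnable part-type embedding; values from the tokens
#' alone.
#'
#' @param part_features h x w x P x C array (e.g. from
#'   [mfs_sample_fuse()]).
#' @param weights from [sgl_init()] (or a model's parameters).
#' @param cfg a [pose_model_config()].
#' @return h x w x P x C array of refined features; the first-layer
#'   first-head attention (cells x P x P, rows summing to 1) is attached
#'   as attribute `"attention"`.
#' @export
sgl_refine <- function(part_features, weights, cfg = pose_model_config()) {
  d <- dim(part_features)
  h <- d[1]; w <- d[2]; P <- d[3]; C <- d[4]
  if (C %% cfg$sgl_heads != 0L) {
    stop("config error: C not divisible by sgl_heads")
  }
  N <- h * w
  tok <- matrix(0, N * P, C)
  for (p in seq_len(P)) {
    tok[seq(p, N * P, by = P), ] <- matrix(part_features[, , p, ], N, C)
  }
  ad_begin()
  tt <- ad_tensor(tok, track = FALSE)
  for (i in seq_len(cfg$sgl_layers)) {
    tt <- sgl_layer_ad(tt, weights, paste0("sgl", i, "_"), cfg, P)
  }
  out <- tokens_to_array(ad_val(tt), h, w, P)
  attr(out, "attention") <- attr(tt, "attn")
  out
}
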