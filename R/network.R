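# Full segmentation network: a four-stage encoder of (MBConv + multi-axis
# attention) units, a CBAM-refined bottleneck, multi-scale attention-gated
# skip connections, and a patch-expanding decoder mirroring the encoder.
#
# Resolution/width chain for a 224 input with stem width 64:
#   stem 112x112x64 -> stages 56x56x64, 28x28x128, 14x14x256, 7x7x512
#   decoder 14x14x256, 28x28x128, 56x56x64 -> final 4x expand -> 224x224 head
#
# Each encoder stage unit k is (downsampling MBConv if k = 1 else MBConv)
# followed by one multi-axis attention block; stage depths are (2, 2, 5, 2).
# Decoder units keep the same composite block type (a non-downsampling MBConv
# followed by the attention pair), which is what the MaxViT-lineage "block"
# denotes; disable with `decoder_mbconv = FALSE` for attention-only stages.

#' Model configuration
#'
#' Fully determines the network topology and therefore its parameter count.
#' The defaults are the base model: stem width 64, stage widths doubling from
#' 64 to 512, encoder depths (2, 2, 5, 2), a three-stage decoder of depth
#' (2, 2, 2), window/grid size 7 and head width 32.
#'
#' @param img_size square input extent; must be divisible by 32 and every
#'   stage resolution (img/4 ... img/32) by `window_p` and `grid_g`
#' @param num_classes output classes (including background)
#' @param in_channels input image channels
#' @param stem_dim stem width (equals the first stage width)
#' @param stage_dims channels per encoder stage; must double stage-to-stage
#' @param encoder_depths units per encoder stage
#' @param decoder_depths units per decoder stage (deep to shallow)
#' @param head_dim,window_p,grid_g,mlp_ratio attention geometry, see
#'   [attention_config()]
#' @param expansion,se_ratio MBConv settings, see [mbconv_config()]
#' @param skip_mode `"mcbam"` (multi-scale gates, the full model), `"cbam"`
#'   (stage-local gates) or `"none"` (plain skips, no bottleneck gate)
#' @param downsample_mode `"mbconv"` or `"plain_conv"` (every MBConv replaced
#'   by a single 3x3 convolution)
#' @param fuse_mode skip fusion: `"concat"` (concatenate + 1x1 projection) or
#'   `"add"`
#' @param decoder_mbconv include a non-downsampling MBConv in each decoder
#'   unit (default `TRUE`)
#' @return a `model_config` object
#' @export
model_config <- function(img_size = 224L, num_classes = 9L, in_channels = 3L,
                         stem_dim = 64L, stage_dims = stem_dim * c(1L, 2L, 4L, 8L),
                         encoder_depths = c(2L, 2L, 5L, 2L),
                         decoder_depths = c(2L, 2L, 2L),
                         head_dim = 32L, window_p = 7L, grid_g = 7L,
                         mlp_ratio = 4, expansion = 4, se_ratio = 0.25,
                         skip_mode = c("mcbam", "cbam", "none"),
                         downsample_mode = c("mbconv", "plain_conv"),
                         fuse_mode = c("concat", "add"),
                         decoder_mbconv = TRUE) {
  skip_mode <- match.arg(skip_mode)
  downsample_mode <- match.arg(downsample_mode)
  fuse_mode <- match.arg(fuse_mode)
  img_size <- as.integer(img_size)
  stage_dims <- as.integer(stage_dims)
  if (img_size %% 32L != 0L) stop("img_size must be divisible by 32")
  stopifnot(length(stage_dims) == 4L, length(encoder_depths) == 4L,
            length(decoder_depths) == 3L, all(encoder_depths >= 1),
            all(decoder_depths >= 1), num_classes >= 2)
  if (!all(stage_dims[-1] == 2L * stage_dims[-4])) {
    stop("stage_dims must double from stage to stage")
  }
  if (stage_dims[1] != stem_dim) {
    stop("the first stage width must equal stem_dim")
  }
  for (s in 1:4) {
    ext <- img_size %/% (2L^(s + 1L))
    if (ext %% window_p != 0L || ext %% grid_g != 0L) {
      stop("stage ", s, " extent ", ext, " is not divisible by the window (",
           window_p, ") and grid (", grid_g, ") sizes")
    }
    if (stage_dims[s] %% head_dim != 0L) {
      stop("stage ", s, " width ", stage_dims[s],
           " is not a multiple of head_dim ", head_dim)
    }
  }
  structure(list(img_size = img_size, num_classes = as.integer(num_classes),
                 in_channels = as.integer(in_channels),
                 stem_dim = as.integer(stem_dim), stage_dims = stage_dims,
                 encoder_depths = as.integer(encoder_depths),
                 decoder_depths = as.integer(decoder_depths),
                 head_dim = as.integer(head_dim),
                 window_p = as.integer(window_p), grid_g = as.integer(grid_g),
                 mlp_ratio = mlp_ratio, expansion = expansion,
                 se_ratio = se_ratio, skip_mode = skip_mode,
                 downsample_mode = downsample_mode, fuse_mode = fuse_mode,
                 decoder_mbconv = isTRUE(decoder_mbconv)),
            class = "model_config")
}

#' Reduced desk-scale configuration
#'
#' A small model for CPU experiments and tests: 64 x 64 inputs, widths 16-128,
#' one unit per stage, window/grid size 2 and head width 8.
#'
#' @param num_classes output classes
#' @param img_size input extent
#' @return a `model_config`
#' @export
reduced_model_config <- function(num_classes = 4L, img_size = 64L) {
  model_config(img_size = img_size, num_classes = num_classes,
               stem_dim = 16L, encoder_depths = c(1L, 1L, 1L, 1L),
               decoder_depths = c(1L, 1L, 1L), head_dim = 8L,
               window_p = 2L, grid_g = 2L, mlp_ratio = 2)
}

stage_attention_config <- function(cfg, dim) {
  attention_config(dim, head_dim = cfg$head_dim, window_p = cfg$window_p,
                   grid_g = cfg$grid_g, mlp_ratio = cfg$mlp_ratio)
}

# ---- patch expanding -------------------------------------------------------

# (N,H,W,C*r^2) -> (N,rH,rW,C) depth-to-space rearrangement
ag_depth_to_space <- function(x, r) {
  d <- dim(val(x))
  cout <- d[4] %/% (r * r)
  stopifnot(cout * r * r == d[4])
  x6 <- ag_reshape(x, c(d[1], d[2], d[3], cout, r, r))
  xp <- ag_aperm(x6, c(1, 5, 2, 6, 3, 4))
  ag_reshape(xp, c(d[1], r * d[2], r * d[3], cout))
}

#' Construct a patch-expanding layer
#'
#' Learned upsampling: a linear channel expansion followed by depth-to-space
#' rearrangement. With `factor = 2` the channels halve while each spatial
#' extent doubles ((H, W, C) -> (2H, 2W, C/2)); with `factor = 4` the
#' channel width is preserved ((H, W, C) -> (4H, 4W, C)), the form used by
#' the final 4x expansion before the classification head.
#'
#' @param in_dim input channels (must be even for `factor = 2`)
#' @param factor spatial upsampling factor (2 or 4)
#' @return a patch-expand module
#' @export
new_patch_expand <- function(in_dim, factor = 2L) {
  stopifnot(factor %in% c(2L, 4L))
  out_dim <- if (factor == 2L) {
    if (in_dim %% 2L != 0L) stop("in_dim must be even for 2x patch expansion")
    in_dim %/% 2L
  } else {
    in_dim
  }
  list(lin = new_linear(in_dim, out_dim * factor * factor),
       in_dim = as.integer(in_dim), out_dim = as.integer(out_dim),
       factor = as.integer(factor))
}

fwd_patch_expand <- function(p, x) {
  d <- dim(val(x))
  if (d[4] != p$in_dim) {
    stop("patch expand expected ", p$in_dim, " channels, got ", d[4])
  }
  tok <- ag_reshape(x, c(d[1] * d[2] * d[3], d[4]))
  up <- fwd_linear(p$lin, tok)
  ag_depth_to_space(ag_reshape(up, c(d[1], d[2], d[3], ncol(val(up)))), p$factor)
}

#' Apply a patch-expanding layer to a single feature map
#' @param pe module from [new_patch_expand()]
#' @param x numeric array (H, W, C)
#' @return upsampled array
#' @export
patch_expand_forward <- function(pe, x) {
  x <- as_hwc(x)
  out <- val(fwd_patch_expand(pe, array(x, c(1, dim(x)))))
  array(out, dim(out)[2:4])
}

# ---- skip fusion -----------------------------------------------------------

#' Construct a skip-fusion layer
#'
#' Merges same-resolution decoder and encoder features. `"concat"`
#' concatenates the two C-channel maps and projects back to C with a learned
#' 1x1 map; `"add"` sums them.
#'
#' @param channels channel count of each input
#' @param mode `"concat"` or `"add"`
#' @return a skip-fuse module
#' @export
new_skip_fuse <- function(channels, mode = c("concat", "add")) {
  mode <- match.arg(mode)
  m <- list(channels = as.integer(channels), mode = mode)
  if (mode == "concat") m$proj <- new_linear(2L * channels, channels)
  m
}

fwd_skip_fuse <- function(p, up, skip) {
  du <- dim(val(up)); ds <- dim(val(skip))
  if (!all(du == ds)) {
    stop("skip fusion requires matching shapes (got ",
         paste(du, collapse = "x"), " vs ", paste(ds, collapse = "x"), ")")
  }
  if (p$mode == "add") return(ag_add(up, skip))
  r <- du[1] * du[2] * du[3]
  tok <- ag_cat_cols(list(ag_reshape(up, c(r, du[4])),
                          ag_reshape(skip, c(r, du[4]))))
  ag_reshape(fwd_linear(p$proj, tok), du)
}

#' Fuse decoder and encoder features at one resolution
#' @param sf module from [new_skip_fuse()]
#' @param up decoder features (H, W, C)
#' @param skip encoder-side features (H, W, C)
#' @return fused array (H, W, C)
#' @export
skip_fuse_forward <- function(sf, up, skip) {
  up <- as_hwc(up); skip <- as_hwc(skip)
  d <- dim(up)
  array(val(fwd_skip_fuse(sf, array(up, c(1, d)), array(skip, c(1, dim(skip))))), d)
}

# ---- model build -----------------------------------------------------------

new_encoder_unit <- function(cfg, in_dim, out_dim, down) {
  mb_cfg <- mbconv_config(in_dim, out_dim, expansion = cfg$expansion,
                          se_ratio = cfg$se_ratio, downsample = down)
  list(mb = new_mbconv(mb_cfg, plain = cfg$downsample_mode == "plain_conv"),
       at = new_maxvit_block(stage_attention_config(cfg, out_dim)))
}

#' Build a segmentation model
#'
#' Instantiates every parameter of the network described by `cfg`. Weights
#' are drawn from the session RNG (truncated normal for linear/attention
#' maps, He-normal for convolutions, zeros for relative-position bias
#' tables), so seed beforehand for reproducible initialisation.
#'
#' @param cfg a [model_config()]
#' @return a `seg_model` object
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  sd_ <- cfg$stage_dims
  enc <- vector("list", 4L)
  for (s in 1:4) {
    in_dim <- if (s == 1L) cfg$stem_dim else sd_[s - 1L]
    units <- vector("list", cfg$encoder_depths[s])
    for (k in seq_len(cfg$encoder_depths[s])) {
      units[[k]] <- new_encoder_unit(cfg, if (k == 1L) in_dim else sd_[s],
                                     sd_[s], down = (k == 1L))
    }
    enc[[s]] <- units
  }
  names(enc) <- paste0("stage", 1:4)

  params <- list(stem = new_stem(cfg$stem_dim, cfg$in_channels), enc = enc)

  if (cfg$skip_mode != "none") {
    params$bottleneck <- new_cbam(cbam_config(sd_[4]))
    skips <- vector("list", 3L)
    for (s in 1:3) {
      if (cfg$skip_mode == "mcbam") {
        c1 <- if (s == 1L) cfg$stem_dim else sd_[s - 1L]
        skips[[s]] <- new_mcbam(sd_[s], c1, sd_[s + 1L])
      } else {
        red <- min(16L, sd_[s])
        skips[[s]] <- new_cbam(cbam_config(sd_[s], reduction = red))
      }
    }
    names(skips) <- paste0("stage", 1:3)
    params$skips <- skips
  }

  dec <- vector("list", 3L)
  for (d in 1:3) {
    s <- 4L - d                           # encoder stage fused at this depth
    dim_in <- sd_[s + 1L]
    dim_out <- sd_[s]
    units <- vector("list", cfg$decoder_depths[d])
    for (k in seq_len(cfg$decoder_depths[d])) {
      units[[k]] <- if (cfg$decoder_mbconv) {
        new_encoder_unit(cfg, dim_out, dim_out, down = FALSE)
      } else {
        list(at = new_maxvit_block(stage_attention_config(cfg, dim_out)))
      }
    }
    dec[[d]] <- list(expand = new_patch_expand(dim_in, 2L),
                     fuse = new_skip_fuse(dim_out, cfg$fuse_mode),
                     units = units)
  }
  names(dec) <- paste0("stage", 1:3)
  params$dec <- dec
  params$final_expand <- new_patch_expand(sd_[1], 4L)
  params$head <- new_linear(sd_[1], cfg$num_classes)

  structure(list(config = cfg, params = params), class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cfg <- x$config
  cat("Multi-axis attention segmentation model\n")
  cat("  input:", cfg$img_size, "x", cfg$img_size, "x", cfg$in_channels,
      " classes:", cfg$num_classes, "\n")
  cat("  stage widths:", paste(cfg$stage_dims, collapse = ", "),
      " encoder depths:", paste(cfg$encoder_depths, collapse = ","), "\n")
  cat("  window/grid:", cfg$window_p, "/", cfg$grid_g,
      " skip:", cfg$skip_mode, " downsampling:", cfg$downsample_mode, "\n")
  cat("  trainable parameters:", format(count_parameters(x), nsmall = 2),
      "M\n")
  invisible(x)
}

#' Count trainable parameters
#' @param model a `seg_model` (or any nested parameter list)
#' @return total trainable scalar count in millions, rounded to 2 decimals
#' @export
count_parameters <- function(model) {
  mod <- if (inherits(model, "seg_model")) model$params else model
  round(n_params(mod) / 1e6, 2)
}

# ---- forward pass ----------------------------------------------------------

fwd_encoder <- function(model, x, st) {
  p <- model$params
  stem_out <- fwd_stem(p$stem, x, st)
  h <- stem_out
  stage_outs <- vector("list", 4L)
  for (s in 1:4) {
    for (unit in p$enc[[s]]) {
      h <- fwd_mbconv(unit$mb, h, st)
      h <- fwd_maxvit(unit$at, h, st)
    }
    stage_outs[[s]] <- h
  }
  list(stem_out = stem_out, stage_outs = stage_outs)
}

skip_features <- function(model, feats, s, st) {
  p <- model$params
  f0 <- feats$stage_outs[[s]]
  switch(model$config$skip_mode,
         mcbam = {
           f1 <- if (s == 1L) feats$stem_out else feats$stage_outs[[s - 1L]]
           fwd_mcbam(p$skips[[s]], f0, f1, feats$stage_outs[[s + 1L]], st)
         },
         cbam = fwd_cbam(p$skips[[s]], f0),
         none = f0)
}

fwd_decoder <- function(model, feats, st) {
  p <- model$params
  h <- feats$stage_outs[[4L]]
  if (model$config$skip_mode != "none") h <- fwd_cbam(p$bottleneck, h)
  for (d in 1:3) {
    s <- 4L - d
    h <- fwd_patch_expand(p$dec[[d]]$expand, h)
    h <- fwd_skip_fuse(p$dec[[d]]$fuse, h, skip_features(model, feats, s, st))
    for (unit in p$dec[[d]]$units) {
      if (!is.null(unit$mb)) h <- fwd_mbconv(unit$mb, h, st)
      h <- fwd_maxvit(unit$at, h, st)
    }
  }
  h <- fwd_patch_expand(p$final_expand, h)
  dh <- dim(val(h))
  tok <- ag_reshape(h, c(dh[1] * dh[2] * dh[3], dh[4]))
  logits <- fwd_linear(p$head, tok)
  ag_reshape(logits, c(dh[1], dh[2], dh[3], model$config$num_classes))
}

fwd_model <- function(model, x, st) {
  d <- dim(val(x))
  cfg <- model$config
  if (d[2] != cfg$img_size || d[3] != cfg$img_size || d[4] != cfg$in_channels) {
    stop("input shape ", paste(d[-1], collapse = "x"),
         " does not match the configured ", cfg$img_size, "x", cfg$img_size,
         "x", cfg$in_channels)
  }
  fwd_decoder(model, fwd_encoder(model, x, st), st)
}

as_batch <- function(images) {
  if (length(dim(images)) == 3L) array(images, c(1L, dim(images)))
  else images
}

#' Encoder features for one image
#' @param model a `seg_model`
#' @param image numeric array (H, W, C)
#' @param train logical; batch-norm mode
#' @return list with `stem_out` (H/2 extent) and `stage_outs` (extents H/4,
#'   H/8, H/16, H/32 with the configured stage widths)
#' @export
encoder_forward <- function(model, image, train = FALSE) {
  st <- list(train = train)
  f <- fwd_encoder(model, as_batch(as_hwc(image)), st)
  squeeze <- function(a) { v <- val(a); array(v, dim(v)[2:4]) }
  list(stem_out = squeeze(f$stem_out),
       stage_outs = lapply(f$stage_outs, squeeze))
}

#' Full forward pass: image(s) to per-pixel class logits
#' @param model a `seg_model`
#' @param images numeric array (H, W, C) or batch (N, H, W, C)
#' @param train logical; batch-norm mode
#' @return logits array matching the input layout, with `num_classes`
#'   channels at the input resolution
#' @export
predict_logits <- function(model, images, train = FALSE) {
  single <- length(dim(images)) == 3L
  out <- val(fwd_model(model, as_batch(images), list(train = train)))
  if (single) array(out, dim(out)[2:4]) else out
}

#' Predict an integer label map
#' @param model a `seg_model`
#' @param image numeric array (H, W, C)
#' @return integer matrix (H, W) of class labels in `[0, num_classes)`
#' @export
predict_labels <- function(model, image) {
  lg <- predict_logits(model, as_hwc(image))
  d <- dim(lg)
  matrix(max.col(matrix(lg, ncol = d[3]), ties.method = "first") - 1L,
         d[1], d[2])
}

# ---- checkpoints -----------------------------------------------------------

#' Save model weights and configuration
#'
#' Writes an RDS checkpoint containing the configuration, every trainable
#' parameter, every buffer (batch-norm running statistics) and a digest of
#' the configuration for compatibility checking on load.
#'
#' @param model a `seg_model`
#' @param path file path
#' @param extra optional named list stored alongside (e.g. optimiser state)
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  ps <- lapply(collect_params(model$params), function(p) p$v)
  bs <- lapply(collect_buffers(model$params), function(b) b$v)
  obj <- list(config = model$config, params = ps, buffers = bs,
              digest = digest::digest(model$config), extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model from a checkpoint
#' @param path file path written by [save_checkpoint()]
#' @return a `seg_model` with restored weights; the stored `extra` list is
#'   attached as attribute `"extra"`
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$digest, digest::digest(obj$config))) {
    stop("checkpoint configuration digest mismatch; file is corrupt")
  }
  model <- build_model(obj$config)
  ps <- collect_params(model$params)
  if (!setequal(names(ps), names(obj$params))) {
    stop("checkpoint parameter set does not match the configuration")
  }
  for (nm in names(ps)) {
    stopifnot(length(ps[[nm]]$v) == length(obj$params[[nm]]))
    ps[[nm]]$v <- obj$params[[nm]]
  }
  bs <- collect_buffers(model$params)
  for (nm in names(bs)) bs[[nm]]$v <- obj$buffers[[nm]]
  attr(model, "extra") <- obj$extra
  model
}
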