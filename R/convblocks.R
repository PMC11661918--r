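# Inverted-bottleneck convolution blocks (MBConv) with squeeze-excitation,
# their stride-2 downsampling variant, and the convolutional stem.
#
# MBConv (no downsampling, channels preserved):
#   x + Proj(SE(DWConv(Conv(Norm(x)))))
# where Norm is BatchNorm, Conv is a 1x1 expansion (+BN+GELU), DWConv a 3x3
# depthwise convolution (+BN+GELU), SE a channel-gating bottleneck, and Proj
# a 1x1 projection back to the input width (no activation after Proj).
#
# The downsampling variant uses a stride-2 depthwise convolution in the main
# branch and pairs it with a pooled, 1x1-projected shortcut:
#   Proj(Pool2D(x)) + Proj(SE(DWConv_s2(Conv(Norm(x)))))

#' MBConv block configuration
#'
#' @param in_dim input channels
#' @param out_dim output channels (must equal `in_dim` unless `downsample`)
#' @param expansion pointwise expansion factor of the inverted bottleneck
#' @param se_ratio squeeze-excitation bottleneck fraction (of the expanded
#'   width)
#' @param downsample logical; stride-2 variant with pooled shortcut
#' @return an `mbconv_config` object
#' @export
mbconv_config <- function(in_dim, out_dim = in_dim, expansion = 4,
                          se_ratio = 0.25, downsample = FALSE) {
  stopifnot(expansion >= 1, se_ratio > 0, se_ratio <= 1)
  if (!downsample && in_dim != out_dim) {
    stop("non-downsampling MBConv requires in_dim == out_dim (residual add)")
  }
  structure(list(in_dim = as.integer(in_dim), out_dim = as.integer(out_dim),
                 expansion = expansion, se_ratio = se_ratio,
                 downsample = isTRUE(downsample)),
            class = "mbconv_config")
}

#' Construct a squeeze-excitation layer
#'
#' Channel gating: a globally average-pooled descriptor is passed through a
#' bottleneck (reduce by `se_ratio`, ReLU, expand, sigmoid), and the
#' resulting per-channel gate in (0, 1) rescales the input map.
#'
#' @param channels input channel count
#' @param se_ratio bottleneck fraction
#' @return an SE module
#' @export
new_se <- function(channels, se_ratio = 0.25) {
  hidden <- max(1L, as.integer(round(channels * se_ratio)))
  list(fc1 = new_linear(channels, hidden, init = "he"),
       fc2 = new_linear(hidden, channels, init = "he"))
}

fwd_se <- function(p, x) {
  pooled <- ag_global_avgpool(x)                       # (N, C)
  gate <- ag_sigmoid(fwd_linear(p$fc2, ag_relu(fwd_linear(p$fc1, pooled))))
  ag_mul_channel(x, gate)
}

#' Apply a squeeze-excitation layer to a feature map
#' @param se module from [new_se()]
#' @param x numeric array (H, W, C)
#' @return gated array of the same shape
#' @export
se_forward <- function(se, x) {
  x <- as_hwc(x)
  d <- dim(x)
  array(val(fwd_se(se, array(x, c(1, d)))), d)
}

#' Construct an MBConv block
#' @param cfg an [mbconv_config()]
#' @param plain if `TRUE`, replace the whole block by a single 3x3
#'   convolution (stride 2 when downsampling) - the plain-convolution
#'   ablation of the downsampling path
#' @return an MBConv module
#' @export
new_mbconv <- function(cfg, plain = FALSE) {
  stopifnot(inherits(cfg, "mbconv_config"))
  if (plain) {
    return(list(cfg = cfg, plain = TRUE,
                conv = new_conv(3, 3, cfg$in_dim, cfg$out_dim),
                bn = new_bn(cfg$out_dim)))
  }
  e <- as.integer(round(cfg$in_dim * cfg$expansion))
  m <- list(cfg = cfg, plain = FALSE,
            bn0 = new_bn(cfg$in_dim),
            conv1 = new_conv(1, 1, cfg$in_dim, e),
            bn1 = new_bn(e),
            dw = new_dwconv(3, e),
            bn2 = new_bn(e),
            se = new_se(e, cfg$se_ratio),
            proj = new_conv(1, 1, e, cfg$out_dim))
  if (cfg$downsample) m$short <- new_conv(1, 1, cfg$in_dim, cfg$out_dim)
  m
}

fwd_mbconv <- function(p, x, st) {
  cfg <- p$cfg
  d <- dim(val(x))
  if (cfg$downsample && (d[2] %% 2 != 0 || d[3] %% 2 != 0)) {
    stop("downsampling MBConv requires even spatial extents, got ",
         d[2], " x ", d[3])
  }
  if (d[4] != cfg$in_dim) {
    stop("channel mismatch: expected ", cfg$in_dim, ", got ", d[4])
  }
  if (isTRUE(p$plain)) {
    s <- if (cfg$downsample) 2L else 1L
    h <- ag_conv2d(x, p$conv$w, p$conv$b, stride = s, pad = 1L)
    return(ag_gelu(fwd_bn(p$bn, h, st)))
  }
  h <- fwd_bn(p$bn0, x, st)
  h <- ag_gelu(fwd_bn(p$bn1, ag_conv2d(h, p$conv1$w, p$conv1$b), st))
  s <- if (cfg$downsample) 2L else 1L
  h <- ag_gelu(fwd_bn(p$bn2, ag_dwconv2d(h, p$dw$w, p$dw$b,
                                         stride = s, pad = 1L), st))
  h <- fwd_se(p$se, h)
  h <- ag_conv2d(h, p$proj$w, p$proj$b)
  if (cfg$downsample) {
    sc <- ag_conv2d(ag_avgpool2(x), p$short$w, p$short$b)
    ag_add(sc, h)
  } else {
    ag_add(x, h)
  }
}

#' Apply an MBConv block to a single feature map
#' @param mb module from [new_mbconv()]
#' @param x numeric array (H, W, C)
#' @param train logical; batch-norm mode (frozen statistics when `FALSE`)
#' @return output array; same extent, or halved extent for the
#'   downsampling variant
#' @export
mbconv_forward <- function(mb, x, train = FALSE) {
  x <- as_hwc(x)
  d <- dim(x)
  out <- val(fwd_mbconv(mb, array(x, c(1, d)), list(train = train)))
  array(out, dim(out)[2:4])
}

#' Construct the convolutional stem
#'
#' Splits the input image into half-resolution patch features: a 3x3 stride-2
#' convolution to `out_dim` channels (+BN+GELU) followed by a 3x3 stride-1
#' convolution. (H, W, 3) -> (H/2, W/2, out_dim).
#'
#' @param out_dim stem width (64 in the base model)
#' @param in_channels input image channels (3)
#' @return a stem module
#' @export
new_stem <- function(out_dim = 64L, in_channels = 3L) {
  list(conv1 = new_conv(3, 3, in_channels, out_dim),
       bn1 = new_bn(out_dim),
       conv2 = new_conv(3, 3, out_dim, out_dim),
       out_dim = as.integer(out_dim))
}

fwd_stem <- function(p, x, st) {
  d <- dim(val(x))
  if (d[2] %% 2 != 0 || d[3] %% 2 != 0) {
    stop("stem requires even image extents, got ", d[2], " x ", d[3])
  }
  h <- ag_conv2d(x, p$conv1$w, p$conv1$b, stride = 2L, pad = 1L)
  h <- ag_gelu(fwd_bn(p$bn1, h, st))
  ag_conv2d(h, p$conv2$w, p$conv2$b, stride = 1L, pad = 1L)
}

#' Apply the stem to an image
#' @param stem module from [new_stem()]
#' @param x numeric array (H, W, 3)
#' @param train logical; batch-norm mode
#' @return array (H/2, W/2, out_dim)
#' @export
stem_forward <- function(stem, x, train = FALSE) {
  x <- as_hwc(x)
  d <- dim(x)
  out <- val(fwd_stem(stem, array(x, c(1, d)), list(train = train)))
  array(out, dim(out)[2:4])
}
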