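# Attention gating of feature maps.
#
# CBAM applies two sequential gates to a map F:
#   channel gate  Mc = sigmoid(MLP(AvgPool(F)) + MLP(MaxPool(F)))  (shared MLP,
#                 ReLU after the first layer),          F'  = Mc (x) F
#   spatial gate  Ms = sigmoid(conv7x7([AvgPoolC; MaxPoolC](F'))), F'' = Ms (x) F'
#
# MCBAM is the multi-scale variant used on skip connections: the channel gate
# is computed from the *deeper* encoder stage F2 (2*C0 channels at half
# resolution), the spatial gate from the *shallower* stage F1 (double
# resolution), and both gates are applied to the current stage's features F0:
#   F0'' = Ms(F1) (x) (Mc(F2) (x) F0)

#' CBAM configuration
#' @param channels feature channels C
#' @param reduction bottleneck reduction r of the shared channel MLP
#' @param spatial_kernel odd kernel size of the spatial-attention convolution
#' @return a `cbam_config` object
#' @export
cbam_config <- function(channels, reduction = 16L, spatial_kernel = 7L) {
  stopifnot(channels >= 1, reduction >= 1, spatial_kernel %% 2 == 1)
  if (channels %% reduction != 0) {
    stop("channels (", channels, ") must be divisible by reduction (",
         reduction, ")")
  }
  structure(list(channels = as.integer(channels),
                 reduction = as.integer(reduction),
                 spatial_kernel = as.integer(spatial_kernel)),
            class = "cbam_config")
}

#' Construct a CBAM gate
#' @param cfg a [cbam_config()]
#' @return a CBAM module
#' @export
new_cbam <- function(cfg) {
  stopifnot(inherits(cfg, "cbam_config"))
  cc <- cfg$channels
  hidden <- cc %/% cfg$reduction
  k <- cfg$spatial_kernel
  list(cfg = cfg,
       fc1 = new_linear(cc, hidden, init = "he"),
       fc2 = new_linear(hidden, cc, init = "he"),
       sconv = new_conv(k, k, 2L, 1L))
}

ag_cbam_channel <- function(p, x) {
  mlp <- function(d) fwd_linear(p$fc2, ag_relu(fwd_linear(p$fc1, d)))
  ag_sigmoid(ag_add(mlp(ag_global_avgpool(x)), mlp(ag_global_maxpool(x))))
}

ag_cbam_spatial <- function(p, x) {
  pooled <- ag_channel_meanmax(x)                      # (N,H,W,2)
  k <- p$cfg$spatial_kernel
  m <- ag_conv2d(pooled, p$sconv$w, p$sconv$b, pad = (k - 1L) %/% 2L)
  d <- dim(val(m))
  ag_sigmoid(ag_reshape(m, d[1:3]))                    # (N,H,W)
}

fwd_cbam <- function(p, x) {
  x1 <- ag_mul_channel(x, ag_cbam_channel(p, x))
  ag_mul_spatial(x1, ag_cbam_spatial(p, x1))
}

#' Channel-attention gate of a CBAM
#' @param cb module from [new_cbam()]
#' @param x numeric array (H, W, C)
#' @return numeric vector of length C with values in (0, 1)
#' @export
channel_attention <- function(cb, x) {
  x <- as_hwc(x)
  as.vector(val(ag_cbam_channel(cb, array(x, c(1, dim(x))))))
}

#' Spatial-attention gate of a CBAM
#' @param cb module from [new_cbam()]
#' @param x numeric array (H, W, C)
#' @return an (H, W) matrix with values in (0, 1)
#' @export
spatial_attention <- function(cb, x) {
  x <- as_hwc(x)
  d <- dim(x)
  matrix(val(ag_cbam_spatial(cb, array(x, c(1, d)))), d[1], d[2])
}

#' Apply CBAM gating (channel gate, then spatial gate)
#' @param cb module from [new_cbam()]
#' @param x numeric array (H, W, C)
#' @return gated array of the same shape
#' @export
cbam_forward <- function(cb, x) {
  x <- as_hwc(x)
  d <- dim(x)
  array(val(fwd_cbam(cb, array(x, c(1, d)))), d)
}

# ---- multi-scale CBAM ------------------------------------------------------

#' Construct a multi-scale attention gate for one skip connection
#'
#' @param c0 channels of the current stage (gated features F0)
#' @param c1 channels of the shallower stage F1 (at twice the resolution)
#' @param c2 channels of the deeper stage F2; must equal `2 * c0`
#' @param spatial_kernel kernel size of the shallow-branch convolution
#'   (applied with stride 2 so the map lands at F0's resolution)
#' @param shared if `TRUE` (default) the two pooled descriptors of F2 share
#'   one C2 -> C0 transform, mirroring CBAM's shared MLP
#' @return an MCBAM module
#' @export
new_mcbam <- function(c0, c1, c2, spatial_kernel = 7L, shared = TRUE) {
  if (c2 != 2L * c0) {
    stop("deep features must have 2*c0 channels (got c2 = ", c2,
         ", c0 = ", c0, ")")
  }
  k <- as.integer(spatial_kernel)
  m <- list(c0 = as.integer(c0), c1 = as.integer(c1), c2 = as.integer(c2),
            k = k, shared = isTRUE(shared),
            chconv = new_linear(c2, c0, init = "he"),
            sconv = new_conv(k, k, c1, 1L),
            sbn = new_bn(1L))
  if (!m$shared) m$chconv2 <- new_linear(c2, c0, init = "he")
  m
}

ag_mcbam_channel <- function(p, f2) {
  d <- dim(val(f2))
  if (d[4] != p$c2) stop("deep features have ", d[4], " channels, expected ", p$c2)
  a <- fwd_linear(p$chconv, ag_global_avgpool(f2))
  mx <- fwd_linear(if (p$shared) p$chconv else p$chconv2, ag_global_maxpool(f2))
  ag_sigmoid(ag_add(a, mx))                            # (N, C0)
}

ag_mcbam_spatial <- function(p, f1, h0, w0, st) {
  d <- dim(val(f1))
  if (d[2] != 2L * h0 || d[3] != 2L * w0) {
    stop("shallow features must be at twice the target resolution (got ",
         d[2], " x ", d[3], ", target ", h0, " x ", w0, ")")
  }
  m <- ag_conv2d(f1, p$sconv$w, p$sconv$b, stride = 2L, pad = (p$k - 1L) %/% 2L)
  m <- fwd_bn(p$sbn, m, st)
  dm <- dim(val(m))
  ag_sigmoid(ag_reshape(m, dm[1:3]))                   # (N, H0, W0)
}

fwd_mcbam <- function(p, f0, f1, f2, st) {
  d0 <- dim(val(f0))
  f0c <- ag_mul_channel(f0, ag_mcbam_channel(p, f2))
  ag_mul_spatial(f0c, ag_mcbam_spatial(p, f1, d0[2], d0[3], st))
}

#' Channel gate of a multi-scale attention module
#'
#' Pools the deeper stage's map to two C2-channel descriptors (average and
#' max), maps both to C0 channels with a shared 1x1 transform, sums and
#' squashes: the result gates the current stage's channels.
#'
#' @param m module from [new_mcbam()]
#' @param f2 deeper-stage features (H0/2, W0/2, 2*C0)
#' @return numeric vector of length C0, values in (0, 1)
#' @export
mcbam_channel_map <- function(m, f2) {
  f2 <- as_hwc(f2)
  as.vector(val(ag_mcbam_channel(m, array(f2, c(1, dim(f2))))))
}

#' Spatial gate of a multi-scale attention module
#'
#' Re-extracts the shallower stage's map with a stride-2 convolution to a
#' single channel at the current stage's resolution, batch-normalises and
#' squashes it.
#'
#' @param m module from [new_mcbam()]
#' @param f1 shallower-stage features (2*H0, 2*W0, C1)
#' @param h0,w0 target extent
#' @param train logical; batch-norm mode
#' @return an (H0, W0) matrix with values in (0, 1)
#' @export
mcbam_spatial_map <- function(m, f1, h0, w0, train = FALSE) {
  f1 <- as_hwc(f1)
  v <- val(ag_mcbam_spatial(m, array(f1, c(1, dim(f1))), h0, w0,
                            list(train = train)))
  matrix(v, h0, w0)
}

#' Apply multi-scale gating to the current stage's features
#'
#' `F0'' = Ms(F1) (x) (Mc(F2) (x) F0)`: channel gate from the deeper stage,
#' spatial gate from the shallower stage, both applied multiplicatively.
#'
#' @param m module from [new_mcbam()]
#' @param f0 current-stage features (H0, W0, C0)
#' @param f1 shallower-stage features (2*H0, 2*W0, C1)
#' @param f2 deeper-stage features (H0/2, W0/2, 2*C0)
#' @param train logical; batch-norm mode
#' @return gated array with F0's shape
#' @export
mcbam_forward <- function(m, f0, f1, f2, train = FALSE) {
  f0 <- as_hwc(f0); f1 <- as_hwc(f1); f2 <- as_hwc(f2)
  d <- dim(f0)
  v <- val(fwd_mcbam(m, array(f0, c(1, d)), array(f1, c(1, dim(f1))),
                     array(f2, c(1, dim(f2))), list(train = train)))
  array(v, d)
}
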