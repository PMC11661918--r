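# Multi-axis self-attention primitives: block (local window) and grid
# (dilated global) partitioning, windowed relative-position attention, and
# the two-stage attention block that applies them in sequence.
#
# Layout conventions: a single feature map is (H, W, C); batched internal
# tensors are (N, H, W, C). A partition rearranges a map into groups of
# tokens; within a group tokens are ordered row-major (column index fastest),
# and block groups are ordered row-major over tiles.

#' Attention configuration
#'
#' Holds the geometry of the two windowed attention stages: `window_p` is the
#' local tile size P (attention within non-overlapping P x P tiles), and
#' `grid_g` the global grid size G (attention across a dilated G x G lattice:
#' tokens sharing the same intra-cell offset attend to one another).
#'
#' @param dim channels per token
#' @param head_dim channels per attention head (`dim` must be a multiple)
#' @param window_p local block partition size P
#' @param grid_g global grid partition size G
#' @param mlp_ratio hidden-width expansion of the position-wise feed-forward
#' @return an `attention_config` object
#' @export
attention_config <- function(dim, head_dim = 32L, window_p = 7L, grid_g = 7L,
                             mlp_ratio = 4) {
  stopifnot(dim >= 1, head_dim >= 1, window_p >= 1, grid_g >= 1, mlp_ratio > 0)
  if (dim %% head_dim != 0) {
    stop("dim (", dim, ") must be a multiple of head_dim (", head_dim, ")")
  }
  structure(list(dim = as.integer(dim), head_dim = as.integer(head_dim),
                 num_heads = as.integer(dim %/% head_dim),
                 window_p = as.integer(window_p), grid_g = as.integer(grid_g),
                 mlp_ratio = mlp_ratio),
            class = "attention_config")
}

check_divisible <- function(h, w, p, what) {
  if (h %% p != 0 || w %% p != 0) {
    stop("feature extent (", h, " x ", w, ") is not divisible by the ",
         what, " size ", p, "; no implicit padding is performed")
  }
}

# ---- batched partition ops (differentiable) --------------------------------

# (N,H,W,C) -> (p^2, N*(H/p)*(W/p), C); groups ordered (N, tile-col, tile-row)
ag_block_part <- function(x, p) {
  d <- dim(val(x))
  n <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  check_divisible(h, w, p, "block window")
  x6 <- ag_reshape(x, c(n, p, h %/% p, p, w %/% p, cc))
  xp <- ag_aperm(x6, c(4, 2, 1, 5, 3, 6))
  ag_reshape(xp, c(p * p, n * (h %/% p) * (w %/% p), cc))
}

ag_block_unpart <- function(wnd, n, h, w, cc, p) {
  x6 <- ag_reshape(wnd, c(p, p, n, w %/% p, h %/% p, cc))
  xp <- ag_aperm(x6, c(3, 2, 5, 1, 4, 6))
  ag_reshape(xp, c(n, h, w, cc))
}

# (N,H,W,C) -> (g^2, N*(H/g)*(W/g), C); tokens strided by (H/g, W/g)
ag_grid_part <- function(x, g) {
  d <- dim(val(x))
  n <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  check_divisible(h, w, g, "grid")
  x6 <- ag_reshape(x, c(n, h %/% g, g, w %/% g, g, cc))
  xp <- ag_aperm(x6, c(5, 3, 1, 4, 2, 6))
  ag_reshape(xp, c(g * g, n * (h %/% g) * (w %/% g), cc))
}

ag_grid_unpart <- function(wnd, n, h, w, cc, g) {
  x6 <- ag_reshape(wnd, c(g, g, n, w %/% g, h %/% g, cc))
  xp <- ag_aperm(x6, c(3, 5, 2, 4, 1, 6))
  ag_reshape(xp, c(n, h, w, cc))
}

# ---- public partition API --------------------------------------------------

new_window_set <- function(windows, origin_shape, kind, size) {
  structure(list(windows = windows, origin_shape = origin_shape,
                 kind = kind, size = as.integer(size)),
            class = "window_set")
}

as_hwc <- function(x) {
  if (length(dim(x)) != 3) stop("expected an (H, W, C) array")
  x
}

#' Partition a feature map into non-overlapping P x P blocks
#'
#' Tiles the map into `(H/p) * (W/p)` groups of `p^2` tokens. Groups are in
#' row-major tile order and tokens are row-major within each tile, so local
#' attention within a group sees one contiguous spatial window.
#'
#' @param x numeric array (H, W, C)
#' @param p window size; H and W must be divisible by `p`
#' @return a `window_set` with `windows` of shape (groups, p^2, C)
#' @export
block_partition <- function(x, p) {
  x <- as_hwc(x)
  d <- dim(x)
  check_divisible(d[1], d[2], p, "block window")
  x4 <- array(x, c(1, d))
  wnd <- ag_block_part(x4, p)          # (p^2, nG, C) since N = 1
  new_window_set(aperm(wnd, c(2, 1, 3)), d, "block", p)
}

#' Reverse a block partition
#' @param w a `window_set` produced by [block_partition()]
#' @return the original (H, W, C) array
#' @export
unblock <- function(w) {
  stopifnot(inherits(w, "window_set"))
  if (w$kind != "block") stop("window_set was not produced by block_partition")
  d <- w$origin_shape
  p <- w$size
  dw <- dim(w$windows)
  if (dw[1] * dw[2] != d[1] * d[2] || dw[3] != d[3]) {
    stop("window_set is inconsistent with its origin_shape")
  }
  wnd <- aperm(w$windows, c(2, 1, 3))
  x4 <- ag_block_unpart(wnd, 1L, d[1], d[2], d[3], p)
  array(x4, d)
}

#' Partition a feature map into a dilated G x G grid
#'
#' Splits H into (G, H/G) and W into (G, W/G) and groups together the tokens
#' that share the same intra-cell offset: each of the `(H/G) * (W/G)` groups
#' holds `G^2` tokens sampled at stride (H/G, W/G) across the whole map, which
#' is what makes grid attention global.
#'
#' @param x numeric array (H, W, C)
#' @param g grid size; H and W must be divisible by `g`
#' @return a `window_set` with `windows` of shape (groups, g^2, C)
#' @export
grid_partition <- function(x, g) {
  x <- as_hwc(x)
  d <- dim(x)
  check_divisible(d[1], d[2], g, "grid")
  x4 <- array(x, c(1, d))
  wnd <- ag_grid_part(x4, g)
  new_window_set(aperm(wnd, c(2, 1, 3)), d, "grid", g)
}

#' Reverse a grid partition
#' @param w a `window_set` produced by [grid_partition()]
#' @return the original (H, W, C) array
#' @export
ungrid <- function(w) {
  stopifnot(inherits(w, "window_set"))
  if (w$kind != "grid") stop("window_set was not produced by grid_partition")
  d <- w$origin_shape
  g <- w$size
  dw <- dim(w$windows)
  if (dw[1] * dw[2] != d[1] * d[2] || dw[3] != d[3]) {
    stop("window_set is inconsistent with its origin_shape")
  }
  wnd <- aperm(w$windows, c(2, 1, 3))
  x4 <- ag_grid_unpart(wnd, 1L, d[1], d[2], d[3], g)
  array(x4, d)
}

#' Shape of the attention problem for one partition
#'
#' Book-keeping for the linear-complexity property: however large the map,
#' attention is computed within groups, so the largest materialised attention
#' matrix is `p^2 x p^2`.
#'
#' @param h,w feature extents
#' @param p window (or grid) size
#' @return named vector with `groups` and `tokens` (= p^2)
#' @export
attention_group_shape <- function(h, w, p) {
  check_divisible(h, w, p, "partition")
  c(groups = (h %/% p) * (w %/% p), tokens = p * p)
}

# ---- relative positional bias ----------------------------------------------

# Column-major (i, j) map from token-pair to offset slot; n = p^2 tokens,
# (2p-1)^2 distinct 2D offsets.
relative_bias_index <- function(p) {
  n <- p * p
  tok_row <- rep(seq_len(p), each = p)   # token order: column fastest
  tok_col <- rep(seq_len(p), times = p)
  di <- outer(tok_row, tok_row, "-")     # (i, j): row offset token i - token j
  dj <- outer(tok_col, tok_col, "-")
  idx <- (di + p - 1L) * (2L * p - 1L) + (dj + p)
  matrix(as.integer(idx), n, n)
}

#' Expand a relative-position bias table into per-pair bias matrices
#'
#' The learnable table has one entry per 2D relative offset between tokens in
#' a `p x p` window, i.e. `(2p-1)^2` entries per head. Entry (i, j) of the
#' returned matrix depends only on the spatial offset between tokens i and j,
#' so, in particular, all diagonal entries share the zero-offset slot.
#'
#' @param table numeric vector of length `(2p-1)^2`, or a matrix with one
#'   column per head
#' @param p window size
#' @return an `(p^2, p^2)` matrix, or an `(p^2, p^2, heads)` array
#' @export
relative_bias_matrix <- function(table, p) {
  need <- (2L * p - 1L)^2
  idx <- relative_bias_index(p)
  if (is.matrix(table)) {
    if (nrow(table) != need) {
      stop("bias table must have ", need, " rows for window size ", p)
    }
    out <- array(0, c(p * p, p * p, ncol(table)))
    for (h in seq_len(ncol(table))) out[, , h] <- table[idx, h]
    out
  } else {
    if (length(table) != need) {
      stop("bias table must have ", need, " entries for window size ", p)
    }
    matrix(table[idx], p * p, p * p)
  }
}

# ---- attention core --------------------------------------------------------

# tok: (n * Gstar, dim) token matrix (token index fastest); returns same
# shape. Heads are folded into the batch dimension of the grouped matmuls,
# so one attention call costs a constant number of array operations
# regardless of the head count.
attn_core <- function(p_attn, tok, n, gstar, st = NULL) {
  dim_ <- p_attn$dim
  hd <- p_attn$head_dim
  heads <- dim_ %/% hd
  b <- gstar * heads
  qkv <- fwd_linear(p_attn$qkv, tok)
  split_heads <- function(m) {
    a <- ag_reshape(m, c(n, gstar, hd, heads))
    ag_reshape(ag_aperm(a, c(2, 4, 1, 3)), c(b, n, hd))
  }
  q <- split_heads(ag_slice_cols(qkv, seq_len(dim_)))
  k <- split_heads(ag_slice_cols(qkv, dim_ + seq_len(dim_)))
  v <- split_heads(ag_slice_cols(qkv, 2L * dim_ + seq_len(dim_)))
  s <- ag_bmm(ag_scale(q, 1 / sqrt(hd)), ag_aperm(k, c(1, 3, 2)))
  s <- ag_rel_bias_add_mh(s, p_attn$table, p_attn$idx, gstar, heads)
  w <- ag_reshape(ag_softmax_rows(ag_reshape(s, c(b * n, n))), c(b, n, n))
  o <- ag_bmm(w, v)                                    # (b, n, hd)
  o <- ag_reshape(o, c(gstar, heads, n, hd))
  o <- ag_reshape(ag_aperm(o, c(3, 1, 4, 2)), c(n * gstar, dim_))
  fwd_linear(p_attn$proj, o)
}

#' Windowed self-attention with relative positional bias
#'
#' Single-group multi-head attention
#' `softmax(Q K' / sqrt(d) + B) V`, where the additive bias B is looked up
#' from `table` by the 2D offset between token pairs. Heads are formed by
#' splitting the channel dimension, attended independently, concatenated and
#' (optionally) linearly projected.
#'
#' @param q,k,v token matrices (n x dim), n a perfect square (p^2)
#' @param table optional bias table: vector `(2p-1)^2` (shared by heads) or a
#'   matrix with one column per head; `NULL` means zero bias
#' @param head_dim channels per head; `d = head_dim` is the softmax scaling
#' @param proj optional list(w, b) output projection; `NULL` returns the
#'   concatenated head outputs unprojected
#' @return an (n x dim) matrix
#' @export
relative_attention <- function(q, k, v, table = NULL, head_dim = ncol(q),
                               proj = NULL) {
  stopifnot(is.matrix(q), all(dim(q) == dim(k)), all(dim(q) == dim(v)))
  if (anyNA(q) || anyNA(k) || anyNA(v)) stop("NaN/NA values in attention inputs")
  n <- nrow(q)
  dim_ <- ncol(q)
  p <- as.integer(round(sqrt(n)))
  if (p * p != n) stop("token count must be a perfect square (p^2)")
  if (dim_ %% head_dim != 0) stop("dim must be a multiple of head_dim")
  heads <- dim_ %/% head_dim
  idx <- relative_bias_index(p)
  if (is.null(table)) {
    tabm <- matrix(0, (2L * p - 1L)^2, heads)
  } else if (is.matrix(table)) {
    stopifnot(ncol(table) == heads)
    tabm <- table
  } else {
    tabm <- matrix(rep(table, heads), ncol = heads)
  }
  scale <- 1 / sqrt(head_dim)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * head_dim + seq_len(head_dim)
    qh <- q[, cols, drop = FALSE] * scale
    kh <- k[, cols, drop = FALSE]
    vh <- v[, cols, drop = FALSE]
    s <- qh %*% t(kh) + matrix(tabm[idx, h], n, n)
    s <- s - apply(s, 1L, max)
    e <- exp(s)
    w <- e / rowSums(e)
    outs[[h]] <- w %*% vh
  }
  out <- do.call(cbind, outs)
  if (!is.null(proj)) out <- out %*% proj$w + rep(proj$b, each = n)
  out
}

#' Position-wise feed-forward network
#'
#' Two linear maps with a GELU non-linearity in between, applied to every
#' token independently: `W2 GELU(W1 x)`.
#'
#' @param x token matrix (n x dim)
#' @param w1,b1 first linear map (dim -> hidden)
#' @param w2,b2 second linear map (hidden -> dim)
#' @return token matrix of the same shape as `x`
#' @export
ffn <- function(x, w1, b1, w2, b2) {
  h <- val(ag_gelu(x %*% w1 + rep(b1, each = nrow(x))))
  h %*% w2 + rep(b2, each = nrow(x))
}

# ---- attention layers ------------------------------------------------------

new_attention_layer <- function(dim, win, head_dim, mlp_ratio) {
  if (dim %% head_dim != 0) stop("dim must be a multiple of head_dim")
  heads <- dim %/% head_dim
  hidden <- as.integer(round(dim * mlp_ratio))
  list(ln1 = new_ln(dim),
       qkv = new_linear(dim, 3L * dim),
       proj = new_linear(dim, dim),
       table = ag_param(matrix(0, (2L * win - 1L)^2, heads)),
       ln2 = new_ln(dim),
       ffn1 = new_linear(dim, hidden),
       ffn2 = new_linear(hidden, dim),
       dim = dim, head_dim = head_dim, win = as.integer(win),
       idx = as.integer(relative_bias_index(win)))
}

# One pre-norm attention stage with its FFN, on (N,H,W,C):
#   x <- x + Unpart(RelAttention(Part(LN(x))))
#   x <- x + MLP(LN(x))
fwd_attention_layer <- function(p, x, kind, st = NULL) {
  d <- dim(val(x))
  n <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  win <- p$win
  wnd <- if (kind == "block") ag_block_part(x, win) else ag_grid_part(x, win)
  ntok <- win * win
  gstar <- n * (h %/% win) * (w %/% win)
  tok <- ag_reshape(wnd, c(ntok * gstar, cc))
  a <- attn_core(p, fwd_ln(p$ln1, tok), ntok, gstar, st)
  a <- ag_reshape(a, c(ntok, gstar, cc))
  back <- if (kind == "block") {
    ag_block_unpart(a, n, h, w, cc, win)
  } else {
    ag_grid_unpart(a, n, h, w, cc, win)
  }
  x <- ag_add(x, back)
  tok2 <- ag_reshape(x, c(n * h * w, cc))
  f <- fwd_linear(p$ffn2, ag_gelu(fwd_linear(p$ffn1, fwd_ln(p$ln2, tok2))))
  ag_add(x, ag_reshape(f, d))
}

#' Construct a two-stage multi-axis attention block
#'
#' The block applies local windowed attention (tile size P) followed by
#' global dilated grid attention (grid size G), each with its own
#' pre-normalisation, relative-position bias table and feed-forward network.
#'
#' @param cfg an [attention_config()]
#' @return a module usable with [maxvit_forward()]
#' @export
new_maxvit_block <- function(cfg) {
  stopifnot(inherits(cfg, "attention_config"))
  list(block = new_attention_layer(cfg$dim, cfg$window_p, cfg$head_dim,
                                   cfg$mlp_ratio),
       grid = new_attention_layer(cfg$dim, cfg$grid_g, cfg$head_dim,
                                  cfg$mlp_ratio))
}

fwd_maxvit <- function(p, x, st = NULL) {
  x <- fwd_attention_layer(p$block, x, "block", st)
  fwd_attention_layer(p$grid, x, "grid", st)
}

#' Apply the local block-attention stage of a multi-axis block
#' @param layer the `$block` component of [new_maxvit_block()]
#' @param x numeric array (H, W, C)
#' @return array of the same shape
#' @export
block_attention_forward <- function(layer, x) {
  x <- as_hwc(x)
  d <- dim(x)
  array(val(fwd_attention_layer(layer, array(x, c(1, d)), "block")), d)
}

#' Apply the global grid-attention stage of a multi-axis block
#' @param layer the `$grid` component of [new_maxvit_block()]
#' @param x numeric array (H, W, C)
#' @return array of the same shape
#' @export
grid_attention_forward <- function(layer, x) {
  x <- as_hwc(x)
  d <- dim(x)
  array(val(fwd_attention_layer(layer, array(x, c(1, d)), "grid")), d)
}

#' Run a full multi-axis attention block (block stage then grid stage)
#' @param blk a module from [new_maxvit_block()]
#' @param x numeric array (H, W, C)
#' @return array of the same shape
#' @export
maxvit_forward <- function(blk, x) {
  x <- as_hwc(x)
  d <- dim(x)
  array(val(fwd_maxvit(blk, array(x, c(1, d)))), d)
}
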