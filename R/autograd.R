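# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Feature maps are numeric arrays in (N, H, W, C) layout; token batches are
# plain matrices (rows = tokens, cols = channels). Every operation below has
# a hand-derived adjoint. A global tape records operations in creation order,
# which is a valid topological order, so the backward pass is a single
# reverse sweep. When the tape is not recording, all ops return plain arrays
# and cost nothing beyond the forward arithmetic.

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$tape <- list()
.ag$n <- 0L

#' Trainable parameter
#'
#' Creates a persistent trainable parameter (an environment holding a value
#' and an accumulated gradient). Parameters survive across tape resets, so a
#' model's weights are built once and updated in place by the optimiser.
#'
#' @param value numeric array/matrix/vector of initial values
#' @return an object of class `ag_param`
#' @keywords internal
ag_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- NULL
  e$trainable <- TRUE
  class(e) <- "ag_param"
  e
}

# Non-trainable state (e.g. batch-norm running statistics), mutated in place.
ag_buffer <- function(value) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$trainable <- FALSE
  class(e) <- "ag_buffer"
  e
}

is_ag <- function(x) inherits(x, c("ag_node", "ag_param"))

#' @keywords internal
val <- function(x) if (is_ag(x) || inherits(x, "ag_buffer")) x$v else x

acc_grad <- function(x, g) {
  if (!is_ag(x)) return(invisible(NULL))
  vdim <- dim(x$v)
  if (!is.null(vdim)) dim(g) <- vdim
  x$g <- if (is.null(x$g)) g else x$g + g
  invisible(NULL)
}

# Register an op result on the tape. `deps` are the inputs whose gradients
# the closure `bw` accumulates; if none of them participates in the graph the
# plain value is returned.
ag_op <- function(v, deps, bw) {
  if (!.ag$recording) return(v)
  track <- FALSE
  for (d in deps) if (is_ag(d)) { track <- TRUE; break }
  if (!track) return(v)
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e$bw <- bw
  class(e) <- "ag_node"
  .ag$n <- .ag$n + 1L
  if (.ag$n > length(.ag$tape)) length(.ag$tape) <- max(256L, 2L * length(.ag$tape))
  .ag$tape[[.ag$n]] <- e
  e
}

#' Run an expression while recording the autodiff tape
#' @keywords internal
ag_record <- function(expr) {
  .ag$recording <- TRUE
  .ag$tape <- vector("list", 1024L)
  .ag$n <- 0L
  on.exit(.ag$recording <- FALSE)
  expr
}

#' Reverse sweep: propagate gradients from a scalar loss node
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(inherits(loss, "ag_node"))
  loss$g <- 1
  for (i in seq(.ag$n, 1L)) {
    nd <- .ag$tape[[i]]
    if (!is.null(nd$g)) nd$bw(nd$g)
  }
  invisible(NULL)
}

ag_clear <- function() {
  .ag$tape <- list()
  .ag$n <- 0L
  invisible(NULL)
}

# ---- arithmetic ------------------------------------------------------------

ag_add <- function(x, y) {
  xv <- val(x); yv <- val(y)
  ag_op(xv + yv, list(x, y), function(g) { acc_grad(x, g); acc_grad(y, g) })
}

ag_sub <- function(x, y) {
  xv <- val(x); yv <- val(y)
  ag_op(xv - yv, list(x, y), function(g) { acc_grad(x, g); acc_grad(y, -g) })
}

ag_mul <- function(x, y) {
  xv <- val(x); yv <- val(y)
  ag_op(xv * yv, list(x, y), function(g) { acc_grad(x, g * yv); acc_grad(y, g * xv) })
}

ag_scale <- function(x, s) {
  xv <- val(x)
  ag_op(xv * s, list(x), function(g) acc_grad(x, g * s))
}

# x matrix (R x C) + bias vector over columns
ag_add_bias <- function(x, b) {
  xv <- val(x); bv <- val(b)
  r <- nrow(xv)
  nc <- ncol(xv)
  ag_op(xv + rep(bv, each = r), list(x, b), function(g) {
    acc_grad(x, g)
    acc_grad(b, .colSums(g, r, nc))
  })
}

ag_matmul <- function(x, w) {
  xv <- val(x); wv <- val(w)
  ag_op(xv %*% wv, list(x, w), function(g) {
    dim(g) <- c(nrow(xv), ncol(wv))
    if (is_ag(x)) acc_grad(x, tcrossprod(g, wv))
    if (is_ag(w)) acc_grad(w, crossprod(xv, g))
  })
}

ag_slice_cols <- function(x, cols) {
  xv <- val(x)
  ag_op(xv[, cols, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    gx[, cols] <- g
    acc_grad(x, gx)
  })
}

ag_cat_cols <- function(xs) {
  vs <- lapply(xs, val)
  nc <- vapply(vs, ncol, 1L)
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  ag_op(do.call(cbind, vs), xs, function(g) {
    for (i in seq_along(xs)) {
      if (is_ag(xs[[i]])) acc_grad(xs[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ag_reshape <- function(x, dims) {
  xv <- val(x)
  v <- xv
  dim(v) <- dims
  olddim <- if (is.null(dim(xv))) length(xv) else dim(xv)
  ag_op(v, list(x), function(g) { dim(g) <- olddim; acc_grad(x, g) })
}

ag_aperm <- function(x, perm) {
  xv <- val(x)
  inv <- order(perm)
  ag_op(aperm(xv, perm), list(x), function(g) acc_grad(x, aperm(g, inv)))
}

# ---- activations -----------------------------------------------------------

ag_relu <- function(x) {
  xv <- val(x)
  m <- xv > 0
  ag_op(xv * m, list(x), function(g) acc_grad(x, g * m))
}

ag_sigmoid <- function(x) {
  xv <- val(x)
  s <- 1 / (1 + exp(-xv))
  ag_op(s, list(x), function(g) acc_grad(x, g * s * (1 - s)))
}

# Exact GELU: x * Phi(x)
ag_gelu <- function(x) {
  xv <- val(x)
  ph <- stats::pnorm(xv)
  ag_op(xv * ph, list(x), function(g) {
    acc_grad(x, g * (ph + xv * 0.3989422804014327 * exp(-0.5 * xv * xv)))
  })
}

row_max <- function(m) {
  r <- m[, 1L]
  nc <- ncol(m)
  if (nc > 1L) for (j in 2:nc) r <- pmax(r, m[, j])
  r
}

# Row-wise softmax of a matrix
ag_softmax_rows <- function(x) {
  xv <- val(x)
  e <- exp(xv - row_max(xv))
  p <- e / rowSums(e)
  ag_op(p, list(x), function(g) {
    acc_grad(x, p * (g - rowSums(p * g)))
  })
}

# ---- normalisation ---------------------------------------------------------

# LayerNorm across columns of a token matrix (R x C)
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- val(x); gv <- val(gamma); bv <- val(beta)
  r <- nrow(xv); cc <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  grep_ <- rep(gv, each = r)
  v <- xhat * grep_ + rep(bv, each = r)
  ag_op(v, list(x, gamma, beta), function(g) {
    if (is_ag(gamma)) acc_grad(gamma, .colSums(g * xhat, r, cc))
    if (is_ag(beta)) acc_grad(beta, .colSums(g, r, cc))
    if (is_ag(x)) {
      dxh <- g * grep_
      acc_grad(x, istd * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)))
    }
  })
}

# BatchNorm over (N, H, W) per channel of an (N, H, W, C) array.
# In training mode batch statistics are used and running buffers updated;
# in inference mode the frozen running statistics make the op a fixed affine.
ag_batchnorm <- function(x, gamma, beta, run_mean, run_var, train,
                         momentum = 0.1, eps = 1e-5) {
  xv <- val(x)
  d <- dim(xv)
  cc <- d[4]
  r <- prod(d[1:3])
  gv <- val(gamma); bv <- val(beta)
  if (train) {
    mu <- .colMeans(xv, r, cc)
    xc <- xv - rep(mu, each = r)
    va <- .colMeans(xc * xc, r, cc)
    run_mean$v <- (1 - momentum) * run_mean$v + momentum * mu
    run_var$v <- (1 - momentum) * run_var$v + momentum * va
  } else {
    mu <- run_mean$v
    va <- run_var$v
    xc <- xv - rep(mu, each = r)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(istd, each = r)
  v <- xhat * rep(gv, each = r) + rep(bv, each = r)
  dim(v) <- d
  ag_op(v, list(x, gamma, beta), function(g) {
    if (is_ag(gamma)) acc_grad(gamma, .colSums(g * xhat, r, cc))
    if (is_ag(beta)) acc_grad(beta, .colSums(g, r, cc))
    if (is_ag(x)) {
      dxh <- g * rep(gv, each = r)
      if (train) {
        gx <- rep(istd, each = r) *
          (dxh - rep(.colMeans(dxh, r, cc), each = r) -
             xhat * rep(.colMeans(dxh * xhat, r, cc), each = r))
      } else {
        gx <- dxh * rep(istd, each = r)
      }
      acc_grad(x, gx)
    }
  })
}

# ---- convolutions ----------------------------------------------------------

pad_hw <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  out[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  out
}

# Dense 2D convolution, x (N,H,W,Ci), w (kh,kw,Ci,Co), optional bias (Co).
# Implemented as a sum over kernel offsets of strided-slice matmuls.
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  xv <- val(x); wv <- val(w)
  d <- dim(xv)
  kd <- dim(wv)
  kh <- kd[1]; kw <- kd[2]; ci <- kd[3]; co <- kd[4]
  stopifnot(d[4] == ci)
  xp <- pad_hw(xv, pad)
  hp <- d[2] + 2 * pad; wp <- d[3] + 2 * pad
  ho <- (hp - kh) %/% stride + 1L
  wo <- (wp - kw) %/% stride + 1L
  n <- d[1]
  r <- n * ho * wo
  ymat <- matrix(0, r, co)
  for (i in seq_len(kh)) {
    rows <- seq.int(i, by = stride, length.out = ho)
    for (j in seq_len(kw)) {
      cols <- seq.int(j, by = stride, length.out = wo)
      xs <- xp[, rows, cols, , drop = FALSE]
      dim(xs) <- c(r, ci)
      ymat <- ymat + xs %*% matrix(wv[i, j, , ], ci, co)
    }
  }
  if (!is.null(b)) ymat <- ymat + rep(val(b), each = r)
  v <- array(ymat, c(n, ho, wo, co))
  ag_op(v, list(x, w, b), function(g) {
    gm <- matrix(g, nrow = r)
    if (!is.null(b) && is_ag(b)) acc_grad(b, colSums(gm))
    need_x <- is_ag(x)
    gxp <- if (need_x) array(0, dim(xp)) else NULL
    gw <- if (is_ag(w)) array(0, kd) else NULL
    for (i in seq_len(kh)) {
      rows <- seq.int(i, by = stride, length.out = ho)
      for (j in seq_len(kw)) {
        cols <- seq.int(j, by = stride, length.out = wo)
        if (!is.null(gw)) {
          xs <- xp[, rows, cols, , drop = FALSE]
          dim(xs) <- c(r, ci)
          gw[i, j, , ] <- gw[i, j, , ] + crossprod(xs, gm)
        }
        if (need_x) {
          gs <- gm %*% t(matrix(wv[i, j, , ], ci, co))
          gxp[, rows, cols, ] <- gxp[, rows, cols, ] + array(gs, c(n, ho, wo, ci))
        }
      }
    }
    if (!is.null(gw)) acc_grad(w, gw)
    if (need_x) {
      gx <- if (pad > 0) {
        gxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE]
      } else gxp
      dim(gx) <- d
      acc_grad(x, gx)
    }
  })
}

# Depthwise 2D convolution, w (kh,kw,C)
ag_dwconv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  xv <- val(x); wv <- val(w)
  d <- dim(xv)
  kd <- dim(wv)
  kh <- kd[1]; kw <- kd[2]; cc <- kd[3]
  stopifnot(d[4] == cc)
  xp <- pad_hw(xv, pad)
  hp <- d[2] + 2 * pad; wp <- d[3] + 2 * pad
  ho <- (hp - kh) %/% stride + 1L
  wo <- (wp - kw) %/% stride + 1L
  n <- d[1]
  r <- n * ho * wo
  ymat <- matrix(0, r, cc)
  for (i in seq_len(kh)) {
    rows <- seq.int(i, by = stride, length.out = ho)
    for (j in seq_len(kw)) {
      cols <- seq.int(j, by = stride, length.out = wo)
      xs <- xp[, rows, cols, , drop = FALSE]
      dim(xs) <- c(r, cc)
      ymat <- ymat + xs * rep(wv[i, j, ], each = r)
    }
  }
  if (!is.null(b)) ymat <- ymat + rep(val(b), each = r)
  v <- array(ymat, c(n, ho, wo, cc))
  ag_op(v, list(x, w, b), function(g) {
    gm <- matrix(g, nrow = r)
    if (!is.null(b) && is_ag(b)) acc_grad(b, colSums(gm))
    need_x <- is_ag(x)
    gxp <- if (need_x) array(0, dim(xp)) else NULL
    gw <- if (is_ag(w)) array(0, kd) else NULL
    for (i in seq_len(kh)) {
      rows <- seq.int(i, by = stride, length.out = ho)
      for (j in seq_len(kw)) {
        cols <- seq.int(j, by = stride, length.out = wo)
        if (!is.null(gw) || need_x) {
          xs <- xp[, rows, cols, , drop = FALSE]
          dim(xs) <- c(r, cc)
        }
        if (!is.null(gw)) gw[i, j, ] <- gw[i, j, ] + colSums(xs * gm)
        if (need_x) {
          gs <- gm * rep(wv[i, j, ], each = r)
          gxp[, rows, cols, ] <- gxp[, rows, cols, ] + array(gs, c(n, ho, wo, cc))
        }
      }
    }
    if (!is.null(gw)) acc_grad(w, gw)
    if (need_x) {
      gx <- if (pad > 0) {
        gxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE]
      } else gxp
      dim(gx) <- d
      acc_grad(x, gx)
    }
  })
}

# ---- pooling ---------------------------------------------------------------

# 2x2 average pooling with stride 2
ag_avgpool2 <- function(x) {
  xv <- val(x)
  d <- dim(xv)
  stopifnot(d[2] %% 2 == 0, d[3] %% 2 == 0)
  ho <- d[2] %/% 2L; wo <- d[3] %/% 2L
  o1 <- seq.int(1L, by = 2L, length.out = ho)
  o2 <- seq.int(2L, by = 2L, length.out = ho)
  c1 <- seq.int(1L, by = 2L, length.out = wo)
  c2 <- seq.int(2L, by = 2L, length.out = wo)
  v <- 0.25 * (xv[, o1, c1, , drop = FALSE] + xv[, o1, c2, , drop = FALSE] +
                 xv[, o2, c1, , drop = FALSE] + xv[, o2, c2, , drop = FALSE])
  dim(v) <- c(d[1], ho, wo, d[4])
  ag_op(v, list(x), function(g) {
    gx <- array(0, d)
    gq <- array(g * 0.25, c(d[1], ho, wo, d[4]))
    gx[, o1, c1, ] <- gq; gx[, o1, c2, ] <- gx[, o1, c2, ] + gq
    gx[, o2, c1, ] <- gx[, o2, c1, ] + gq; gx[, o2, c2, ] <- gx[, o2, c2, ] + gq
    acc_grad(x, gx)
  })
}

# Global average pool over (H, W): (N,H,W,C) -> (N,C)
ag_global_avgpool <- function(x) {
  xv <- val(x)
  d <- dim(xv)
  hw <- d[2] * d[3]
  m <- matrix(aperm(xv, c(2, 3, 1, 4)), nrow = hw)
  v <- matrix(colMeans(m), d[1], d[4])
  ag_op(v, list(x), function(g) {
    tmp <- array(rep(as.vector(g / hw), each = hw), c(d[2], d[3], d[1], d[4]))
    acc_grad(x, aperm(tmp, c(3, 1, 2, 4)))
  })
}

# Global max pool over (H, W): (N,H,W,C) -> (N,C)
ag_global_maxpool <- function(x) {
  xv <- val(x)
  d <- dim(xv)
  hw <- d[2] * d[3]
  m <- matrix(aperm(xv, c(2, 3, 1, 4)), nrow = hw)
  idx <- max.col(t(m), ties.method = "first")
  sel <- cbind(idx, seq_len(ncol(m)))
  v <- matrix(m[sel], d[1], d[4])
  ag_op(v, list(x), function(g) {
    gm <- matrix(0, hw, ncol(m))
    gm[sel] <- as.vector(g)
    dim(gm) <- c(d[2], d[3], d[1], d[4])
    acc_grad(x, aperm(gm, c(3, 1, 2, 4)))
  })
}

# Per-position mean and max over channels: (N,H,W,C) -> (N,H,W,2)
ag_channel_meanmax <- function(x) {
  xv <- val(x)
  d <- dim(xv)
  r <- prod(d[1:3])
  m <- matrix(xv, nrow = r)
  idx <- max.col(m, ties.method = "first")
  sel <- cbind(seq_len(r), idx)
  v <- array(c(rowMeans(m), m[sel]), c(d[1], d[2], d[3], 2L))
  ag_op(v, list(x), function(g) {
    gm <- matrix(g, nrow = r)
    gx <- matrix(gm[, 1] / d[4], r, d[4])
    gx[sel] <- gx[sel] + gm[, 2]
    dim(gx) <- d
    acc_grad(x, gx)
  })
}

# ---- broadcast gating ------------------------------------------------------

# x (N,H,W,C) * gate (N,C), broadcast over space
ag_mul_channel <- function(x, gate) {
  xv <- val(x); gv <- val(gate)
  d <- dim(xv)
  ge <- aperm(array(as.vector(gv), c(d[1], d[4], d[2], d[3])), c(1, 3, 4, 2))
  ag_op(xv * ge, list(x, gate), function(g) {
    if (is_ag(x)) acc_grad(x, g * ge)
    if (is_ag(gate)) {
      red <- colSums(matrix(aperm(g * xv, c(2, 3, 1, 4)), nrow = d[2] * d[3]))
      acc_grad(gate, matrix(red, d[1], d[4]))
    }
  })
}

# x (N,H,W,C) * gate (N,H,W), broadcast over channels
ag_mul_spatial <- function(x, gate) {
  xv <- val(x); gv <- val(gate)
  d <- dim(xv)
  ge <- array(rep(as.vector(gv), times = d[4]), d)
  ag_op(xv * ge, list(x, gate), function(g) {
    if (is_ag(x)) acc_grad(x, g * ge)
    if (is_ag(gate)) {
      red <- rowSums(matrix(g * xv, ncol = d[4]))
      dim(red) <- d[1:3]
      acc_grad(gate, red)
    }
  })
}

# ---- batched matrix multiply ----------------------------------------------

bmm_raw <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[3] == db[2])
  B <- da[1]; n <- da[2]; m <- da[3]; p <- db[3]
  out <- array(0, c(B, n, p))
  bexp_idx <- rep(seq_len(p), each = n)
  for (k in seq_len(m)) {
    av <- a[, , k]                       # (B, n)
    bv <- matrix(b[, k, ], B, p)         # (B, p)
    out <- out + array(rep(as.vector(av), times = p), c(B, n, p)) *
      array(as.vector(bv[, bexp_idx]), c(B, n, p))
  }
  out
}

# a (B,n,m) x b (B,m,p) -> (B,n,p)
ag_bmm <- function(a, b) {
  av <- val(a); bv <- val(b)
  v <- bmm_raw(av, bv)
  ag_op(v, list(a, b), function(g) {
    if (is_ag(a)) acc_grad(a, bmm_raw(g, aperm(bv, c(1, 3, 2))))
    if (is_ag(b)) acc_grad(b, bmm_raw(aperm(av, c(1, 3, 2)), g))
  })
}

# scores (B,n,n) + relative bias looked up from one head's column of the
# bias table; idx is the n^2 offset-index map (column-major over (i,j)).
ag_rel_bias_add <- function(scores, table, head, idx) {
  sv <- val(scores); tv <- val(table)
  B <- dim(sv)[1]
  bias <- tv[idx, head]
  v <- sv + rep(bias, each = B)
  ag_op(v, list(scores, table), function(g) {
    if (is_ag(scores)) acc_grad(scores, g)
    if (is_ag(table)) {
      per_pair <- .colSums(g, B, length(idx))
      gt <- matrix(0, nrow(tv), ncol(tv))
      slot <- numeric(nrow(tv))
      for (t in seq_along(idx)) slot[idx[t]] <- slot[idx[t]] + per_pair[t]
      gt[, head] <- slot
      acc_grad(table, gt)
    }
  })
}

# scores (gstar*heads, n, n), batch index ordered group-fastest then head;
# adds each head's relative bias looked up from its table column by the
# n^2 offset-index map.
ag_rel_bias_add_mh <- function(scores, table, idx, gstar, heads) {
  sv <- val(scores); tv <- val(table)
  npair <- length(idx)
  m1 <- tv[idx, , drop = FALSE]                 # (n^2, heads)
  v <- sv + rep(as.vector(t(m1)), each = gstar)
  ag_op(v, list(scores, table), function(g) {
    if (is_ag(scores)) acc_grad(scores, g)
    if (is_ag(table)) {
      per <- .colSums(g, gstar, heads * npair)  # ordered (head, pair)
      dim(per) <- c(heads, npair)
      gt <- matrix(0, nrow(tv), ncol(tv))
      for (t in seq_len(npair)) gt[idx[t], ] <- gt[idx[t], ] + per[, t]
      acc_grad(table, gt)
    }
  })
}

# mean of all elements -> scalar
ag_mean_all <- function(x) {
  xv <- val(x)
  n <- length(xv)
  ag_op(mean(xv), list(x), function(g) acc_grad(x, array(g / n, dim(xv))))
}
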