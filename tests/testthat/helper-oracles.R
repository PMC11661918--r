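# Shared test oracles: brute-force references kept deliberately independent
# of the implementation paths they check.

# Central finite-difference gradient of a scalar-valued closure w.r.t. an
# ag_param, compared against the recorded analytic gradient.
fd_gradient_gap <- function(make_loss, par, h = 1e-5) {
  maxunet:::zero_grads(list(par))
  loss <- maxunet:::ag_record(make_loss())
  maxunet:::ag_backward(loss)
  maxunet:::ag_clear()
  ga <- par$g
  gn <- array(0, dim(par$v))
  if (is.null(dim(par$v))) gn <- numeric(length(par$v))
  v0 <- par$v
  for (i in seq_along(v0)) {
    par$v[i] <- v0[i] + h
    lp <- maxunet:::val(make_loss())
    par$v[i] <- v0[i] - h
    lm <- maxunet:::val(make_loss())
    par$v[i] <- v0[i]
    gn[i] <- (lp - lm) / (2 * h)
  }
  max(abs(ga - gn))
}

# Double-loop softmax attention oracle (single group, multi-head).
attention_oracle <- function(q, k, v, tab, head_dim) {
  n <- nrow(q)
  p <- as.integer(sqrt(n))
  heads <- ncol(q) / head_dim
  outs <- NULL
  for (h in seq_len(heads)) {
    cl <- (h - 1) * head_dim + seq_len(head_dim)
    bias <- if (is.null(tab)) matrix(0, n, n) else {
      relative_bias_matrix(if (is.matrix(tab)) tab[, h] else tab, p)
    }
    oh <- matrix(0, n, head_dim)
    for (i in seq_len(n)) {
      s <- numeric(n)
      for (j in seq_len(n)) {
        s[j] <- sum(q[i, cl] * k[j, cl]) / sqrt(head_dim) + bias[i, j]
      }
      w <- exp(s - max(s))
      w <- w / sum(w)
      acc <- numeric(head_dim)
      for (j in seq_len(n)) acc <- acc + w[j] * v[j, cl]
      oh[i, ] <- acc
    }
    outs <- cbind(outs, oh)
  }
  outs
}

# All-pairs boundary-distance HD95 oracle.
hd95_oracle <- function(x, y, q = 0.95) {
  bx <- which(boundary_mask(x), arr.ind = TRUE)
  by <- which(boundary_mask(y), arr.ind = TRUE)
  d <- sqrt(outer(bx[, 1], by[, 1], "-")^2 + outer(bx[, 2], by[, 2], "-")^2)
  pooled <- c(apply(d, 1, min), apply(d, 2, min))
  stats::quantile(pooled, q, type = 7, names = FALSE)
}

# Exact (worst-case) symmetric Hausdorff distance by brute force.
hausdorff_exact <- function(x, y) {
  bx <- which(boundary_mask(x), arr.ind = TRUE)
  by <- which(boundary_mask(y), arr.ind = TRUE)
  d <- sqrt(outer(bx[, 1], by[, 1], "-")^2 + outer(bx[, 2], by[, 2], "-")^2)
  max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}

# Tiny attention/model configs reused across tests.
tiny_attention_cfg <- function(dim = 8L) {
  attention_config(dim, head_dim = 4L, window_p = 2L, grid_g = 2L,
                   mlp_ratio = 2)
}

tiny_model_cfg <- function(num_classes = 4L) {
  model_config(img_size = 64L, num_classes = num_classes, stem_dim = 8L,
               encoder_depths = c(1L, 1L, 1L, 1L),
               decoder_depths = c(1L, 1L, 1L), head_dim = 8L,
               window_p = 2L, grid_g = 2L, mlp_ratio = 1)
}
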