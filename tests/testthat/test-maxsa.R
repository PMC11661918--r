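# Multi-axis attention primitives: partitions, relative bias, windowed
# attention and the composed attention block.

row_major_map <- function(n) {
  # (n x n x 1) map whose value at (row r, col c) is n*(r-1) + (c-1)
  aperm(array(seq_len(n * n) - 1, c(n, n, 1)), c(2, 1, 3))
}

test_that("block partition enumerates tiles row-major and inverts exactly", {
  x <- row_major_map(4)
  w <- block_partition(x, 2)
  expect_equal(dim(w$windows), c(4L, 4L, 1L))
  expect_equal(w$windows[1, , 1], c(0, 1, 4, 5))
  expect_equal(w$windows[2, , 1], c(2, 3, 6, 7))
  expect_equal(w$windows[3, , 1], c(8, 9, 12, 13))
  expect_equal(w$windows[4, , 1], c(10, 11, 14, 15))
  expect_equal(unblock(w), x)

  # shape arithmetic: an 8x8 map with p = 4 gives 4 groups of 16 tokens
  x8 <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  w8 <- block_partition(x8, 4)
  expect_equal(dim(w8$windows), c(4L, 16L, 5L))
  # single-window case: the whole map flattened
  xs <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  ws <- block_partition(xs, 3)
  expect_equal(dim(ws$windows)[1], 1L)
  expect_equal(unblock(ws), xs)
  expect_error(block_partition(array(0, c(6, 8, 1)), 4), "divisible")
})

test_that("grid partition strides across the map and inverts exactly", {
  x <- row_major_map(4)
  g <- grid_partition(x, 2)
  expect_equal(g$windows[1, , 1], c(0, 2, 8, 10))
  expect_equal(ungrid(g), x)
  # 8x8 with g = 2: 16 groups of 4 tokens
  x8 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  g8 <- grid_partition(x8, 2)
  expect_equal(dim(g8$windows), c(16L, 4L, 3L))
  # one-group degenerate case
  xs <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
  gs <- grid_partition(xs, 2)
  expect_equal(dim(gs$windows)[1], 1L)
  expect_equal(ungrid(gs), xs)
  expect_error(grid_partition(array(0, c(6, 4, 1)), 4), "divisible")
})

test_that("partitions are exact inverses over random shapes and values", {
  set.seed(202)
  shapes <- expand.grid(hw = c(4, 6, 8, 12), p = c(2, 3), c = c(1, 3))
  shapes <- shapes[shapes$hw %% shapes$p == 0, ]
  count <- 0
  for (rep_ in 1:10) {
    for (i in seq_len(nrow(shapes))) {
      d <- c(shapes$hw[i], shapes$hw[i], shapes$c[i])
      x <- array(rnorm(prod(d)), d)
      expect_identical(unblock(block_partition(x, shapes$p[i])), x)
      expect_identical(ungrid(grid_partition(x, shapes$p[i])), x)
      count <- count + 2
    }
  }
  expect_gte(count, 200)
  # a group covers exactly the expected share of the map
  gs <- attention_group_shape(28, 28, 7)
  expect_equal(unname(gs["groups"] * gs["tokens"]), 28 * 28)
})

test_that("relative bias matrices depend only on token offsets", {
  # p = 1: single entry
  expect_equal(relative_bias_matrix(3.5, 1), matrix(3.5, 1, 1))
  # p = 2: 9 slots, all diagonal entries share the zero-offset slot
  tab <- seq_len(9)
  b <- relative_bias_matrix(tab, 2)
  expect_equal(dim(b), c(4L, 4L))
  expect_true(all(diag(b) == b[1, 1]))
  # equal offsets map to equal entries: tokens (1,2) and (3,4) are both
  # "one column apart" within the window
  expect_equal(b[1, 2], b[3, 4])
  expect_equal(b[2, 1], b[4, 3])
  expect_equal(length(unique(as.vector(b))), 9L)
  expect_error(relative_bias_matrix(1:8, 2), "9 entries")
})

test_that("relative attention matches the double-loop oracle (n <= 16)", {
  set.seed(303)
  worst <- 0
  for (trial in 1:100) {
    p <- sample(c(2L, 3L, 4L), 1)
    n <- p * p
    if (n > 16) next
    hd <- sample(c(2L, 4L), 1)
    heads <- sample(1:2, 1)
    dm <- hd * heads
    q <- matrix(rnorm(n * dm), n)
    k <- matrix(rnorm(n * dm), n)
    v <- matrix(rnorm(n * dm), n)
    tab <- matrix(rnorm((2 * p - 1)^2 * heads), ncol = heads)
    out <- relative_attention(q, k, v, tab, head_dim = hd)
    worst <- max(worst, max(abs(out - attention_oracle(q, k, v, tab, hd))))
  }
  expect_lt(worst, 1e-5)
})

test_that("attention outputs are convex combinations of values", {
  set.seed(404)
  n <- 9; hd <- 4
  q <- matrix(rnorm(n * hd), n)
  k <- matrix(rnorm(n * hd), n)
  v <- matrix(rnorm(n * hd), n)
  out <- relative_attention(q, k, v, NULL, head_dim = hd)
  for (j in seq_len(hd)) {
    expect_true(all(out[, j] >= min(v[, j]) - 1e-9))
    expect_true(all(out[, j] <= max(v[, j]) + 1e-9))
  }
  # zero queries + zero bias: uniform weights, every row = mean of values
  out0 <- relative_attention(matrix(0, n, hd), k, v, NULL, head_dim = hd)
  expect_equal(out0, matrix(rep(colMeans(v), each = n), n), tolerance = 1e-12)
  # n = 1: weight is exactly 1, output equals the value row
  o1 <- relative_attention(matrix(1, 1, 2), matrix(2, 1, 2),
                           matrix(c(3, -4), 1, 2), NULL, head_dim = 2)
  expect_equal(o1, matrix(c(3, -4), 1, 2))
  expect_error(relative_attention(matrix(NaN, 1, 2), matrix(0, 1, 2),
                                  matrix(0, 1, 2), NULL, 2), "NaN")
})

test_that("ffn is position-wise and matches a closed-form evaluation", {
  set.seed(505)
  w1 <- matrix(rnorm(6), 2, 3); b1 <- rnorm(3)
  w2 <- matrix(rnorm(6), 3, 2); b2 <- rnorm(2)
  x <- matrix(rnorm(8), 4, 2)
  out <- ffn(x, w1, b1, w2, b2)
  # single-token closed form with the exact GELU x * pnorm(x)
  h <- as.vector(x[2, ] %*% w1) + b1
  h <- h * pnorm(h)
  expect_equal(out[2, ], as.vector(h %*% w2) + b2, tolerance = 1e-12)
  # permuting tokens permutes outputs identically
  perm <- c(3, 1, 4, 2)
  expect_equal(ffn(x[perm, ], w1, b1, w2, b2), out[perm, ])
  # zero weights, zero bias: zero output
  expect_equal(ffn(x, 0 * w1, 0 * b1, 0 * w2, 0 * b2), matrix(0, 4, 2))
})

test_that("attention layers preserve shape and reduce to identity when zeroed", {
  set.seed(606)
  cfg <- tiny_attention_cfg(8L)
  blk <- new_maxvit_block(cfg)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  out <- maxvit_forward(blk, x)
  expect_equal(dim(out), dim(x))
  # sequential composition of the two stages
  mid <- block_attention_forward(blk$block, x)
  expect_equal(grid_attention_forward(blk$grid, mid), out, tolerance = 1e-12)
  # zeroed residual branches: exact identity
  zero_params(blk)
  expect_equal(maxvit_forward(blk, x), x)
  # divisibility violations propagate
  expect_error(maxvit_forward(new_maxvit_block(tiny_attention_cfg(8L)),
                              array(0, c(5, 4, 8))), "divisible")
})

test_that("a block attention layer equals the composition of its primitives", {
  set.seed(707)
  cfg <- tiny_attention_cfg(4L)
  blk <- new_maxvit_block(cfg)
  lay <- blk$block
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  got <- block_attention_forward(lay, x)

  # oracle: LN -> partition -> relative attention per group -> reverse ->
  # residual; then token-wise LN -> FFN -> residual
  ln <- function(m, g, b) {
    mu <- rowMeans(m)
    sd_ <- sqrt(rowMeans((m - mu)^2) + 1e-5)
    t(g * t((m - mu) / sd_) + b)
  }
  tok <- matrix(aperm(x, c(3, 1, 2)), nrow = dim(x)[3])  # C x (H W)
  tok <- t(tok)                                           # tokens x C
  normed <- ln(tok, lay$ln1$gamma$v, lay$ln1$beta$v)
  xn <- array(t(normed), c(4, 4, 4))
  xn <- aperm(array(xn, c(4, 4, 4)), c(2, 3, 1))          # back to (H, W, C)
  w <- block_partition(xn, 2)
  att <- w
  for (g in seq_len(dim(w$windows)[1])) {
    grp <- w$windows[g, , ]
    qkv <- grp %*% lay$qkv$w$v + rep(lay$qkv$b$v, each = nrow(grp))
    q <- qkv[, 1:4]; k <- qkv[, 5:8]; v <- qkv[, 9:12]
    att$windows[g, , ] <- relative_attention(
      q, k, v, lay$table$v, head_dim = 4,
      proj = list(w = lay$proj$w$v, b = lay$proj$b$v))
  }
  x1 <- x + unblock(att)
  tok1 <- t(matrix(aperm(x1, c(3, 1, 2)), nrow = 4))
  f <- ffn(ln(tok1, lay$ln2$gamma$v, lay$ln2$beta$v),
           lay$ffn1$w$v, lay$ffn1$b$v, lay$ffn2$w$v, lay$ffn2$b$v)
  oracle <- x1 + aperm(array(t(tok1 * 0 + f), c(4, 4, 4)), c(2, 3, 1))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("attention cost stays per-group however large the map", {
  for (hw in c(14, 28, 56)) {
    gs <- attention_group_shape(hw, hw, 7)
    expect_equal(unname(gs["tokens"]), 49)       # largest matrix is 49 x 49
    expect_equal(unname(gs["groups"]), (hw / 7)^2)
  }
})
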