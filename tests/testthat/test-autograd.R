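# The autodiff engine is the substrate for every trainable module, so its
# adjoints are checked wholesale against central finite differences.

test_that("every primitive operation matches finite-difference gradients", {
  set.seed(101)
  x <- array(rnorm(2 * 4 * 4 * 3), c(2, 4, 4, 3))
  xp <- maxunet:::ag_param(x)
  probe4 <- array(seq_len(96) / 31, c(2, 4, 4, 3))

  cases <- list(
    conv_w = function() {
      w <- maxunet:::ag_param(array(rnorm(27 * 5) * 0.3, c(3, 3, 3, 5)))
      list(par = w, loss = function() maxunet:::ag_mean_all(
        maxunet:::ag_relu(maxunet:::ag_conv2d(x, w, NULL, 1L, 1L))))
    },
    conv_x_strided = function() {
      w <- array(rnorm(27 * 5) * 0.3, c(3, 3, 3, 5))
      list(par = xp, loss = function() maxunet:::ag_mean_all(
        maxunet:::ag_gelu(maxunet:::ag_conv2d(xp, w, NULL, 2L, 1L))))
    },
    dwconv = function() {
      w <- maxunet:::ag_param(array(rnorm(27) * 0.3, c(3, 3, 3)))
      list(par = w, loss = function() maxunet:::ag_mean_all(
        maxunet:::ag_sigmoid(maxunet:::ag_dwconv2d(x, w, NULL, 1L, 1L))))
    },
    batchnorm_train = function() {
      g <- maxunet:::ag_param(c(1.1, 0.9, 1.0))
      rm_ <- maxunet:::ag_buffer(numeric(3))
      rv_ <- maxunet:::ag_buffer(rep(1, 3))
      list(par = xp, loss = function() maxunet:::ag_mean_all(
        maxunet:::ag_mul(maxunet:::ag_batchnorm(xp, g, numeric(3), rm_, rv_,
                                                TRUE), probe4)))
    },
    layernorm = function() {
      xm <- maxunet:::ag_param(matrix(rnorm(15), 5, 3))
      beta <- rnorm(3) / 10
      list(par = xm, loss = function() maxunet:::ag_mean_all(
        maxunet:::ag_mul(maxunet:::ag_layernorm(xm, rep(1, 3), beta),
                         matrix(seq_len(15), 5, 3))))
    },
    softmax = function() {
      xm <- maxunet:::ag_param(matrix(rnorm(15), 5, 3))
      list(par = xm, loss = function() maxunet:::ag_mean_all(
        maxunet:::ag_mul(maxunet:::ag_softmax_rows(xm),
                         matrix(seq_len(15), 5, 3))))
    },
    bmm = function() {
      a <- maxunet:::ag_param(array(rnorm(24), c(2, 3, 4)))
      b <- array(rnorm(40), c(2, 4, 5))
      list(par = a, loss = function() maxunet:::ag_mean_all(
        maxunet:::ag_mul(maxunet:::ag_bmm(a, b),
                         array(seq_len(30) / 10, c(2, 3, 5)))))
    },
    rel_bias_table = function() {
      tb <- maxunet:::ag_param(matrix(rnorm(18), 9, 2))
      idx <- as.integer(maxunet:::relative_bias_index(2L))
      s <- array(rnorm(32), c(2, 4, 4))
      list(par = tb, loss = function() maxunet:::ag_mean_all(
        maxunet:::ag_mul(maxunet:::ag_rel_bias_add(s, tb, 2L, idx),
                         array(seq_len(32) / 7, c(2, 4, 4)))))
    },
    global_max = function() {
      list(par = xp, loss = function() maxunet:::ag_mean_all(
        maxunet:::ag_mul(maxunet:::ag_global_maxpool(xp), matrix(1:6, 2, 3))))
    },
    channel_meanmax = function() {
      list(par = xp, loss = function() maxunet:::ag_mean_all(
        maxunet:::ag_mul(maxunet:::ag_channel_meanmax(xp),
                         array(seq_len(64) / 9, c(2, 4, 4, 2)))))
    },
    mul_channel_gate = function() {
      gt <- maxunet:::ag_param(matrix(rnorm(6), 2, 3))
      list(par = gt, loss = function() maxunet:::ag_mean_all(
        maxunet:::ag_mul(maxunet:::ag_mul_channel(x, gt), x)))
    },
    mul_spatial_gate = function() {
      gs <- maxunet:::ag_param(array(rnorm(32), c(2, 4, 4)))
      list(par = gs, loss = function() maxunet:::ag_mean_all(
        maxunet:::ag_mul(maxunet:::ag_mul_spatial(x, gs), x)))
    },
    avgpool = function() {
      list(par = xp, loss = function() maxunet:::ag_mean_all(
        maxunet:::ag_mul(maxunet:::ag_avgpool2(xp), array(1:12, c(2, 2, 2, 3)))))
    },
    slice_cat_aperm = function() {
      xm <- maxunet:::ag_param(matrix(rnorm(12), 4, 3))
      list(par = xm, loss = function() {
        a <- maxunet:::ag_slice_cols(xm, 1:2)
        b <- maxunet:::ag_slice_cols(xm, 3)
        cat_ <- maxunet:::ag_cat_cols(list(b, a))
        pr <- maxunet:::ag_reshape(maxunet:::ag_aperm(
          maxunet:::ag_reshape(cat_, c(2, 2, 3)), c(3, 1, 2)), c(3, 4))
        maxunet:::ag_mean_all(maxunet:::ag_mul(pr, matrix(1:12, 3, 4)))
      })
    })

  for (nm in names(cases)) {
    case <- cases[[nm]]()
    expect_lt(fd_gradient_gap(case$loss, case$par), 1e-7, label = nm)
  }
})

test_that("parameters accumulate gradients across reuse and tape resets work", {
  w <- maxunet:::ag_param(matrix(0.5, 2, 2))
  x <- matrix(1, 3, 2)
  loss <- maxunet:::ag_record({
    y1 <- maxunet:::ag_matmul(x, w)
    y2 <- maxunet:::ag_matmul(x, w)  # parameter used twice
    maxunet:::ag_mean_all(maxunet:::ag_add(y1, y2))
  })
  maxunet:::ag_backward(loss)
  maxunet:::ag_clear()
  expect_equal(w$g, matrix(2 * 3 / 12, 2, 2) * 2)  # both uses contribute
  # outside recording, ops return plain arrays
  out <- maxunet:::ag_matmul(x, w)
  expect_true(is.matrix(out))
})
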