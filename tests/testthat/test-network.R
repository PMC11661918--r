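# Network assembly: configuration validation, stage chains, patch
# expansion, skip fusion, end-to-end shape, determinism, gradient flow and
# checkpointing. Heavy checks run on the tiny 64 x 64 configuration.

test_that("model configuration enforces its invariants", {
  expect_error(model_config(img_size = 200), "divisible by 32")
  expect_error(model_config(stage_dims = c(64, 128, 256, 511)), "double")
  expect_error(model_config(img_size = 64), "not divisible")  # 2 vs P = 7
  expect_error(model_config(stem_dim = 48), "head_dim|stage")
  cfg <- model_config()
  expect_equal(cfg$stage_dims, c(64L, 128L, 256L, 512L))
  expect_equal(cfg$encoder_depths, c(2L, 2L, 5L, 2L))
  expect_equal(sum(cfg$encoder_depths), 11L)  # total attention blocks
})

test_that("encoder follows the resolution and width chain", {
  set.seed(121)
  model <- build_model(tiny_model_cfg())
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  f <- encoder_forward(model, img)
  expect_equal(dim(f$stem_out), c(32L, 32L, 8L))
  exts <- c(16L, 8L, 4L, 2L)
  widths <- c(8L, 16L, 32L, 64L)
  for (s in 1:4) {
    expect_equal(dim(f$stage_outs[[s]]), c(exts[s], exts[s], widths[s]))
  }
})

test_that("patch expansion doubles extent, halves channels, and rearranges
           values bijectively", {
  set.seed(131)
  pe <- new_patch_expand(8L, 2L)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  out <- patch_expand_forward(pe, x)
  expect_equal(dim(out), c(8L, 8L, 4L))
  # pixel*channel volume doubles: 4x pixels, half channels
  expect_equal(prod(dim(out)), 2 * prod(dim(x)))
  expect_error(new_patch_expand(7L, 2L), "even")
  # identity-like expansion: each input channel copied into one output slot
  # makes the rearrangement a pure bijection of values
  pe$lin$w$v[] <- 0
  pe$lin$b$v[] <- 0
  for (k in seq_len(8)) pe$lin$w$v[k, k] <- 1   # out slot k <- in channel k
  out2 <- patch_expand_forward(pe, x)
  expect_equal(sort(as.vector(out2[out2 != 0])),
               sort(as.vector(x[seq_len(prod(dim(x)))])))
  # the 4x final expansion preserves channel width
  pf <- new_patch_expand(8L, 4L)
  expect_equal(dim(patch_expand_forward(pf, x)), c(16L, 16L, 8L))
})

test_that("skip fusion validates shapes and honours constructed weights", {
  set.seed(141)
  sf <- new_skip_fuse(6L)
  up <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  sk <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  expect_equal(dim(skip_fuse_forward(sf, up, sk)), dim(up))
  expect_error(skip_fuse_forward(sf, up, array(0, c(2, 2, 6))), "matching")
  # projection = 0.5 * (I | I): output is the mean of the two inputs
  sf$proj$w$v <- rbind(diag(6), diag(6)) / 2
  sf$proj$b$v[] <- 0
  expect_equal(skip_fuse_forward(sf, up, sk), (up + sk) / 2, tolerance = 1e-12)
  # zero projection: zero output
  zero_params(sf)
  expect_equal(skip_fuse_forward(sf, up, sk), array(0, dim(up)))
  # additive mode
  sfa <- new_skip_fuse(6L, mode = "add")
  expect_equal(skip_fuse_forward(sfa, up, sk), up + sk)
})

test_that("full forward yields per-pixel logits and is deterministic", {
  set.seed(151)
  model <- build_model(tiny_model_cfg(num_classes = 5L))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  lg <- predict_logits(model, img)
  expect_equal(dim(lg), c(64L, 64L, 5L))
  expect_identical(predict_logits(model, img), lg)
  lab <- predict_labels(model, img)
  expect_true(all(lab >= 0 & lab < 5))
  expect_error(predict_logits(model, array(0, c(32, 32, 3))), "does not match")
})

test_that("gradient flows to every trainable parameter (no dead branches)", {
  set.seed(161)
  model <- build_model(tiny_model_cfg())
  params <- maxunet:::collect_params(model$params)
  imgs <- array(runif(2 * 64 * 64 * 3), c(2, 64, 64, 3))
  labs <- array(sample(0:3, 2 * 64 * 64, TRUE), c(2, 64, 64))
  maxunet:::zero_grads(params)
  loss <- maxunet:::ag_record({
    lg <- maxunet:::fwd_model(model, imgs, list(train = TRUE))
    maxunet:::ag_seg_loss(lg, labs, 0.5, 0.5)
  })
  maxunet:::ag_backward(loss)
  maxunet:::ag_clear()
  missing_ <- names(params)[vapply(params, function(p) is.null(p$g), TRUE)]
  expect_identical(missing_, character(0))
  nonzero <- vapply(params, function(p) any(p$g != 0), TRUE)
  expect_gt(mean(nonzero), 0.99)
})

test_that("parameter counting is exact and size-invariant", {
  lin <- maxunet:::new_linear(10L, 10L)
  expect_equal(maxunet:::n_params(lin), 110)           # 100 weights + 10 biases
  cfg64 <- tiny_model_cfg()
  cfg64b <- tiny_model_cfg(num_classes = 4L)
  expect_equal(count_parameters(build_model(cfg64)),
               count_parameters(build_model(cfg64b)))  # rebuilt identically
})

test_that("ablation flags change only the targeted component", {
  base_args <- list(img_size = 64L, num_classes = 4L, stem_dim = 8L,
                    encoder_depths = c(1L, 1L, 1L, 1L),
                    decoder_depths = c(1L, 1L, 1L), head_dim = 8L,
                    window_p = 2L, grid_g = 2L, mlp_ratio = 1)
  n_of <- function(...) {
    cfg <- do.call(model_config, c(base_args, list(...)))
    maxunet:::n_params(build_model(cfg)$params)
  }
  set.seed(171)
  n_mcbam <- n_of(skip_mode = "mcbam")
  n_cbam <- n_of(skip_mode = "cbam")
  n_none <- n_of(skip_mode = "none")
  expect_gt(n_mcbam, n_cbam)
  expect_gt(n_cbam, n_none)
  # the plain-convolution downsampling variant builds and runs
  mpc <- build_model(do.call(model_config,
                             c(base_args, list(downsample_mode = "plain_conv"))))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_equal(dim(predict_logits(mpc, img)), c(64L, 64L, 4L))
  mnone <- build_model(do.call(model_config, c(base_args,
                                               list(skip_mode = "none"))))
  expect_equal(dim(predict_logits(mnone, img)), c(64L, 64L, 4L))
})

test_that("checkpoints round-trip weights, buffers and configuration", {
  set.seed(181)
  model <- build_model(tiny_model_cfg())
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  before <- predict_logits(model, img)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  restored <- load_checkpoint(path)
  expect_identical(predict_logits(restored, img), before)
  # tampered config digest is rejected
  obj <- readRDS(path)
  obj$config$num_classes <- 5L
  saveRDS(obj, path)
  expect_error(load_checkpoint(path), "digest")
})
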