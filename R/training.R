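# Loss, optimiser and training/evaluation drivers.
#
# The segmentation loss is the de-facto standard compound for this family of
# benchmarks: w_ce * cross-entropy + w_dice * (1 - soft multi-class Dice),
# computed on logits. Optimisation is AdamW (decoupled weight decay).

#' Training configuration
#'
#' @param lr AdamW learning rate
#' @param weight_decay decoupled weight decay
#' @param batch_size mini-batch size
#' @param steps number of optimisation steps
#' @param seed RNG seed controlling batching, augmentation and
#'   initial weights drawn inside [train_model()]
#' @param loss_weights length-2 vector (cross-entropy, Dice); must sum to 1
#' @param augment_data apply random flip/rotation augmentation per batch
#' @param lr_schedule `"constant"` (default) or `"cosine"` decay to zero
#' @return a `train_config` object
#' @export
train_config <- function(lr = 2e-4, weight_decay = 1e-4, batch_size = 8L,
                         steps = 100L, seed = 1L,
                         loss_weights = c(ce = 0.5, dice = 0.5),
                         augment_data = TRUE,
                         lr_schedule = c("constant", "cosine")) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(lr > 0, weight_decay >= 0, batch_size >= 1, steps >= 1,
            length(loss_weights) == 2, all(loss_weights >= 0))
  if (abs(sum(loss_weights) - 1) > 1e-8) stop("loss_weights must sum to 1")
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps), seed = as.integer(seed),
                 loss_weights = loss_weights,
                 augment_data = isTRUE(augment_data),
                 lr_schedule = lr_schedule),
            class = "train_config")
}

# Fused segmentation loss with hand-derived gradient.
# logits (N,H,W,K) node; labels (N,H,W) integer array in [0, K).
ag_seg_loss <- function(logits, labels, w_ce = 0.5, w_dice = 0.5, eps = 1e-6) {
  z <- val(logits)
  d <- dim(z)
  k <- d[4]
  m <- prod(d[1:3])
  lab <- as.integer(labels)
  if (any(lab < 0L) || any(lab >= k)) {
    stop("label values must lie in [0, n_classes)")
  }
  zm <- matrix(z, m, k)
  ez <- exp(zm - row_max(zm))
  p <- ez / rowSums(ez)
  sel <- cbind(seq_len(m), lab + 1L)
  ce <- -mean(log(pmax(p[sel], 1e-12)))
  onehot <- matrix(0, m, k)
  onehot[sel] <- 1
  num <- 2 * colSums(p * onehot) + eps
  den <- colSums(p) + colSums(onehot) + eps
  dice_loss <- 1 - mean(num / den)
  v <- w_ce * ce + w_dice * dice_loss
  ag_op(v, list(logits), function(g) {
    dp_ce <- (p - onehot) / m
    dnum <- matrix(2 * rep(1 / den, each = m) * onehot, m, k)
    dden <- matrix(rep(num / den^2, each = m), m, k)
    dp_dice <- -(dnum - dden) / k
    dp <- g * w_dice * dp_dice
    dz <- p * (dp - rowSums(p * dp))            # softmax jacobian-transpose
    dz <- dz + g * w_ce * dp_ce
    dim(dz) <- d
    acc_grad(logits, dz)
  })
}

#' Combined cross-entropy + soft-Dice segmentation loss
#'
#' `w[1] * CE + w[2] * (1 - mean_c soft-Dice_c)` with the soft Dice of class
#' c defined as `2 sum(p_c y_c) / (sum(p_c) + sum(y_c))` over all pixels of
#' the batch (all classes, including background, enter the mean).
#'
#' @param logits numeric array (H, W, K) or (N, H, W, K)
#' @param labels integer matrix/array with values in `[0, K)`
#' @param w length-2 weights (cross-entropy, Dice) summing to 1
#' @return a scalar loss (non-negative)
#' @export
seg_loss <- function(logits, labels, w = c(0.5, 0.5)) {
  if (length(dim(logits)) == 3L) {
    logits <- array(logits, c(1L, dim(logits)))
    labels <- array(labels, c(1L, dim(labels)))
  }
  val(ag_seg_loss(logits, labels, w[1], w[2]))
}

# ---- AdamW -----------------------------------------------------------------

new_adamw <- function(params, lr, weight_decay, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim(p$v) %||% length(p$v)))
  st$v <- lapply(params, function(p) array(0, dim(p$v) %||% length(p$v)))
  st$t <- 0L
  st$lr <- lr; st$wd <- weight_decay
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamw_step <- function(st, params, lr = st$lr) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$g
    if (is.null(g)) next
    st$m[[nm]] <- st$beta1 * st$m[[nm]] + (1 - st$beta1) * g
    st$v[[nm]] <- st$beta2 * st$v[[nm]] + (1 - st$beta2) * g * g
    upd <- (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + st$eps)
    p$v <- p$v - lr * (upd + st$wd * p$v)
  }
  invisible(NULL)
}

# ---- training loop ---------------------------------------------------------

batch_arrays <- function(dataset, idx, do_augment) {
  n <- length(idx)
  d1 <- dim(dataset[[idx[1]]]$image)
  images <- array(0, c(n, d1))
  labels <- array(0L, c(n, d1[1], d1[2]))
  for (i in seq_len(n)) {
    smp <- dataset[[idx[i]]]
    if (do_augment) smp <- augment(smp$image, smp$mask)
    images[i, , , ] <- smp$image
    labels[i, , ] <- smp$mask
  }
  list(images = images, labels = labels)
}

#' Train a segmentation model
#'
#' Seeded mini-batch AdamW optimisation of the compound segmentation loss,
#' with optional flip/rotation augmentation. Training is fully reproducible
#' given `cfg$seed` on a single CPU. Aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param model a `seg_model` (updated in place and returned)
#' @param dataset a `seg_dataset` (e.g. from [make_dataset()])
#' @param cfg a [train_config()]
#' @param checkpoint_dir if non-`NULL`, `best.rds` (lowest loss) and
#'   `last.rds` (with optimiser state for resuming) are written there
#' @param resume_from path to a `last.rds` checkpoint to continue from
#' @param verbose print a log line every 10 steps
#' @return list with `model`, `history` (data.frame step/loss/lr) and
#'   checkpoint paths (or `NULL`)
#' @export
train_model <- function(model, dataset, cfg, checkpoint_dir = NULL,
                        resume_from = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), length(dataset) >= 1)
  params <- collect_params(model$params)
  opt <- new_adamw(params, cfg$lr, cfg$weight_decay)
  step0 <- 0L
  if (is.null(resume_from)) {
    set.seed(cfg$seed)
  } else {
    ck <- load_checkpoint(resume_from)
    if (!identical(ck$config, model$config)) {
      stop("resume checkpoint was trained with a different configuration")
    }
    src <- collect_params(ck$params)
    for (nm in names(params)) params[[nm]]$v <- src[[nm]]$v
    bs <- collect_buffers(model$params)
    bsrc <- collect_buffers(ck$params)
    for (nm in names(bs)) bs[[nm]]$v <- bsrc[[nm]]$v
    extra <- attr(ck, "extra")
    opt$m <- extra$opt_m; opt$v <- extra$opt_v; opt$t <- extra$opt_t
    step0 <- extra$step
    assign(".Random.seed", extra$rng, envir = globalenv())
  }
  history <- data.frame(step = integer(0), loss = numeric(0), lr = numeric(0))
  best_loss <- Inf
  best_path <- last_path <- NULL
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    best_path <- file.path(checkpoint_dir, "best.rds")
    last_path <- file.path(checkpoint_dir, "last.rds")
  }
  st <- list(train = TRUE)
  for (step in seq_len(cfg$steps)) {
    idx <- sample.int(length(dataset), cfg$batch_size, replace = TRUE)
    batch <- batch_arrays(dataset, idx, cfg$augment_data)
    zero_grads(params)
    loss_node <- ag_record({
      logits <- fwd_model(model, batch$images, st)
      ag_seg_loss(logits, batch$labels,
                  cfg$loss_weights[1], cfg$loss_weights[2])
    })
    loss <- val(loss_node)
    if (!is.finite(loss)) {
      stop("training diverged at step ", step0 + step,
           " (loss = ", loss, "); lower the learning rate")
    }
    ag_backward(loss_node)
    ag_clear()
    lr_t <- if (cfg$lr_schedule == "cosine") {
      cfg$lr * 0.5 * (1 + cos(pi * (step - 1) / cfg$steps))
    } else cfg$lr
    adamw_step(opt, params, lr_t)
    history <- rbind(history,
                     data.frame(step = step0 + step, loss = loss, lr = lr_t))
    if (verbose && (step %% 10L == 0L || step == 1L)) {
      message(sprintf("step %d  loss %.4f  lr %.2e", step0 + step, loss, lr_t))
    }
    if (!is.null(best_path) && loss < best_loss) {
      best_loss <- loss
      save_checkpoint(model, best_path)
    }
  }
  if (!is.null(last_path)) {
    save_checkpoint(model, last_path,
                    extra = list(opt_m = opt$m, opt_v = opt$v, opt_t = opt$t,
                                 step = step0 + cfg$steps,
                                 rng = get(".Random.seed",
                                           envir = globalenv())))
  }
  list(model = model, history = history, best = best_path, last = last_path)
}

#' Evaluate a model on a dataset
#'
#' Argmax over logits yields a label map per image; per-image metric
#' reports (see [evaluate_masks()]) are macro-averaged over the dataset.
#'
#' @param model a `seg_model` or a checkpoint path
#' @param dataset a `seg_dataset`
#' @param empty_value HD95 sentinel convention, see [hd95()]
#' @return list with `per_image` (list of `metric_report`), `mean_macro`
#'   (named vector) and `per_class` (data.frame of per-class means)
#' @export
evaluate_model <- function(model, dataset, empty_value = c("na", "diagonal")) {
  empty_value <- match.arg(empty_value)
  if (is.character(model)) model <- load_checkpoint(model)
  k <- attr(dataset, "n_classes")
  if (!is.null(k) && k != model$config$num_classes) {
    stop("dataset has ", k, " classes but the model predicts ",
         model$config$num_classes)
  }
  k <- model$config$num_classes
  reports <- lapply(dataset, function(smp) {
    evaluate_masks(predict_labels(model, smp$image), smp$mask, k,
                   empty_value = empty_value)
  })
  macro <- do.call(rbind, lapply(reports, function(r) r$macro))
  per_class <- Reduce(`+`, lapply(reports, function(r) {
    m <- as.matrix(r$per_class[, c("dsc", "iou", "hd95")])
    m[is.na(m)] <- 0
    m
  })) / length(reports)
  list(per_image = reports,
       mean_macro = c(dsc = mean(macro[, "dsc"]), iou = mean(macro[, "iou"]),
                      hd95 = mean(macro[, "hd95"], na.rm = TRUE)),
       per_class = data.frame(class = seq_len(k - 1L), per_class))
}
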