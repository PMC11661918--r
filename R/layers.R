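# Parameter containers and elementary layers. A "module" is a plain nested
# list of ag_param / ag_buffer objects plus bare config fields; forward
# functions take (params, input, state). `state` carries train/eval mode.

init_trunc_normal <- function(dims, sd = 0.02) {
  n <- prod(dims)
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  array(x, dims)
}

init_he <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

new_linear <- function(ci, co, init = c("trunc", "he")) {
  init <- match.arg(init)
  w <- if (init == "trunc") init_trunc_normal(c(ci, co)) else init_he(c(ci, co), ci)
  list(w = ag_param(w), b = ag_param(numeric(co)))
}

fwd_linear <- function(p, x) ag_add_bias(ag_matmul(x, p$w), p$b)

new_conv <- function(kh, kw, ci, co) {
  list(w = ag_param(init_he(c(kh, kw, ci, co), kh * kw * ci)),
       b = ag_param(numeric(co)), k = c(kh, kw))
}

new_dwconv <- function(k, cc) {
  list(w = ag_param(init_he(c(k, k, cc), k * k)),
       b = ag_param(numeric(cc)), k = k)
}

new_bn <- function(cc) {
  list(gamma = ag_param(rep(1, cc)), beta = ag_param(numeric(cc)),
       rm = ag_buffer(numeric(cc)), rv = ag_buffer(rep(1, cc)))
}

fwd_bn <- function(p, x, st) {
  ag_batchnorm(x, p$gamma, p$beta, p$rm, p$rv, train = isTRUE(st$train))
}

new_ln <- function(cc) {
  list(gamma = ag_param(rep(1, cc)), beta = ag_param(numeric(cc)))
}

fwd_ln <- function(p, x) ag_layernorm(x, p$gamma, p$beta)

# ---- parameter bookkeeping -------------------------------------------------

collect_objs <- function(x, prefix = "", cls) {
  out <- list()
  if (inherits(x, cls)) {
    out[[prefix]] <- x
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      child <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      out <- c(out, collect_objs(x[[i]], child, cls))
    }
  }
  out
}

#' Enumerate the trainable parameters of a module
#' @param module a nested parameter list (e.g. a model's `params`)
#' @return named list of `ag_param` objects
#' @keywords internal
collect_params <- function(module) collect_objs(module, cls = "ag_param")

collect_buffers <- function(module) collect_objs(module, cls = "ag_buffer")

#' Set every trainable parameter of a module to zero (in place)
#'
#' Used by the residual-contract tests: a block whose branch weights are all
#' zero must reduce to the identity (or to its shortcut branch).
#' @param module nested parameter list
#' @export
zero_params <- function(module) {
  for (p in collect_params(module)) p$v[] <- 0
  invisible(module)
}

n_params <- function(module) {
  sum(vapply(collect_params(module), function(p) length(p$v), 1))
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}
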