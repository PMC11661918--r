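# Segmentation evaluation: Dice similarity coefficient, intersection over
# union, and the 95th-percentile Hausdorff distance between segmentation
# boundaries, reported per foreground class and macro-averaged.

as_mask <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x) || is.integer(x)) return(x != 0)
  stop("mask must be logical or numeric")
}

check_same_grid <- function(x, y) {
  if (!all(dim(x) == dim(y))) {
    stop("masks must share the same grid (got ",
         paste(dim(x), collapse = "x"), " vs ", paste(dim(y), collapse = "x"), ")")
  }
}

#' Dice similarity coefficient
#'
#' `2 |X intersect Y| / (|X| + |Y|)` for two binary masks. Two empty masks
#' are in perfect agreement and score 1.
#'
#' @param x,y logical (or 0/1) matrices on the same grid
#' @return a score in [0, 1]
#' @export
dsc <- function(x, y) {
  x <- as_mask(x); y <- as_mask(y)
  check_same_grid(x, y)
  denom <- sum(x) + sum(y)
  if (denom == 0) return(1)
  2 * sum(x & y) / denom
}

#' Intersection over union (Jaccard index)
#'
#' `|X intersect Y| / |X union Y|`; two empty masks score 1.
#'
#' @param x,y logical (or 0/1) matrices on the same grid
#' @return a score in [0, 1]
#' @export
iou <- function(x, y) {
  x <- as_mask(x); y <- as_mask(y)
  check_same_grid(x, y)
  u <- sum(x | y)
  if (u == 0) return(1)
  sum(x & y) / u
}

#' Boundary pixels of a binary mask
#'
#' A mask pixel belongs to the boundary if at least one of its 4-neighbours
#' (or the image border) lies outside the mask.
#'
#' @param m logical matrix
#' @return logical matrix marking boundary pixels
#' @export
boundary_mask <- function(m) {
  m <- as_mask(m)
  d <- dim(m)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
  inner <- pad[1:d[1], 2:(d[2] + 1L)] & pad[3:(d[1] + 2L), 2:(d[2] + 1L)] &
    pad[2:(d[1] + 1L), 1:d[2]] & pad[2:(d[1] + 1L), 3:(d[2] + 2L)]
  m & !inner
}

# 1D squared Euclidean distance transform: lower envelope of the parabolas
# (q - i)^2 + f(i) over positions i with finite f (Felzenszwalb & Huttenlocher)
dt1d <- function(f) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(rep(Inf, n))
  v <- integer(length(fin))
  z <- numeric(length(fin) + 1L)
  k <- 1L; v[1L] <- fin[1L]; z[1L] <- -Inf; z[2L] <- Inf
  for (q in fin[-1L]) {
    repeat {
      p <- v[k]
      s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * q - 2 * p)
      if (s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Squared EDT to the TRUE pixels of a logical matrix
sq_edt <- function(feature) {
  d <- dim(feature)
  g <- matrix(Inf, d[1], d[2])
  g[feature] <- 0
  for (j in seq_len(d[2])) g[, j] <- dt1d(g[, j])
  for (i in seq_len(d[1])) g[i, ] <- dt1d(g[i, ])
  g
}

#' 95th-percentile Hausdorff distance between mask boundaries
#'
#' Pools the directed boundary-to-boundary Euclidean distances in both
#' directions and takes the 95th percentile with linear interpolation, an
#' outlier-robust surface error. Distances are computed with a two-pass
#' squared Euclidean distance transform. If either mask is empty the value
#' is undefined: `empty_value = "na"` returns `NA`, `"diagonal"` returns the
#' grid diagonal as a worst-case penalty.
#'
#' @param x,y logical (or 0/1) matrices on the same grid
#' @param percentile probability of the pooled-distance quantile (0.95)
#' @param spacing pixel spacing (distances are multiplied by it)
#' @param empty_value sentinel convention for an empty mask
#' @return distance in pixel units (or the sentinel)
#' @export
hd95 <- function(x, y, percentile = 0.95, spacing = 1,
                 empty_value = c("na", "diagonal")) {
  empty_value <- match.arg(empty_value)
  x <- as_mask(x); y <- as_mask(y)
  check_same_grid(x, y)
  if (sum(x) == 0 && sum(y) == 0) return(0)
  if (sum(x) == 0 || sum(y) == 0) {
    return(if (empty_value == "na") NA_real_ else
      spacing * sqrt(sum((dim(x) - 1)^2)))
  }
  bx <- boundary_mask(x)
  by <- boundary_mask(y)
  d_to_y <- sqrt(sq_edt(by))
  d_to_x <- sqrt(sq_edt(bx))
  pooled <- c(d_to_y[bx], d_to_x[by]) * spacing
  as.numeric(stats::quantile(pooled, percentile, type = 7, names = FALSE))
}

#' Per-class and macro segmentation metrics
#'
#' One-vs-rest DSC, IoU and HD95 for every foreground class (background,
#' label 0, is excluded), plus unweighted macro averages. A class absent
#' from both maps counts as perfect (DSC = IoU = 1, HD95 = 0); a class
#' present in exactly one map has undefined HD95, handled by `empty_value`.
#' `NA` HD95 values are dropped from the macro mean.
#'
#' @param pred,truth integer matrices with labels in `[0, n_classes)`
#' @param n_classes number of classes including background
#' @param empty_value HD95 sentinel convention, see [hd95()]
#' @return a `metric_report`: list with `per_class` (data.frame) and `macro`
#'   (named numeric vector)
#' @export
evaluate_masks <- function(pred, truth, n_classes,
                           empty_value = c("na", "diagonal")) {
  empty_value <- match.arg(empty_value)
  check_same_grid(pred, truth)
  if (any(pred < 0 | pred >= n_classes) || any(truth < 0 | truth >= n_classes)) {
    stop("label values must lie in [0, n_classes)")
  }
  cls <- seq_len(n_classes - 1L)
  per <- data.frame(class = cls, dsc = NA_real_, iou = NA_real_,
                    hd95 = NA_real_)
  for (i in seq_along(cls)) {
    pm <- pred == cls[i]
    tm <- truth == cls[i]
    per$dsc[i] <- dsc(pm, tm)
    per$iou[i] <- iou(pm, tm)
    per$hd95[i] <- hd95(pm, tm, empty_value = empty_value)
  }
  macro <- c(dsc = mean(per$dsc), iou = mean(per$iou),
             hd95 = if (all(is.na(per$hd95))) NA_real_ else
               mean(per$hd95, na.rm = TRUE))
  structure(list(per_class = per, macro = macro), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Segmentation metrics (per foreground class):\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("macro: DSC %.4f  IoU %.4f  HD95 %s\n",
              x$macro["dsc"], x$macro["iou"],
              ifelse(is.na(x$macro["hd95"]), "NA",
                     sprintf("%.4f", x$macro["hd95"]))))
  invisible(x)
}
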