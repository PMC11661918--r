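# Seeded synthetic segmentation fixtures and dataset I/O.
#
# The generator emulates the structure of the targeted inputs - a handful of
# organ-like elliptical regions of distinct classes on a dark background,
# with the intensity image derived deterministically from the label map plus
# Gaussian noise and replicated to three channels (the form in which
# grayscale CT/MRI slices enter the network). Masks are single-channel
# integer PNGs; volumes can be read from minimal NIfTI-1 files.

#' Fixture specification
#'
#' @param size square image extent (divisible by 32)
#' @param n_classes number of classes including background (>= 2)
#' @param n_shapes foreground ellipses per image; later shapes overwrite
#'   earlier ones, classes cycle over `1..n_classes-1`
#' @param noise_sd additive Gaussian intensity noise (image scale is [0, 1])
#' @param seed base RNG seed; together with the sample index it fully
#'   determines each sample
#' @return a `fixture_spec` object
#' @export
fixture_spec <- function(size = 64L, n_classes = 4L, n_shapes = 3L,
                         noise_sd = 0.05, seed = 42L) {
  stopifnot(size %% 32 == 0, n_classes >= 2, n_shapes >= 1, noise_sd >= 0)
  structure(list(size = as.integer(size), n_classes = as.integer(n_classes),
                 n_shapes = as.integer(n_shapes), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

label_intensity <- function(label, n_classes) (label + 0.5) / n_classes

#' Generate one synthetic image/mask pair
#'
#' Draws `n_shapes` rotated ellipses ("organs") of varying size at random
#' positions; each pixel's intensity is a fixed function of its label,
#' `(label + 0.5) / n_classes`, plus Gaussian noise, clipped to [0, 1] and
#' replicated to three identical channels. Output is a pure function of
#' `(spec$seed, index)`.
#'
#' @param spec a [fixture_spec()]
#' @param index sample index (>= 1)
#' @return list with `image` (size, size, 3) and `mask` (integer matrix with
#'   values in `[0, n_classes)`)
#' @export
generate_sample <- function(spec, index = 1L) {
  stopifnot(inherits(spec, "fixture_spec"), index >= 1)
  s <- spec$size
  sample_seed <- (spec$seed * 131071 + index * 7919) %% 2147483629L
  with_local_seed(sample_seed, {
    mask <- matrix(0L, s, s)
    gx <- matrix(rep(seq_len(s), times = s), s)   # row coordinate
    gy <- matrix(rep(seq_len(s), each = s), s)    # column coordinate
    for (k in seq_len(spec$n_shapes)) {
      cls <- ((k - 1L) %% (spec$n_classes - 1L)) + 1L
      cx <- stats::runif(1, 0.2, 0.8) * s
      cy <- stats::runif(1, 0.2, 0.8) * s
      ax <- stats::runif(1, 0.08, 0.28) * s
      ay <- stats::runif(1, 0.08, 0.28) * s
      th <- stats::runif(1, 0, pi)
      u <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
      v <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
      mask[(u / ax)^2 + (v / ay)^2 <= 1] <- cls
    }
    img <- label_intensity(mask, spec$n_classes)
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(s * s, 0, spec$noise_sd), s, s)
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = array(rep(img, 3L), c(s, s, 3L)), mask = mask)
  })
}

#' Generate an in-memory dataset of fixtures
#' @param spec a [fixture_spec()]
#' @param n number of samples
#' @return a `seg_dataset`: list of image/mask pairs with an `n_classes`
#'   attribute
#' @export
make_dataset <- function(spec, n) {
  out <- lapply(seq_len(n), function(i) generate_sample(spec, i))
  structure(out, class = "seg_dataset", n_classes = spec$n_classes)
}

# ---- PNG dataset layout ----------------------------------------------------

#' Write a fixture dataset to disk as paired PNGs
#'
#' Layout: `dir/images/sample_###.png` (8-bit RGB) and
#' `dir/masks/sample_###.png` (8-bit single-channel, pixel value = label),
#' paired by stem name. 8-bit masks cap the class count at 256.
#'
#' @param spec a [fixture_spec()]
#' @param n number of samples
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(spec, n, dir) {
  stopifnot(spec$n_classes <= 256L)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    smp <- generate_sample(spec, i)
    stem <- sprintf("sample_%03d.png", i)
    png::writePNG(smp$image, file.path(dir, "images", stem))
    png::writePNG(smp$mask / 255, file.path(dir, "masks", stem))
  }
  invisible(dir)
}

#' Read a single-channel integer label mask from PNG
#' @param path PNG file (8-bit; pixel value = label)
#' @return integer matrix
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Read an intensity image from PNG as an (H, W, 3) array in [0, 1]
#' @param path PNG file; grayscale images are replicated to three channels
#' @return numeric array (H, W, 3)
#' @export
read_image_png <- function(path) {
  im <- png::readPNG(path)
  if (length(dim(im)) == 2L) im <- array(rep(im, 3L), c(dim(im), 3L))
  if (dim(im)[3L] > 3L) im <- im[, , 1:3, drop = FALSE]
  im
}

#' Read a paired image/mask dataset from disk
#'
#' Expects the layout written by [write_dataset()]. Masks are recovered
#' exactly (8-bit integer round trip).
#'
#' @param dir dataset directory with `images/` and `masks/`
#' @param n_classes expected class count; mask values are validated
#' @return a `seg_dataset`
#' @export
read_dataset <- function(dir, n_classes) {
  imgs <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$"))
  msks <- sort(list.files(file.path(dir, "masks"), pattern = "\\.png$"))
  if (length(imgs) == 0) stop("no images found under ", dir)
  if (!identical(imgs, msks)) {
    orphan <- c(setdiff(imgs, msks), setdiff(msks, imgs))
    stop("unpaired dataset files: ", paste(orphan, collapse = ", "))
  }
  out <- lapply(imgs, function(f) {
    image <- read_image_png(file.path(dir, "images", f))
    mask <- read_mask_png(file.path(dir, "masks", f))
    if (any(mask >= n_classes)) {
      stop("mask ", f, " contains labels >= n_classes (", n_classes, ")")
    }
    list(image = image, mask = mask)
  })
  structure(out, class = "seg_dataset", n_classes = as.integer(n_classes))
}

# ---- augmentation ----------------------------------------------------------

rot90m <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1L, , drop = FALSE]
  m
}

apply_plane <- function(x, f) {
  if (is.matrix(x)) return(f(x))
  out <- NULL
  for (c_ in seq_len(dim(x)[3])) {
    p <- f(x[, , c_])
    if (is.null(out)) out <- array(0, c(dim(p), dim(x)[3]))
    out[, , c_] <- p
  }
  out
}

#' Random flip / right-angle rotation augmentation
#'
#' Applies a horizontal flip (p = 0.5), a vertical flip (p = 0.5) and a
#' rotation by a random multiple of 90 degrees - identically to image and
#' mask, so the pair stays aligned. Right-angle transforms are label-exact
#' (no interpolation). Uses the session RNG; seed for reproducibility.
#'
#' @param image numeric array (H, W, C)
#' @param mask integer matrix (H, W)
#' @return list with transformed `image` and `mask`
#' @export
augment <- function(image, mask) {
  do_h <- stats::runif(1) < 0.5
  do_v <- stats::runif(1) < 0.5
  k <- sample(0:3, 1L)
  f <- function(m) {
    if (do_h) m <- m[, ncol(m):1L, drop = FALSE]
    if (do_v) m <- m[nrow(m):1L, , drop = FALSE]
    rot90m(m, k)
  }
  list(image = apply_plane(image, f), mask = f(mask))
}

# ---- minimal NIfTI-1 I/O ---------------------------------------------------
# No NIfTI reader ships with the available R stack, so a minimal NIfTI-1
# codec is included: single-file .nii (optionally gzipped), little-endian,
# datatypes uint8/int16/int32/float32/float64, no extensions.

nifti_datatypes <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),
  `4` = list(what = "integer", size = 2L, signed = TRUE),
  `8` = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "numeric", size = 4L, signed = TRUE),
  `64` = list(what = "numeric", size = 8L, signed = TRUE)
)

#' Write a 3D array as a minimal NIfTI-1 volume
#' @param vol numeric or integer 3D array
#' @param path output path; a `.gz` suffix triggers gzip compression
#' @param datatype NIfTI datatype code: 2 (uint8), 4 (int16), 8 (int32),
#'   16 (float32) or 64 (float64)
#' @export
write_nifti <- function(vol, path, datatype = 16L) {
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  stopifnot(length(dim(vol)) == 3L)
  hdr <- raw(348)
  put <- function(x, offset, size, what = "integer") {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(offset + 1L):(offset + length(b))] <<- b
  }
  put(348L, 0L, 4L)
  dims <- c(3L, dim(vol), 1L, 1L, 1L, 1L)
  put(as.integer(dims), 40L, 2L)
  put(as.integer(datatype), 70L, 2L)
  put(as.integer(8L * dt$size), 72L, 2L)
  put(c(1, 1, 1, 1, 1, 1, 1, 1), 76L, 4L, "double")   # pixdim
  put(352, 108L, 4L, "double")                        # vox_offset
  put(1, 112L, 4L, "double")                          # scl_slope
  put(0, 116L, 4L, "double")                          # scl_inter
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)                              # no extensions
  if (dt$what == "integer") {
    writeBin(as.integer(round(as.vector(vol))), con, size = dt$size,
             endian = "little")
  } else {
    writeBin(as.double(as.vector(vol)), con, size = dt$size,
             endian = "little")
  }
  invisible(path)
}

#' Read a minimal NIfTI-1 volume
#' @param path `.nii` or `.nii.gz` file
#' @return numeric 3D array (scale slope/intercept applied)
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, raw(), n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  take <- function(offset, n, size, what = "integer", signed = TRUE) {
    readBin(hdr[(offset + 1L):(offset + n * size)], what, n = n, size = size,
            signed = signed, endian = "little")
  }
  if (take(0L, 1L, 4L) != 348L) stop(path, " is not a NIfTI-1 file")
  dims <- take(40L, 8L, 2L)
  if (dims[1] < 3L) stop("expected a 3D volume")
  datatype <- take(70L, 1L, 2L)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  vox_offset <- take(108L, 1L, 4L, "numeric")
  slope <- take(112L, 1L, 4L, "numeric")
  inter <- take(116L, 1L, 4L, "numeric")
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0L) readBin(con, raw(), n = skip)
  nvox <- prod(dims[2:4])
  data <- if (dt$size == 1L) {
    as.numeric(readBin(con, "integer", n = nvox, size = 1L, signed = FALSE))
  } else {
    as.numeric(readBin(con, dt$what, n = nvox, size = dt$size,
                       signed = dt$signed, endian = "little"))
  }
  if (length(data) < nvox) stop("truncated NIfTI data in ", path)
  if (slope != 0 && !(slope == 1 && inter == 0)) data <- data * slope + inter
  array(data, dims[2:4])
}

#' Read axial slices from a NIfTI volume/label pair
#'
#' Intensities are min-max scaled to [0, 1] over the whole volume and
#' replicated to three channels; labels are cast to integers. Slicing is
#' along the third axis.
#'
#' @param vol_path intensity volume (.nii / .nii.gz)
#' @param label_path label volume with identical dimensions
#' @return a `seg_dataset` of (image, mask) pairs, one per axial slice
#' @export
read_nifti_slices <- function(vol_path, label_path) {
  vol <- read_nifti(vol_path)
  lab <- read_nifti(label_path)
  if (!all(dim(vol) == dim(lab))) {
    stop("volume and label dimensions differ (",
         paste(dim(vol), collapse = "x"), " vs ",
         paste(dim(lab), collapse = "x"), ")")
  }
  rng <- range(vol)
  if (diff(rng) > 0) vol <- (vol - rng[1]) / diff(rng) else vol <- vol * 0
  lab_int <- round(lab)
  n_classes <- as.integer(max(lab_int)) + 1L
  out <- lapply(seq_len(dim(vol)[3]), function(k) {
    sl <- vol[, , k]
    list(image = array(rep(sl, 3L), c(dim(sl), 3L)),
         mask = matrix(as.integer(lab_int[, , k]), nrow(sl), ncol(sl)))
  })
  structure(out, class = "seg_dataset", n_classes = max(2L, n_classes))
}
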