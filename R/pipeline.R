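#' Raster image container
#'
#' A thin wrapper around a `W x H x 3` numeric array of 0--255 intensities
#' with an explicit channel-order tag. The first array dimension is x
#' (columns of the displayed image), the second y, matching the
#' convention of `EBImage`. The channel order is recorded, never assumed:
#' camera pipelines commonly hand over BGR data, and a silent channel
#' swap corrupts luminance-based thresholding.
#'
#' @param pixels numeric array, `W x H x 3`, values in 0--255.
#' @param channel_order `"RGB"` or `"BGR"`.
#' @return object of class `raster_image`.
#' @export
raster_image <- function(pixels, channel_order = c("RGB", "BGR")) {
  channel_order <- match.arg(channel_order)
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1) stop("empty image")
  structure(pixels, channel_order = channel_order, class = "raster_image")
}

#' @export
dim.raster_image <- function(x) dim(unclass(x))

img_dims <- function(img) dim(unclass(img))[1:2]

#' Read a colony image from PNG or JPEG
#'
#' @param path file path; format inferred from the extension.
#' @return a [raster_image()] in RGB order, 0--255.
#' @export
read_colony_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext))
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  raster_image(aperm(a, c(2, 1, 3)) * 255, channel_order = "RGB")
}

#' Write a raster image as PNG
#'
#' @param img a [raster_image()].
#' @param path output path.
#' @export
write_colony_image <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  a <- unclass(img)
  if (attr(img, "channel_order") == "BGR") a <- a[, , 3:1, drop = FALSE]
  png::writePNG(aperm(a, c(2, 1, 3)) / 255, path)
  invisible(path)
}

# Separable resampling weights mapping n input pixels to m output pixels.
# Downscale uses area-weighted (box) averaging; upscale bilinear with
# edge clamping. Sparse so that full-frame resampling stays cheap.
resample_weights <- function(n, m) {
  if (m == n) return(Matrix::Diagonal(n))
  if (m < n) {               # area average: output j covers [j*n/m, (j+1)*n/m)
    step <- n / m
    i <- integer(0); j <- integer(0); w <- numeric(0)
    for (jj in seq_len(m)) {
      lo <- (jj - 1) * step; hi <- jj * step
      cells <- seq(floor(lo) + 1, ceiling(hi))
      cover <- pmin(hi, cells) - pmax(lo, cells - 1)
      keep <- cover > 1e-12 & cells <= n
      i <- c(i, rep(jj, sum(keep))); j <- c(j, cells[keep])
      w <- c(w, cover[keep] / step)
    }
    Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(m, n))
  } else {                   # bilinear
    src <- (seq_len(m) - 0.5) * n / m - 0.5
    i0 <- pmin(pmax(floor(src), 0), n - 1)
    frac <- src - i0
    i1 <- pmin(i0 + 1, n - 1)
    Matrix::sparseMatrix(i = rep(seq_len(m), 2),
                         j = c(i0, i1) + 1,
                         x = c(1 - frac, frac),
                         dims = c(m, n))
  }
}

resample_matrix <- function(x, out_w, out_h) {
  Mw <- resample_weights(nrow(x), out_w)
  Mh <- resample_weights(ncol(x), out_h)
  as.matrix(Mw %*% x %*% Matrix::t(Mh))
}

#' Standardize an image to the reference resolution
#'
#' Rescales preserving aspect ratio to fit within `width x height`
#' (area-weighted resampling on downscale, bilinear on upscale, so thin
#' filaments are not aliased away), then pads symmetrically to the exact
#' target size with the agar background level (default: the median
#' intensity of the input's 1-pixel border). Anisotropic stretching is
#' never applied because it would bias the area ratio underlying the
#' f-measure. A no-op when the image already has the target size.
#'
#' @param img a [raster_image()].
#' @param width,height target resolution in pixels (default 2560 x 1920,
#'   the reference acquisition resolution).
#' @param pad_value intensity used for the padding border, or `NULL` to
#'   estimate it from the image border.
#' @return a [raster_image()] of exactly `width x height`, with a
#'   `standardize_meta` attribute recording scale, padding and pad value.
#' @export
standardize <- function(img, width = 2560, height = 1920, pad_value = NULL) {
  stopifnot(inherits(img, "raster_image"))
  d <- img_dims(img)
  if (d[1] == width && d[2] == height) {
    attr(img, "standardize_meta") <- list(scale = 1, pad = c(0, 0, 0, 0),
                                          pad_value = NA_real_)
    return(img)
  }
  s <- min(width / d[1], height / d[2])
  new_w <- max(1, round(d[1] * s)); new_h <- max(1, round(d[2] * s))
  a <- unclass(img)
  if (is.null(pad_value)) {
    border <- c(a[1, , ], a[d[1], , ], a[, 1, ], a[, d[2], ])
    pad_value <- median(border)
  }
  out <- array(pad_value, dim = c(width, height, 3))
  x0 <- floor((width - new_w) / 2); y0 <- floor((height - new_h) / 2)
  for (ch in 1:3)
    out[x0 + seq_len(new_w), y0 + seq_len(new_h), ch] <-
      resample_matrix(a[, , ch], new_w, new_h)
  res <- raster_image(pmin(pmax(out, 0), 255),
                      channel_order = attr(img, "channel_order"))
  attr(res, "standardize_meta") <- list(
    scale = s,
    pad = c(left = x0, top = y0, right = width - new_w - x0,
            bottom = height - new_h - y0),
    pad_value = pad_value)
  res
}

#' Convert a color image to grayscale luminance
#'
#' Applies the Rec. 601 luminance combination
#' `0.299 R + 0.587 G + 0.114 B`, honoring the recorded channel order.
#'
#' @param img a [raster_image()] with a known channel order.
#' @return a `gray_image`: numeric `W x H` matrix of 0--255 intensities.
#' @export
to_gray <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  ord <- attr(img, "channel_order")
  if (is.null(ord) || !ord %in% c("RGB", "BGR"))
    stop("unknown channel order; refusing to guess")
  a <- unclass(img)
  idx <- if (ord == "RGB") 1:3 else 3:1       # positions of R, G, B
  g <- 0.299 * a[, , idx[1]] + 0.587 * a[, , idx[2]] + 0.114 * a[, , idx[3]]
  structure(g, class = "gray_image")
}

# Discrete 1-D Gaussian weights of odd length k, normalized to sum 1.
gaussian_kernel_1d <- function(k, sigma) {
  half <- (k - 1) / 2
  if (sigma <= 0) {                      # delta-kernel limit: identity
    w <- numeric(k); w[half + 1] <- 1
    return(w)
  }
  w <- exp(-((-half):half)^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian smoothing with a small square kernel
#'
#' Convolves with a normalized `kernel x kernel` discrete Gaussian
#' (weights `exp(-d^2 / 2 sigma^2)`, normalized to sum 1); the border is
#' handled by edge replication so mean intensity is preserved up to
#' floating-point rounding.
#'
#' @param img a `gray_image` (or plain matrix) of 0--255 intensities.
#' @param kernel odd kernel side length, default 5.
#' @param sigma Gaussian standard deviation in pixels; `sigma <= 0`
#'   degenerates to the identity.
#' @return a `gray_image` of the same size.
#' @export
gaussian_blur <- function(img, kernel = 5, sigma = 1.1) {
  if (kernel %% 2 == 0) stop("kernel size must be odd")
  g <- unclass(img)
  w1 <- gaussian_kernel_1d(kernel, sigma)
  k2 <- outer(w1, w1)
  out <- EBImage::imageData(
    EBImage::filter2(EBImage::Image(g), k2, boundary = "replicate"))
  structure(out, class = "gray_image")
}

# Otsu threshold on the 0--255 scale (256 levels).
otsu_threshold <- function(g) {
  255 * EBImage::otsu(EBImage::Image(pmin(pmax(g, 0), 255) / 255),
                      range = c(0, 1), levels = 256)
}

#' Binarize a grayscale image
#'
#' Splits pixels into colony foreground and agar background at a manual
#' threshold, or at an automatic threshold chosen by Otsu's
#' between-class-variance criterion (the chosen value is recorded on the
#' returned mask for reproducibility). An empty or full-frame foreground
#' is treated as a segmentation failure, the programmatic analogue of
#' rejecting an unusable photograph.
#'
#' @param img a `gray_image`, 0--255.
#' @param threshold numeric in `[0, 255]`, or `"auto"` for Otsu.
#' @param polarity `"foreground-bright"` (colony brighter than agar,
#'   the default) or `"foreground-dark"`.
#' @return a `binary_mask`: logical `W x H` matrix with attributes
#'   `threshold_used` and `polarity`.
#' @export
binarize <- function(img, threshold = "auto",
                     polarity = c("foreground-bright", "foreground-dark")) {
  polarity <- match.arg(polarity)
  g <- unclass(img)
  if (identical(threshold, "auto")) {
    thr <- otsu_threshold(g)
  } else {
    thr <- as.numeric(threshold)
    if (is.na(thr) || thr < 0 || thr > 255)
      stop("threshold must be in [0, 255] or \"auto\"")
  }
  mask <- if (polarity == "foreground-bright") g > thr else g < thr
  nf <- sum(mask)
  if (nf == 0 || nf == length(mask))
    stop("segmentation failure: foreground is ",
         if (nf == 0) "empty" else "the full frame",
         " at threshold ", round(thr, 2))
  structure(mask, threshold_used = thr, polarity = polarity,
            class = "binary_mask")
}

#' Fill small enclosed voids in a binary mask
#'
#' Background components with no path to the image border (enclosed
#' voids, e.g. pockets between overlapping filaments or where filaments
#' merge into the central mass) become foreground when their area is at
#' most `max_void_px`. Border-connected background is agar and is never
#' touched. Foreground never shrinks, and the operation is idempotent.
#'
#' @param mask a `binary_mask` (or logical matrix).
#' @param max_void_px largest void area (pixels) to fill; `Inf` fills all
#'   enclosed voids.
#' @return a `binary_mask` with the same attributes.
#' @export
fill_voids <- function(mask, max_void_px = Inf) {
  m <- unclass(mask) > 0
  bg <- !m
  if (!any(bg)) return(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bg * 1)))
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  sizes <- tabulate(lab[lab > 0])
  fill <- setdiff(which(sizes <= max_void_px), border_labels)
  if (length(fill)) m[lab %in% fill] <- TRUE
  structure(m, threshold_used = attr(mask, "threshold_used"),
            polarity = attr(mask, "polarity"), class = "binary_mask")
}
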